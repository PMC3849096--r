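test_that("toy models reproduce their documented ground truth", {
  m <- make_toy_model("TOY1")
  expect_equal(solve_fba(m)$objective_value, 8, tolerance = 1e-8)
  expect_error(make_toy_model("TOY9"), "arg")
  # truth facts re-verified with the independent oracle, not trusted
  expect_equal(oracle_fba(m)$objective_value, 8, tolerance = 1e-6)
  expect_equal(oracle_fba(knockout(m, "THD"))$objective_value, 16 / 3,
               tolerance = 1e-6)
  expect_equal(oracle_fba(knockout(m, c("THD", "ZWF_alt")))$objective_value, 0,
               tolerance = 1e-6)
  sc <- oracle_screen_candidates(m, "NADPH_c", "THD")
  expect_identical(sc$candidates, "ZWF_alt")
  expect_length(oracle_support_patterns(make_toy_model("TOY1-dup")), 3)
})

test_that("generated scenarios are deterministic down to the SBML bytes", {
  a <- make_random_network(seed = 7, n_alt_producers = 3)
  b <- make_random_network(seed = 7, n_alt_producers = 3)
  fa <- withr::local_tempfile(fileext = ".xml")
  fb <- withr::local_tempfile(fileext = ".xml")
  write_sbml(a$model, fa); write_sbml(b$model, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$expression$activity, b$expression$activity)
  d <- make_random_network(seed = 8, n_alt_producers = 3)
  fd <- withr::local_tempfile(fileext = ".xml")
  write_sbml(d$model, fd)
  expect_false(identical(readLines(fa), readLines(fd)))
  # the generator never disturbs the session RNG
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_random_network(seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("scenario truth is verified by the oracles at test time", {
  for (s in c(7, 13)) {
    sc <- make_random_network(seed = s, n_alt_producers = 2, n_decoys = 1,
                              dead_end_substrate = FALSE)
    expect_equal(sc$truth$optimal_objective,
                 oracle_fba(sc$model)$objective_value, tolerance = 1e-6)
    got <- oracle_screen_candidates(sc$model, "NADPH_c", "THD")
    expect_setequal(got$candidates, sc$truth$alternative_producers)
  }
  # zero planted producers -> empty candidate set
  sc0 <- make_random_network(seed = 3, n_alt_producers = 0)
  res0 <- screen_alternative_producers(sc0$model, "NADPH_c", "THD")
  expect_equal(nrow(res0$candidates), 0)
})

test_that("zero-noise plates reproduce truth; replicates suppress false positives", {
  truth <- data.frame(substrate = paste0("X", 1:20), element_class = "C",
                      growth = rep(c(TRUE, FALSE), 10))
  pm <- make_pm_plates(truth, noise_sd = 0, n_replicates = 3, seed = 2)
  calls <- call_substrates(pm$plates)
  calls <- calls[match(truth$substrate, calls$substrate), ]
  expect_identical(calls$growth, truth$growth)
  # determinism
  pm2 <- make_pm_plates(truth, noise_sd = 0.02, n_replicates = 3, seed = 2)
  pm3 <- make_pm_plates(truth, noise_sd = 0.02, n_replicates = 3, seed = 2)
  expect_identical(pm2$plates[[2]]$wells$reading, pm3$plates[[2]]$wells$reading)

  # with noise at threshold scale, the all-replicates rule yields fewer false
  # positives than single-replicate calling (Monte Carlo, fixed seeds)
  neg <- data.frame(substrate = paste0("N", 1:40), element_class = "C",
                    growth = FALSE)
  fp3 <- fp1 <- 0L
  for (s in 1:60) {
    pmn <- make_pm_plates(neg, noise_sd = 0.05, n_replicates = 3, seed = s)
    c3 <- call_substrates(pmn$plates)
    c1 <- call_substrates(pmn$plates[1])
    fp3 <- fp3 + sum(c3$growth[c3$substrate %in% neg$substrate])
    fp1 <- fp1 + sum(c1$growth[c1$substrate %in% neg$substrate])
  }
  expect_lt(fp3, fp1)
})

test_that("scenario bundles write the four artifact kinds and re-read", {
  sc <- make_random_network(seed = 11, n_substrates = 2, n_alt_producers = 1)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_setequal(list.files(dir),
                  c("model.xml", "expr.tsv", "plates.csv", "truth.json"))
  m <- read_sbml(file.path(dir, "model.xml"))
  expect_model_equal(sc$model, m)
  p <- read_expression(file.path(dir, "expr.tsv"))
  expect_equal(p$activity, sc$expression$activity, tolerance = 1e-12)
  plates <- load_pm_data(file.path(dir, "plates.csv"))
  expect_length(plates, 3)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(tr$alternative_producers, sc$truth$alternative_producers)
})
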