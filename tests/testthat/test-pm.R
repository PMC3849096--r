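test_that("PM plates round-trip through CSV and are validated", {
  truth <- data.frame(substrate = c("S1", "S2", "U1"),
                      element_class = "C", growth = c(TRUE, FALSE, TRUE))
  pm <- make_pm_plates(truth, noise_sd = 0.01, n_replicates = 2, seed = 5)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_pm_csv(pm$plates, tf)
  plates <- load_pm_data(tf)
  expect_length(plates, 2)
  expect_identical(plates[[1]]$wells$reading, pm$plates[[1]]$wells$reading)
  expect_identical(plates[[2]]$condition, "photosynthetic")

  # missing well
  df <- utils::read.csv(tf)
  utils::write.csv(df[!(df$well == "H12" & df$replicate == 1), ], tf,
                   row.names = FALSE)
  expect_error(load_pm_data(tf), "missing well.*H12")
  # duplicate well
  utils::write.csv(rbind(df, df[df$well == "B2" & df$replicate == 1, ]), tf,
                   row.names = FALSE)
  expect_error(load_pm_data(tf), "duplicate well.*B2")
  # negative reading
  df2 <- df; df2$reading[5] <- -1
  utils::write.csv(df2, tf, row.names = FALSE)
  expect_error(load_pm_data(tf), "negative")
})

test_that("growth calling applies background correction, thresholds and the replicate rule", {
  mk <- function(cond, readings_by_rep, a1 = 0.03) {
    lapply(seq_along(readings_by_rep), function(i) {
      wells <- data.frame(well = cofactorscope:::.PM_WELLS,
                          substrate = c("negative control", "X",
                                        rep("water", 94)),
                          element_class = "C",
                          reading = c(a1, readings_by_rep[[i]], rep(a1, 94)))
      structure(list(plate_id = "P", condition = cond, replicate = i,
                     wells = wells), class = "pm_plate")
    })
  }
  # photosynthetic: 0.09 - 0.03 = 0.06 >= 0.05 -> growth
  calls <- call_substrates(mk("photosynthetic", list(0.09)))
  expect_true(calls$growth[calls$substrate == "X"])
  # aerobic: corrected 4.9 Omnilog units < 5 -> no growth
  calls2 <- call_substrates(mk("aerobic", list(4.9 + 3), a1 = 3))
  expect_false(calls2$growth[calls2$substrate == "X"])
  expect_equal(calls2$corrected_value[calls2$substrate == "X"], 4.9)
  # replicate rule: one passing and one failing replicate -> no growth
  calls3 <- call_substrates(mk("photosynthetic", list(0.10, 0.07)))
  expect_false(calls3$growth[calls3$substrate == "X"])
  expect_equal(calls3$n_replicates[calls3$substrate == "X"], 2)
  # corrected readings floor at zero
  calls4 <- call_substrates(mk("photosynthetic", list(0.01)))
  expect_equal(calls4$corrected_value[calls4$substrate == "X"], 0)
  # monotonicity: raising a reading never flips growth to no-growth
  for (r in seq(0, 0.2, by = 0.025)) {
    lo <- call_substrates(mk("photosynthetic", list(r)))
    hi <- call_substrates(mk("photosynthetic", list(r + 0.01)))
    expect_gte(hi$growth[hi$substrate == "X"], lo$growth[lo$substrate == "X"])
  }
})

test_that("the consistency cross-tab follows the 2x2 definition", {
  m <- make_toy_model("TOY1")
  calls <- data.frame(substrate = c("A", "B", "C", "D"),
                      element_class = "C", condition = "photosynthetic",
                      corrected_value = c(0.1, 0.1, 0, 0),
                      growth = c(TRUE, TRUE, FALSE, FALSE),
                      n_replicates = 3)
  # A: predicted growth (maps to EX_S); B: no exchange; C: predicted growth;
  # D: absent -> {GG, NGG, GNG, NGNG} one each
  smap <- c(A = "EX_S", B = NA, C = "EX_S", D = NA)
  rep_ <- compare_model_pm(m, list(), calls, smap)
  tab <- rep_$by_class
  expect_equal(unlist(tab[tab$element_class == "C", c("GG", "GNG", "NGG", "NGNG")]),
               c(GG = 1, GNG = 1, NGG = 1, NGNG = 1))
  expect_equal(tab$total, nrow(calls))
  expect_equal(rep_$agreement, 0.5)
  expect_error(compare_model_pm(m, list(), calls, smap[1:2]), "cover")
})

test_that("zero-noise plates close the loop at 100% agreement", {
  sc <- make_random_network(seed = 21, n_substrates = 2, n_alt_producers = 1)
  m <- sc$model
  truth <- data.frame(
    substrate = c(sc$truth$growth_substrates, sc$truth$dead_end_substrates),
    element_class = "C",
    growth = c(rep(TRUE, length(sc$truth$growth_substrates)),
               rep(FALSE, length(sc$truth$dead_end_substrates))))
  pm <- make_pm_plates(truth, noise_sd = 0, n_replicates = 3, seed = 9)
  calls <- call_substrates(pm$plates)
  smap <- stats::setNames(paste0("EX_", truth$substrate), truth$substrate)
  smap <- c(smap, water = NA, "negative control" = NA)
  rep_ <- compare_model_pm(m, list(C = "EX_S1"), calls, smap)
  expect_equal(rep_$agreement, 1)
  expect_equal(sum(rep_$by_class$total), nrow(rep_$detail))
  expect_equal(sum(unlist(rep_$by_class[, c("GG", "GNG", "NGG", "NGNG")])),
               nrow(rep_$detail))
})

test_that("NGG gap-filling finds the minimal addition set", {
  m <- make_toy_model("TOY1")
  # remove the transporter: the substrate becomes NGG
  m2 <- metabolic_model("toy_noTS", unname(m$metabolites),
                        unname(m$reactions[names(m$reactions) != "T_S"]),
                        "BIOMASS")
  calls <- data.frame(substrate = "S", element_class = "C",
                      condition = "photosynthetic", corrected_value = 0.15,
                      growth = TRUE, n_replicates = 3)
  smap <- c(S = "EX_S")
  rep_ <- compare_model_pm(m2, list(), calls, smap)
  expect_identical(rep_$detail$category, "NG-G")
  cat_ <- make_universal_catalogue(m, n_decoys = 2)   # contains U_T_S + decoys
  props <- propose_refinements(m2, rep_, cat_$reactions, list(), calls, smap,
                               extra_metabolites = cat_$metabolites)
  expect_length(props, 1)
  expect_identical(props[[1]]$action, "add-reactions")
  expect_identical(props[[1]]$reactions, "U_T_S")
  expect_true(props[[1]]$accepted)
  expect_equal(props[[1]]$new_inconsistencies, 0L)
  # matches the exhaustive minimum-cardinality oracle
  want <- oracle_min_additions(m2, cat_$reactions, cat_$metabolites,
                               "EX_S", "C", list())
  expect_identical(props[[1]]$reactions, want)

  # unfixable without the catalogue: "none found"
  props2 <- propose_refinements(m2, rep_, cat_$reactions[
    !vapply(cat_$reactions, function(r) r$id == "U_T_S", NA)],
    list(), calls, smap, extra_metabolites = cat_$metabolites)
  expect_match(props2[[1]]$action, "none found")
})

test_that("GNG removals are accepted only without side effects", {
  sc <- make_random_network(seed = 31, n_substrates = 2, n_alt_producers = 0)
  m <- sc$model
  # claim S2 does not grow although the model can use it: GNG
  calls <- data.frame(substrate = c("S1", "S2"), element_class = "C",
                      condition = "photosynthetic",
                      corrected_value = c(0.15, 0),
                      growth = c(TRUE, FALSE), n_replicates = 3)
  smap <- c(S1 = "EX_S1", S2 = "EX_S2")
  rep_ <- compare_model_pm(m, list(C = "EX_S1"), calls, smap)
  expect_setequal(rep_$detail$category, c("G-G", "G-NG"))
  props <- propose_refinements(m, rep_, list(), list(C = "EX_S1"), calls, smap)
  expect_length(props, 1)
  expect_identical(props[[1]]$type, "GNG")
  expect_identical(props[[1]]$action, "remove-transport")
  expect_identical(props[[1]]$reactions, "T_S2")
  expect_true(props[[1]]$accepted)
  expect_equal(props[[1]]$new_inconsistencies, 0L)
  # applying the removal flips the substrate without breaking the GG one
  m3 <- knockout(m, "T_S2")
  rep3 <- compare_model_pm(m3, list(C = "EX_S1"), calls, smap)
  expect_equal(rep3$agreement, 1)
})
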