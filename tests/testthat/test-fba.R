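test_that("FBA reproduces the hand-checked toy optima", {
  m <- make_toy_model("TOY1")
  f <- solve_fba(m)
  expect_identical(f$status, "optimal")
  expect_equal(f$objective_value, 8, tolerance = 1e-8)
  # steady state and bound feasibility on the returned vertex
  S <- build_stoich_matrix(m)
  expect_lt(max(abs(S %*% f$fluxes)), 1e-6)
  lbs <- vapply(m$reactions, `[[`, 0, "lower_bound")
  ubs <- vapply(m$reactions, `[[`, 0, "upper_bound")
  expect_true(all(f$fluxes >= lbs - 1e-8 & f$fluxes <= ubs + 1e-8))

  expect_equal(solve_fba(knockout(m, "THD"))$objective_value, 16 / 3,
               tolerance = 1e-8)
  expect_equal(solve_fba(knockout(m, c("THD", "ZWF_alt")))$objective_value, 0,
               tolerance = 1e-8)

  # objective clamped to zero flux: optimal with objective 0
  m0 <- knockout(m, "BIOMASS")
  f0 <- solve_fba(m0)
  expect_identical(f0$status, "optimal")
  expect_equal(f0$objective_value, 0)
})

test_that("gene knockouts propagate through GPRs", {
  m <- make_toy_model("TOY1")
  # deleting one subunit of the transhydrogenase complex disables it
  expect_equal(solve_fba(knockout(m, gene_ids = "gThA"))$objective_value,
               16 / 3, tolerance = 1e-8)
  # an isozyme pair survives single deletion
  md <- make_toy_model("TOY1-dup")
  expect_equal(solve_fba(knockout(md, gene_ids = "g1"))$objective_value,
               8, tolerance = 1e-8)
  expect_error(knockout(m, "NOPE"), "unknown reaction")
  expect_error(knockout(m, gene_ids = "gX"), "unknown gene")
})

test_that("knockouts never increase the optimum", {
  for (s in 1:6) {
    sc <- make_random_network(seed = s, n_alt_producers = s %% 3)
    wt <- solve_fba(sc$model)$objective_value
    for (rid in names(sc$model$reactions)) {
      ko <- solve_fba(knockout(sc$model, rid))
      val <- if (ko$status == "optimal") ko$objective_value else 0
      expect_lte(val, wt + 1e-8)
    }
  }
})

test_that("applying a medium resets unlisted exchanges to secretion-only", {
  m <- make_toy_model("TOY1")
  med <- medium(list(EX_S = c(-4, 100)))
  m2 <- apply_medium(m, med)
  expect_equal(m2$reactions$EX_S$lower_bound, -4)
  # original untouched (copy-on-apply)
  expect_equal(m$reactions$EX_S$lower_bound, -4)
  m3 <- apply_medium(m, medium())
  expect_equal(m3$reactions$EX_S$lower_bound, 0)
  expect_equal(solve_fba(m3)$objective_value, 0)   # no carbon in
  # free exchange copied verbatim
  m4 <- apply_medium(m, medium(list(EX_S = c(-100, 100))))
  expect_equal(m4$reactions$EX_S$lower_bound, -100)
  expect_equal(m4$reactions$EX_S$upper_bound, 100)
  expect_error(apply_medium(m, medium(list(EX_missing = c(-1, 1)))), "unknown")
})

test_that("the ATP maintenance bound is set by the medium", {
  m <- make_toy_model("TOY1")
  atpm <- reaction("ATPM", c(PRE_c = -1), lower_bound = 0, upper_bound = 100,
                   name = "ATP maintenance stand-in")
  m2 <- metabolic_model("toy_atpm", unname(m$metabolites),
                        c(unname(m$reactions), list(atpm)), "BIOMASS")
  m3 <- apply_medium(m2, medium(list(EX_S = c(-4, 100)), atpm = 8.39))
  expect_equal(m3$reactions$ATPM$lower_bound, 8.39)
  # the default maintenance demand exceeds what 4 mmol/gDW/h substrate can
  # supply in this toy: the model is infeasible, the constraint bites
  expect_identical(solve_fba(m3)$status, "infeasible")
  # at an affordable maintenance level growth pays exactly the upkeep
  m4 <- apply_medium(m2, medium(list(EX_S = c(-4, 100)), atpm = 2))
  f <- solve_fba(m4)
  expect_equal(f$fluxes[["ATPM"]], 2, tolerance = 1e-6)
  expect_lt(f$objective_value, 8)
})

test_that("FVA brackets the FBA vertex and matches the oracle on toys", {
  m <- make_toy_model("TOY1")
  fva <- run_fva(m, 1)
  f <- solve_fba(m)
  for (i in seq_len(nrow(fva))) {
    expect_lte(fva$min_flux[i], f$fluxes[[fva$reaction_id[i]]] + 1e-6)
    expect_gte(fva$max_flux[i], f$fluxes[[fva$reaction_id[i]]] - 1e-6)
  }
  # unique optimum: catabolic flux pinned at 4
  expect_equal(unlist(fva[fva$reaction_id == "R_CAT", 2:3]),
               c(min_flux = 4, max_flux = 4), tolerance = 1e-6)
  # duplicated pathway: either copy can carry 0..4
  md <- make_toy_model("TOY1-dup")
  fvad <- run_fva(md, 1)
  expect_equal(unlist(fvad[fvad$reaction_id == "R_CAT", 2:3]), c(min_flux = 0, max_flux = 4),
               tolerance = 1e-6)
  # fraction 0: the feasibility range, contained in declared bounds
  fva0 <- run_fva(m, 0)
  lbs <- vapply(m$reactions, `[[`, 0, "lower_bound")
  ubs <- vapply(m$reactions, `[[`, 0, "upper_bound")
  expect_true(all(fva0$min_flux >= lbs - 1e-6 & fva0$max_flux <= ubs + 1e-6))
  # oracle agreement at both fractions
  for (frac in c(0, 1)) {
    got <- run_fva(m, frac)
    want <- oracle_fva(m, frac)
    expect_equal(got$min_flux, want$min_flux, tolerance = 1e-6)
    expect_equal(got$max_flux, want$max_flux, tolerance = 1e-6)
  }
})

test_that("substrate growth prediction follows the uptake protocol", {
  m <- make_toy_model("TOY1")
  gc1 <- predict_substrate_growth(m, "EX_S", "C")
  expect_true(gc1$predicted_growth)
  expect_equal(gc1$growth_rate, 8, tolerance = 1e-8)

  gc2 <- predict_substrate_growth(m, "EX_unobtainium", "C")
  expect_false(gc2$predicted_growth)
  expect_identical(gc2$reason, "no transporter/exchange")

  # transport gap: uptake dead-ends without the transporter
  gc3 <- predict_substrate_growth(knockout(m, "T_S"), "EX_S", "C")
  expect_false(gc3$predicted_growth)

  # closing the default source of the tested class
  sc <- make_random_network(seed = 4, n_substrates = 2, n_alt_producers = 0)
  gc4 <- predict_substrate_growth(sc$model, "EX_S2", "C",
                                  defaults = list(C = "EX_S1"))
  expect_true(gc4$predicted_growth)
  # and the default really was closed: growth is fueled by S2 alone
  m5 <- knockout(sc$model, "T_S2")
  gc5 <- predict_substrate_growth(m5, "EX_S2", "C", defaults = list(C = "EX_S1"))
  expect_false(gc5$predicted_growth)
})

test_that("FBA matches the vertex-enumeration oracle on toy networks", {
  models <- list(make_toy_model("TOY1"), make_toy_model("TOY1-dup"),
                 make_toy_model("TOY1-H"))
  for (m in models) {
    expect_equal(solve_fba(m)$objective_value,
                 oracle_fba(m)$objective_value, tolerance = 1e-6)
  }
  for (s in 1:5) {
    sc <- make_random_network(seed = s, n_alt_producers = s %% 3,
                              n_decoys = 1, dead_end_substrate = FALSE)
    expect_equal(solve_fba(sc$model)$objective_value,
                 oracle_fba(sc$model)$objective_value, tolerance = 1e-6)
  }
})
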