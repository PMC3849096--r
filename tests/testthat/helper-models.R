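# field-by-field model comparison (stoichiometry and GPRs as maps/trees,
# ignoring storage order)
expect_model_equal <- function(m1, m2) {
  expect_setequal(names(m1$metabolites), names(m2$metabolites))
  expect_setequal(names(m1$reactions), names(m2$reactions))
  expect_identical(m1$objective_id, m2$objective_id)
  expect_setequal(m1$genes, m2$genes)
  for (id in names(m1$metabolites)) {
    a <- m1$metabolites[[id]]; b <- m2$metabolites[[id]]
    expect_identical(a$compartment, b$compartment)
    expect_identical(a$name, b$name)
    expect_identical(a$formula, b$formula)
    expect_identical(a$charge, b$charge)
  }
  for (id in names(m1$reactions)) {
    a <- m1$reactions[[id]]; b <- m2$reactions[[id]]
    s1 <- a$stoichiometry[order(names(a$stoichiometry))]
    s2 <- b$stoichiometry[order(names(b$stoichiometry))]
    expect_equal(as.numeric(s1), as.numeric(s2), info = id)
    expect_identical(names(s1), names(s2))
    expect_equal(a$lower_bound, b$lower_bound, info = id)
    expect_equal(a$upper_bound, b$upper_bound, info = id)
    expect_identical(gpr_to_string(a$gpr), gpr_to_string(b$gpr), info = id)
    expect_identical(a$category, b$category, info = id)
  }
  invisible(TRUE)
}
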