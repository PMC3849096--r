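#' Growth-call tolerance
#'
#' An FBA objective value above this counts as growth. LP solvers return
#' numerical dust, so "greater than zero" needs a tolerance in practice.
#' @export
GROWTH_TOL <- 1e-6

#' Define a growth medium
#'
#' A medium is the set of exchange-reaction bounds that represent nutrient
#' availability, plus the non-growth-associated ATP maintenance flux. By the
#' sign convention here, negative exchange flux is uptake, so a carbon source
#' supplied at 4 mmol/gDW/h has bounds `c(-4, 100)` and a freely exchanged
#' compound `c(-100, 100)`.
#'
#' @param bounds named list/vector mapping exchange reaction ids to
#'   `c(lower, upper)` bounds in mmol/gDW/h.
#' @param atpm lower bound imposed on the ATP maintenance reaction
#'   (default 8.39 mmol/gDW/h).
#' @param atpm_id id of the maintenance reaction, if the model has one.
#' @return a `medium` object.
#' @export
medium <- function(bounds = list(), atpm = 8.39, atpm_id = "ATPM") {
  bounds <- lapply(bounds, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2L || b[1] > b[2]) stop("medium bounds must be c(lower, upper)")
    b
  })
  structure(list(bounds = bounds, atpm = atpm, atpm_id = atpm_id),
            class = "medium")
}

#' Apply a medium to a model
#'
#' All exchange reactions not listed in the medium become secretion-only
#' `(0, 100)`; listed exchanges get the medium's bounds; the ATP maintenance
#' lower bound is set if the model has the maintenance reaction. The input
#' model is untouched (copy on apply).
#'
#' @param model a `metabolic_model`.
#' @param med a [medium()].
#' @return a new constrained `metabolic_model`.
#' @export
apply_medium <- function(model, med) {
  ex <- .exchange_ids(model)
  unknown <- setdiff(names(med$bounds), .rxn_ids(model))
  if (length(unknown))
    stop("medium references unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  for (id in ex) {
    b <- med$bounds[[id]]
    if (is.null(b)) b <- c(0, 100)
    model <- .set_bounds(model, id, lb = b[1], ub = b[2])
  }
  ## medium entries for non-exchange reactions (rare, e.g. light uptake
  ## pseudo-reactions) are applied verbatim
  for (id in setdiff(names(med$bounds), ex))
    model <- .set_bounds(model, id, lb = med$bounds[[id]][1],
                         ub = med$bounds[[id]][2])
  if (!is.null(med$atpm_id) && med$atpm_id %in% .rxn_ids(model))
    model <- .set_bounds(model, med$atpm_id, lb = med$atpm)
  model
}

#' Flux balance analysis
#'
#' Maximizes flux through the biomass objective subject to steady-state mass
#' balance `S v = 0` and the model's flux bounds. Returns one optimal vertex;
#' degenerate problems have many (see [enumerate_alternative_optima()]).
#'
#' @param model a `metabolic_model`.
#' @return a `flux_solution`: list with `status` ("optimal", "infeasible",
#'   "unbounded"), `objective_value`, and `fluxes` (named vector; empty
#'   unless optimal).
#' @export
solve_fba <- function(model) {
  S <- build_stoich_matrix(model)
  b <- .bounds_vec(model)
  obj <- as.numeric(.rxn_ids(model) == model$objective_id)
  r <- solve_lp(obj, Aeq = S, beq = numeric(nrow(S)), lb = b$lb, ub = b$ub,
                maximize = TRUE)
  fluxes <- if (r$status == "optimal")
    stats::setNames(r$x, .rxn_ids(model)) else stats::setNames(numeric(0), character(0))
  structure(list(status = r$status,
                 objective_value = if (r$status == "optimal") r$objval else NA_real_,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective is held at `fraction_of_optimum` times its FBA optimum
#' (default 1: the optimal face).
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum number in \[0, 1\].
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame with columns `reaction_id`, `min_flux`, `max_flux`.
#' @export
run_fva <- function(model, fraction_of_optimum = 1, reactions = .rxn_ids(model)) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  fba <- solve_fba(model)
  if (fba$status != "optimal")
    stop("FVA requires an FBA optimum (status: ", fba$status, ")")
  model2 <- .set_bounds(model, model$objective_id,
                        lb = max(fraction_of_optimum * fba$objective_value,
                                 model$reactions[[model$objective_id]]$lower_bound))
  S <- build_stoich_matrix(model2)
  b <- .bounds_vec(model2)
  ids <- .rxn_ids(model2)
  out <- lapply(reactions, function(rid) {
    obj <- as.numeric(ids == rid)
    lo <- solve_lp(obj, Aeq = S, beq = numeric(nrow(S)), lb = b$lb, ub = b$ub,
                   maximize = FALSE)
    hi <- solve_lp(obj, Aeq = S, beq = numeric(nrow(S)), lb = b$lb, ub = b$ub,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for '", rid, "' returned ", lo$status, "/", hi$status)
    data.frame(reaction_id = rid, min_flux = lo$objval, max_flux = hi$objval)
  })
  do.call(rbind, out)
}

#' Delete reactions or genes
#'
#' Reaction knockouts set bounds to `(0, 0)`. Gene knockouts disable every
#' reaction whose GPR evaluates FALSE with the deleted genes absent: an
#' `and` (complex) dies with any subunit, an `or` (isozymes) survives while
#' one remains.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids,gene_ids ids to delete (either or both).
#' @return a new `metabolic_model` with the deletions applied.
#' @export
knockout <- function(model, reaction_ids = character(0), gene_ids = character(0)) {
  unknown <- setdiff(reaction_ids, .rxn_ids(model))
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  unknown_g <- setdiff(gene_ids, model$genes)
  if (length(unknown_g)) stop("unknown gene id(s): ", paste(unknown_g, collapse = ", "))
  for (id in reaction_ids) model <- .set_bounds(model, id, lb = 0, ub = 0)
  if (length(gene_ids)) {
    for (r in model$reactions) {
      if (!is.null(r$gpr) && !gpr_eval(r$gpr, deleted = gene_ids))
        model <- .set_bounds(model, r$id, lb = 0, ub = 0)
    }
  }
  model
}

#' Predict growth on a single substrate
#'
#' Reproduces the phenotype-microarray simulation protocol: the default
#' source of the tested element class is closed, the test substrate's
#' exchange is opened at an uptake of 4 mmol/gDW/h for carbon or
#' 1 mmol/gDW/h for N/P/S sources, and FBA growth above [GROWTH_TOL] is
#' called growth. Substrates the model cannot exchange are called no-growth
#' with reason `"no transporter/exchange"`.
#'
#' @param model a `metabolic_model`, usually already medium-constrained via
#'   [apply_medium()].
#' @param substrate_exchange_id exchange reaction id of the test substrate
#'   (may be absent from the model).
#' @param element_class one of `"C"`, `"N"`, `"P"`, `"S"`.
#' @param defaults named list mapping element classes to the default-source
#'   exchange ids kept open during tests of the other classes (e.g.
#'   `list(C = "EX_succ", N = "EX_nh4")`).
#' @param uptake_rates uptake magnitudes per element class.
#' @return a `growth_call`: list with `substrate`, `element_class`,
#'   `predicted_growth`, `growth_rate`, `reason`.
#' @export
predict_substrate_growth <- function(model, substrate_exchange_id, element_class,
                                     defaults = list(),
                                     uptake_rates = c(C = 4, N = 1, P = 1, S = 1)) {
  stopifnot(element_class %in% c("C", "N", "P", "S"))
  def <- defaults[[element_class]]
  if (!is.null(def) && def %in% .rxn_ids(model) &&
      !identical(def, substrate_exchange_id))
    model <- .set_bounds(model, def, lb = 0)
  if (!substrate_exchange_id %in% .rxn_ids(model)) {
    return(structure(list(substrate = substrate_exchange_id,
                          element_class = element_class,
                          predicted_growth = FALSE, growth_rate = 0,
                          reason = "no transporter/exchange"),
                     class = "growth_call"))
  }
  rate <- uptake_rates[[element_class]]
  model <- .set_bounds(model, substrate_exchange_id, lb = -rate, ub = 100)
  fba <- solve_fba(model)
  rate_out <- if (fba$status == "optimal") fba$objective_value else 0
  structure(list(substrate = substrate_exchange_id,
                 element_class = element_class,
                 predicted_growth = rate_out > GROWTH_TOL,
                 growth_rate = rate_out,
                 reason = if (fba$status == "optimal") NA_character_ else fba$status),
            class = "growth_call")
}
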