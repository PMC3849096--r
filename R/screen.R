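## Cofactor-producer screen.
##
## The question: which reactions in a network can independently supply a
## redox cofactor (canonically NADPH) when the reference producer — the
## transhydrogenase — is unavailable? The screen (i) collects every reaction
## coupled to the cofactor, (ii) annotates each with FVA-derived
## synthesis-direction capability and single-knockout essentiality,
## (iii) closes the synthesis direction of every non-essential capable
## producer and checks growth collapses to zero, then (iv) re-opens each
## producer alone and records which restore growth.

#' Find reactions coupled to a cofactor
#'
#' Every reaction with a nonzero stoichiometric coefficient for the cofactor
#' metabolite, annotated with whether its feasibility-range flux (FVA at
#' fraction 0) can run in the cofactor-synthesis direction, and whether its
#' single knockout abolishes growth.
#'
#' @param model a `metabolic_model`, already medium-constrained.
#' @param cofactor_id metabolite id of the cofactor (e.g. `"NADPH_c"`).
#' @param counting `"either"` (default) counts reactions with the cofactor
#'   on either side; `"consumption"` counts only reactions consuming it in
#'   the forward direction (the two readings of "cofactor-requiring").
#' @param eps flux threshold for synthesis capability.
#' @return data.frame with columns `reaction_id`, `coefficient`,
#'   `synthesis_capable`, `essential`.
#' @export
find_cofactor_reactions <- function(model, cofactor_id,
                                    counting = c("either", "consumption"),
                                    eps = 1e-6) {
  counting <- match.arg(counting)
  if (!cofactor_id %in% names(model$metabolites))
    stop("unknown metabolite '", cofactor_id, "'")
  coef <- vapply(model$reactions, function(r) {
    v <- r$stoichiometry[cofactor_id]
    if (is.na(v)) 0 else unname(v)
  }, 0)
  keep <- if (counting == "either") coef != 0 else coef < 0
  ids <- .rxn_ids(model)[keep]
  if (!length(ids))
    return(data.frame(reaction_id = character(0), coefficient = numeric(0),
                      synthesis_capable = logical(0), essential = logical(0)))
  fva <- run_fva(model, fraction_of_optimum = 0, reactions = ids)
  synth <- mapply(function(rid, cf) {
    rng <- fva[fva$reaction_id == rid, ]
    ## production rate of the cofactor is cf * v; can it exceed eps?
    if (cf > 0) rng$max_flux * cf > eps else rng$min_flux * cf > eps
  }, ids, coef[keep])
  ess <- vapply(ids, function(rid) {
    ko <- solve_fba(knockout(model, reaction_ids = rid))
    ko$status != "optimal" || ko$objective_value <= GROWTH_TOL
  }, logical(1))
  data.frame(reaction_id = ids, coefficient = unname(coef[keep]),
             synthesis_capable = unname(synth), essential = unname(ess),
             row.names = NULL)
}

## close only the cofactor-synthesis direction of a reaction:
## production occurs where coefficient * v > 0
.close_synthesis <- function(model, rid, coefficient) {
  r <- model$reactions[[rid]]
  if (coefficient > 0) .set_bounds(model, rid, ub = min(r$upper_bound, 0))
  else .set_bounds(model, rid, lb = max(r$lower_bound, 0))
}

.reopen <- function(model, rid, original) {
  r <- original$reactions[[rid]]
  .set_bounds(model, rid, lb = r$lower_bound, ub = r$upper_bound)
}

#' Screen for alternative cofactor producers
#'
#' Closes the synthesis direction of every independently non-essential,
#' synthesis-capable cofactor-coupled reaction (reversible reactions are
#' bounded to their consumption side rather than deleted; set
#' `full_delete = TRUE` for sensitivity checks), verifies that growth drops
#' to zero, then re-opens the reference reaction alone and each other
#' member alone. Members that independently restore growth above
#' [GROWTH_TOL] are the candidate alternative producers.
#'
#' The biomass objective and demand pseudo-reactions are never part of the
#' knockout/candidate set: they are cofactor sinks, not producers.
#'
#' @inheritParams find_cofactor_reactions
#' @param reference_reaction_id the reference producer (must be
#'   synthesis-capable).
#' @param full_delete close both directions instead of only synthesis.
#' @return a `screen_result`: list with `cofactor_id`,
#'   `total_cofactor_reactions`, `nonessential_synthesis_capable`,
#'   `baseline_growth`, `reference_restores`, `reference_rate`,
#'   `candidates` (data.frame reaction_id, restored_rate), `table`
#'   (the [find_cofactor_reactions()] annotation).
#' @export
screen_alternative_producers <- function(model, cofactor_id,
                                         reference_reaction_id,
                                         counting = "either",
                                         full_delete = FALSE) {
  tab <- find_cofactor_reactions(model, cofactor_id, counting = counting)
  if (!reference_reaction_id %in% tab$reaction_id[tab$synthesis_capable])
    stop("reference reaction '", reference_reaction_id,
         "' is not synthesis-capable for ", cofactor_id)
  pseudo <- c(model$objective_id,
              .rxn_ids(model)[classify_reactions(model) == "demand"])
  set <- tab[tab$synthesis_capable & !tab$essential &
             !tab$reaction_id %in% pseudo, ]
  ## the reference is screened with the set even if essential on this medium
  if (!reference_reaction_id %in% set$reaction_id)
    set <- rbind(set, tab[tab$reaction_id == reference_reaction_id, ])

  closed <- model
  for (i in seq_len(nrow(set))) {
    closed <- if (full_delete)
      knockout(closed, reaction_ids = set$reaction_id[i])
    else .close_synthesis(closed, set$reaction_id[i], set$coefficient[i])
  }
  base <- solve_fba(closed)
  base_rate <- if (base$status == "optimal") base$objective_value else 0
  if (base_rate > GROWTH_TOL) {
    leaky <- run_fva(closed, fraction_of_optimum = 1)
    leaky <- leaky$reaction_id[abs(leaky$max_flux) > GROWTH_TOL |
                               abs(leaky$min_flux) > GROWTH_TOL]
    stop("screen ill-posed: growth persists (", format(base_rate, digits = 4),
         ") after closing all producers; flux-carrying reactions: ",
         paste(leaky, collapse = ", "))
  }

  restore_rate <- function(rid) {
    m <- .reopen(closed, rid, model)
    f <- solve_fba(m)
    if (f$status == "optimal") f$objective_value else 0
  }
  ref_rate <- restore_rate(reference_reaction_id)
  others <- setdiff(set$reaction_id, reference_reaction_id)
  rates <- vapply(others, restore_rate, 0)
  cand <- data.frame(reaction_id = others[rates > GROWTH_TOL],
                     restored_rate = unname(rates[rates > GROWTH_TOL]),
                     row.names = NULL)
  cand <- cand[order(cand$reaction_id), , drop = FALSE]

  structure(list(cofactor_id = cofactor_id,
                 total_cofactor_reactions = nrow(tab),
                 nonessential_synthesis_capable =
                   sum(tab$synthesis_capable & !tab$essential &
                       !tab$reaction_id %in% pseudo),
                 baseline_growth = base_rate,
                 reference_restores = ref_rate > GROWTH_TOL,
                 reference_rate = ref_rate,
                 candidates = cand,
                 table = tab),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> cofactor:", x$cofactor_id, "\n",
      " coupled reactions:", x$total_cofactor_reactions,
      " non-essential synthesis-capable:", x$nonessential_synthesis_capable, "\n",
      " baseline growth:", format(x$baseline_growth, digits = 4),
      " reference restores:", x$reference_restores,
      "(", format(x$reference_rate, digits = 6), ")\n",
      " candidates:", if (nrow(x$candidates)) paste(x$candidates$reaction_id, collapse = ", ")
                      else "(none)", "\n")
  invisible(x)
}
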