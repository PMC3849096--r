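## Alternative optimal flux distributions.
##
## FBA optima are rarely unique: the optimum is a face of the flux polytope,
## and different vertices of that face route flux through different reaction
## sets. We enumerate distinct *support patterns* (the sets of reactions
## carrying |v| > eps) on the optimal face with a MILP: binary activity
## indicators are linked to split forward/backward fluxes by big-M
## constraints, and each found pattern is excluded by an integer cut before
## re-solving. Because the face is a continuum, fewer distinct patterns than
## the requested n may exist; the remaining solutions are then padded with
## seeded random convex combinations of the found vertices so that mean/SEM
## summaries over a fixed n are well defined.

#' Enumerate alternative optimal flux distributions
#'
#' Fixes the objective at its FBA optimum, then iteratively solves MILPs
#' with per-direction binary activity indicators (activity epsilon 1e-6,
#' big-M equal to the global flux bound) and integer cuts excluding every
#' support pattern already found. Stops at `k` distinct patterns or at
#' exhaustion of the optimal face.
#'
#' @param model a `metabolic_model` with a finite FBA optimum.
#' @param k number of solutions requested (>= 1).
#' @param seed integer seed driving the convex-combination padding.
#' @param pad if TRUE (default), when fewer than `k` distinct support
#'   patterns exist the solution list is padded to length `k` with random
#'   convex combinations of the found solutions (all of which remain optimal
#'   and mass-balanced); if FALSE only the distinct solutions are returned.
#' @param eps activity threshold linking binaries to fluxes
#'   (mmol/gDW/h). The default 1e-4 is far below any meaningful flux at the
#'   +/-100 bound scale while staying well clear of the LP solver's noise
#'   floor; pushing it lower degrades the big-M link rows' conditioning.
#' @param time_limit seconds allowed per MILP cut iteration.
#' @return an `alt_optima_set`: list with `objective_value`, `solutions`
#'   (list of flux vectors), `support_patterns` (list of character vectors),
#'   `exhausted`, `status`.
#' @export
enumerate_alternative_optima <- function(model, k = 1000, seed = 1,
                                         pad = TRUE, eps = 1e-4,
                                         time_limit = 10) {
  if (k < 1) stop("k must be >= 1")
  fba <- solve_fba(model)
  if (fba$status != "optimal")
    stop("no optimum to enumerate around (FBA status: ", fba$status, ")")
  ids <- .rxn_ids(model)
  n <- length(ids)
  S <- build_stoich_matrix(model)
  b <- .bounds_vec(model)
  obj_row <- as.numeric(ids == model$objective_id)

  ## variable layout: p (forward parts), q (backward parts), yp, yq
  ## v = p - q;  p in [max(lb,0), max(ub,0)],  q in [max(-ub,0), max(-lb,0)]
  p_ub <- pmax(b$ub, 0); p_lb <- pmax(b$lb, 0)
  q_ub <- pmax(-b$lb, 0); q_lb <- pmax(-b$ub, 0)
  nv <- 4L * n
  idx_p <- seq_len(n); idx_q <- n + seq_len(n)
  idx_yp <- 2L * n + seq_len(n); idx_yq <- 3L * n + seq_len(n)
  bigM <- max(abs(c(b$lb, b$ub)), 1)

  Aeq <- matrix(0, nrow(S) + 1L, nv)
  Aeq[seq_len(nrow(S)), idx_p] <- S
  Aeq[seq_len(nrow(S)), idx_q] <- -S
  Aeq[nrow(S) + 1L, idx_p] <- obj_row
  Aeq[nrow(S) + 1L, idx_q] <- -obj_row
  beq <- c(numeric(nrow(S)), fba$objective_value)

  ## big-M links and one-direction-at-a-time
  rows <- list(); rhs <- numeric(0)
  add_row <- function(cols, vals, r) {
    e <- numeric(nv); e[cols] <- vals
    rows[[length(rows) + 1L]] <<- e; rhs[length(rhs) + 1L] <<- r
  }
  for (j in seq_len(n)) {
    if (p_ub[j] > 0) {
      add_row(c(idx_p[j], idx_yp[j]), c(1, -bigM), 0)      # p <= M yp
      add_row(c(idx_p[j], idx_yp[j]), c(-1, eps), 0)       # p >= eps yp
    }
    if (q_ub[j] > 0) {
      add_row(c(idx_q[j], idx_yq[j]), c(1, -bigM), 0)
      add_row(c(idx_q[j], idx_yq[j]), c(-1, eps), 0)
    }
    if (p_ub[j] > 0 && q_ub[j] > 0)
      add_row(c(idx_yp[j], idx_yq[j]), c(1, 1), 1)         # yp + yq <= 1
  }
  base_Aub <- do.call(rbind, rows); base_bub <- rhs

  lbv <- c(p_lb, q_lb, numeric(n), numeric(n))
  ubv <- c(p_ub, q_ub, as.numeric(p_ub > 0), as.numeric(q_ub > 0))
  binary <- c(idx_yp[p_ub > 0], idx_yq[q_ub > 0])
  ## maximize total activity: deterministic tie-break favouring rich patterns
  obj_milp <- numeric(nv); obj_milp[c(idx_yp, idx_yq)] <- 1

  patterns <- list(); solutions <- list()
  status <- "complete"; exhausted <- FALSE

  ## seed pattern: the FBA vertex itself
  v0 <- fba$fluxes
  patterns[[1]] <- ids[abs(v0) > eps]
  solutions[[1]] <- v0

  cut_row <- function(pattern) {
    e <- numeric(nv)
    in_p <- ids %in% pattern
    e[idx_yp] <- ifelse(in_p, 1, -1)
    e[idx_yq] <- ifelse(in_p, 1, -1)
    list(row = e, rhs = sum(in_p) - 1)
  }

  Aub <- base_Aub; bub <- base_bub
  cr <- cut_row(patterns[[1]])
  Aub <- rbind(Aub, cr$row); bub <- c(bub, cr$rhs)

  while (length(patterns) < k) {
    r <- solve_milp(obj_milp, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                    lb = lbv, ub = ubv, binary = binary, maximize = TRUE,
                    time_limit = time_limit)
    if (r$status == "infeasible") { exhausted <- TRUE; break }
    if (r$status != "optimal") { status <- "partial"; break }
    v_raw <- r$x[idx_p] - r$x[idx_q]
    pat <- ids[abs(v_raw) > eps / 2]
    if (any(vapply(patterns, function(p) setequal(p, pat), logical(1)))) {
      ## numerically rediscovered pattern: stop rather than loop
      status <- "partial"
      break
    }
    ## polish: re-solve a plain LP with the support fixed, for a clean
    ## representative flux vector (the MILP tableau carries eps-scale noise)
    lb2 <- b$lb; ub2 <- b$ub
    for (j in seq_len(n)) {
      if (ids[j] %in% pat) {
        if (r$x[idx_p[j]] > eps / 2) lb2[j] <- max(lb2[j], eps)
        else ub2[j] <- min(ub2[j], -eps)
      } else { lb2[j] <- 0; ub2[j] <- 0 }
    }
    pol <- solve_lp(numeric(n), Aeq = rbind(S, obj_row),
                    beq = c(numeric(nrow(S)), fba$objective_value),
                    lb = lb2, ub = ub2)
    v <- if (pol$status == "optimal") pol$x else v_raw
    v[abs(v) < eps / 2] <- 0
    patterns[[length(patterns) + 1L]] <- pat
    solutions[[length(solutions) + 1L]] <- stats::setNames(v, ids)
    cr <- cut_row(pat)
    Aub <- rbind(Aub, cr$row); bub <- c(bub, cr$rhs)
  }
  if (length(patterns) < k && !exhausted && status == "complete")
    exhausted <- TRUE

  if (pad && length(solutions) < k) {
    rng <- .seeded_rng(seed)
    base <- solutions
    while (length(solutions) < k) {
      w <- rng(length(base))
      w <- w / sum(w)
      v <- Reduce(`+`, Map(function(s, wi) s * wi, base, w))
      solutions[[length(solutions) + 1L]] <- v
    }
  }

  structure(list(objective_value = fba$objective_value,
                 solutions = solutions,
                 support_patterns = patterns,
                 exhausted = exhausted,
                 status = status),
            class = "alt_optima_set")
}

## independent uniform draws from a locally seeded RNG; never touches the
## global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(env$state)
    out <- stats::runif(n)
    env$state <- as.integer((as.double(env$state) * 69069 + 1) %% 2147483647)
    out
  }
}

#' @export
print.alt_optima_set <- function(x, ...) {
  cat("<alt_optima_set> objective:", format(x$objective_value, digits = 6),
      " distinct patterns:", length(x$support_patterns),
      " solutions:", length(x$solutions),
      " exhausted:", x$exhausted, "\n")
  invisible(x)
}

#' Estimate cofactor demand from alternative optima
#'
#' With every other cofactor-producing route closed (the caller's job, see
#' [screen_alternative_producers()]), the flux through a single reference
#' producer — canonically the transhydrogenase — equals the cell's cofactor
#' demand. Averaging that flux over alternative optimal solutions gives a
#' demand estimate that does not depend on which optimal vertex the solver
#' happens to return.
#'
#' @param model a `metabolic_model` (reference reaction still open).
#' @param reference_reaction_id the reference producer, e.g. the
#'   transhydrogenase.
#' @param k number of alternative optima to average over (default 1000).
#' @param seed integer seed for the enumeration padding.
#' @return a `demand_estimate`: list with `reaction_id`, `mean_flux`, `sem`,
#'   `n_solutions`.
#' @export
estimate_cofactor_demand <- function(model, reference_reaction_id, k = 1000,
                                     seed = 1) {
  if (!reference_reaction_id %in% .rxn_ids(model))
    stop("reference reaction '", reference_reaction_id, "' not in model")
  rr <- model$reactions[[reference_reaction_id]]
  if (rr$lower_bound == 0 && rr$upper_bound == 0)
    stop("reference reaction '", reference_reaction_id, "' is closed")
  ao <- enumerate_alternative_optima(model, k = k, seed = seed, pad = TRUE)
  if (!length(ao$solutions)) stop("no optimal solutions found")
  fl <- vapply(ao$solutions, `[[`, 0, reference_reaction_id)
  sem <- if (length(fl) > 1L) stats::sd(fl) / sqrt(length(fl)) else 0
  if (!is.finite(sem)) sem <- 0
  structure(list(reaction_id = reference_reaction_id,
                 mean_flux = mean(fl), sem = sem, n_solutions = length(fl)),
            class = "demand_estimate")
}

#' @export
print.demand_estimate <- function(x, ...) {
  cat("<demand_estimate>", x$reaction_id, ": ",
      format(x$mean_flux, digits = 6), "+/-", format(x$sem, digits = 3),
      "(SEM, n =", x$n_solutions, ")\n")
  invisible(x)
}
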