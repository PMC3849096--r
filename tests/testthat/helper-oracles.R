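# Brute-force oracles, written independently of the package's LP/MILP path:
# vertex enumeration by QR-factored basis enumeration, exhaustive subset
# search for minimal additions, and an oracle re-implementation of the
# producer screen on top of oracle FBA. Only usable at desk scale
# (<= ~12 reactions), which is the point.

# All vertices of {v : S v = 0, lb <= v <= ub}. A vertex fixes n - rank(S)
# coordinates at their bounds; the rest solve the equality system uniquely.
oracle_vertices <- function(S, lb, ub, tol = 1e-8) {
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  free <- n - r
  verts <- list()
  add_vertex <- function(v) {
    if (max(abs(S %*% v)) > 1e-6) return()
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) return()
    verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (free == 0L) {
    v <- qr.coef(qrS, numeric(nrow(S)))  # only v = 0 solves S v = 0 uniquely
    v[is.na(v)] <- 0
    add_vertex(v)
  } else {
    combos <- utils::combn(n, free, simplify = FALSE)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), free)))
    for (N in combos) {
      B <- setdiff(seq_len(n), N)
      SB <- S[, B, drop = FALSE]
      qrB <- qr(SB)
      if (qrB$rank < length(B)) next
      ## all 2^free bound assignments solved in one factorized call
      VN <- t(ifelse(grid, rep(ub[N], each = nrow(grid)),
                     rep(lb[N], each = nrow(grid))))
      RHS <- -S[, N, drop = FALSE] %*% VN
      VB <- tryCatch(qr.coef(qrB, RHS), error = function(e) NULL)
      if (is.null(VB)) next
      for (g in seq_len(ncol(VB))) {
        if (anyNA(VB[, g])) next
        v <- numeric(n)
        v[N] <- VN[, g]; v[B] <- VB[, g]
        add_vertex(v)
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(0), nrow = n))
  V <- do.call(cbind, verts)
  V[, !duplicated(round(t(V), 6)), drop = FALSE]
}

oracle_fba <- function(model) {
  S <- build_stoich_matrix(model)
  b <- list(lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
            ub = vapply(model$reactions, `[[`, 0, "upper_bound"))
  V <- oracle_vertices(S, b$lb, b$ub)
  if (ncol(V) == 0) return(list(status = "infeasible", objective_value = NA_real_, V = V))
  obj <- as.numeric(names(model$reactions) == model$objective_id)
  vals <- as.vector(crossprod(V, obj))
  list(status = "optimal", objective_value = max(vals), V = V, values = vals)
}

# min/max flux per reaction over the optimal face (fraction 1) or over the
# whole polytope (fraction 0); faces of a polytope inherit its vertices
oracle_fva <- function(model, fraction = 1, tol = 1e-6) {
  fb <- oracle_fba(model)
  stopifnot(fb$status == "optimal")
  keep <- if (fraction >= 1) fb$values >= fb$objective_value - tol else
    rep(TRUE, length(fb$values))
  V <- fb$V[, keep, drop = FALSE]
  data.frame(reaction_id = names(model$reactions),
             min_flux = apply(V, 1, min),
             max_flux = apply(V, 1, max), row.names = NULL)
}

# achievable support patterns on the optimal face. For networks whose
# internal reactions are irreversible and whose exchange fluxes keep one
# sign across the face (the generator's networks), supports of face points
# are exactly unions of face-vertex supports.
oracle_support_patterns <- function(model, eps = 1e-4, tol = 1e-6) {
  fb <- oracle_fba(model)
  stopifnot(fb$status == "optimal")
  V <- fb$V[, fb$values >= fb$objective_value - tol, drop = FALSE]
  ids <- names(model$reactions)
  supports <- lapply(seq_len(ncol(V)), function(j) ids[abs(V[, j]) > eps])
  nv <- ncol(V)
  pats <- list()
  for (mask in 1:(2^nv - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nv) - 1)) > 0)
    u <- sort(unique(unlist(supports[sel])))
    key <- paste(u, collapse = "|")
    if (is.null(pats[[key]])) {
      ## verify with an explicit strict convex combination
      w <- rep(1 / length(sel), length(sel))
      v <- as.vector(V[, sel, drop = FALSE] %*% w)
      if (setequal(ids[abs(v) > eps], u)) pats[[key]] <- u
    }
  }
  unname(pats)
}

oracle_grows <- function(model) {
  fb <- oracle_fba(model)
  fb$status == "optimal" && fb$objective_value > 1e-6
}

# screen re-implementation on oracle FBA/FVA: close synthesis directions of
# non-essential synthesis-capable cofactor reactions, re-open one at a time
oracle_screen_candidates <- function(model, cofactor_id, reference_id) {
  ids <- names(model$reactions)
  coef <- vapply(model$reactions, function(r) {
    v <- r$stoichiometry[cofactor_id]; if (is.na(v)) 0 else unname(v)
  }, 0)
  touched <- ids[coef != 0]
  fva0 <- oracle_fva(model, fraction = 0)
  synth <- vapply(touched, function(rid) {
    cf <- coef[[rid]]
    rng <- fva0[fva0$reaction_id == rid, ]
    if (cf > 0) rng$max_flux * cf > 1e-6 else rng$min_flux * cf > 1e-6
  }, logical(1))
  ess <- vapply(touched, function(rid)
    !oracle_grows(knockout(model, reaction_ids = rid)), logical(1))
  pseudo <- c(model$objective_id, ids[classify_reactions(model) == "demand"])
  set <- touched[synth & !ess & !touched %in% pseudo]
  set <- union(set, reference_id)
  closed <- model
  for (rid in set) {
    cf <- coef[[rid]]
    r <- closed$reactions[[rid]]
    closed$reactions[[rid]][[if (cf > 0) "upper_bound" else "lower_bound"]] <-
      if (cf > 0) min(r$upper_bound, 0) else max(r$lower_bound, 0)
  }
  reopen <- function(rid) {
    m2 <- closed
    m2$reactions[[rid]]$lower_bound <- model$reactions[[rid]]$lower_bound
    m2$reactions[[rid]]$upper_bound <- model$reactions[[rid]]$upper_bound
    m2
  }
  cands <- Filter(function(rid) oracle_grows(reopen(rid)),
                  setdiff(set, reference_id))
  list(baseline_grows = oracle_grows(closed),
       reference_restores = oracle_grows(reopen(reference_id)),
       candidates = sort(unlist(cands)))
}

# exhaustive minimum-cardinality addition search (refinement oracle)
oracle_min_additions <- function(model, catalogue, extra_mets, exchange_id,
                                 element_class, defaults, cap = 3) {
  cat_ids <- sort(vapply(catalogue, `[[`, "", "id"))
  catalogue <- catalogue[order(vapply(catalogue, `[[`, "", "id"))]
  for (size in 0:cap) {
    combos <- if (size == 0) list(integer(0)) else
      utils::combn(seq_along(catalogue), size, simplify = FALSE)
    for (cb in combos) {
      mets <- model$metabolites
      for (em in extra_mets) mets[[em$id]] <- em
      m2 <- tryCatch(metabolic_model(model$id, mets,
        c(unname(model$reactions), catalogue[cb]), model$objective_id),
        error = function(e) NULL)
      if (is.null(m2)) next
      gc_ <- predict_substrate_growth(m2, exchange_id, element_class,
                                      defaults = defaults)
      if (gc_$predicted_growth) return(cat_ids[cb])
    }
  }
  NULL
}
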