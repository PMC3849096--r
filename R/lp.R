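#' Solve a bounded linear program
#'
#' Two-phase primal simplex for problems of the form
#' \deqn{\max\ c^\top x \quad \mathrm{s.t.}\quad A_{eq} x = b_{eq},\;
#'       A_{ub} x \le b_{ub},\; lb \le x \le ub.}
#' This is the workhorse behind [solve_fba()], [run_fva()] and the
#' branch-and-bound MILP used for alternative-optima enumeration. The
#' implementation is a dense tableau simplex with Bland's pivoting rule
#' (anti-cycling), adequate for the desk-scale networks this package targets
#' (tens to a few hundred variables), not for genome-scale speed records.
#'
#' All variable bounds must be finite; flux-balance problems here always are
#' (the global bound convention is +/-100 mmol/gDW/h).
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param Aeq,beq equality constraints (`Aeq` is k x n), or `NULL`.
#' @param Aub,bub inequality constraints `Aub x <= bub`, or `NULL`.
#' @param lb,ub finite lower/upper bounds, length n.
#' @param maximize logical; `FALSE` minimizes.
#' @param tol numerical tolerance for pivoting and feasibility.
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "maxiter"), `x` (solution, `NULL` unless optimal) and `objval`.
#' @export
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  if (!is.null(Aeq)) {
    Aeq <- matrix(as.numeric(Aeq), ncol = n)
    beq <- as.numeric(beq)
    stopifnot(nrow(Aeq) == length(beq))
  }
  if (!is.null(Aub)) {
    Aub <- matrix(as.numeric(Aub), ncol = n)
    bub <- as.numeric(bub)
    stopifnot(nrow(Aub) == length(bub))
  }

  ## shift x = v - lb >= 0; upper bounds become rows x_j + t_j = u_j
  u <- ub - lb
  cc <- if (maximize) obj else -obj

  rows <- list(); rhs <- c(); type <- c()           # type: "eq" or "le"
  if (!is.null(Aeq)) {
    d <- beq - as.vector(Aeq %*% lb)
    for (i in seq_along(d)) { rows[[length(rows) + 1L]] <- Aeq[i, ]; rhs <- c(rhs, d[i]); type <- c(type, "eq") }
  }
  if (!is.null(Aub)) {
    d <- bub - as.vector(Aub %*% lb)
    for (i in seq_along(d)) { rows[[length(rows) + 1L]] <- Aub[i, ]; rhs <- c(rhs, d[i]); type <- c(type, "le") }
  }
  ## upper-bound rows only for variables with u > 0 (u == 0 fixes x_j = 0)
  fixed <- u <= 1e-12
  for (j in which(!fixed)) {
    e <- numeric(n); e[j] <- 1
    rows[[length(rows) + 1L]] <- e; rhs <- c(rhs, u[j]); type <- c(type, "le")
  }
  if (any(fixed)) {
    for (j in which(fixed)) {
      e <- numeric(n); e[j] <- 1
      rows[[length(rows) + 1L]] <- e; rhs <- c(rhs, 0); type <- c(type, "eq")
    }
  }
  m <- length(rows)
  A <- do.call(rbind, rows)
  b <- rhs

  ## normalize to b >= 0; "le" with negative rhs becomes ">=" (surplus)
  slack_sign <- ifelse(type == "le", 1, 0)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  slack_sign[neg & type == "le"] <- -1

  n_slack <- sum(type == "le")
  slack_col <- integer(m); slack_col[type == "le"] <- seq_len(n_slack)
  ## artificials for eq rows and surplus (>=) rows
  need_art <- type == "eq" | (type == "le" & slack_sign == -1)
  n_art <- sum(need_art)
  N <- n + n_slack + n_art

  Tm <- matrix(0, m, N)
  Tm[, seq_len(n)] <- A
  art_col <- integer(m)
  ai <- 0L
  for (i in seq_len(m)) {
    if (slack_col[i] > 0L) Tm[i, n + slack_col[i]] <- slack_sign[i]
    if (need_art[i]) { ai <- ai + 1L; art_col[i] <- n + n_slack + ai; Tm[i, art_col[i]] <- 1 }
  }
  basis <- integer(m)
  for (i in seq_len(m)) basis[i] <- if (need_art[i]) art_col[i] else n + slack_col[i]

  res <- .simplex_phases(Tm, b, basis, cc, n, n_slack, n_art, tol)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objval = NA_real_))
  x <- res$x[seq_len(n)] + lb
  x <- pmin(pmax(x, lb), ub)              # shave numerical dust off bounds
  ## guard against numerical corruption: a returned optimum must satisfy the
  ## original constraints well beyond round-off scale
  viol <- 0
  if (!is.null(Aeq) && length(beq))
    viol <- max(viol, abs(Aeq %*% x - beq))
  if (!is.null(Aub) && length(bub))
    viol <- max(viol, Aub %*% x - bub)
  if (viol > 1e-6)
    return(list(status = "numerical", x = NULL, objval = NA_real_))
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}

## Runs phase 1 (if artificials present) and phase 2 on the prepared tableau.
.simplex_phases <- function(Tm, b, basis, cc, n, n_slack, n_art, tol) {
  m <- nrow(Tm); N <- ncol(Tm)
  art_idx <- if (n_art > 0) (n + n_slack + 1L):N else integer(0)

  if (n_art > 0) {
    obj1 <- numeric(N); obj1[art_idx] <- -1          # maximize -sum(artificials)
    r <- .simplex_iterate(Tm, b, basis, obj1, tol, forbid = integer(0))
    if (r$status == "maxiter") return(list(status = "maxiter"))
    Tm <- r$Tm; b <- r$b; basis <- r$basis
    if (r$objval < -1e-7) return(list(status = "infeasible"))
    ## pivot remaining artificials (at zero) out of the basis where possible
    for (i in which(basis %in% art_idx)) {
      piv <- which(abs(Tm[i, seq_len(n + n_slack)]) > 1e-7)
      if (length(piv)) {
        r2 <- .pivot(Tm, b, basis, i, piv[1])
        Tm <- r2$Tm; b <- r2$b; basis <- r2$basis
      }
      ## else: redundant row; harmless to leave the artificial basic at 0
    }
  }

  obj2 <- c(cc, numeric(N - n))
  r <- .simplex_iterate(Tm, b, basis, obj2, tol, forbid = art_idx)
  if (r$status != "optimal") return(list(status = r$status))
  x <- numeric(N)
  x[r$basis] <- r$b
  list(status = "optimal", x = x, objval = r$objval)
}

## Primal simplex on tableau rows Tm x = b, x >= 0. Entering variable by
## Bland's rule (anti-cycling); leaving row among min-ratio candidates by
## largest pivot element (numerical stability), smallest basic index on ties.
## Pivot elements below `piv_tol` are treated as zero: pivoting on noise-level
## entries corrupts the tableau catastrophically.
.simplex_iterate <- function(Tm, b, basis, obj, tol, forbid, max_iter = 20000L,
                             piv_tol = 1e-7) {
  m <- nrow(Tm); N <- ncol(Tm)
  allowed <- setdiff(seq_len(N), forbid)
  for (it in seq_len(max_iter)) {
    ## reduced costs: obj - obj_B' B^-1 A  (tableau kept in canonical form)
    y <- obj[basis]
    red <- obj - as.vector(crossprod(Tm, y))
    red[basis] <- 0
    enter <- allowed[which(red[allowed] > piv_tol)]
    if (!length(enter)) {
      return(list(status = "optimal", Tm = Tm, b = b, basis = basis,
                  objval = sum(obj[basis] * b)))
    }
    j <- min(enter)                                   # Bland: smallest index
    col <- Tm[, j]
    pos <- which(col > piv_tol)
    if (!length(pos)) {
      if (any(col > tol)) {
        ## only noise-level positive entries: treat the column as unusable
        allowed <- setdiff(allowed, j)
        next
      }
      return(list(status = "unbounded"))
    }
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.max(col[cand])]                   # stable pivot element
    p <- .pivot(Tm, b, basis, i, j)
    Tm <- p$Tm; b <- p$b; basis <- p$basis
  }
  list(status = "maxiter")
}

.pivot <- function(Tm, b, basis, i, j) {
  piv <- Tm[i, j]
  Tm[i, ] <- Tm[i, ] / piv
  b[i] <- b[i] / piv
  other <- setdiff(seq_len(nrow(Tm)), i)
  f <- Tm[other, j]
  Tm[other, ] <- Tm[other, , drop = FALSE] - outer(f, Tm[i, ])
  b[other] <- b[other] - f * b[i]
  Tm[, j] <- 0; Tm[i, j] <- 1
  basis[i] <- j
  list(Tm = Tm, b = b, basis = basis)
}

#' Solve a small mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over a declared set of binary variables, with
#' LP relaxations solved by [solve_lp()]. Intended for the integer-cut
#' enumeration of alternative optimal flux distributions, where the binaries
#' are reaction-activity indicators; problem sizes stay small by design.
#'
#' @inheritParams solve_lp
#' @param binary integer indices of variables restricted to \{0, 1\}.
#' @param time_limit seconds; on expiry the incumbent (if any) is returned
#'   with status "timeout".
#' @return list with `status` ("optimal", "infeasible", "timeout",
#'   "unbounded"), `x`, `objval`.
#' @export
solve_milp <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                       lb, ub, binary = integer(0), maximize = TRUE,
                       tol = 1e-6, time_limit = 10) {
  t0 <- Sys.time()
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  lb[binary] <- pmax(lb[binary], 0); ub[binary] <- pmin(ub[binary], 1)
  best <- NULL; best_val <- if (maximize) -Inf else Inf
  timed_out <- FALSE
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      timed_out <- TRUE; break
    }
    node <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    rel <- solve_lp(obj, Aeq, beq, Aub, bub, node$lb, node$ub,
                    maximize = maximize)
    if (rel$status == "unbounded") return(list(status = "unbounded", x = NULL, objval = NA_real_))
    if (rel$status != "optimal") next
    if (maximize && rel$objval <= best_val + tol) next
    if (!maximize && rel$objval >= best_val - tol) next
    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (!length(binary) || all(frac < tol)) {
      if (!length(binary) || all(frac == 0)) {
        best <- rel$x; best_val <- rel$objval
        next
      }
      ## rounding may break big-M link rows: fix the binaries and re-solve
      lb_f <- node$lb; ub_f <- node$ub
      lb_f[binary] <- ub_f[binary] <- round(rel$x[binary])
      fx <- solve_lp(obj, Aeq, beq, Aub, bub, lb_f, ub_f, maximize = maximize)
      if (fx$status == "optimal") {
        if ((maximize && fx$objval > best_val) ||
            (!maximize && fx$objval < best_val)) {
          best <- fx$x; best_val <- fx$objval
        }
        ## the fixed solution may be short of the relaxation bound: keep
        ## branching unless the node is closed
        if (abs(fx$objval - rel$objval) <= tol) next
      }
      ## otherwise branch on the least-integral binary after all
    }
    jb <- binary[which.max(frac)]
    dn <- node; dn$ub[jb] <- 0
    up <- node; up$lb[jb] <- 1
    ## explore the branch nearer the relaxation value first
    if (rel$x[jb] >= 0.5) stack <- c(stack, list(dn), list(up))
    else stack <- c(stack, list(up), list(dn))
  }
  if (is.null(best)) {
    status <- if (timed_out) "timeout" else "infeasible"
    return(list(status = status, x = NULL, objval = NA_real_))
  }
  list(status = if (timed_out) "timeout" else "optimal",
       x = best, objval = best_val)
}
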