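#' Normalize raw expression values to activities
#'
#' E-flux works with relative gene activities in \[0, 1\]. The default
#' normalization divides every value by the dataset-wide maximum, so the
#' most-expressed gene defines full capacity; `"per-gene"` divides each
#' gene's value by that gene's own maximum across the columns of a matrix
#' (conditions), putting every gene on its own scale.
#'
#' @param raw named non-negative numeric vector (gene -> value), or a
#'   numeric matrix with genes as rownames and conditions as columns when
#'   `method = "per-gene"` (a `condition` column is then selected).
#' @param method `"global-max"` (default) or `"per-gene"`.
#' @param condition column to return when `raw` is a matrix.
#' @param provenance free-text tag recorded on the profile.
#' @return an `expression_profile`: list with `activity` (named numeric in
#'   \[0, 1\]) and `provenance`.
#' @export
normalize_expression <- function(raw, method = c("global-max", "per-gene"),
                                 condition = NULL, provenance = "") {
  method <- match.arg(method)
  if (is.matrix(raw)) {
    if (any(raw < 0, na.rm = TRUE)) stop("negative expression values")
    act <- switch(method,
      "global-max" = raw / max(raw, na.rm = TRUE),
      "per-gene" = raw / apply(raw, 1, function(x) max(x, na.rm = TRUE)))
    if (is.null(condition)) condition <- colnames(raw)[1]
    v <- act[, condition]
    v <- v[is.finite(v)]
    if (!length(v) || max(v) <= 0) stop("cannot normalize: no positive values")
    return(structure(list(activity = v, provenance = provenance),
                     class = "expression_profile"))
  }
  raw <- unlist(raw)
  if (is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("expression values must be named by gene id")
  if (any(raw < 0)) stop("negative expression values")
  mx <- max(raw)
  if (mx <= 0) stop("cannot normalize: all expression values are zero")
  structure(list(activity = raw / mx, provenance = provenance),
            class = "expression_profile")
}

#' Read a gene-expression table
#'
#' Two-column TSV (gene_id, value) or a wide TSV with a gene_id column plus
#' one column per condition.
#'
#' @param path TSV path; a header is expected.
#' @param condition column name for wide tables (default: the single value
#'   column).
#' @inheritParams normalize_expression
#' @return an `expression_profile`.
#' @export
read_expression <- function(path, condition = NULL,
                            method = "global-max") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column and >= 1 value column")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- genes
  if (ncol(vals) == 1L)
    normalize_expression(stats::setNames(vals[, 1], genes), method = method,
                         provenance = basename(path))
  else
    normalize_expression(vals, method = method, condition = condition,
                         provenance = basename(path))
}

#' Constrain a model with expression data (E-flux)
#'
#' Shrinks each GPR-bearing reaction's flux bounds in proportion to its gene
#' activity: upper bound `vmax_scale * a`, lower bound `-vmax_scale * a` for
#' reversible reactions and 0 otherwise, always intersected with the
#' original bounds so no interval widens. Reactions without gene association
#' keep their `(0, 100)` / `(-100, 100)` bounds; exchange and demand
#' pseudo-reactions are never expression-constrained (they have no enzymes).
#'
#' @param model a `metabolic_model`.
#' @param profile an `expression_profile` from [normalize_expression()].
#' @param vmax_scale flux scale in mmol/gDW/h mapped to activity 1
#'   (default 100, the global bound convention).
#' @return an `eflux_result`: list with `model` (constrained copy) and
#'   `activity` (named vector of the scalar applied per reaction; 1 where
#'   unconstrained).
#' @export
apply_eflux <- function(model, profile, vmax_scale = 100) {
  stopifnot(inherits(profile, "expression_profile"))
  acts <- stats::setNames(rep(1, length(model$reactions)), .rxn_ids(model))
  for (r in model$reactions) {
    if (is.null(r$gpr) || r$category %in% c("exchange", "demand")) next
    a <- gpr_activity(r$gpr, profile)
    acts[[r$id]] <- a
    reversible <- r$lower_bound < 0
    new_ub <- min(r$upper_bound, vmax_scale * a)
    new_lb <- if (reversible) max(r$lower_bound, -vmax_scale * a)
              else max(r$lower_bound, 0)
    if (new_ub < new_lb) new_ub <- new_lb      # forced flux (lb > 0) cannot close
    model <- .set_bounds(model, r$id, lb = new_lb, ub = new_ub)
  }
  structure(list(model = model, activity = acts), class = "eflux_result")
}
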