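#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers, with `and`
#' (enzyme complexes: every subunit required) and `or` (isozymes: any one
#' suffices), case-insensitive, with parentheses. The empty string means "no
#' gene association".
#'
#' @param text GPR string, e.g. `"(gA and gB) or gC"`.
#' @return a GPR tree: `NULL` for no association, a character scalar for a
#'   single gene, or `list(op = "and"|"or", args = list(...))`.
#' @examples
#' parse_gpr("(gThA and gThB) or gAlt")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokenize(text)
  st <- .gpr_parse_or(toks, 1L)
  if (st$pos <= length(toks))
    stop("malformed GPR, unexpected token '", toks[st$pos], "' in: ", text)
  st$node
}

.gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.gpr_parse_or <- function(toks, pos) {
  st <- .gpr_parse_and(toks, pos)
  args <- list(st$node); pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "or") {
    st <- .gpr_parse_and(toks, pos + 1L)
    args[[length(args) + 1L]] <- st$node; pos <- st$pos
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, pos = pos)
}

.gpr_parse_and <- function(toks, pos) {
  st <- .gpr_parse_atom(toks, pos)
  args <- list(st$node); pos <- st$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "and") {
    st <- .gpr_parse_atom(toks, pos + 1L)
    args[[length(args) + 1L]] <- st$node; pos <- st$pos
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, pos = pos)
}

.gpr_parse_atom <- function(toks, pos) {
  if (pos > length(toks)) stop("malformed GPR: unexpected end of rule")
  tk <- toks[pos]
  if (tk == "(") {
    st <- .gpr_parse_or(toks, pos + 1L)
    if (st$pos > length(toks) || toks[st$pos] != ")")
      stop("malformed GPR: unbalanced parentheses")
    return(list(node = st$node, pos = st$pos + 1L))
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("malformed GPR: unexpected '", tk, "'")
  list(node = tk, pos = pos + 1L)
}

#' Render a GPR tree back to a string
#' @param gpr a GPR tree from [parse_gpr()].
#' @return character scalar (`""` for no association).
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- gpr_to_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' Genes referenced by a GPR tree
#' @inheritParams gpr_to_string
#' @return character vector of unique gene ids (empty if no association).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR rule under gene deletions
#'
#' A reaction remains catalyzable if its GPR evaluates TRUE with the deleted
#' genes set to FALSE: `and` requires all subunits, `or` survives as long as
#' one isozyme remains. Empty GPR always evaluates TRUE (nothing to delete).
#'
#' @inheritParams gpr_to_string
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar.
#' @export
gpr_eval <- function(gpr, deleted = character(0)) {
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) return(!(gpr %in% deleted))
  vals <- vapply(gpr$args, gpr_eval, logical(1), deleted = deleted)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' Reaction activity from expression under the E-flux GPR rules
#'
#' Isozymes (`or`) take the maximum of their children's activities, enzyme
#' complexes (`and`) the minimum — the most-expressed isozyme and the
#' least-expressed subunit set the reaction's capacity. A reaction with no
#' gene association is unconstrained (activity 1).
#'
#' @inheritParams gpr_to_string
#' @param profile an `expression_profile` from [normalize_expression()], or a
#'   named numeric vector of activities in \[0, 1\].
#' @param missing value used for genes absent from the profile; the default 1
#'   leaves reactions with unmeasured genes unconstrained (a missing probe is
#'   not evidence of absence). A warning lists the missing genes.
#' @return numeric scalar in \[0, 1\].
#' @export
gpr_activity <- function(gpr, profile, missing = 1) {
  act <- if (inherits(profile, "expression_profile")) profile$activity else profile
  miss <- setdiff(gpr_genes(gpr), names(act))
  if (length(miss))
    warning("genes absent from expression profile treated as activity ",
            missing, ": ", paste(miss, collapse = ", "))
  .gpr_activity_rec(gpr, act, missing)
}

.gpr_activity_rec <- function(gpr, act, missing) {
  if (is.null(gpr)) return(1)
  if (is.character(gpr)) {
    v <- unname(act[gpr])
    return(if (is.na(v)) missing else v)
  }
  vals <- vapply(gpr$args, .gpr_activity_rec, numeric(1), act = act,
                 missing = missing)
  if (gpr$op == "and") min(vals) else max(vals)
}
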