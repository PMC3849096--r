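#' Construct a metabolite
#'
#' @param id unique metabolite identifier (compartment-suffixed by
#'   convention, e.g. `"glc_c"`).
#' @param name human-readable name.
#' @param compartment compartment code; the standard three are `"c"`
#'   (cytosol), `"p"` (periplasm) and `"e"` (extracellular).
#' @param formula optional chemical formula.
#' @param charge optional integer charge.
#' @return a `metabolite` object.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NULL,
                       charge = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = charge),
            class = "metabolite")
}

#' Construct a reaction
#'
#' Stoichiometry follows the usual sign convention: negative coefficients are
#' consumed, positive produced. Bounds are fluxes in mmol/gDW/h; a reaction
#' is reversible iff `lower_bound < 0 < upper_bound`. The GPR may be given as
#' a rule string (parsed with [parse_gpr()]) or a pre-built tree.
#'
#' @param id,name identifiers.
#' @param stoichiometry named numeric vector, names are metabolite ids.
#' @param lower_bound,upper_bound flux bounds (defaults 0, 100).
#' @param gpr GPR rule string or tree; `""`/`NULL` = no association.
#' @param category one of `"enzymatic"`, `"transport"`, `"exchange"`,
#'   `"demand"`, `"spontaneous"`, or `NA` to infer structurally when the
#'   model is assembled.
#' @return a `reaction` object.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 100,
                     name = id, gpr = NULL, category = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!length(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  if (any(stoichiometry == 0))
    stop("reaction '", id, "': zero stoichiometric coefficients not allowed")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (!is.na(category) &&
      !category %in% c("enzymatic", "transport", "exchange", "demand", "spontaneous"))
    stop("reaction '", id, "': unknown category '", category, "'")
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, category = category),
            class = "reaction")
}

#' Assemble a metabolic model
#'
#' Validates the invariants a constraint-based model needs: unique ids,
#' resolvable stoichiometry, consistent bounds, an existing objective, and a
#' gene list equal to the union of GPR leaves. Reaction categories left `NA`
#' are inferred structurally (see [classify_reactions()]).
#'
#' @param id model identifier.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the biomass (objective) reaction.
#' @param compartments named character vector of compartment names; inferred
#'   from the metabolites when `NULL`.
#' @return a validated `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective_id,
                            compartments = NULL) {
  mets <- stats::setNames(metabolites, vapply(metabolites, `[[`, "", "id"))
  rxns <- stats::setNames(reactions, vapply(reactions, `[[`, "", "id"))
  if (is.null(compartments)) {
    cps <- unique(vapply(mets, `[[`, "", "compartment"))
    compartments <- stats::setNames(cps, cps)
  }
  genes <- sort(unique(unlist(lapply(rxns, function(r) gpr_genes(r$gpr)))))
  if (is.null(genes)) genes <- character(0)
  model <- structure(list(id = id, metabolites = mets, reactions = rxns,
                          genes = genes, objective_id = objective_id,
                          compartments = compartments),
                     class = "metabolic_model")
  validate_model(model)
  model <- .infer_categories(model)
  model
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, stoichiometry resolution, bound ordering, objective
#' existence and compartment declarations; stops with an informative error on
#' the first violation.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  if (anyDuplicated(mids))
    stop("duplicate metabolite ids: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (m in model$metabolites)
    if (!m$compartment %in% names(model$compartments))
      stop("metabolite '", m$id, "': undeclared compartment '", m$compartment, "'")
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound)
      stop("reaction '", r$id, "': lower_bound > upper_bound")
    unknown <- setdiff(names(r$stoichiometry), mids)
    if (length(unknown))
      stop("reaction '", r$id, "': unknown metabolites ",
           paste(unknown, collapse = ", "))
  }
  if (!model$objective_id %in% rids)
    stop("no objective: objective_id '", model$objective_id,
         "' is not a reaction in the model")
  invisible(model)
}

.infer_categories <- function(model) {
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    if (is.na(r$category))
      model$reactions[[i]]$category <- .classify_one(model, r)
  }
  model
}

.classify_one <- function(model, r) {
  mets <- names(r$stoichiometry)
  comps <- vapply(mets, function(m) model$metabolites[[m]]$compartment, "")
  if (length(mets) == 1L) {
    if (comps == "e") return("exchange")
    return("demand")
  }
  if (length(unique(comps)) > 1L) return("transport")
  "enzymatic"
}

#' Classify reactions structurally
#'
#' Exchange reactions touch a single extracellular species (the system
#' boundary); single-metabolite sinks in internal compartments are demands;
#' reactions spanning compartments are transports; everything else is
#' enzymatic unless explicitly flagged spontaneous when the model was built.
#'
#' @param model a `metabolic_model`.
#' @return named character vector, reaction id -> category.
#' @export
classify_reactions <- function(model) {
  vapply(model$reactions, `[[`, "", "category")
}

#' Build the stoichiometric matrix S
#'
#' Rows are metabolites, columns reactions; entry (i, j) is the
#' stoichiometric coefficient of metabolite i in reaction j. Steady-state
#' mass balance is then S v = 0.
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix with metabolite/reaction dimnames.
#' @export
build_stoich_matrix <- function(model) {
  m <- length(model$metabolites); n <- length(model$reactions)
  S <- matrix(0, m, n,
              dimnames = list(names(model$metabolites), names(model$reactions)))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Model statistics
#'
#' The standard partition used to summarise genome-scale reconstructions:
#' gene, metabolite and reaction totals; enzymatic / transport / exchange /
#' demand / spontaneous categories; gene-associated versus orphan reactions;
#' reversible (lower bound < 0 < upper bound) versus irreversible.
#'
#' @param model a `metabolic_model`.
#' @return a `model_stats` object (named integer list).
#' @export
model_statistics <- function(model) {
  cats <- classify_reactions(model)
  lbs <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ubs <- vapply(model$reactions, `[[`, 0, "upper_bound")
  has_gene <- vapply(model$reactions,
                     function(r) length(gpr_genes(r$gpr)) > 0, logical(1))
  rev <- lbs < 0 & ubs > 0
  structure(list(
    genes = length(model$genes),
    metabolites = length(model$metabolites),
    reactions = length(model$reactions),
    enzymatic = sum(cats == "enzymatic"),
    transport = sum(cats == "transport"),
    exchange = sum(cats == "exchange"),
    demand = sum(cats == "demand"),
    spontaneous = sum(cats == "spontaneous"),
    gene_associated = sum(has_gene),
    no_gene_association = sum(!has_gene & cats != "spontaneous"),
    reversible = sum(rev),
    irreversible = sum(!rev)
  ), class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  df <- data.frame(category = names(unclass(x)),
                   count = unlist(unclass(x)), row.names = NULL)
  print(df, right = FALSE)
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", length(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(x$genes), "\n",
      "  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

## ---- small internal accessors used across modules ----

.rxn_ids <- function(model) names(model$reactions)

.bounds_vec <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"))
}

.set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) stop("unknown reaction '", id, "'")
  if (!is.null(lb)) model$reactions[[id]]$lower_bound <- lb
  if (!is.null(ub)) model$reactions[[id]]$upper_bound <- ub
  model
}

.exchange_ids <- function(model) {
  names(which(classify_reactions(model) == "exchange"))
}
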