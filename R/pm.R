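## Phenotype-microarray analysis: plate ingestion, growth calling,
## model-versus-plate consistency, and refinement proposals.

.PM_WELLS <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))

#' Condition-specific growth-call thresholds
#'
#' Corrected readings at or above the threshold in *every* replicate are
#' called growth. Photosynthetic and anaerobic plates are scored by optical
#' density (OD650, threshold 0.05 after background correction); aerobic
#' plates by tetrazolium-dye respiration (5 Omnilog units after background
#' correction).
#' @export
PM_THRESHOLDS <- c(photosynthetic = 0.05, aerobic = 5, anaerobic = 0.05)

#' Load phenotype-microarray readings
#'
#' CSV with columns `plate_id, condition, well, substrate, element_class,
#' replicate, reading`. Each plate x replicate must have exactly the 96
#' wells A1-H12 with the A1 negative control present and non-negative
#' readings.
#'
#' @param path CSV path.
#' @return list of `pm_plate` objects (one per plate x replicate), each a
#'   list with `plate_id`, `condition`, `replicate`, `wells` (data.frame).
#' @export
load_pm_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "condition", "well", "substrate", "element_class",
            "replicate", "reading")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("PM file missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$reading < 0)) stop("negative PM readings")
  key <- interaction(df$plate_id, df$replicate, drop = TRUE)
  plates <- lapply(split(df, key), function(g) {
    pid <- g$plate_id[1]; rep_i <- g$replicate[1]
    if (length(unique(g$condition)) != 1L)
      stop("plate ", pid, " replicate ", rep_i, ": mixed conditions")
    dup <- g$well[duplicated(g$well)]
    if (length(dup))
      stop("plate ", pid, " replicate ", rep_i, ": duplicate well(s) ",
           paste(unique(dup), collapse = ", "))
    missing_wells <- setdiff(.PM_WELLS, g$well)
    if (length(missing_wells))
      stop("plate ", pid, " replicate ", rep_i, ": missing well(s) ",
           paste(missing_wells, collapse = ", "))
    structure(list(plate_id = pid, condition = g$condition[1],
                   replicate = rep_i,
                   wells = g[match(.PM_WELLS, g$well),
                             c("well", "substrate", "element_class", "reading")]),
              class = "pm_plate")
  })
  unname(plates)
}

#' Write plates back to the PM CSV format
#' @param plates list of `pm_plate` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pm_csv <- function(plates, path) {
  rows <- lapply(plates, function(p)
    cbind(plate_id = p$plate_id, condition = p$condition,
          p$wells[, c("well", "substrate", "element_class")],
          replicate = p$replicate, reading = p$wells$reading))
  df <- do.call(rbind, rows)
  utils::write.csv(df[, c("plate_id", "condition", "well", "substrate",
                          "element_class", "replicate", "reading")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Call substrate growth from PM plates
#'
#' Per plate x replicate, the A1 negative-control reading is subtracted from
#' every well (negative corrected values floored at 0). A substrate is
#' called growth iff its corrected reading reaches the condition threshold
#' in *all* replicates — the replicate rule that suppresses one-off false
#' positives.
#'
#' @param plates list of `pm_plate` objects (may span conditions; calls are
#'   made per condition).
#' @param thresholds named threshold vector, see [PM_THRESHOLDS].
#' @return data.frame with columns `substrate`, `element_class`,
#'   `condition`, `corrected_value` (the replicate minimum — the decisive
#'   reading), `growth`, `n_replicates`.
#' @export
call_substrates <- function(plates, thresholds = PM_THRESHOLDS) {
  per_rep <- lapply(plates, function(p) {
    if (!p$condition %in% names(thresholds))
      stop("no threshold for condition '", p$condition, "'")
    a1 <- p$wells$reading[p$wells$well == "A1"]
    w <- p$wells[p$wells$well != "A1", ]
    data.frame(substrate = w$substrate, element_class = w$element_class,
               condition = p$condition,
               corrected = pmax(w$reading - a1, 0))
  })
  all_df <- do.call(rbind, per_rep)
  keys <- unique(all_df[, c("substrate", "element_class", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- all_df$substrate == k$substrate & all_df$condition == k$condition &
           all_df$element_class == k$element_class
    vals <- all_df$corrected[sel]
    thr <- thresholds[[k$condition]]
    data.frame(substrate = k$substrate, element_class = k$element_class,
               condition = k$condition, corrected_value = min(vals),
               growth = all(vals >= thr), n_replicates = length(vals))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare model predictions with PM growth calls
#'
#' Runs [predict_substrate_growth()] for every called substrate (uptake 4
#' mmol/gDW/h for carbon, 1 for N/P/S) and cross-tabulates prediction
#' against observation into the four consistency categories: GG (growth
#' predicted, growth observed), GNG, NGG, NGNG. Substrates absent from the
#' model (`NA` in the map) are predicted no-growth, so an observed-growth
#' substrate without an exchange lands in NGG — the gap-filling queue.
#'
#' @param model a `metabolic_model`, medium-constrained.
#' @param defaults default-source exchanges per element class, as in
#'   [predict_substrate_growth()].
#' @param calls data.frame from [call_substrates()].
#' @param substrate_map named character vector, substrate name ->
#'   exchange reaction id (`NA` = compound not in model). Must cover every
#'   called substrate.
#' @return a `consistency_report`: list with `detail` (per-substrate
#'   data.frame), `by_class` (counts per element class), `agreement`
#'   ((GG + NGNG) / total).
#' @export
compare_model_pm <- function(model, defaults, calls, substrate_map) {
  uncovered <- setdiff(calls$substrate, names(substrate_map))
  if (length(uncovered))
    stop("substrate_map does not cover: ", paste(uncovered, collapse = ", "))
  detail <- lapply(seq_len(nrow(calls)), function(i) {
    s <- calls[i, ]
    ex <- substrate_map[[s$substrate]]
    pred <- if (is.na(ex)) FALSE else
      predict_substrate_growth(model, ex, s$element_class,
                               defaults = defaults)$predicted_growth
    cat4 <- paste0(if (pred) "G" else "NG", "-", if (s$growth) "G" else "NG")
    data.frame(substrate = s$substrate, element_class = s$element_class,
               exchange_id = if (is.na(ex)) NA_character_ else ex,
               predicted = pred, observed = s$growth, category = cat4)
  })
  detail <- do.call(rbind, detail)
  lev <- c("G-G", "G-NG", "NG-G", "NG-NG")
  by_class <- do.call(rbind, lapply(split(detail, detail$element_class), function(g)
    data.frame(element_class = g$element_class[1],
               GG = sum(g$category == "G-G"), GNG = sum(g$category == "G-NG"),
               NGG = sum(g$category == "NG-G"), NGNG = sum(g$category == "NG-NG"),
               total = nrow(g))))
  rownames(by_class) <- NULL
  agreement <- sum(detail$category %in% c("G-G", "NG-NG")) / nrow(detail)
  structure(list(detail = detail, by_class = by_class, agreement = agreement),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  print(x$by_class)
  cat("overall agreement:", sprintf("%.1f%%", 100 * x$agreement), "\n")
  invisible(x)
}

#' Propose model refinements from PM inconsistencies
#'
#' NGG substrates (observed growth the model cannot reproduce) trigger a
#' breadth-first search over the universal reaction catalogue by increasing
#' subset cardinality (cap default 3, lexicographic tie-break): the first
#' subset whose addition lets the model grow on the substrate is proposed.
#' An exchange reaction for the substrate is auto-generated when missing
#' (it is boundary plumbing, not biology, and does not count toward the
#' cardinality). GNG substrates (predicted growth never observed) propose
#' removing the substrate's transport reaction(s); a removal is accepted
#' only when re-running the full comparison introduces no new
#' inconsistency.
#'
#' @param model a `metabolic_model`, medium-constrained.
#' @param report a `consistency_report` from [compare_model_pm()].
#' @param universal_reactions list of [reaction()] objects sharing the
#'   model's metabolite namespace (a universal catalogue); metabolites they
#'   introduce must be supplied via `extra_metabolites`.
#' @param defaults as in [compare_model_pm()].
#' @param calls,substrate_map the inputs of the comparison (needed to
#'   re-check side effects).
#' @param extra_metabolites list of [metabolite()] objects referenced by
#'   catalogue reactions but absent from the model.
#' @param cap maximum addition-set cardinality.
#' @return list of `refinement_proposal` objects: `substrate`, `type`
#'   ("NGG"/"GNG"), `action` ("add-reactions", "remove-transport",
#'   "none found"), `reactions`, `new_inconsistencies`, `accepted`.
#' @export
propose_refinements <- function(model, report, universal_reactions,
                                defaults, calls, substrate_map,
                                extra_metabolites = list(), cap = 3) {
  det <- report$detail
  proposals <- list()

  count_bad <- function(rep2) sum(rep2$detail$category %in% c("G-NG", "NG-G"))
  base_bad <- count_bad(report)

  augment <- function(m, rxns) {
    new_mets <- setdiff(unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)))),
                        names(m$metabolites))
    mets <- m$metabolites
    for (em in extra_metabolites)
      if (em$id %in% new_mets) mets[[em$id]] <- em
    still <- setdiff(new_mets, names(mets))
    if (length(still))
      stop("catalogue reactions reference unknown metabolite(s): ",
           paste(still, collapse = ", "))
    metabolic_model(id = m$id, metabolites = mets,
                    reactions = c(unname(m$reactions), rxns),
                    objective_id = m$objective_id,
                    compartments = {
                      cps <- unique(vapply(mets, `[[`, "", "compartment"))
                      stats::setNames(cps, cps)
                    })
  }

  cat_ids <- vapply(universal_reactions, `[[`, "", "id")
  ord <- order(cat_ids)
  universal_reactions <- universal_reactions[ord]
  cat_ids <- cat_ids[ord]

  for (i in which(det$category == "NG-G")) {
    s <- det[i, ]
    ex <- s$exchange_id
    found <- NULL
    for (size in 0:min(cap, length(universal_reactions))) {
      if (!is.null(found)) break
      combos <- if (size == 0) list(integer(0))
                else utils::combn(seq_along(universal_reactions), size, simplify = FALSE)
      for (cb in combos) {
        add <- universal_reactions[cb]
        m2 <- tryCatch(augment(model, add), error = function(e) NULL)
        if (is.null(m2)) next
        ex2 <- ex
        if (is.na(ex2) || !ex2 %in% .rxn_ids(m2)) {
          ## auto-generate the exchange for the substrate's extracellular
          ## species if one of the added reactions names it
          e_mets <- unlist(lapply(add, function(r) names(r$stoichiometry)))
          e_mets <- e_mets[vapply(e_mets, function(mm)
            m2$metabolites[[mm]]$compartment == "e", logical(1))]
          if (!length(e_mets)) next
          ex2 <- paste0("EX_", e_mets[1])
          if (!ex2 %in% .rxn_ids(m2))
            m2 <- augment(m2, list(reaction(ex2,
              stats::setNames(-1, e_mets[1]), lower_bound = 0,
              upper_bound = 100, category = "exchange")))
        }
        gc_ <- predict_substrate_growth(m2, ex2, s$element_class, defaults = defaults)
        if (gc_$predicted_growth) { found <- list(add = add, ids = cat_ids[cb], m2 = m2); break }
      }
    }
    if (is.null(found)) {
      proposals[[length(proposals) + 1L]] <- structure(
        list(substrate = s$substrate, type = "NGG",
             action = paste0("none found (cap ", cap, ")"),
             reactions = character(0), new_inconsistencies = NA_integer_,
             accepted = FALSE), class = "refinement_proposal")
    } else {
      mm <- substrate_map
      if (is.na(mm[[s$substrate]])) {
        exs <- setdiff(.rxn_ids(found$m2), .rxn_ids(model))
        mm[[s$substrate]] <- grep("^EX_", exs, value = TRUE)[1]
      }
      rep2 <- compare_model_pm(found$m2, defaults, calls, mm)
      proposals[[length(proposals) + 1L]] <- structure(
        list(substrate = s$substrate, type = "NGG", action = "add-reactions",
             reactions = found$ids,
             new_inconsistencies = max(count_bad(rep2) - (base_bad - 1L), 0L),
             accepted = TRUE), class = "refinement_proposal")
    }
  }

  ## GNG: remove the substrate's transporter(s) when side-effect free
  for (i in which(det$category == "G-NG")) {
    s <- det[i, ]
    ex <- s$exchange_id
    e_met <- if (!is.na(ex) && ex %in% .rxn_ids(model))
      names(model$reactions[[ex]]$stoichiometry)[1] else NA_character_
    trans <- if (!is.na(e_met))
      .rxn_ids(model)[vapply(model$reactions, function(r)
        r$category == "transport" && e_met %in% names(r$stoichiometry),
        logical(1))] else character(0)
    if (!length(trans)) {
      proposals[[length(proposals) + 1L]] <- structure(
        list(substrate = s$substrate, type = "GNG",
             action = "no transporter found", reactions = character(0),
             new_inconsistencies = NA_integer_, accepted = FALSE),
        class = "refinement_proposal")
      next
    }
    m2 <- knockout(model, reaction_ids = trans)
    rep2 <- compare_model_pm(m2, defaults, calls, substrate_map)
    new_bad <- count_bad(rep2) - (base_bad - 1L)   # this GNG itself is fixed
    ok <- new_bad <= 0
    proposals[[length(proposals) + 1L]] <- structure(
      list(substrate = s$substrate, type = "GNG", action = "remove-transport",
           reactions = trans, new_inconsistencies = max(new_bad, 0L),
           accepted = ok), class = "refinement_proposal")
  }
  proposals
}

#' @export
print.refinement_proposal <- function(x, ...) {
  cat("<refinement_proposal>", x$type, "for", x$substrate, "->", x$action,
      if (length(x$reactions)) paste0("[", paste(x$reactions, collapse = ", "), "]") else "",
      if (isTRUE(x$accepted)) "(accepted)" else "(not accepted)", "\n")
  invisible(x)
}
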