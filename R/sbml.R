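## SBML I/O. Canonical dialect: Level 3 Version 1 with the fbc-v2 package
## (flux bounds as parameters, gene product associations, objectives).
## Reading falls back to the older COBRA-style Level 2 dialect (bounds in
## kineticLaw parameters, "GENE_ASSOCIATION:" note strings).

.SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML
#'
#' Accepts SBML Level 3 with the fbc package (canonical) or Level 2 with
#' COBRA-style bounds and `GENE_ASSOCIATION` notes. The returned model is
#' fully validated; an absent fbc objective is resolved by looking for a
#' unique reaction whose id or name contains "biomass" (case-insensitive) —
#' ambiguity or absence is an error, never a guess.
#'
#' @param path path to an SBML file.
#' @return a validated [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)               # malformed XML errors name the line
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop("not an SBML document (root element <", root, ">)")
  level <- xml2::xml_attr(doc, "level")
  if (identical(level, "3")) .read_sbml_l3(doc) else .read_sbml_l2(doc)
}

.ns_map <- function(doc) {
  ns <- xml2::xml_ns(doc)
  ns
}

.find_all <- function(node, ns, name) {
  xml2::xml_find_all(node, paste0(".//d1:", name), ns)
}

.read_sbml_l3 <- function(doc) {
  ns <- .ns_map(doc)
  fbc_pref <- names(ns)[ns == .SBML_FBC_NS][1]
  has_fbc <- !is.na(fbc_pref)
  fa <- function(node, attr) {
    v <- xml2::xml_attr(node, attr)
    if (!is.na(v) || !has_fbc) return(v)
    xml2::xml_attr(node, paste0(fbc_pref, ":", attr), ns = ns)
  }
  model_node <- xml2::xml_find_first(doc, "./d1:model", ns)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  mets <- lapply(.find_all(model_node, ns, "listOfSpecies/d1:species"), function(s) {
    ch <- fa(s, "charge")
    metabolite(id = xml2::xml_attr(s, "id"),
               name = {nm <- xml2::xml_attr(s, "name"); if (is.na(nm)) xml2::xml_attr(s, "id") else nm},
               compartment = xml2::xml_attr(s, "compartment"),
               formula = {f <- fa(s, "chemicalFormula"); if (is.na(f)) NULL else f},
               charge = if (is.na(ch)) NULL else as.integer(ch))
  })

  params <- .find_all(model_node, ns, "listOfParameters/d1:parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  gp_nodes <- if (has_fbc)
    xml2::xml_find_all(model_node,
                       paste0(".//", fbc_pref, ":listOfGeneProducts/", fbc_pref, ":geneProduct"), ns)
  else list()
  gp_map <- if (length(gp_nodes)) {
    ids <- vapply(gp_nodes, function(g) fa(g, "id"), "")
    labs <- vapply(gp_nodes, function(g) {
      l <- fa(g, "label"); if (is.na(l)) fa(g, "id") else l
    }, "")
    stats::setNames(labs, ids)
  } else character(0)

  rxns <- lapply(.find_all(model_node, ns, "listOfReactions/d1:reaction"), function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    sto <- .read_stoich(rn, ns)
    lb_ref <- fa(rn, "lowerFluxBound"); ub_ref <- fa(rn, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else if (reversible) -100 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 100
    gpa <- if (has_fbc)
      xml2::xml_find_first(rn, paste0("./", fbc_pref, ":geneProductAssociation"), ns)
    else xml2::xml_missing()
    gpr <- if (inherits(gpa, "xml_missing") || is.na(xml2::xml_name(gpa))) NULL
           else .read_gpa(xml2::xml_child(gpa), gp_map, fa)
    notes <- xml2::xml_text(xml2::xml_find_first(rn, "./d1:notes", ns))
    cat_note <- if (!is.na(notes) && grepl("COFACTORSCOPE_CATEGORY:", notes))
      sub(".*COFACTORSCOPE_CATEGORY:\\s*([a-z]+).*", "\\1", notes)
    else NA_character_
    reaction(id = rid,
             name = {nm <- xml2::xml_attr(rn, "name"); if (is.na(nm)) rid else nm},
             stoichiometry = sto, lower_bound = lb, upper_bound = ub,
             gpr = gpr, category = cat_note)
  })

  obj_id <- .read_objective_l3(model_node, ns, fbc_pref, has_fbc, fa)
  if (is.na(obj_id)) obj_id <- .objective_fallback(rxns)

  comp_nodes <- .find_all(model_node, ns, "listOfCompartments/d1:compartment")
  comps <- stats::setNames(xml2::xml_attr(comp_nodes, "id"),
                           xml2::xml_attr(comp_nodes, "id"))

  metabolic_model(id = model_id, metabolites = mets, reactions = rxns,
                  objective_id = obj_id, compartments = comps)
}

.read_stoich <- function(rn, ns) {
  refs <- function(which, sign) {
    nodes <- xml2::xml_find_all(rn, paste0("./d1:", which, "/d1:speciesReference"), ns)
    if (!length(nodes)) return(numeric(0))
    st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
    st[is.na(st)] <- 1
    stats::setNames(sign * st, xml2::xml_attr(nodes, "species"))
  }
  out <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
  tapply(out, names(out), sum)[unique(names(out))]
}

.read_gpa <- function(node, gp_map, fa) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- fa(node, "geneProduct")
    lab <- gp_map[gid]
    return(if (is.na(lab)) gid else unname(lab))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm, args = lapply(kids, .read_gpa, gp_map = gp_map, fa = fa)))
  }
  stop("unsupported element <", nm, "> in gene product association")
}

.read_objective_l3 <- function(model_node, ns, fbc_pref, has_fbc, fa) {
  if (!has_fbc) return(NA_character_)
  objs <- xml2::xml_find_all(model_node,
    paste0("./", fbc_pref, ":listOfObjectives/", fbc_pref, ":objective"), ns)
  if (!length(objs)) return(NA_character_)
  flux_objs <- xml2::xml_find_all(objs[[1]],
    paste0("./", fbc_pref, ":listOfFluxObjectives/", fbc_pref, ":fluxObjective"), ns)
  if (!length(flux_objs)) return(NA_character_)
  fa(flux_objs[[1]], "reaction")
}

.objective_fallback <- function(rxns) {
  ids <- vapply(rxns, `[[`, "", "id")
  nms <- vapply(rxns, `[[`, "", "name")
  hits <- ids[grepl("biomass", ids, ignore.case = TRUE) |
              grepl("biomass", nms, ignore.case = TRUE)]
  if (length(hits) == 0L)
    stop("no objective: no fbc objective and no reaction named like 'biomass'")
  if (length(hits) > 1L)
    stop("no objective: ambiguous biomass candidates: ",
         paste(hits, collapse = ", "))
  hits
}

.read_sbml_l2 <- function(doc) {
  ns <- .ns_map(doc)
  model_node <- xml2::xml_find_first(doc, "./d1:model", ns)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  sp_nodes <- .find_all(model_node, ns, "listOfSpecies/d1:species")
  boundary <- vapply(sp_nodes, function(s)
    identical(xml2::xml_attr(s, "boundaryCondition"), "true"), logical(1))
  mets <- lapply(sp_nodes[!boundary], function(s) {
    metabolite(id = xml2::xml_attr(s, "id"),
               name = {nm <- xml2::xml_attr(s, "name"); if (is.na(nm)) xml2::xml_attr(s, "id") else nm},
               compartment = xml2::xml_attr(s, "compartment"))
  })
  boundary_ids <- vapply(sp_nodes[boundary], function(s) xml2::xml_attr(s, "id"), "")

  obj_from_coeff <- character(0)
  rxns <- lapply(.find_all(model_node, ns, "listOfReactions/d1:reaction"), function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    sto <- .read_stoich(rn, ns)
    sto <- sto[!names(sto) %in% boundary_ids]
    reversible <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    kl <- xml2::xml_find_all(rn, "./d1:kineticLaw//d1:parameter", ns)
    kv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                          xml2::xml_attr(kl, "id"))
    lb <- if ("LOWER_BOUND" %in% names(kv)) kv[["LOWER_BOUND"]] else if (reversible) -100 else 0
    ub <- if ("UPPER_BOUND" %in% names(kv)) kv[["UPPER_BOUND"]] else 100
    if (isTRUE(kv["OBJECTIVE_COEFFICIENT"] != 0))
      obj_from_coeff <<- c(obj_from_coeff, rid)
    notes <- xml2::xml_text(xml2::xml_find_first(rn, "./d1:notes", ns))
    gpr <- if (!is.na(notes) && grepl("GENE_ASSOCIATION", notes)) {
      line <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^\n]*", notes))
      parse_gpr(sub("GENE_ASSOCIATION:\\s*", "", line))
    } else NULL
    reaction(id = rid,
             name = {nm <- xml2::xml_attr(rn, "name"); if (is.na(nm)) rid else nm},
             stoichiometry = sto, lower_bound = lb, upper_bound = ub, gpr = gpr)
  })

  obj_id <- if (length(obj_from_coeff) == 1L) obj_from_coeff
            else .objective_fallback(rxns)

  comp_nodes <- .find_all(model_node, ns, "listOfCompartments/d1:compartment")
  comps <- stats::setNames(xml2::xml_attr(comp_nodes, "id"),
                           xml2::xml_attr(comp_nodes, "id"))
  metabolic_model(id = model_id, metabolites = mets, reactions = rxns,
                  objective_id = obj_id, compartments = comps)
}

#' Write a metabolic model to SBML (Level 3 + fbc)
#'
#' Emits SBML Level 3 Version 1 with the fbc-v2 package: flux bounds as
#' shared parameters, GPRs as gene product associations, the biomass
#' objective as the active maximization objective. `read_sbml(write_sbml(m))`
#' is the identity on valid models.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  gene_sid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

  ## flux-bound parameters, one per distinct value
  bvals <- sort(unique(c(vapply(model$reactions, `[[`, 0, "lower_bound"),
                         vapply(model$reactions, `[[`, 0, "upper_bound"))))
  bid <- stats::setNames(paste0("cs_bnd_", seq_along(bvals)), num(bvals))

  gpa_xml <- function(g, ind) {
    pad <- strrep(" ", ind)
    if (is.character(g))
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="', gene_sid(g), '"/>'))
    kids <- vapply(g$args, gpa_xml, "", ind = ind + 2L)
    paste0(pad, "<fbc:", g$op, ">\n", paste(kids, collapse = "\n"),
           "\n", pad, "</fbc:", g$op, ">")
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', .SBML_L3_NS, '" xmlns:fbc="', .SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="false">'),
    "    <listOfCompartments>",
    vapply(names(model$compartments), function(cp)
      paste0('      <compartment id="', esc(cp), '" name="',
             esc(model$compartments[[cp]]), '" constant="true"/>'), ""),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    vapply(model$metabolites, function(m) {
      extra <- ""
      if (!is.null(m$charge)) extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
      if (!is.null(m$formula)) extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
      paste0('      <species id="', esc(m$id), '" name="', esc(m$name),
             '" compartment="', esc(m$compartment),
             '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
             extra, "/>")
    }, ""),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    vapply(seq_along(bvals), function(i)
      paste0('      <parameter id="', bid[[i]], '" value="', num(bvals[i]),
             '" constant="true"/>'), ""),
    "    </listOfParameters>",
    "    <listOfReactions>"
  )

  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    lines <- c(lines, paste0(
      '      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', rev, '" fast="false" fbc:lowerFluxBound="',
      bid[[num(r$lower_bound)]], '" fbc:upperFluxBound="',
      bid[[num(r$upper_bound)]], '">'))
    inferred <- .classify_one(model, r)
    if (!identical(r$category, inferred))
      lines <- c(lines,
        "        <notes>",
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        paste0("            <p>COFACTORSCOPE_CATEGORY: ", r$category, "</p>"),
        "          </body>",
        "        </notes>")
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
        vapply(names(reac), function(m)
          paste0('          <speciesReference species="', esc(m),
                 '" stoichiometry="', num(-reac[[m]]), '" constant="true"/>'), ""),
        "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
        vapply(names(prod), function(m)
          paste0('          <speciesReference species="', esc(m),
                 '" stoichiometry="', num(prod[[m]]), '" constant="true"/>'), ""),
        "        </listOfProducts>")
    }
    if (!is.null(r$gpr))
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gpa_xml(r$gpr, 10L), "        </fbc:geneProductAssociation>")
    lines <- c(lines, "      </reaction>")
  }

  lines <- c(lines,
    "    </listOfReactions>",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    paste0('          <fbc:fluxObjective fbc:reaction="', esc(model$objective_id),
           '" fbc:coefficient="1"/>'),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>")
  if (length(model$genes))
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
      vapply(model$genes, function(g)
        paste0('      <fbc:geneProduct fbc:id="', gene_sid(g), '" fbc:label="',
               esc(g), '"/>'), ""),
      "    </fbc:listOfGeneProducts>")
  lines <- c(lines, "  </model>", "</sbml>")

  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
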