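## Seeded generators for toy metabolic networks, expression profiles,
## phenotype-microarray plates and a toy universal catalogue. These emulate
## the data a cofactor study consumes — a genome-scale model with a
## transhydrogenase and alternative NADPH producers, expression tables over
## its genes, Biolog-style 96-well plates — at a scale where every result
## can be checked against brute-force oracles.

## run expr with a private RNG stream; the global .Random.seed is restored
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Build a hand-checkable toy cofactor network
#'
#' `TOY1` is the minimal network with the architecture of interest: uptake
#' and transport of a substrate S, a catabolic reaction emitting NADH, a
#' transhydrogenase THD (two-subunit complex, `gThA and gThB`) converting
#' NADH to NADPH, one alternative NADPH producer ZWF_alt, a respiratory NADH
#' sink, and a biomass objective consuming precursor + NADPH. Its FBA
#' optimum at 4 mmol/gDW/h substrate uptake is 8.0; deleting THD drops it to
#' 16/3 (the ZWF_alt route); deleting both NADPH routes kills growth.
#' `TOY1-dup` adds a duplicate catabolic reaction (R_CAT2, isozyme gene
#' g1b), giving the optimal face three distinct support patterns.
#' `TOY1-H` couples the transhydrogenase and the respiratory reaction to a
#' periplasmic proton cycle, exercising multi-compartment handling.
#'
#' @param name one of `"TOY1"`, `"TOY1-dup"`, `"TOY1-H"`.
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function(name = c("TOY1", "TOY1-dup", "TOY1-H")) {
  name <- match.arg(name)
  mets <- list(
    metabolite("S_e", "substrate (extracellular)", "e"),
    metabolite("S_c", "substrate", "c"),
    metabolite("PRE_c", "biomass precursor", "c"),
    metabolite("NAD_c", "NAD+", "c"),
    metabolite("NADH_c", "NADH", "c"),
    metabolite("NADP_c", "NADP+", "c"),
    metabolite("NADPH_c", "NADPH", "c"),
    metabolite("BM_c", "biomass", "c"))
  thd_sto <- c(NADH_c = -1, NADP_c = -1, NAD_c = 1, NADPH_c = 1)
  resp_sto <- c(NADH_c = -1, NAD_c = 1)
  if (name == "TOY1-H") {
    mets <- c(mets, list(metabolite("H_c", "proton", "c"),
                         metabolite("H_p", "proton (periplasm)", "p")))
    thd_sto <- c(NADH_c = -1, NADP_c = -1, H_p = -2,
                 NAD_c = 1, NADPH_c = 1, H_c = 2)
    resp_sto <- c(NADH_c = -1, H_c = -2, NAD_c = 1, H_p = 2)
  }
  rxns <- list(
    reaction("EX_S", c(S_e = -1), lower_bound = -4, upper_bound = 100,
             name = "substrate exchange"),
    reaction("T_S", c(S_e = -1, S_c = 1), gpr = "gT",
             name = "substrate transport"),
    reaction("R_CAT", c(S_c = -1, NAD_c = -3, PRE_c = 2, NADH_c = 3),
             gpr = "g1", name = "catabolism"),
    reaction("THD", thd_sto, gpr = "gThA and gThB", name = "transhydrogenase"),
    reaction("ZWF_alt", c(S_c = -1, NADP_c = -2, PRE_c = 1, NADPH_c = 2),
             gpr = "g2", name = "alternative NADPH producer"),
    reaction("RESP", resp_sto, gpr = "g3", name = "NADH oxidation"),
    reaction("BIOMASS", c(PRE_c = -1, NADPH_c = -1, NADP_c = 1, BM_c = 1),
             name = "biomass objective"),
    reaction("DM_BM", c(BM_c = -1), name = "biomass drain"))
  if (name == "TOY1-dup")
    rxns <- append(rxns, list(
      reaction("R_CAT2", c(S_c = -1, NAD_c = -3, PRE_c = 2, NADH_c = 3),
               gpr = "g1b", name = "catabolism (duplicate)")), after = 3)
  metabolic_model(id = gsub("-", "_", name), metabolites = mets,
                  reactions = rxns, objective_id = "BIOMASS")
}

#' Generate a randomized cofactor network with planted producers
#'
#' Layered networks with the TOY1 architecture and randomized stoichiometric
#' coefficients: `n_substrates` uptake/transport/catabolism routes feeding
#' NADH and precursor, a transhydrogenase, `n_alt_producers` planted
#' alternative NADPH producers (each independently able to restore growth
#' when the transhydrogenase is closed), plus optional decoys — an
#' irreversible NADPH *consumer* and a dead-end "producer" that FVA rules
#' out — and one dead-end substrate with transport but no catabolism. The
#' generator verifies its own ground truth with FBA before returning and
#' retries with derived sub-seeds on failure.
#'
#' @param seed integer seed; the same seed reproduces the scenario exactly.
#' @param n_substrates catabolizable substrates (>= 1).
#' @param n_alt_producers planted alternative producers (>= 0).
#' @param n_decoys decoy reactions (0-2).
#' @param dead_end_substrate add a transportable but non-catabolizable
#'   substrate (tests transport gaps and NGNG calls).
#' @param max_retries bounded regeneration attempts.
#' @return a `synthetic_scenario`: list with `model`, `truth` (list:
#'   `alternative_producers`, `reference`, `growth_substrates`,
#'   `dead_end_substrates`, `optimal_objective`), `expression`
#'   (an `expression_profile`), `seed`.
#' @export
make_random_network <- function(seed, n_substrates = 1, n_alt_producers = 1,
                                n_decoys = 1, dead_end_substrate = TRUE,
                                max_retries = 5) {
  stopifnot(n_substrates >= 1, n_alt_producers >= 0, n_decoys >= 0)
  for (try_i in seq_len(max_retries)) {
    sub_seed <- (seed + 7919L * (try_i - 1L)) %% .Machine$integer.max
    sc <- .with_seed(sub_seed, .build_random_network(
      seed, n_substrates, n_alt_producers, n_decoys, dead_end_substrate))
    if (.verify_scenario(sc)) return(sc)
  }
  stop("random network failed self-verification after ", max_retries, " attempts")
}

.build_random_network <- function(seed, n_substrates, n_alt_producers,
                                  n_decoys, dead_end_substrate) {
  mets <- list(
    metabolite("PRE_c", "biomass precursor", "c"),
    metabolite("NAD_c", "NAD+", "c"),
    metabolite("NADH_c", "NADH", "c"),
    metabolite("NADP_c", "NADP+", "c"),
    metabolite("NADPH_c", "NADPH", "c"),
    metabolite("BM_c", "biomass", "c"))
  rxns <- list(
    reaction("THD", c(NADH_c = -1, NADP_c = -1, NAD_c = 1, NADPH_c = 1),
             gpr = "gThA and gThB", name = "transhydrogenase"),
    reaction("RESP", c(NADH_c = -1, NAD_c = 1), gpr = "gResp"),
    reaction("BIOMASS", c(PRE_c = -1, NADPH_c = -1, NADP_c = 1, BM_c = 1)),
    reaction("DM_BM", c(BM_c = -1)))
  subs <- character(0)
  for (i in seq_len(n_substrates)) {
    sid <- paste0("S", i)
    subs <- c(subs, sid)
    ## NADH yield a must cover the NADPH demand of the p precursors, or the
    ## transhydrogenase route cannot run for this substrate
    a <- sample(1:3, 1); p <- sample(seq_len(min(a, 2)), 1)
    mets <- c(mets, list(metabolite(paste0(sid, "_e"), compartment = "e"),
                         metabolite(paste0(sid, "_c"), compartment = "c")))
    sto <- stats::setNames(c(-1, -a, p, a),
                           c(paste0(sid, "_c"), "NAD_c", "PRE_c", "NADH_c"))
    rxns <- c(rxns, list(
      reaction(paste0("EX_", sid), stats::setNames(-1, paste0(sid, "_e")),
               lower_bound = if (i == 1) -4 else 0),
      reaction(paste0("T_", sid),
               stats::setNames(c(-1, 1), paste0(sid, c("_e", "_c"))),
               gpr = paste0("gT", i)),
      reaction(paste0("CAT_", sid), sto, gpr = paste0("gC", i))))
  }
  alt_ids <- character(0)
  for (j in seq_len(n_alt_producers)) {
    aid <- paste0("ALT_", j)
    alt_ids <- c(alt_ids, aid)
    cc <- sample(1:2, 1)
    rxns <- c(rxns, list(reaction(aid,
      stats::setNames(c(-1, -cc, 1, cc), c("S1_c", "NADP_c", "PRE_c", "NADPH_c")),
      gpr = paste0("gA", j))))
  }
  if (n_decoys >= 1)               # irreversible NADPH consumer
    rxns <- c(rxns, list(reaction("DEC_use",
      c(PRE_c = -1, NADPH_c = -1, NADP_c = 1), gpr = "gDec1")))
  if (n_decoys >= 2) {             # dead-end "producer": FVA-incapable
    mets <- c(mets, list(metabolite("DEADP_c", "dead-end product", "c")))
    rxns <- c(rxns, list(reaction("DEC_dead",
      c(S1_c = -1, NADP_c = -1, DEADP_c = 1, NADPH_c = 1), gpr = "gDec2")))
  }
  dead_subs <- character(0)
  if (dead_end_substrate) {
    mets <- c(mets, list(metabolite("U1_e", compartment = "e"),
                         metabolite("U1_c", compartment = "c")))
    rxns <- c(rxns, list(
      reaction("EX_U1", c(U1_e = -1), lower_bound = 0),
      reaction("T_U1", c(U1_e = -1, U1_c = 1), gpr = "gTU")))
    dead_subs <- "U1"
  }
  model <- metabolic_model(id = sprintf("synthnet_seed%d", seed),
                           metabolites = mets, reactions = rxns,
                           objective_id = "BIOMASS")
  fba <- solve_fba(model)
  genes <- model$genes
  raw <- stats::setNames(stats::runif(length(genes), 10, 100), genes)
  structure(list(
    model = model,
    truth = list(alternative_producers = sort(alt_ids),
                 reference = "THD",
                 growth_substrates = subs,
                 dead_end_substrates = dead_subs,
                 optimal_objective = fba$objective_value),
    expression = normalize_expression(raw,
      provenance = sprintf("synthetic seed %d", seed)),
    seed = seed), class = "synthetic_scenario")
}

## ground truth re-checked with the production FBA; tests re-verify it again
## with the independent oracles
.verify_scenario <- function(sc) {
  m <- sc$model
  fba <- solve_fba(m)
  if (fba$status != "optimal" || fba$objective_value <= GROWTH_TOL) return(FALSE)
  ## the reference route alone must support growth
  if (length(sc$truth$alternative_producers)) {
    fr <- solve_fba(knockout(m, reaction_ids = sc$truth$alternative_producers))
    if (fr$status != "optimal" || fr$objective_value <= GROWTH_TOL) return(FALSE)
  }
  closed <- knockout(m, reaction_ids = c("THD", sc$truth$alternative_producers))
  f0 <- solve_fba(closed)
  if (f0$status == "optimal" && f0$objective_value > GROWTH_TOL) return(FALSE)
  for (aid in sc$truth$alternative_producers) {
    f1 <- solve_fba(knockout(m, reaction_ids = setdiff(
      c("THD", sc$truth$alternative_producers), aid)))
    if (f1$status != "optimal" || f1$objective_value <= GROWTH_TOL) return(FALSE)
  }
  TRUE
}

#' Generate synthetic phenotype-microarray plates with known truth
#'
#' Builds `n_replicates` 96-well plates for a truth table of substrates:
#' growth substrates get corrected readings centred at 3x the condition
#' threshold, non-growth substrates at 0.2x, with Gaussian noise of standard
#' deviation `noise_sd` (floored at zero); the A1 negative-control baseline
#' (half the threshold) is added to every raw reading, exactly as the
#' calling step subtracts it. Unassigned wells hold water (truth:
#' no growth).
#'
#' @param truth data.frame with columns `substrate`, `element_class`,
#'   `growth` (logical ground truth).
#' @param condition `"photosynthetic"`, `"aerobic"` or `"anaerobic"`.
#' @param noise_sd Gaussian noise on corrected readings (same units as the
#'   condition's threshold).
#' @param n_replicates plates generated (the replicate rule needs >= 2).
#' @param seed integer seed.
#' @param plate_id plate label.
#' @return list with `plates` (list of `pm_plate`) and `truth_calls`
#'   (data.frame substrate, element_class, condition, growth).
#' @export
make_pm_plates <- function(truth, condition = "photosynthetic", noise_sd = 0,
                           n_replicates = 3, seed = 1, plate_id = "SPM1") {
  stopifnot(noise_sd >= 0, n_replicates >= 1,
            all(c("substrate", "element_class", "growth") %in% names(truth)))
  if (nrow(truth) > 95) stop("at most 95 substrates fit on one plate")
  thr <- PM_THRESHOLDS[[condition]]
  a1 <- 0.5 * thr
  wells <- .PM_WELLS
  sub_wells <- wells[2:(1 + nrow(truth))]
  water_wells <- setdiff(wells[-1], sub_wells)
  ## readings rounded to 6 decimals: instrument-scale precision, and plates
  ## survive CSV round trips bit for bit
  plates <- .with_seed(seed, lapply(seq_len(n_replicates), function(rep_i) {
    corrected <- ifelse(truth$growth, 3 * thr, 0.2 * thr) +
      stats::rnorm(nrow(truth), 0, noise_sd)
    corrected <- round(pmax(corrected, 0), 6)
    df <- rbind(
      data.frame(well = "A1", substrate = "negative control",
                 element_class = "C", reading = a1),
      data.frame(well = sub_wells, substrate = truth$substrate,
                 element_class = truth$element_class,
                 reading = round(corrected + a1, 6)),
      if (length(water_wells))
        data.frame(well = water_wells, substrate = "water",
                   element_class = "C",
                   reading = round(pmax(stats::rnorm(length(water_wells), 0,
                                                     noise_sd), 0) + a1, 6)))
    df <- df[match(wells, df$well), ]
    rownames(df) <- NULL
    structure(list(plate_id = plate_id, condition = condition,
                   replicate = rep_i, wells = df), class = "pm_plate")
  }))
  truth_calls <- data.frame(substrate = truth$substrate,
                            element_class = truth$element_class,
                            condition = condition, growth = truth$growth)
  list(plates = plates, truth_calls = truth_calls)
}

#' Build a toy universal reaction catalogue
#'
#' The refinement search draws candidate additions from a universal
#' catalogue. This one contains a transporter for every extracellular
#' metabolite of the model (whether or not the model already has it) plus
#' `n_decoys` dead-end decoy reactions that can never enable growth, so
#' minimal-addition searches have something to reject.
#'
#' @param model a `metabolic_model`.
#' @param n_decoys decoy reactions to add.
#' @return list with `reactions` (list of [reaction()]) and `metabolites`
#'   (extra [metabolite()]s the decoys reference).
#' @export
make_universal_catalogue <- function(model, n_decoys = 2) {
  rxns <- list(); extra <- list()
  for (m in model$metabolites) {
    if (m$compartment != "e") next
    base <- sub("_e$", "", m$id)
    cyt <- paste0(base, "_c")
    if (!cyt %in% names(model$metabolites)) next
    rxns <- c(rxns, list(reaction(paste0("U_T_", base),
      stats::setNames(c(-1, 1), c(m$id, cyt)), name = paste0(base, " transport"),
      category = "transport")))
  }
  for (d in seq_len(n_decoys)) {
    did <- paste0("UDEAD", d, "_c")
    extra <- c(extra, list(metabolite(did, "catalogue dead end", "c")))
    src <- names(model$metabolites)[1]
    rxns <- c(rxns, list(reaction(paste0("U_DEC_", d),
      stats::setNames(c(-1, 1), c(src, did)), name = "decoy conversion")))
  }
  list(reactions = rxns, metabolites = extra)
}

#' Write a synthetic scenario to a directory
#'
#' Emits `model.xml` (SBML), `expr.tsv`, `plates.csv`, `truth.json` — the
#' same four artifact kinds a real study would ship.
#'
#' @param scenario a `synthetic_scenario` from [make_random_network()].
#' @param dir output directory (created if needed).
#' @param noise_sd,n_replicates forwarded to [make_pm_plates()].
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, noise_sd = 0, n_replicates = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sbml(scenario$model, file.path(dir, "model.xml"))
  act <- scenario$expression$activity
  utils::write.table(data.frame(gene_id = names(act), value = act),
                     file.path(dir, "expr.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth_tab <- data.frame(
    substrate = c(scenario$truth$growth_substrates,
                  scenario$truth$dead_end_substrates),
    element_class = "C",
    growth = c(rep(TRUE, length(scenario$truth$growth_substrates)),
               rep(FALSE, length(scenario$truth$dead_end_substrates))))
  pm <- make_pm_plates(truth_tab, noise_sd = noise_sd,
                       n_replicates = n_replicates, seed = scenario$seed)
  write_pm_csv(pm$plates, file.path(dir, "plates.csv"))
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
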