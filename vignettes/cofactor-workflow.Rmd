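---
title: "Constraint-based dissection of NADPH metabolism: models, methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based dissection of NADPH metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofactorscope)
```

## The problem

Facultative photosynthetic bacteria such as *Rhodobacter sphaeroides* balance
two redox currencies: NADH, produced by catabolism, and NADPH, consumed by
biosynthesis. The membrane transhydrogenase (PntAB) interconverts them, and
the cell also carries alternative NADPH-producing reactions (glucose-6-phosphate
dehydrogenase, NADP-dependent malic enzyme and isocitrate dehydrogenase, and
others) whose contribution depends on the carbon source and energy mode.
`cofactorscope` implements the constraint-based toolchain for dissecting this
architecture on a genome-scale metabolic model: which reactions *can* supply
NADPH, how much NADPH growth demands, how expression data reshapes the
feasible flux space, and how well the model's substrate-utilization
predictions agree with phenotype-microarray (PM) data.

## The core model

All analyses live on one linear program. Given the stoichiometric matrix
$S \in \mathbb{R}^{m \times n}$ (metabolites by reactions), flux balance
analysis (FBA) solves

$$\max_v \; v_{\mathrm{Biomass}} \quad \text{s.t.} \quad S v = 0, \quad
v_{\min} \le v \le v_{\max},$$

with bounds of $\pm 100$ mmol/gDW/h for reversible and $[0, 100]$ for
forward-only reactions. Exchange pseudo-reactions move metabolites across the
system boundary; negative exchange flux is uptake. A medium is a set of
exchange bounds: every exchange not named is secretion-only $(0, 100)$, the
tested carbon source is opened at $-4$ mmol/gDW/h ($-1$ for N/P/S sources),
freely exchanged compounds get $(-100, 100)$, and the non-growth ATP
maintenance flux is fixed from below at 8.39 mmol/gDW/h when the model
carries a maintenance reaction. Flux variability analysis (FVA) re-solves the
LP per reaction, minimizing and maximizing its flux with the biomass flux
held at a fraction of the optimum (default 1, i.e. the optimal face; the
capability annotations in the screen use fraction 0, the feasibility range).

## Expression constraints (E-flux)

Gene-expression measurements shrink the bounds of enzyme-catalyzed
reactions. Raw values are normalized to activities in $[0,1]$, by default by
dividing by the dataset-wide maximum (a per-gene-across-conditions mode is
available; which of the two a given published dataset used is usually not
recoverable, so it is an explicit switch rather than a guess). Each
reaction's activity is its GPR rule evaluated over activities — isozymes
(`or`) take the max, complex subunits (`and`) the min — and its bounds
become $\pm 100 \cdot a$, intersected with the originals. Three deliberate
choices:

* exchange and demand pseudo-reactions are never constrained (no enzymes);
* genes absent from the profile count as activity 1 with a warning — an
  unmeasured probe is not evidence of absence, and zeroing it would silently
  kill reactions;
* a unit profile must reproduce plain FBA exactly (tested to 1e-8), and
  pointwise-lower activities can never raise the optimum (tested over 100
  random profiles).

## Alternative optima and cofactor demand

FBA optima are faces of a polytope, not points, so any single flux vector is
an arbitrary representative. We characterize the optimal face by its
distinct *support patterns* — the sets of reactions carrying $|v| >
\varepsilon$ — enumerated with a MILP: the objective is fixed at its
optimum, each reaction direction gets a binary activity indicator $y$ linked
by $\varepsilon y \le v \le M y$ (reversible reactions get one indicator per
direction, $y^+ + y^- \le 1$), and each found pattern is excluded by an
integer cut before re-solving. Exhaustion of the face is detected as MILP
infeasibility.

The NADPH demand estimate uses this machinery: with every other
NADPH-producing route closed, all NADPH must flow through the reference
transhydrogenase, so its flux *is* the demand. Averaging that flux (with its
SEM) over a fixed number of alternative optima — 1000 by default — gives an
estimate that does not depend on which vertex a solver happens to return.
Because a continuous face often has fewer distinct support patterns than
1000, the solution list is padded with seeded random convex combinations of
the found vertices: convex combinations stay optimal and mass-balanced, so
the mean/SEM contract is preserved while the padding is explicit (the
`exhausted` flag and the distinct-pattern count are always reported).

## The producer screen

`find_cofactor_reactions()` collects every reaction whose stoichiometry
touches the cofactor, annotates synthesis-direction capability (can its
feasibility-range flux produce the cofactor?) and one-at-a-time knockout
essentiality under the screen's medium. `screen_alternative_producers()`
then closes the synthesis direction of every non-essential capable reaction
— for reversible reactions only the producing direction is bounded away,
since capability is directional; full deletion is available behind a flag —
verifies the baseline growth is zero (a nonzero baseline aborts the screen
with a list of leaky reactions), and re-opens members one at a time. The
biomass objective and demand sinks are never screen members: they consume
the cofactor but are not producers. Reactions that merely touch the cofactor
but cannot carry steady-state producing flux (e.g. dead-end side products)
are filtered out by the FVA capability test, which the synthetic decoys
exercise.

Both counting conventions for "cofactor-requiring" are exposed
(`counting = "either"` or `"consumption"`), because published tallies of
such reactions are ambiguous between them; the screen itself is insensitive
to the choice beyond the reported totals.

## Phenotype microarrays and refinement

PM plates are 96-well assays (wells A1–H12) with a negative control at A1.
Calling subtracts the A1 reading from every well (floored at 0 — negative
growth is meaningless), then applies a condition threshold: 0.05 OD650 for
photosynthetic growth, 5 Omnilog units for aerobic respiration. Anaerobic
OD-based endpoints reuse the 0.05 OD threshold, configurable. A substrate is
a growth substrate only if it clears the threshold in *every* replicate;
the Monte-Carlo test shows this all-replicates rule cuts false positives
relative to single-replicate calling when noise reaches threshold scale.

Model and plate meet in a 2x2 table per element class: GG, GNG, NGG, NGNG
(model prediction–PM observation). NGG inconsistencies trigger gap filling:
a breadth-first search over a user-supplied universal reaction catalogue by
increasing subset cardinality (cap 3 by default, lexicographic tie-break for
determinism), returning the first subset that lets the model grow on the
substrate; an exchange reaction for the substrate is auto-generated when
missing, since it is boundary plumbing rather than biology, and does not
count toward the cardinality. GNG inconsistencies propose removing the
substrate's transporters, accepted only when re-running the full comparison
introduces no new inconsistency. Gene-evidence weighting of candidate
additions is out of scope; a per-reaction prior column in the catalogue can
encode it externally.

## Synthetic data: what it emulates, what it does not

The generators produce the four artifact kinds the analyses consume — SBML
models, expression tables, PM plates, a universal catalogue — with known
ground truth:

* `make_toy_model()` builds TOY1, a minimal network with the architecture of
  interest (uptake, NADH-emitting catabolism, two-subunit transhydrogenase,
  one alternative NADPH producer, respiration, NADPH-consuming biomass). Its
  optima are hand-checkable: 8.0 at 4 mmol/gDW/h uptake, 16/3 with the
  transhydrogenase deleted, 0 with both NADPH routes gone. TOY1 collapses
  the proton-coupled transhydrogenase to a proton-free stoichiometry so the
  algebra stays on paper; TOY1-H restores a periplasmic proton cycle (its
  optimum drops to 20/3 because respiration must also pump the protons the
  transhydrogenase consumes), exercising multi-compartment handling.
* `make_random_network()` randomizes the catabolic and producer
  stoichiometries, plants a known set of alternative producers (each
  verified at generation to independently restore growth), and adds decoys:
  an NADPH consumer, a dead-end "producer" that FVA must rule out, and a
  transportable but non-catabolizable substrate. Catabolic NADH yield is
  sampled no smaller than the precursor yield so the transhydrogenase route
  is always stoichiometrically viable — that is the study condition, not a
  tuning knob.
* `make_pm_plates()` draws growth wells at 3x threshold and non-growth wells
  at 0.2x, adds Gaussian noise and the A1 baseline, and returns the truth
  calls alongside.

These networks are deliberately *not* genome-scale: they reproduce the
cofactor-network topology, degenerate optima and screen structure at a size
where exhaustive oracles (vertex enumeration, subset search) can certify
every answer. Passing tests therefore demonstrate algorithmic correctness,
not biological fidelity of any particular genome-scale reconstruction; runs
on a real reconstruction inherit that model's curation quality.

## Numerical choices

No LP solver is assumed from the environment: the package carries a dense
two-phase tableau simplex (Bland's entering rule; among min-ratio leaving
candidates the largest pivot element, since pivoting on noise-scale entries
corrupts the tableau) and a depth-first branch-and-bound MILP on top of it.
Returned optima are verified against the original constraints and demoted to
a `numerical` status rather than silently accepted; branch-and-bound
re-solves a bounds-fixed LP before accepting any rounded-integer incumbent.
This is adequate and exact at desk scale (tens to a few hundred variables);
it is not a performance claim for genome-scale FVA.

* Growth tolerance: objective $> 10^{-6}$ counts as growth ("greater than
  zero" needs a numerical floor).
* Activity epsilon for support patterns: $\varepsilon = 10^{-4}$ mmol/gDW/h.
  Fluxes of interest here are $O(1)$–$O(10)$, so this is four to five orders
  below signal while staying well above the simplex's noise floor; pushing
  it to $10^{-6}$ makes the $\varepsilon y \le v$ link rows nearly parallel
  to the binary box and destabilizes the MILP.
* Each enumerated support pattern is "polished" by re-solving a plain LP
  with that support fixed, so reported flux vectors are clean vertices.
* FVA holds the objective at exactly its optimum by default; the fraction is
  a parameter because published variability statements rarely pin it down.
* Degenerate optima: `solve_fba()` returns an arbitrary vertex by contract;
  anything that needs uniqueness must go through the enumeration.

## Problem sizes in the test suite

The oracle-equivalence suite runs the toys plus 20 seeded random networks of
at most 12 reactions — the scale at which vertex enumeration
($\binom{n}{n-r} 2^{n-r}$ basis candidates) and exhaustive subset search
stay exact and fast; producer-recovery, E-flux monotonicity (100 random
profiles) and the zero-noise PM loop run at the same scale. These sizes are
the package's own statistical design: large enough to exercise every branch
(degenerate faces, decoys, dead ends), small enough that every expected
value in the tests is computed by an independent oracle rather than asserted
from memory.

## Known limitations

* The simplex is dense and unscaled; genome-scale models load and validate,
  but FVA across thousands of reactions is slow by design of scope.
* No thermodynamic/loopless constraints, no parsimonious FBA, no MOMA/ROOM,
  no flux sampling (enumeration plus convex padding only), no kinetic PM
  curve fitting (endpoint or summary readings only).
* Classification of "spontaneous" reactions relies on annotation; the
  structural classifier only separates exchange/demand/transport/enzymatic.
* The refinement search proposes minimal reaction sets; it does not weigh
  genomic evidence for candidate enzymes.

## A worked example

```{r example, eval = FALSE}
m <- make_toy_model("TOY1")
solve_fba(m)$objective_value                      # 8.0
screen_alternative_producers(m, "NADPH_c", "THD") # candidates: ZWF_alt
estimate_cofactor_demand(knockout(m, "ZWF_alt"), "THD", k = 1000, seed = 1)
# mean 8.0, SEM 0: the demand is pinned on this face
```

The `analysis/` directory runs the full workflow end to end
(`01_build_models.R` … `05_pm_consistency.R`), writing its tables under
`results/`.
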