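---
title: "Contextualizing stoichiometric signaling networks with sigflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing stoichiometric signaling networks with sigflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigflux)
library(dplyr)
```

## The modeling formalism

sigflux treats a signaling cascade as a stoichiometric network: activated
proteins, complexes, ligands and energy metabolites are compounds;
binding, phosphorylation, translocation and output-formation steps are
reactions with fixed stoichiometry. At (pseudo-)steady state every
compound's production balances its consumption, so the feasible flux
vectors form the polytope `{v : S v = 0, lb <= v <= ub}`. This brings
three standard constraint-based tools to signaling:

* **FBA** (`fba()`): maximize or minimize one reaction's flux — here
  typically an output such as a nuclear transcription-factor demand.
* **Parsimonious FBA** (`fba_min_norm()`): among objective-optimal flux
  vectors, pick one with minimal total flux `sum(|v|)`. This is the
  reference distribution used for fold-change mapping; it suppresses
  futile cycles, which matters because signaling reconstructions contain
  internal loops by design (they are part of network function and are
  deliberately *not* removed — no loopless correction is applied).
* **FVA** (`fva()`): per-reaction feasible range. We report *raw*
  capability — no objective is fixed first — because the scientific
  question is "how much output could this stimulation produce at all",
  not "how much slack remains at optimality". A fraction-of-optimum FVA
  is deliberately absent from the surface to keep that semantics single.

Assumptions inherited from the formalism: signaling "flux" is an
arbitrary-unit activity rate, not a concentration; one unit of ligand
uptake is the stimulation dose; kinetic and saturation effects are
outside the model. Flux units are therefore reported on the same
numeric scale as the bounds (the `1000` sentinel marks "effectively
unconstrained").

## Gene–reaction rules and tailoring

Each reaction may carry a Boolean gene rule: `AND` for complexes and
multi-protein requirements, `OR` for functional isoforms. The grammar
(`parse_gpr()`) is case-insensitive and requires parentheses to mix
operators at one level, so precedence is always explicit in the files.

Tailoring (`tailor_model()`) pins `lb = ub = 0` on every reaction whose
rule is false under a presence/absence call map. Three choices here were
genuinely open and are worth recording:

* **Unlisted genes default to present.** Reactions are disabled on
  *evidence of absence* only; a gene the platform does not measure must
  not silently delete a reaction. Configurable via `default_call`.
* **Probe selection.** For genes with several probes, the call follows
  the single probe with the highest mean intensity in the control group.
  This biases toward presence (the safe direction) and makes the call
  deterministic. Detection p-values are consumed as computed upstream;
  this package does not reimplement microarray preprocessing.
* **Replicate aggregation.** A gene is present when a majority (> 50 %)
  of the group's samples detect it below the cutoff; `any` and `all` are
  available. The cutoff itself defaults to a loose `0.02` with `0.01` as
  the conventional stringent companion; both are plain arguments, and
  `run_tailor()` emits a side-by-side statistics table for any cutoff
  pair, because the choice of cutoff — not its particular value — is the
  methodological point.

Condition-specific tailoring (`condition_tailor()`) composes: genes newly
absent under the condition disable reactions; genes newly *present* but
absent from the base model stay excluded, i.e. the effective absent set
is the union. This keeps the condition model a restriction of the
cell-type model.

Differential expression (`call_differential_expression()`) uses the
twofold / FDR 0.05 probe rule with a 50 % probe-fraction requirement per
gene; genes with some but too few regulated probes are reported
*subthreshold* and excluded from flux mapping, and mixed-direction genes
are demoted with a warning (the scaling rule is directional; the
isoform data that motivated the rule never produced this case, so the
conservative choice is to stand aside).

## Fold-change bound mapping

`reaction_fold_changes()` assigns each reaction the arithmetic mean of
its regulated genes' fold changes (`FCrxn`) and records the data set's
maximal up- and down-regulation as references (`FC-up`, `FC-down`).
`apply_fold_change_bounds()` then, around a min-norm reference flux
`v_ref` for the same I/O configuration:

* up-regulated, `v_ref > 0`: `lb <- max(lb, (FCrxn / FC-up) * v_ref)` —
  the maximally regulated reaction is pinned at its full reference flux,
  weaker regulation proportionally less (mirrored for `v_ref < 0`);
* down-regulated, `v_ref >= 0`: `ub <- (1 - FCrxn / FC-down) * ub` — a
  graded cap reaching hard shut-off at the reference fold change;
* `v_ref = 0`: untouched — expression data cannot orient a reaction that
  carries no reference flux.

The rule is isolated in this single function so an alternative scaling
can be swapped in without touching anything else. Note one consequence
verified in the tests: *enforcing* flux through one output can lower the
achievable maxima of sibling outputs, because stimulation supplies a
fixed one unit of ligand and enforcement diverts shared precursors. The
invariant that always holds is feasible-set shrinkage — no output's FVA
maximum ever increases.

## I/O relationships and energy scans

`configure_io()` implements the stimulation protocol: all ligand
exchanges and binding reactions are closed, then the chosen pair is
fixed (`lb = ub = -1` uptake, `lb = ub = 1` binding), with co-stimulation
expressed as a nested pair so arbitrary receptor combinations compose.
Energy scenarios: `sensitivity` (ATP and GTP at `lb = -25, ub = 0`, used
for 50-point robustness scans) and `quantitative` (ATP `-100`, GTP `-50`,
the roomier supply used under fold-change mapping). A curve is classified
`dependent` when its response varies by more than `1e-6` flux units
across the grid. Baseline rows (all inputs closed) are computed by the
capability matrix so loop-sustained output flux can be subtracted; grid
points where the pinned stimulation is infeasible (e.g. zero ATP with no
escape route for the bound receptor signal) are recorded as `NA`, not
errors.

## Numerical core

No LP solver package is assumed: `lp_solve()` is a dense two-phase
revised simplex on bounded variables, with Bland's smallest-index rule
for both entering and leaving choices — flux polytopes are highly
degenerate and anti-cycling is not optional. All structural bounds are
finite (the `1000` sentinel), so every flux LP is bounded and the only
honest statuses are `optimal` and `infeasible`. The basic solution is
recomputed from a fresh factorization each iteration; at the network
sizes this package targets (tens to a few hundred reactions) robustness
is worth more than the saved milliseconds. Tolerances: `1e-9` on reduced
costs and pivots, `1e-6` flux units for feasibility snapping,
blocked-reaction classification and dependence calls. The L1 min-norm is
a deliberate divergence from the quadratic `minNorm` of the classical
toolbox: it serves the same purpose (suppressing loop flux) while
keeping the whole stack inside linear programming.

Correctness is established by triangulation in the test suite: random
rules against R's own logical evaluator (full truth tables), random
small networks against an exhaustive vertex-enumeration oracle, and the
packaged miniTLR fixture against a committed expectations table produced
by `tools/minitlr_oracle.py` with scipy's HiGHS solver — an
implementation sharing no code with this package.

## What the synthetic generator does and does not emulate

`generate_toy_network()` builds receptor → adaptor/kinase cascade →
output networks with the structural features that the analysis layer
must handle: per-receptor ligand/exchange/binding triples, `OR`-isozyme
cascade steps (ATP-coupled at a configurable fraction), `AND`-gated
two-gene output complexes, random receptor-to-output wiring recorded as
reachability ground truth, planted orphan ligands (dead ends) and
isolated 2-cycles (loops). Coefficients are restricted to 1 and 2 so all
expected yields are exact rationals. `generate_expression_data()` plants
an absent gene set with detection p-values exactly 0/1 at `noise = 0`
(any cutoff recovers truth — the property the recovery tests rely on)
and decoy low-intensity probes to exercise probe selection.

What is *not* emulated: realistic microarray intensity distributions,
probe cross-hybridization, correlated replicate noise, and the scale and
redundancy structure of a curated 980-reaction reconstruction. Passing
recovery tests therefore demonstrate the correctness of the calling and
tailoring *logic*, not robustness to real microarray noise; on real
data the cutoff choice and manual curation dominate, which is exactly
why the two-cutoff comparison report exists.

The fixed `mini_tlr()` fixture (37 reactions, 26 compounds, 20 genes)
adds the hand-designed cases the random generator cannot guarantee: a
co-stimulation-gated IRF-style output, a GTP-coupled ROS branch, an
output reaction sitting on an internal loop (nonzero baseline), and a
two-isozyme adaptor shared by all receptors.

## Problem sizes and determinism

The shipped tests and the acceptance script run: 200 random rules with
full truth tables, 30 random ≤ 6-reaction networks against the
enumeration oracle, 20 seeded toy networks for tailoring and regulation
recovery, and 50-point robustness scans on miniTLR — sizes chosen so the
whole suite triangulates every numerical path in a couple of minutes on
one core while staying exhaustive where exhaustiveness is the point
(truth tables, vertex enumeration). All generators take explicit integer
seeds and never touch the global RNG stream; identical seeds give
byte-identical TSV outputs from the pipeline runners.

## Known limitations

* Signaling flux units are arbitrary; only ratios and zero/nonzero
  patterns are interpretable.
* Loops are retained by design; raw FVA maxima on loop reactions hit the
  bound sentinel and must be read via baseline subtraction.
* `import_sbml()` covers the subset of SBML L3 + FBC that
  `export_sbml()` emits; the TSV triple is the canonical format.
* Compound merging for synonymously named species is an input-file
  concern: the reader takes ids literally.
* The fold-change scaling implements a linear interpolation between "no
  constraint" and "pinned at reference"; other monotone scalings are
  plausible and would slot into the same operation.
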