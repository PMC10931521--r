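---
title: "Methods: task scoring, metabolomics classification, and condition-specific flux analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task scoring, metabolomics classification, and condition-specific flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidescope)
```

This vignette explains the models and procedures implemented in
`tidescope`, the assumptions behind them, the parameters that matter,
and the design decisions taken where the methodology was genuinely open.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The constraint-based core

All analyses operate on a genome-scale metabolic network: metabolites
with compartments, reactions with a sparse stoichiometric matrix $S$,
flux bounds $l \le v \le u$, gene-protein-reaction (GPR) rules, and a
linear objective $c$. Flux balance analysis (FBA) solves
$\max\, c^\top v$ subject to $S v = 0$ and the bounds; parsimonious FBA
(pFBA) additionally minimizes $\sum_r |v_r|$ subject to retaining a
fraction of the FBA optimum. A metabolic task (for example, ATP
production from glucose) is a set of allowed uptakes, required
secretions and reaction-bound overrides checked for feasibility with all
other exchanges closed.

**LP solver.** The linear programs are solved by a dense two-phase
primal simplex implemented in the package: Dantzig pricing with a switch
to Bland's rule after a pivot budget (guaranteeing termination under
degeneracy), a relative-tolerance ratio test that prefers large pivot
elements for numerical stability, pivot tolerance $10^{-9}$, and a
steady-state residual check $\lVert S v\rVert_\infty \le 10^{-6}$ on
every returned solution. Absolute-flux objectives are handled by the
standard split $v = p - q$, $p, q \ge 0$. Infinite user bounds are
clamped at $\pm 10^8$ and a solution pressing against a clamped bound is
reported as unbounded. The solver is validated in the test suite against
exhaustive vertex enumeration on small networks and against an
independent LP implementation.

**Flux sampling.** Sampling uses hit-and-run with isotropic directions
drawn in the null space of $S$ *augmented with unit rows for
fixed-bound reactions* — without the augmentation, any direction moving
a fixed maintenance demand gives a zero-length chord and the chain never
leaves its start. The chain starts from a maximum-margin interior point
(one LP: maximize a uniform slack $t$ inside all non-fixed bounds and
extra inequalities), records every `thinning`-th state (default 100),
and is fully determined by its integer seed. For a point polytope all
samples coincide, which is the correct degenerate behavior. Condition
sampling keeps the objective-fraction constraint
$c^\top v \ge f \cdot \mathrm{opt}$ active during sampling, so every
sample respects the parsimonious regime. No thermodynamic/loopless
constraints are imposed.

# Task scores from differential expression

Each gene significant at FDR < `fdr_threshold` (default 0.01, strict
`<`) carries its log2 fold change as a signed weight; all other genes
carry 0. Only genes present in the model are used. Weights propagate
through GPR trees: an `and` node takes the child value of minimum
absolute magnitude (a complex is only as perturbed as its
least-perturbed subunit), an `or` node the maximum absolute magnitude
(any isozyme's change can change the reaction); ties of equal magnitude
resolve toward the positive value, then to the leftmost child, making
the result deterministic. This combination rule is a design choice — the
propagation convention is not uniquely determined by the task-scoring
idea — and alternative conventions can be supplied by evaluating trees
directly.

A task's score is the arithmetic mean of propagated weights over its
scored reaction set, zero-weight reactions included; reactions without a
GPR are excluded (weights are defined only through genes). The scored
set is either the GPR-bearing reactions active in the parsimonious
solution of the task LP, or a curated per-task list when the task
carries one. The toy catalogue uses curated lists (each task's defining
pathway): the parsimonious active set drags the shared ATP machinery
into every task, which blurs task-level attribution of planted effects.
Both options remain available on real task catalogues.

**Permutation test.** The multiset of gene weights is reshuffled
uniformly over the model's genes `n_perm` times (default 1000) and the
score recomputed per shuffle. One-sided empirical p-values use the
add-one correction $p_{up} = (1 + \#\{\text{null} \ge
\text{obs}\})/(n_{perm}+1)$ and analogously for $p_{down}$, so both are
strictly positive. The significance and direction call uses the
two-sided empirical p-value $\min(1,\, 2\min(p_{up}, p_{down}))$
compared against `alpha` (default 0.1, no multiple-task correction; a BH
option can be applied downstream on the returned p-values). The
two-sided form matters: flagging on $\min(p_{up}, p_{down}) < \alpha$
alone would flag a fraction $2\alpha$ of tasks under an exchangeable
null (two tails of $\alpha$ each), whereas the doubled form is
calibrated at its nominal level — the acceptance suite verifies a flag
rate of 0.10 ± 0.03 under random weights. Directions are reported
separately as increased/decreased from the smaller tail.

Two mechanisms follow from this construction and are verified by tests:
scaling all gene weights rescales all scores but leaves p-values
unchanged, and adding background differentially expressed genes widens
the permutation null (the reason a condition with massive transcriptional
change needs a larger task score to reach significance).

# Metabolomics preprocessing and classification

The chain is fixed: **filter → impute → normalize → classify**, guarded
by a stage flag so normalization cannot run twice.

- *Filter*: a metabolite is removed iff its missing fraction is strictly
  greater than `max_missing_fraction` (default 0.6); exactly 60% missing
  is retained.
- *Impute*: each missing cell becomes half the per-metabolite minimum
  observed raw area count. This rule presumes left-censored missingness
  (values below detection).
- *Normalize*: per metabolite, $x \mapsto \log_b x - \mathrm{center}$.
  Log base 2 and mean centering are defaults; median centering is
  provided because both conventions circulate for this kind of data and
  the choice is not consequential for rank-based testing. The row center
  is exactly zero after the transform.

**Testing.** `mannWhitney()` implements the exact test by enumeration of
all group labelings with midranks for ties (the default whenever
$\min(n) \le 8$), and an asymptotic mode (normal approximation with
continuity and tie correction, via `stats::wilcox.test`). With the
customary $n = 3$ per group, the smallest attainable exact two-sided
p-value is exactly 0.1 — a design-level fact the package surfaces: at an
FDR threshold of 0.1 the exact test can never produce a single
significant call after Benjamini-Hochberg correction across a metabolite
panel, and even the two-sided asymptotic floor (~0.081) cannot unless
more than 80% of the panel is significant.

`classifyMetabolites()` therefore defaults to the asymptotic,
*directional* (one-sided toward the observed mean difference) p-value:
produced/consumed calls are directional hypotheses, and this is the only
variant under which FDR < 0.1 calls are attainable at $n = 3$.
Directional testing is anti-conservative by up to a factor of two under
the null; `alternative = "two.sided"` restores the symmetric test, and
BH correction is applied within each contrast family (all metabolites ×
one contrast). Classes follow from the calls: `consumed_only` (some
significant blank-media calls, all consumed), `produced_or_consumed`,
`differential_without_blank_significance` (a treatment-vs-control
difference whose direction of production change cannot be anchored
without blank significance), `unchanged`.

# Model tailoring and the condition constraint recipe

`mapReferenceReactions()` extracts a tissue subnetwork from a general
model by shared reaction identifiers, with species-specific additions;
ids that fail to map are reported in the curation ledger, never silently
dropped. `addExchangesForMeasured()` adds exchange reactions (from the
general model) for measured metabolites with significant
produced/consumed calls, matching by exact KEGG compound id (name-based
fallback is deliberately off: ambiguity risk). When the extracellular
species would otherwise be disconnected, the lexicographically first
transport reaction from the general model is co-added — an exchange
without its transporter is dead — and each co-addition is ledgered. The
operation is idempotent. The ledger records one entry per structural
change, so the diff between input and output models reconstructs exactly
from it.

`applyConditionConstraints()` applies the recipe: consumed-metabolite
exchanges at lower bound `uptake_bound` (default −10, a theoretical
overabundance), an ATP-hydrolysis objective with upper bound 100 flux
units, DNA and RNA demand reactions fixed at 1 unit each (general cell
maintenance; the unit is model-relative, defined by the demand's
stoichiometry), and internal upper bounds of $10^6$ so internal caps do
not constrain the solution space. If the result is infeasible, each
maintenance demand is relaxed in turn and the blocking demands are named
in the model's notes.

# Condition-specific extraction and comparison

`pruneToCondition()` integrates per-condition transcript abundance
(median TPM per gene): GPR propagation with `and` = min and `or` = sum,
log transform ($\log(1+a)$; TPM spans orders of magnitude, and a linear
rescale would let a few highly expressed genes compress the contrast
between suppressed and ordinary pathways), min-max rescale to $[0,1]$
over assessed reactions, cost $= 0.01 + 0.99\,(1 - \text{scaled})$
(the floor keeps every carried flux weakly penalized so unused reactions
drop out); unassessed reactions get the median cost. A cost-weighted
absolute-flux minimization subject to retaining `objective_fraction`
(default 0.9) of the FBA optimum is solved, and reactions with
$|v| < 10^{-9}$ are pruned (the objective and fixed-bound reactions are
never pruned). The report carries the retained objective fraction and a
Spearman rank-correlation p-value between $|v|$ and abundance over kept,
assessed reactions. This extraction is a contract-defined simplified
procedure with the published knobs (TPM input, 90% objective fraction,
50 samples); parity with any published extraction tool is a non-goal —
the contract is internal consistency and planted-truth recovery.

Downstream comparison: `sharedReactions()` (lexicographic intersection),
`brayCurtisMatrix()` on $|v|$ profiles (the distance requires
nonnegativity; all-zero pairs get distance 0 with a note),
`ordinate2d()` (vegan's monotone-regression NMDS engine with a classical
metric start plus seeded random restarts, keeping the lowest stress; an
all-zero distance matrix returns the exact trivial embedding), and
`rankDistinguishingReactions()` (ranger random forest with permutation
importance, seeded and single-threaded for reproducibility; a
model-free standardized-mean-difference fallback must agree on cleanly
separated features). Optional label-permutation nulls report both
per-reaction 95th percentiles and the familywise 95th percentile of the
maximum importance — the correct reference for "is anything
distinguishing at all", since per-reaction thresholds over $m$ reactions
false-alarm at rate $1-0.95^m$.

# The synthetic-data generator

The generator produces every pipeline input with known ground truth and
is byte-reproducible given its parameters and seed.

**Toy network** (`makeToyModel()`): 44 reactions, 34 metabolites, 48
genes, two compartments, 11 exchanges with KEGG-style compound ids.
ATP is produced by two alternative oxidative routes — glycolysis-fed
pyruvate oxidation and fatty-acid uptake/activation/oxidation — that are
deliberately *stoichiometrically symmetric*: same ATP yield per unit
flux and per O2, same byproduct burden, two-step supply chains gated by
two-gene complexes. Symmetry is the point: with a bounded ATP objective
either route alone saturates the optimum, so the choice between them
carries no stoichiometric information and must be decided by transcript
evidence — exactly the property transcript-guided extraction claims to
recover. (During development, asymmetries as small as one extra CO2 per
reaction unit in one route's byproduct stoichiometry were enough to
override a 20-fold transcript suppression; the symmetric design makes
the planted-truth test meaningful.) The toy glycolysis is ATP-neutral
for the same reason. Product pathways (RNA, DNA, lipid, ROS
detoxification) each carry a feasible metabolic task with designed
minimal cuts, and nucleotide synthesis has alternative precursor
(glucose vs ribose) and base (de novo vs salvage) routes.

**DE tables** (`simulateDE()`): planted-task genes draw
$\mathrm{lfc} \sim N(\pm\,\text{effect}, 0.25)$ with
$\mathrm{fdr} \sim U(0, 0.005)$; background genes are DEGs with
probability `background_deg_rate` (default 0.05), else
$\mathrm{fdr} \sim U(0.2, 1)$.

**Abundance matrices** (`simulateAbundances()`): log-normal baselines
shared with blank media; planted consumed metabolites scaled by
$1 - 0.9$ and produced by $1 + 4$ in their groups; $n = 3$ per group
(the design that exposes the exact-test floor). The default planted set
emulates spent-media metabolomics — 18 of 22 metabolites changed vs
blank (media nutrients consumed and secretion products accumulated in
both groups, plus ten condition-specific effects) — because in real
spent media most measured metabolites do differ from a cell-free blank,
and because BH power arithmetic at $n = 3$ requires at least nine
signals per contrast family for any FDR < 0.1 call to exist.
Missingness is *left-censored* (cells in the lowest abundance quantile
drop out with high probability), the mechanism half-minimum imputation
presumes; two extra metabolites are engineered above the 60% missingness
cutoff so the filter has something to remove. Missing-at-random masking
is deliberately not the default: a single randomly missing cell in a
produced metabolite's signal group would be imputed to half the row
minimum and destroy the group separation, making classification
unstable at $n = 3$ in a way real detection-limit dropout is not.

**TPM profiles** (`simulateTPM()`): log-normal baselines (median 100);
the suppressed pathway's genes scaled by 0.05 (20-fold suppression) per
condition.

What the generator does *not* emulate: real GENRE scale (thousands of
reactions), correlated gene expression, batch effects, metabolite
annotation ambiguity, or instrument-specific missingness structure.
Passing tests therefore demonstrate correctness of the statistical
machinery and the planted-truth recovery properties at toy scale, not
performance on any particular real tissue.

# Problem sizes and reproducibility

Default analysis sizes — 1000 permutations per task, 50 flux samples per
condition at thinning 100, 100-seed recovery and detection experiments,
500 calibration evaluations — were chosen so the statistical properties
of interest (calibration within ±0.03, ≥95/100 recovery rates) are
measurable with comfortable margins while a complete run of the suite
and the acceptance script stays in the minutes range on a single CPU.
Every stochastic component takes an explicit integer seed (no wall-clock
seeding anywhere); the pipeline writes a manifest of configuration,
seeds and per-file checksums, and identical configurations reproduce
every result file byte for byte.

# Known limitations

- The GPR weight-combination rule and the abundance rule (`and` = min,
  `or` = sum) are conventions; other published variants (means, medians)
  exist and would change scores.
- The directional metabolomics test is anti-conservative by up to 2× at
  the per-test level; it is the price of any attainable FDR < 0.1 call
  at $n = 3$, and is documented rather than hidden.
- Hit-and-run mixing is adequate for toy-scale polytopes but no
  convergence diagnostics are computed; for large networks a rounded
  sampler would be preferable.
- The condition-specific extraction is a simplified transcript-cost
  pruning, not a reimplementation of any published extraction algorithm.
- The dense simplex is suitable for networks up to a few hundred
  reactions; genome-scale models would need a sparse LP backend.
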