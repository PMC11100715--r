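---
title: "From signed networks to cell-state transition hypotheses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From signed networks to cell-state transition hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stateshift` turns signed, directed protein-interaction networks annotated
with per-cell-state up/down calls into an executable Boolean model, screens
that model with single-node knockouts, and uses machine-learning transfer
plus additive attributions to nominate mechanisms for observed cell-state
transitions in glioblastoma (MES, AC, NPC, OPC). This vignette documents the
model, its assumptions, the tunable parameters, and the design decisions
taken where the methodology was genuinely open.

## 1. The Boolean model and rule synthesis

Every protein is a binary node; the synchronous update applies all rules at
once. The central constraint is biological: each cell-state profile (the
up/down pattern the upstream network inference assigns to a state) must be a
*fixed point* of the dynamics, so that the model "at rest" reproduces each
phenotype exactly.

For each non-input node we search, deterministically, the two-layer gate
family `combine(activators) AND NOT combine(inhibitors)` with each
combinator OR or AND, in the fixed order (OR,OR), (OR,AND), (AND,OR),
(AND,AND); the first gate satisfying `f(profile) = profile[node]` for every
profile wins. Determinism matters more here than optimality: identical
inputs must give byte-identical models.

When no simple gate fits, we fall back to an exhaustive search over
sign-monotone truth tables on the node's regulators (capped at 10
regulators). Because the constraints only pin down at most one input pattern
per profile, the minimal solution is closed-form: output 1 exactly on the
up-closure, in the signed partial order (activators increasing, inhibitors
decreasing, dual-sign regulators held equal), of the patterns constrained to
1. This is the unique monotone table with the fewest 1-outputs, so the
documented "fewest ones, then lexicographic" preference never actually needs
its lexicographic arm. Constraints are *contradictory* when one pattern
demands both outputs, or when a 0-constraint dominates a 1-constraint in the
signed order (no monotone table exists); both cases are reported per node in
the `FeasibilityReport`, and the simple gate satisfying the most profiles
(ties resolved toward earlier profiles in the fixed order MES, AC, NPC, OPC,
then earlier gate order) is installed so simulation can proceed.

Input nodes (no incoming edges) hold whatever value the initial condition
gives them — equivalent to clamping them at their profile value, which is
how the per-state simulations are initialized.

### Update schemes

The default engine is the synchronous deterministic update: it is
reproducible, admits an exhaustive state-transition-graph oracle (every test
of the simulator is checked against one), and — for models whose profiles
are true fixed points — agrees with asynchronous dynamics on absorbing
states. A continuous-time asynchronous mode (`async_gillespie`) is provided
for completeness: unstable nodes flip one at a time with unit rates,
exponential dwell times, and uniform choice among unstable nodes; it returns
the time-weighted state distribution after burn-in plus the absorbing fixed
point when reached. Synchronous simulation raises an explicit error if
`max_steps` is exceeded (possible only when the transient is longer than the
budget, e.g. under misconfigured clamps); limit cycles are returned with
their full state set and period. Where a single representative state of a
cycle is needed (similarity matrices, screens), we use the first state of
the cycle in trajectory order — deterministic, and flagged in the output.

## 2. The knockout screen

A knockout clamps a node's rule to the constant 0 for the entire simulation
(not a one-time flip). From each state's baseline steady state, every ON
node is knocked out once; the post-knockout steady state is compared to all
reference steady states via Hamming distance and similarity `1 − d/n`.
Z-scores are computed per (start state, reference) column across that
start's knockouts — the orientation under which positive z means "shifted
toward that reference". Input nodes that are ON are included in the screen:
clamping an input OFF is a meaningful perturbation, and the single-knockout
contract still rejects knockouts of OFF or already-clamped nodes. Assignment
is argmax similarity with the fixed MES, AC, NPC, OPC tie-break.

## 3. Patient state assignment

**Cluster labeling.** Cluster markers are one-vs-rest Wilcoxon rank-sum
tests (one-sided, normal approximation — exact p-values are unavailable with
tied counts anyway), Benjamini–Hochberg adjusted within cluster at a default
`alpha = 0.05` (the test is standard; the cutoff is our choice). Labels come
from the upper-tail hypergeometric probability of the marker/module overlap;
the label is the largest −log₁₀ p with ties broken by module order.

**Deconvolution.** The chain is: CPM normalization of cells and bulk;
reference matrix = per-state mean CPM; optional per-gene ordinary least
squares of single-cell pseudobulk on observed bulk over individuals profiled
by both assays (slope clipped at 0, zero-variance genes falling back to the
identity); nonnegative least squares per sample; clip-and-renormalize onto
the simplex (simple and idempotent). The overlap transform needs to know
which cells belong to which overlap individual, so `deconvolve()` takes a
`cell_individuals` vector alongside `overlap_ids`; with no overlap
individuals the transform is the identity — the mode used for cohorts with
no matched single-cell data. The per-gene regression is a deliberate
approximation: CPM column factors differ across overlap individuals, so the
tests require it to beat the identity transform under per-gene platform
bias rather than to be exact. Dominant states are the argmax over the four
malignant states only; healthy cell types may appear in labeling but never
in the dominant-state argmax.

## 4. Footprint activity inference

The WMEAN score of a regulator is `Σ wᵢxᵢ / Σ|wᵢ|` over its measured
targets, z-normalized against `n_perm` permutations of the gene labels.
Defaults `n_perm = 1000` and `min_targets = 5` follow common
footprint-inference practice; regulators with degenerate permutation nulls
(sd = 0) score 0 and are flagged rather than dropped silently. Regulon
tables are filtered to confidence grades A–C. The statistic fed to WMEAN is
the per-sample log₂ fold change against a healthy reference
(`log2((CPM + pc)/(mean healthy CPM + pc))`, pseudocount 1) on the
per-sample path, or any signed differential statistic on the cohort path.

Phospho-level activities for cohorts without phosphoproteomics are imputed
as `phos = rna × ref_phos/ref_rna` from a dual-assay reference cohort; the
direction of this ratio rule is a convention, so the inverse is exposed as
`invert = TRUE`. Denominators below `epsilon`
(default 1e-6) are replaced sign-preservingly and flagged. Booleanization
maps positive activity to 1 and everything else — including exactly zero —
to 0.

## 5. Machine-learning transfer and attribution

Training rows are the post-knockout steady states, labeled with their
assigned state; baseline (non-knockout) steady states are excluded by
default (`include_baselines` adds them). The four model kinds ship with
fixed default hyperparameters: elastic-net mixing 0.14 (strength by
10-fold cross-validation), KNN with 13 neighbors on 80 recursively selected
features, random forest with 1000 trees and 35 features per split, boosted
trees with 100 trees, learning rate 0.1, depth 1, subsample 0.1. The KNN
classifier is implemented directly (Euclidean distances, class vote
fractions, deterministic tie-breaks) so that full class-score vectors are
available; its "recursive elimination" is backward elimination ranked by
pooled standardized class-mean separation. Boruta-style all-relevant
selection (shadow features, binomial hit tests, ≤100 random-forest runs) is
wired to the tree models and off by default — depth-1 boosting already
selects features. Bit-flip augmentation of the training rows (default rate
0.05, 10 copies) is available and off by default.

**Attributions.** Per-class Shapley contributions are computed tree by tree:
each tree's value function is the cover-weighted conditional expectation
(unseen splits averaged by child cover — the path-dependent TreeSHAP
quantity), and Shapley values are obtained by exact subset enumeration over
the features that tree splits on, then summed over the ensemble in double
precision. For the depth-1 trees of the default configuration each stump
contributes only through its single split feature, so the computation is
linear in the ensemble size; enumeration is capped at 12 features per tree.
Computing in float64 is what lets the additivity identity
`base + Σ contributions = margin` hold to ~1e-15, where single-precision
library implementations drift to ~1e-6 on hundred-tree ensembles; the tests
nevertheless cross-check both the contributions and the margins against the
boosting library's native TreeSHAP (at float32 tolerance) and against a
brute-force all-feature subset oracle.

**Transition hypotheses.** For a paired primary/recurrent profile whose
predictions differ, a feature is *flipped* if its binary state changed and
its attribution toward the recurrent-state class increased (threshold 0,
configurable). Candidate knockouts are screen rows from the primary state
assigned to the recurrent state whose steady state matches the recurrent
value of at least one flipped feature; for each we enumerate all simple
directed paths (≤ 4 edges by default) from the knocked-out node to the
feature, with the cumulative edge sign (NA if any step carries both signs).
Hypotheses are ranked by flipped features explained, then path length.

## 6. What the synthetic data emulates — and what it does not

`generate_ground_truth_model()` plants attractors constructively: n_states
mutually inhibiting hubs (`hub_s = NOT(OR of other hubs)`) guarantee one
self-consistent configuration per state at any size, and downstream nodes
take their first regulator from the hubs and any others from strictly
earlier nodes, so each hub configuration extends deterministically to a full
fixed point. This guarantees ≥ n_states attractors without rejection
sampling. The cost is structure: real networks have feedback beyond the hub
layer, overlapping modules and near-threshold nodes, so passing recovery
tests here demonstrates correctness of the machinery, not performance on
arbitrary biological topologies.

Count data are negative binomial. Single cells use size 2 (strong
overdispersion typical of UMI data) with a 4-fold elevation of a state's
module genes in its own cells; bulk mixtures default to size 20 — a
biological-replicate dispersion of 0.05, reflecting that bulk tissue
averages over millions of cells and is far less noisy than single cells.
Regulon statistics are linear-additive with Gaussian noise; patient pairs
are profiles with independent bit flips. None of the generators simulate
doublets, ambient RNA, batch effects, compositional library effects or
transcriptome-scale gene counts, and all distributions are explicit artifact
choices recorded in each run's manifest.

All generator randomness flows through one explicit seed per call
(`withr::with_seed`); no global RNG state is touched.

## 7. Problem sizes and numerical choices in the validation suite

The test suite verifies, among others: exact agreement of the synchronous
simulator with exhaustive state-transition-graph attractors on 200 random
sign-consistent models (n ≤ 10, every initial state); fixed-point recovery
of rule synthesis on 100 generated instances (n ≤ 12); exact z-column
moments and Hamming/similarity identities on full screens; noiseless
deconvolution to 1e-6 (at depth 1e9, where integer rounding of generated
counts is negligible against the tolerance) and negative-binomial recovery
at depth 1e6 with mean RMSE < 0.05 over 40 samples; WMEAN detection of a
planted activity (z > 3 in ≥ 99% of 200 seeds at n_perm = 1000) and null
calibration (mean within ±0.1, sd in [0.8, 1.2] over 1000 random regulons);
and classifier transfer. The transfer check trains boosted trees with the
default hyperparameters on a 144-node, 4-state ground truth — the scale of
the merged network those hyperparameters belong to; with `subsample = 0.1`,
each boosting round sees ~13 of the ~130 screen rows, which is the regime
the configuration was designed for, and per-class balanced accuracy on
held-out profiles with 5% bit-flip noise is required to reach 0.9 (observed
0.93–1.00 across seeds). On much smaller models the same subsample leaves
1–2 rows per round and accuracy collapses — a scale mismatch, not a failure
of the method.

`scripts/acceptance.R` re-measures all of these quantities from scratch at a
single seed and writes them as JSON; the README shows how to run it.

## 8. Known limitations

Rule synthesis constrains only the fixed points, not basins of attraction or
transient behavior; different feasible gates can produce different screen
outcomes, and the deterministic enumeration picks one consistent realization.
The truth-table fallback is exponential in regulator count (hence the cap).
The deconvolution overlap transform is a per-gene linear approximation. The
asynchronous mode uses unit flip rates for all nodes. Multi-node knockouts,
gain-of-function clamps and probabilistic per-node rates are out of scope.
Balanced accuracies reported on synthetic ground truth say nothing about
clinical cohorts, which require the corresponding external datasets.
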