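---
title: "Predicting MCI-to-AD conversion with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MCI-to-AD conversion with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcinet)
```

## The problem and the modelling stance

Mild cognitive impairment (MCI) is a precursor phase of Alzheimer's disease
(AD); a minority of MCI patients convert to AD within an 18-month follow-up
window. Cohorts of this kind typically provide a few hundred subjects, a few
hundred continuous candidate markers (structural MRI volumetrics and
thicknesses plus multiplex plasma proteomics), a cognitive severity score
(ADAS-cog, 0–85, higher is worse) and the binary conversion outcome.

`mcinet` treats prediction as inference in a learned discrete Bayesian
network over a small selected marker panel and the conversion indicator.
Compared with a purely discriminative classifier, the network's structure is
a deliverable in its own right: arcs are candidate dependence (potentially
causal) relations among markers and conversion, and the same fitted joint
distribution answers every conditional query exactly.

## Stage by stage

### Cleaning

Markers whose missing-entry fraction exceeds `max_missing` are dropped
before anything else. The threshold defaults to 0.10 — chosen once as a
conservative value that removes a minority of markers in cohorts of this
shape; it is a configuration knob, not an estimate. Remaining missing cells
are filled with the per-marker median of *observed* values. Median
imputation is deterministic, robust to the heavy tails typical of
immunoassay panels, and uses no label information, so it cannot leak outcome
signal. During cross-validation the medians are always computed on the
training fold and applied to the held-out fold.

### Two-stage marker selection

Stage one screens each marker with a one-way ANOVA F-test between
converters and non-converters and keeps `P < alpha` (default 0.05). The
screen is intentionally *not* multiplicity-corrected — it is a
recall-oriented filter whose false positives are cheap (later stages remove
them), while a family-wise correction at several hundred markers would cost
real signal. A Benjamini–Hochberg switch exists for users who want it. The
degenerate zero-variance case (F = 0/0) is reported as `p = 1` with a
warning rather than `NA`, so downstream set arithmetic stays total.

Stage two regresses the ADAS-cog score on the screened markers under an L1
penalty,

$$\min_\beta \tfrac12\,\lVert y - X\beta\rVert_2^2 + \lambda\,\lVert\beta\rVert_1 ,$$

and keeps the markers with nonzero coefficients. The full solution path is
computed by least angle regression with the lasso modification: the path is
piecewise linear in $\lambda$, predictors enter at equiangular knots and
leave when a coefficient crosses zero. Markers are standardized internally
(the penalty must act on comparable scales) and coefficients are reported on
the original scale. $\lambda$ is chosen by 10-fold cross-validation over the
path, minimizing squared prediction error, with a fixed-$\lambda$ escape
hatch; CV is the standard, reproducible default when no external choice is
available. The test suite verifies the path against an independent
coordinate-descent solver (`glmnet`) at twenty penalties per design and
against the orthogonal-design soft-threshold closed form
$\beta(\lambda) = \operatorname{sign}(b)\max(|b|-\lambda,0)/\sum x^2$.

Using the cognitive-severity score, rather than the conversion label, as the
stage-two response is the design's semi-mechanistic move: it keeps markers
that track disease severity even where the binary outcome is noisy. The raw
ADAS-cog score is used as the response.

### Discretization

Structure learning and inference are discrete. Each selected marker is cut
at training-sample quantiles into `bins` bins (default 3). Tertiles balance
resolution against conditional-probability-table sparsity at n ≈ 300: with
three bins a node with two parents already has 27 cells. Markers with too
few distinct values fall back to fewer bins with a warning; values outside
the training range map to the extreme bins, so test-time application is
total. Cut points are always fitted on training subjects only.

### Structure learning (MMHC)

The max-min hill-climbing algorithm combines a constraint-based skeleton
with score-based orientation:

* **Skeleton (MMPC).** Candidate parent–children sets grow by the max-min
  heuristic — add the variable whose *weakest* association with the target
  over all conditioning subsets of the current set is strongest — and shrink
  by conditional-independence removal, then are symmetrized with the AND
  rule. Associations are G² likelihood-ratio tests with
  df $=(r_X-1)(r_Y-1)\prod_i r_{Z_i}$; a test with fewer than `5 * df`
  observations is declared unreliable and treated as independence, the
  standard heuristic guarding against vacuous rejections in sparse tables.
  Conditioning sets are capped at 3 variables (`max_sx`), which is exact for
  the graph sizes this pipeline produces.
* **Search.** Greedy add/delete/reverse hill climbing maximizes a
  decomposable score — BDeu with equivalent sample size 1 by default (the
  score MMHC was originally evaluated with), BIC as an alternative — with
  additions restricted to skeleton pairs. Every tie (max-min association,
  equal-score moves, min-fill) is broken lexicographically, and the only
  randomness anywhere in the package flows from explicit seeds, so structure
  learning is fully reproducible. Acyclicity is checked after every move.

The conversion node participates as an ordinary node — no edges are forced
into or out of it. Markers left with degree 0 are pruned (and reported);
a model whose *conversion node* is isolated is rejected, since it would
predict the prior for everyone.

### Exact inference

CPTs are fitted with Dirichlet-uniform smoothing,
$\hat p_{jk} = (n_{jk} + s/(rq))/(n_j + s/q)$ with `ess` $s$ (default 1), so
unseen parent configurations fall back to uniform rather than 0/0.
Conversion posteriors are computed on a junction tree: moralize,
triangulate by min-fill, take the maximal elimination cliques, join them by
a maximum-spanning tree on separator sizes, and calibrate with two-pass
(Shafer–Shenoy) sum-product message passing. Messages are a pure function of
the initial potentials, so recalibration is idempotent to machine precision.
Evidence enters as likelihood findings; evidence with zero probability under
the fitted joint raises an explicit error. At prediction time a subject's
available discretized markers are entered as evidence and any marker missing
from the subject or absent from the network is simply omitted — the tree
marginalizes it, which is the exact treatment under the fitted joint.
The randomized test suite holds the tree to total-variation distance
< 1e-10 against brute-force enumeration of the joint.

### Evaluation

Folds are stratified by default: with ~99 converters across 10 folds,
unstratified splitting risks converter-free folds. Fold sizes differ by at
most one, per-fold class counts likewise. Everything — imputation, both
selection stages, discretization, structure, CPTs — is refitted inside each
training fold by default, because global selection before cross-validation
leaks test information into the marker panel; a `selection = "outside"`
switch reproduces the global-selection design when fidelity to that
protocol matters. A fold that learns no predictive structure is flagged and
its held-out subjects are scored with the training prevalence, keeping the
out-of-fold probability vector total. ROC curves sweep the unique scores;
AUC is the trapezoid area and equals the normalized Mann–Whitney statistic
with half-credit ties, which the tests assert to 1e-12. The default
classification threshold on the posterior is 0.5.

### Disruption profiling

Subjects are ranked by predicted conversion probability and split into a
high-risk and a low-risk group (defaults 11 and 48, the subgroup sizes used
in cohorts of this size; ties at a boundary break by subject id). The
markers separating the groups (ANOVA, `P < 0.05`) form the profile panel.
Each high-risk subject's panel values are z-scored against the low-risk
("reference") group's mean and sample SD; for the reference subjects
themselves the z-scores are computed leave-one-out, since scoring a subject
against statistics containing its own values shrinks its deviations and
would bias the group comparison (the permutation test in the suite verifies
the comparison is calibrated under random relabelling). For a state vector
$z$ over $m$ panel markers:

$$K = \left|\tfrac1m\textstyle\sum_i z_i\right|, \qquad
\Phi = \sqrt{\tfrac1m\textstyle\sum_i (z_i-\bar z)^2}, \qquad
U = \sqrt{\tfrac1m\textstyle\sum_i z_i^2},$$

so $K$ captures the consistent (same-direction) multi-marker shift, $\Phi$
the inconsistent dispersion, and $U$ responds to both, with the exact
identity $U^2 = K^2 + \Phi^2$. The originating formulation of these three
parameters is only characterized verbally in the sources available to this
package, so this decomposition was chosen as the implementation: it is
dimensionless,
satisfies every verbally stated property (comprehensive / consistent /
inconsistent, regular reference polygon), and is exactly testable. Whether
the original weighs markers by network topology is unknown; this
implementation weighs them equally. The signed mean is reported alongside
$K$ so directionality is not lost. The balance-map export divides each
group's marker means by the reference means, putting the reference group at
1 on every axis — a regular polygon on a radar plot, whose deformation
visualizes disruption.

Two calibration caveats are deliberate: panel selection by the *same*
high/low contrast being profiled makes the subsequent U/Φ comparison
anti-conservative under the null (the panel is enriched for chance
differences), which mirrors the two-step design this module implements; the
permutation test therefore profiles over the full panel. And the low-risk
group is the reference because cohorts of this design include no cognitively
normal arm.

## The synthetic cohort generator

`cohort_spec()` defaults encode the target study conditions: 316 subjects
with converter fraction 99/316, 200 markers of which 10 are informative,
10% of marker columns carrying 5% missing entries (missing completely at
random — no mechanism being specified, MCAR is the choice that keeps the
ANOVA screen unbiased), and an ADAS-cog score calibrated so expected group
means are 22.36 (converters) and 16.94 (non-converters), clipped to
[0, 85].

Informative markers are generated from a discrete-latent ground truth:
conversion is a Bernoulli root, each informative marker has a binary latent
state with $P(S{=}1) = 0.9$ under conversion and $0.1$ otherwise, and the
observed value is Gaussian around a state-dependent mean. The gap between
state means is calibrated so the observed between-label Cohen's d equals
`effect_size` exactly in expectation (the mixture variance caps attainable
d below ≈ 2.67). The latent-discrete construction is what makes structure
recovery and discretization testable: the generating DAG has a well-defined
CPDAG, and the continuous jitter exercises the quantile binning. The default
effect size is 1.0 — comparable to the separation the ADAS-cog score itself
shows between converters and non-converters (≈ 1.15) and realistic for the
stronger MRI markers. ADAS noise SD defaults to 4.2 score points, which
reproduces within-group SDs near the 4.56/4.84 reference values.

What the generator does *not* emulate: FreeSurfer region-volume scales and
covariance, immunoassay dynamic ranges and floor effects, inter-marker
correlation beyond the shared conversion parent, age/sex structure, and
informative missingness. Passing tests on this generator therefore
demonstrate algorithmic correctness and signal recovery under the stated
statistical structure — not clinical performance on real cohort data.

## Numerical and reproducibility choices

* All tie-breaks are lexicographic; one global seed fans out to per-stage
  seeds through a fixed counter; reruns of `run_all()` with the same config
  are byte-identical.
* Problem sizes in the tests and the acceptance script — 100 random
  networks of ≤ 8 binary nodes against enumeration, 50 random 30×8 lasso
  designs, 20 structure-recovery replicates at n = 5000, one 300-subject
  end-to-end cohort with 50 markers — were chosen so the entire suite
  exercises every stage at full depth while remaining a desk-scale
  computation.
* Headline clinical performance figures reported for models of this design
  on controlled-access cohort data are not reproduction targets here: they
  depend on data this package does not ship. The acceptance script instead
  recomputes the
  package's own verifiable quantities (oracle agreement, recovery rates,
  synthetic-cohort operating characteristics).

## Known limitations

* Only discrete networks: continuous markers must pass through quantile
  binning, which discards within-bin information.
* No hybrid or Gaussian networks, no approximate inference (unnecessary at
  these sizes), no bootstrap model averaging of structures.
* The lasso stage offers no elastic-net or stability-selection variants.
* The disruption decomposition is one defensible reading of a partially
  specified statistic (see above); conclusions that depend on topological
  weighting of markers are outside its scope.
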