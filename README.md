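# mcinet

Predicting conversion from mild cognitive impairment (MCI) to Alzheimer's
disease (AD) from continuous MRI and plasma biomarker panels, with a
semi-mechanistic discrete Bayesian network — and profiling the
network-balance disruption of the highest-risk patients.

`mcinet` is aimed at researchers working with MCI cohorts (a few hundred
subjects, several hundred candidate markers, an ADAS-cog score and an
18-month conversion outcome) who want a prediction model whose structure is
itself interpretable: a learned graph of dependencies among markers and the
conversion state, rather than a black-box classifier.

## The method

1. **Cleaning** — markers with more than a configurable fraction of missing
   entries (default 10%) are dropped; the rest are median-imputed.
2. **Two-stage marker selection** — a one-way ANOVA F-test per marker
   between converters and non-converters keeps markers with `P < 0.05`;
   an L1-penalised (lasso) regression of the ADAS-cog score on the
   survivors, solved exactly by least angle regression (LARS) with the
   lasso modification, keeps the markers with nonzero coefficients. The
   penalty is chosen by 10-fold cross-validation on squared prediction
   error. The objective is

   `min_b (1/2) * || y - X b ||^2 + lambda * || b ||_1`

3. **Structure learning** — selected markers are discretized into quantile
   bins (tertiles by default) and a Bayesian network over the markers plus
   the binary conversion node is learned with max-min hill-climbing (MMHC):
   a G-squared conditional-independence skeleton phase (max-min
   parents-children) followed by BDeu-scored greedy search restricted to
   that skeleton. Markers that fail to connect to the network are removed.
4. **Exact inference** — conditional probability tables are fitted with
   Dirichlet-uniform smoothing and conversion posteriors
   `P(convert | markers)` are computed exactly on a junction tree
   (moralization, min-fill triangulation, clique-tree message passing).
5. **Evaluation** — stratified 10-fold cross-validation with every stage
   (imputation, selection, discretization, structure, parameters) refitted
   inside each training fold; ROC, AUC, accuracy, sensitivity, specificity.
6. **Disruption profiling** — subjects are split into a high-risk and a
   low-risk group by predicted probability; each high-risk subject's marker
   panel is z-scored against the low-risk (reference) group, and three
   network-balance parameters summarize the deviation vector `z`:
   `K = |mean(z)|` (consistent shift), `Phi = population sd(z)`
   (inconsistent dispersion), `U = rms(z)` (comprehensive), with the exact
   identity `U^2 = K^2 + Phi^2`.

A synthetic-cohort generator with a known ground-truth network, known
informative markers and an ADAS-cog score calibrated to reference MCI group
means (converters 22.36, non-converters 16.94) makes every stage testable
against a recoverable truth.

## Worked example

```r
library(mcinet)

spec <- cohort_spec(n_subjects = 300, n_markers = 50, n_informative = 10,
                    effect_size = 1.2, seed = 11)
cohort <- generate_cohort(spec)
print(cohort$table)
#> marker_table: 300 subjects x 50 markers
#>   converters: 81 / 300 (27.0%)
#>   missing entries: 66
#>   ADAS-cog: mean 18.68 (converters 22.09, non-converters 17.42)

cv <- cross_validate(cohort$table, cv_config(seed = 5))
round(c(auc = cv$roc$auc, acc = cv$metrics$accuracy,
        sens = cv$metrics$sensitivity, spec = cv$metrics$specificity), 3)
#>   auc   acc  sens  spec
#> 0.894 0.840 0.605 0.927
```

The out-of-fold AUC of 0.894 says the learned networks rank a random true
converter above a random non-converter 89% of the time; at the default 0.5
posterior threshold the model is conservative (specificity 0.927,
sensitivity 0.605), as expected with a 1:2 class imbalance.

End-to-end runs write all artifacts (selection funnel, DAG as JSON/DOT,
metrics, disruption profile, manifest) to a directory:

```r
run_all(run_config(simulate = list(n_subjects = 300), seed = 1,
                   out_dir = "run1"))
```

A thin command-line front end is installed at `inst/cli/mcinet`
(`mcinet run-all --seed 1 --out_dir run1`).

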