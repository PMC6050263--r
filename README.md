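# endofactor

Mixed-membership neurobiological factors from resting-state connectivity
fingerprints.

Categorical psychiatric diagnoses often sit awkwardly on top of brain
biology: distinct diagnostic groups share large-scale network dysfunction,
and one diagnosis can cover several neural presentations. `endofactor`
derives *brain-defined* phenotypes from functional-connectivity
fingerprints — the vector of Pearson correlations between all pairs of
nodes in a fixed network (210 edges for the default 21-node default-mode /
dorsal-attention / salience network) — and validates them against
categorical labels without circularity. It is aimed at computational
psychiatry and connectomics researchers who want a fully testable,
simulation-backed implementation of this modelling chain.

The core model is hierarchical:

1. **Indian Buffet Process latent-feature model.** Fingerprints follow the
   linear-Gaussian model `X = Z A + E` with binary assignments `Z` under an
   IBP prior, so the number of hidden connectivity properties `K` is
   inferred, not fixed. Inference is collapsed Gibbs sampling (loadings
   integrated out analytically), with Metropolis–Hastings feature
   births/deaths, grid resampling of the noise and loading scales, a
   conjugate update for the IBP concentration, and restart-based selection
   of the maximum-posterior sample.
2. **Latent Dirichlet allocation.** Subjects are documents whose tokens are
   their active properties; `k` factors (default 3) give each subject a
   weight vector `theta` on the simplex (mixed membership) and each factor
   a property distribution `phi`, renderable as an edge-weight map
   `W = phi %*% A`.
3. **Pre-validation.** `m = 10` stratified splits; each subject's factor
   weights and dominant-factor label are inferred by an internal model
   trained only on the other splits, so the labels can be used downstream
   as if measured on an independent cohort.
4. **Evaluation.** One-vs-rest linear SVMs (cost 1, fold-wise
   standardization from training data only) quantify how predictable the
   brain-derived labels and the categorical labels are from fingerprints;
   fold-accuracy distributions are compared with Welch t-tests; factor
   weights are correlated with symptom scores.

A synthetic-cohort generator plants exactly this structure (binary
properties, factor layer, site offsets, noise, and clinical labels that are
40%-corrupted dominant-factor labels) so that every stage is validated
against ground truth without any data download.

## Worked example

```r
library(endofactor)

cfg <- run_config(
  synthetic   = synthetic_config(),          # standard cohort
  ibp         = ibp_config(n_sweeps = 300, burn_in = 150, n_restarts = 2),
  lda         = lda_config(k = 3),
  global_seed = 1)                           # m = 10 pre-validation splits
report <- run_full_pipeline(cfg)
print(report)
```

```
endofactor pipeline report
  subjects: 600   edges: 210   hidden properties: 18   factors: 3
  classification experiments (mean +/- sd %, chance 33.33%):
    biolabel_from_fingerprint               91.00 +/- 2.96
    clinical_from_fingerprint               41.83 +/- 5.47
    clinical_from_fingerprint_plus_theta    41.00 +/- 4.66
    clinical_from_theta_only                51.67 +/- 5.21
  biolabel vs clinical: t = 25.00, p = 6.3e-13
```

Reading the output: the sampler discovered 18 hidden connectivity
properties (15 were planted); compressed to three factors, the resulting
pre-validated brain-derived labels are far more predictable from
connectivity (91.0%) than the 40%-corrupted categorical labels are
(41.8%) — the difference a Welch t-test puts at p ≈ 6e-13. Adding the
three factor weights to the fingerprints leaves the mean accuracy
statistically unchanged (41.0%, p = 0.72) while shrinking the spread of
the fold accuracies (5.47 → 4.66), and the three factor weights alone
(51.7%) carry at least the categorical-label signal of all 210 edges.
That is the package's synthetic mirror of the findings that brain-derived
phenotypes out-predict categorical diagnoses, that factor weights make
individual predictions more reliable rather than more accurate on
average, and that a handful of numbers per subject suffices. (In this
idealized generative world the factor weights are a *sufficient* summary,
so the theta-only experiment overshoots the raw-edge accuracy instead of
matching it; the methods vignette discusses why.)

`write_report(report, "out/")` writes a JSON summary plus TSV tables
(per-fold accuracies, factor–score associations, property occurrence by
group, pre-validated labels).

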