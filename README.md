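# phenodec

Deep-learning phenotype discovery and comparative effectiveness for
rheumatoid arthritis (RA) treatment registries.

RA is heterogeneous: patients starting their first biologic or targeted
synthetic DMARD (b/tsDMARD) differ widely in serostatus, disease burden,
co-medication and demographics, and may respond differently to individual
agents. `phenodec` implements an analysis chain that

1. **clusters** patients at cohort entry (start of the first b/tsDMARD) with
   *deep embedded clustering* (DEC) on the latent space of a
   missingness-adaptive autoencoder — no imputation; masked entries
   contribute nothing to the representation;
2. **profiles** each cluster, marks its most extreme characteristics
   (highest/lowest value per feature within a run), and groups the clusters
   from all runs (k ∈ {3, 4, 5} × two feature specifications = 24 clusters)
   into phenotype groups by signature similarity;
3. **estimates comparative effectiveness** of b/tsDMARDs within every
   cluster with Cox proportional-hazards models (reference: TNF inhibitors
   at class level, adalimumab at drug level) for two outcomes —
   discontinuation for non-response, and a ≥20% DAS28-esr reduction as a
   response proxy — within 15 months of follow-up;
4. **filters findings for robustness**: a result is only reported when it is
   significant with a consistent direction in the majority of a group's
   clusters; and
5. **validates** the surviving findings in clinically interpretable strata
   (e.g. "≥2 csDMARDs and prednisone", "men", "low disease burden") with
   age- (and sex-) adjusted Cox models.

Because clinical registries cannot be redistributed, the package ships a
**synthetic registry generator** that plants five known patient phenotypes
and a known group-by-drug treatment effect, so the entire chain — from
eligibility filtering to stratified validation — is testable end to end.

## The models

**Masked autoencoder.** Each patient is a pair `(x, m)` of feature values
and an observation mask. The first encoder layer computes
`a = ((x ⊙ m) W) · d/Σm + b`, so unobserved entries contribute exactly
nothing and the pre-activation scale is comparable across missingness
levels; reconstruction loss is the MSE over observed entries only.

**DEC.** With latent points `z_i` and centroids `μ_j`, soft assignments use
the Student-t kernel `q_ij ∝ (1 + ‖z_i − μ_j‖²/α)^−(α+1)/2` (α = 1), the
self-sharpening target is `p_ij ∝ q_ij²/f_j` with cluster frequency
`f_j = Σ_i q_ij`, and encoder and centroids are trained against
`KL(P‖Q) = Σ_ij p_ij log(p_ij/q_ij)`, with centroids initialized by k-means
and convergence declared when fewer than 0.1% of hard labels change between
target refreshes. Cluster quality is tracked with the mean silhouette score.

**Survival models.** Crude (and in validation, age/sex-adjusted) Cox
partial-likelihood fits with Efron tie handling; Wald 95% CIs; estimates
with fewer than 5 events at an exposure level are suppressed.

## Worked example

```r
library(phenodec)

res <- run_pipeline(pipeline_config(seed = 1,
                                    sim = sim_config(n_patients = 1500)))
res
```

```
Pipeline run (seed 1, config f58012f565e4270cd3ca73f2199d5d19)
  1500 patients simulated, 1500 eligible
  6 clustering runs, 24 clusters, grouped into 5 groups
  grouping purity vs planted phenotypes: 0.917

Group signatures:
  group 1 (7 clusters): bmi highest, das28 highest, family_history highest,
    leflunomide lowest, pain_vas highest, sex_male highest, sf12_phys lowest,
    smoking_ever highest, sulfasalazine lowest, tender highest
  ...

Robust findings (356 unsuppressed cluster-level estimates tested, no multiplicity correction):
  group 1, response20, non-TNFi (class): benefit in 5/7 clusters, HR 1.67-1.73
  group 1, response20, tocilizumab (drug): benefit in 6/7 clusters, HR 2.49-3.69
  ...

Stratified validation:
  group1: response20 non-TNFi (benefit) -> confirmed (adjusted HR 1.68)
  group1: response20 tocilizumab (benefit) -> confirmed (adjusted HR 3.48)
  ...
```

Reading this: the synthetic cohort plants a male phenotype in which
tocilizumab triples the response hazard relative to adalimumab. The male
clusters found by DEC carry a significant tocilizumab benefit in 6 of the
group's 7 clusters (HR range shown), the robustness filter reports it, and the
derived "men" stratum confirms it with an age-adjusted Cox HR — the same
reporting shape used for a real registry. `grouping purity` measures how
faithfully the 24 clusters regroup into the five planted phenotypes.

Individual stages are exported too:

```r
reg  <- simulate_registry(sim_config(n_patients = 1500, seed = 1))
coh  <- select_cohort(reg)                  # eligibility + entry DAS28
f1   <- build_features(reg, coh, feature_spec(1))
ae   <- pretrain(f1, ae_config())           # masked autoencoder
run  <- train_dec(f1, ae, dec_config(k = 5))
glance(run)                                 # k, silhouette, convergence
autoplot(run)                               # latent space scatter
```

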