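---
title: "Methods: masked-autoencoder DEC and cluster-level comparative effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-autoencoder DEC and cluster-level comparative effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models implemented in `phenodec`, the choices
made where the design was genuinely open, and what the synthetic-registry
tests do and do not demonstrate about real data.

## The analysis chain

Patients enter the cohort at the start of their first b/tsDMARD.
Eligibility requires a first treatment on or after the first recorded visit
and a DAS28-esr measurement in the closed window `[entry − 183, entry]`
days. Months are fixed-day conventions throughout: 6 months = 183 days,
15 months = 456 days; records on the entry day count as in-window.

Two feature specifications feed the clustering. Both use three lookback
classes: *ever before* (demographics, lifestyle, serostatus, disease
duration), *at entry* (csDMARD and prednisone flags — an episode must span
the entry day), and *6-month window* (disease activity, laboratory and
patient-reported measures — most recent value within 183 days, otherwise
masked). Specification 2 additionally carries, for every window feature, a
recency channel `(days since measurement)/183 ∈ [0, 1]`, masked with its
parent. Two-level categoricals are one-hot encoded and a missing category
masks the whole block, so the autoencoder's masking mechanism handles
missing categories and missing measurements uniformly. All channels are
standardized over observed values; masked positions store a sentinel 0 that
is never read as data — the mask is authoritative, and tests fuzz the
sentinel to prove it.

## Missingness-adaptive autoencoder

Clinical registry features are incompletely observed (in the emulated
cohort, from ~4% for rheumatoid factor to ~32% for family history).
Imputation before clustering injects fabricated values precisely where data
are weakest. Instead the autoencoder consumes `(x, mask)` pairs:

* masked entries are zeroed before the first layer, so they contribute
  exactly nothing to any activation;
* the first-layer pre-activation is rescaled by `d / (number observed)` per
  sample, keeping its magnitude comparable between a patient with 90% and
  one with 50% observed channels;
* the reconstruction loss is the mean squared error over observed entries
  only.

With no missingness this reduces bit-for-bit to a standard forward pass.
The default architecture is `d – 64 – 32 – 10` with ReLU hidden activations
and linear latent/output layers, trained with Adam (learning rate 1e-3,
batch 256, 100 epochs) — a small network chosen for a cohort of a few
thousand patients and a few dozen channels; all widths are configuration.
Training is seeded and deterministic on a single-threaded BLAS; a tolerance
of 1e-6 is documented for environments with non-deterministic reductions.

## Deep embedded clustering

DEC jointly refines the encoder and a set of latent centroids. Soft
assignments use the Student-t kernel with α = 1 (the conventional default;
α is configurable), the target distribution squares and renormalizes the
assignments (sharpening each row toward its dominant cluster while the
frequency term discourages degenerate solutions), and both encoder and
centroids take Adam steps against `KL(P‖Q)`. Choices:

* centroids are initialized by k-means on the initial embeddings (20
  restarts, seeded);
* the target `P` is refreshed every 5 gradient steps; training stops when
  fewer than 0.1% of hard labels change between refreshes, or after 200
  refreshes;
* hard-label ties break toward the lowest cluster index;
* a cluster that empties at a refresh is re-seeded at the point farthest
  from its nearest centroid (logged);
* silhouettes are computed in the latent space for DEC and in the imputed
  raw space for the k-means baseline — each method is scored in the space
  it optimizes.

The run design is one DEC run per (feature specification, k) with
k ∈ {3, 4, 5}: six runs, 24 clusters. The deliberate overlap between runs
is what the robustness filter later exploits — similar but not identical
clusterings act as a form of resampling.

## Cluster profiles, grouping, and strata

Profiles summarize *raw* (unstandardized) values over observed entries
only. Within each run, the cluster(s) attaining the maximum (minimum) of a
feature are marked "highest" ("lowest"); ties flag all tied clusters. The
24 clusters are then grouped by average-linkage agglomeration on the
Jaccard similarity of these signatures, cut at five groups. The original
analysis grouped clusters by visual inspection; automating it makes the
step reproducible, and merging ties break toward the lexicographically
smallest pair so the grouping is order-invariant. A manual override (an
explicit cluster-to-group map) can replace the automatic grouping.

Stratum derivation maps each group's consensus signature through a
threshold library of atomic clinical conditions (DAS28-esr > 5.1 or ≤ 3.2,
HAQ > 1.5 or < 0.7, pain/activity VAS > 6 or < 4, duration > 8 years,
csDMARD count ≥ 2, prednisone use, sex, serostatus). Two rules keep chance
extremes out of strata, operationalizing "most distinct characteristics":
a signature element must be shared by at least two thirds of the group's
member clusters, and the disease-burden OR-composite enters only when at
least two burden measures point the same way. Atoms sharing an OR group are
disjunctive; everything else is conjunctive. When a stratum predicate
touches a missing value the atom is false, but the patient can still
qualify through other OR branches — a conservative inclusion rule whose
excluded counts are logged.

## Comparative effectiveness and the robustness filter

Survival records run from entry to at most 456 days. For non-response, the
event is discontinuation with a physician-recorded non-response reason;
discontinuation for any other reason censors. For response, the event is
the first post-entry visit with DAS28-esr at or below 80% of the entry
value (the boundary counts); any discontinuation censors. End of record
censors both.

Cox fits use Efron tie handling (the least-biased of the standard choices
for tied event days) and Wald 95% intervals. Exposure coding is either
drug class (reference: TNF inhibitors) or individual drug (reference:
adalimumab). Estimates at exposure levels with fewer than five events are
suppressed rather than reported — small-count estimates from partial
likelihoods are unstable — and fits that fail or degenerate are suppressed
with a diagnostic rather than raised. Significance is an unadjusted 95% CI
excluding 1, matching the descriptive, hypothesis-generating character of
the analysis; the number of fitted families is recorded so a reader can
judge multiplicity.

The robustness filter reports a (group, outcome, exposure, direction)
result only when it is significant with a consistent direction in **more
than half** of the group's clusters. "Majority" is the operational reading
chosen here (the alternative, "all clusters", is stricter than the
described reporting and fails whenever a single small cluster suppresses);
the rule is monotone: adding a non-significant cluster to a group can only
weaken or preserve a finding, never create one.

Validation refits each stratum crude and age-(and sex-)adjusted, with age
linear (no functional form is prescribed by the underlying description; a
linear term is the parsimonious default at these sample sizes) and sex
omitted in sex-restricted strata (collinearity guard, asserted in tests).
A finding is *confirmed* when the adjusted estimate is significant in the
same direction, *inestimable* when suppressed, otherwise *not confirmed*.

## The synthetic registry

The generator emulates a first-b/tsDMARD RA cohort: ~76% women, mean age
55, mean DAS28-esr 4.3 at entry, two thirds on methotrexate, and
feature-level missingness at realistic rates (e.g. 27% missing ACPA, 32%
missing family history), applied as independent per-feature masking (MCAR)
after value generation — the marginal rates are known, the mechanism is
not, so the simplest mechanism is the default and a group-dependent variant
can be configured through the profiles. Five latent phenotypes are planted,
mirroring the structure such analyses recover: (1) combination-therapy
patients with high csDMARD and prednisone use; (2) men, with more smoking
and higher BMI; (3) seronegative patients with little prednisone use;
(4) seropositive patients with high disease burden and long duration; and
(5) patients with low disease burden. Within-group dispersions are chosen
so the phenotypes are coherent — the target of the emulation is a registry
in which clustering *can* recover near-pure groups (the emulated analysis
found clusters that were >99% male or >99% RF-negative), while cohort-level
marginals stay at their published values.

Event times are exponential per outcome with hazard
`baseline × exp(log HR[group, drug, outcome])`, so planted hazard ratios
are exact under the downstream Cox model. The default plants a single
differential effect — tocilizumab triples the response hazard in the male
phenotype — against baseline hazards sized by a power calculation: a
reference-arm response fraction of about one third by day 456 gives a
~300-patient cluster roughly 90% power to detect the diluted planted
effect. Other-cause discontinuation (3e-4/day), registry dropout
(1e-4/day) and an administrative horizon (600 days) provide censoring.
Routine follow-up visits fluctuate above the response threshold so only
the planted event time triggers a response.

**What the synthetic tests show — and don't.** They demonstrate that the
implementation recovers planted structure and planted effects through the
full chain at realistic marginals, missingness and event counts. They do
not demonstrate that real RA registries contain such phenotypes: real
feature correlations, informative visit processes, calendar-time
prescribing trends, and confounding by indication are all absent by design
(treatment assignment is independent of phenotype by default, which is why
crude and adjusted estimates coincide in the simulator's balanced mode).

## Problem sizes and determinism

The bundled tests exercise the end-to-end pipeline at n = 1500 patients
(about half the emulated cohort) across 10 master seeds, DEC
planted-partition recovery at n = 1500, Cox calibration on 200 simulated
clusters, and HR-2 recovery at n = 2000 over 20 seeds — sizes at which
every documented property is stable on a single desktop core. One master
seed derives every stage seed through fixed offsets; re-running a pipeline
with the same configuration reproduces all artefacts, and each artefact
carries the configuration hash.

## Known limitations

* The grouping automates a step that was originally expert judgement;
  Jaccard similarity on rank-1 extreme signatures is one reasonable
  operationalization, and the consensus-support thresholds (2/3, two
  burden atoms) are implementation choices exposed as parameters.
* The suppression threshold (5 events) is a single cutoff; real reporting
  decisions can be more nuanced.
* MCAR masking understates the difficulty of informative missingness.
* The autoencoder is a fixed-width architecture, not an adaptively grown
  one; its contract (no imputation, masking invariance, per-sample fan-in
  rescaling) is what the tests pin down.
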