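---
title: "Individual-specific functional network mapping: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific functional network mapping: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmapr)
```

## The problem

Group-average functional connectivity (FC) obscures how cortical network
topography varies across individuals, especially in early development where
anatomically matched regions can express different connectivity profiles.
netmapr implements a precision-mapping pipeline for this setting:

1. **Templates.** Each scan session yields a parcel-by-parcel Pearson FC
   matrix. Every row — a parcel's profile of correlations to all P parcels —
   is one sample. Profiles from all sessions are concatenated and clustered
   with k-means under correlation distance (1 − r); the K cluster centroids
   are age-appropriate *network templates*. Reproducible patterns can emerge
   even when present in only a subset of children.
2. **K selection.** Sessions are split in half 20 times; each half is
   clustered independently at each K, labels are cross-predicted from the
   other half's centroids by maximum correlation, and agreement is scored
   with normalized mutual information (NMI). The stability curve's local
   peak selects K.
3. **Individual mapping.** Each vertex's profile of correlations to all
   parcels is compared with every template; the vertex joins the network
   with the highest Pearson correlation (winner-take-all). No magnitude
   threshold or distance exclusion: weak and anticorrelated edges carry
   signal.
4. **Reliability and population structure.** Split-half and longitudinal
   NMI (within vs between subjects, permutation nulls, data-amount
   titration); per-vertex spatial probability, modal consensus, agreement
   and versatility; thresholded consensus maps.
5. **Network-level statistics.** Within-network FC under individualized vs
   consensus topography (paired t, Benjamini–Hochberg FDR), surface-area
   laterality, silhouette separation, spatial-probability × FC similarity to
   prior network sets, linear mixed-effects models of laterality against age
   and developmental quotients, and subject-grouped cross-validated ridge
   prediction of age.

Real infant datasets of this kind are access-restricted, so the package
carries a first-class synthetic-cohort generator with planted ground truth;
every claim the test suite makes is a claim about recovery of known
structure.

## Preprocessing model

Head motion is summarized by framewise displacement (FD): the L1 norm of
backward-differenced realignment parameters, rotations converted to arc
length on a 50 mm sphere (the conventional radius; the source convention
leaves it implicit). Fast-TR infant acquisitions alias respiration into the
realignment traces, so the six parameters are notch-filtered (0.27–0.5 Hz
by default) before differencing. The notch is a second-order Butterworth
bandstop obtained by bilinear transform with prewarping and applied
forward–backward (zero phase); no suitable filter-design package is
available in the supported environment, so the biquad is implemented here
and unit-tested against its analytic frequency response. Parameters are
demeaned before filtering — FD depends only on differences, and this makes
FD exactly invariant to constant parameter offsets despite filter edge
transients. The first frame's FD is 0 by convention.

Censoring retains frames with FD < 0.2 mm, only in runs of ≥ 3 consecutive
retained frames, after dropping the first 5 frames. Empty retention is a
valid outcome and surfaces as explicit insufficient-data errors downstream.

## Clustering choices

Correlation-distance k-means operates on row-standardized profiles (center,
unit norm), where Pearson r is a dot product; the centroid update is the
renormalized mean direction, which makes the 1 − r objective provably
non-increasing — asserted on every replicate. Initialization is k-means++;
the final template fit takes the best of 1000 restarts. The stability sweep
clusters 2 × 39 × 20 half-cohorts, so it uses 5 restarts per fit: the
sweep needs the *ranking* of K values, not the global optimum of each fit,
and the reported curves are insensitive to more restarts. Centroids are
canonically ordered by descending cluster size. Empty clusters are
re-seeded with the worst-fit samples; persistent emptiness is an error, not
a silent drop.

**Choosing K.** Local maxima of the mean-NMI curve are reported with the
curve itself (endpoints of the sweep are not eligible — a peak must decline
on both sides). The default `chosen_k` policy takes the local maximum with
the highest mean NMI, breaking ties toward higher K. A policy preferring
the highest-K local maximum above the curve's median was tried first and
proved fragile: past the true peak the curve declines by only ~10^-3 NMI
per K, and seed-level wiggles create spurious high-K "maxima" that such a
policy selects. Both policies (and a plain global maximum) remain available
in the configuration.

A caveat the synthetic experiments expose: because each profile retains its
self-correlation entry (exactly 1 at the parcel's own position), splitting
a true network by parcel identity is *consistent* across halves, so the
stability curve declines only gently after the planted K and the peak can
land one or two clusters above it. At the scaled-down acceptance geometry
(20 sessions × 100 parcels, 23 planted patterns) the recovered peak sits at
23–25 depending on the seed. Dropping self-entries is exposed as a mapping
flag (`exclude_self_parcel`), default off to match the all-parcel profile
definition.

## NMI conventions

NMI = 2·I(A;B)/(H(A)+H(B)) (arithmetic-mean normalization). If either
partition has zero entropy the value is 0, unless both are the same trivial
single-cluster partition (then 1). Excluded (NA) vertices are dropped
pairwise. The permutation null shuffles one labeling's vertex order,
preserving cluster sizes; its analytic expectation,
(K_A−1)(K_B−1)/(2N) nats over the mean entropy, is used as an independent
oracle in tests. For 23-network partitions of 59,412 vertices the null mean
is ≈ 0.0013 — two orders of magnitude below observed within-subject
reliability, which is the point of reporting it.

## The synthetic world

The generator states one world and the tests live in it:

* **Surface**: vertices split evenly between hemispheres; parcels are
  contiguous index ranges with mildly varying sizes; per-vertex areas are
  log-normal (median ≈ 2.7 mm², the fs_LR-32k order of magnitude). No mesh
  geometry exists; "adjacency" means neighboring vertex indices within a
  hemisphere, and "borders" are index-space borders. This is a documented
  limitation, not an approximation of geodesic structure.
* **Group structure**: parcels are dealt round-robin to K networks; the
  planted parcel correlation matrix is r_w = 0.4 within and r_b = 0.05
  between networks (unit diagonal), repaired to the nearest positive
  semidefinite matrix by eigenvalue clipping at 1e-8 and diagonal
  renormalization when needed; repairs that would move entries by more than
  0.1 are rejected as ill-posed.
* **Individuals** deviate from the group mainly at network borders: each
  vertex flips to a uniformly drawn other network with probability
  flip_rate (default 0.1), multiplied by boundary_bias (default 3–4 in the
  tests) at border vertices. The deviation process is a free model, not an
  estimate — no published characterization exists to calibrate against.
* **Sessions**: latent parcel series are drawn from the planted covariance
  via Cholesky; each vertex carries the latent series of a source parcel in
  its own individual network plus Gaussian noise. Defaults follow the
  acquisition described for the source cohorts: TR 0.8 s, 420 frames per
  run. Vertex noise SD 0.5 represents a clean session; the titration
  analyses use 2.5, which reproduces the data-limited regime (split-half
  NMI rising from ≈ 0.45 at 2.5 min toward ≈ 1 at 10 min) reported for
  infant data.
* **Motion**: a two-state Markov chain with persistence 0.8 toggles quiet
  white-noise increments against smooth high-motion drifts calibrated so FD
  crosses 0.2 mm on ≈ p_high of frames, in bursts — so the epoch rule has
  something to do.
* **Behavior**: VDQ = 100 + β·LI + subject intercept + noise, with NVDQ
  generated identically at β = 0 as a built-in negative control;
  age-equivalent subscale scores are back-computed so the quotient formulas
  round-trip exactly.

What a green test does **not** establish: anything about real BOLD
autocorrelation, sleep-stage composition, registration error, geodesic
border geometry, or the behavior of the pipeline under nuisance structure
the generator does not model (global signal, motion-correlated signal
loss). The synthetic world is block-structured and stationary; real infant
FC is neither.

## Statistical choices

* Mixed models use lme4 with a random intercept per subject. Satterthwaite
  degrees of freedom are unavailable in the supported environment, so
  p-values use residual df (n − p − 1); the method is recorded in every
  result object. Singular fits are reported, never hidden. With one session
  per subject the model degenerates gracefully to OLS (the nobs-vs-levels
  checks are relaxed deliberately).
* Age is modeled in years, uncentered; the coding is configurable and the
  source convention is unstated.
* Ridge age prediction selects its penalty by inner cross-validation over a
  logarithmic grid (10^2 to 10^-4) within each training fold; outer folds
  are grouped by subject so no subject's sessions span folds.
* Paired within-network FC comparisons use BH FDR across networks.
  Laterality models are reported without multiplicity correction,
  mirroring the hypothesis-driven reporting convention of the source
  analyses.
* Within-network FC is operationalized as the mean of vertex-to-parcel FC
  entries between a network's member vertices and the parcels
  majority-assigned to it under the same topography. The vertex-level
  averaging in the source is not fully specified; this is the cheapest
  faithful reading and is isolated in one function for substitution.
* Versatility is normalized Shannon entropy of a vertex's assignment
  frequencies. The cited versatility measure is not restated by its
  source; normalized entropy satisfies every property claimed for it
  (0 when unanimous, 1 when uniform, strictly increasing as mass spreads
  over more networks at fixed modal frequency).

## Degenerate inputs and tie-breaking

Zero-variance vertices produce NA profile rows that stay in place
(indexing is sacred) and are excluded from matching with a count; zero-variance
parcels are errors naming the parcel. Winner-take-all and modal-consensus
ties break toward the lowest network index and are counted and logged —
silent ties can mask degenerate templates. Minutes-to-frames conversion
rounds up, guaranteeing at least the requested duration. Odd split-half
counts give the extra frame to the first half.

## Known limitations

* Index-space borders (no mesh); no geodesic smoothing or spatial priors.
* No soft/overlapping assignment; a vertex has exactly one network.
* No volumetric/surface preprocessing: the package starts at surface BOLD
  matrices and realignment parameters.
* The stability plateau above the true K (self-entry artifact) means K
  selection on block-equicorrelated synthetic data should be read as
  "23 ± 2", not an exact recovery; the acceptance tolerance reflects this.
* Permutation-null magnitudes depend on network-size entropy; the package
  reports both the simulated and analytic values so discrepancies are
  attributable.
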