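---
title: "Discriminating brain states from functional connectivity: methods and design"
author: "fcstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating brain states from functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcstates)
```

## The problem

Steady-state fMRI experiments record multi-node (region-of-interest) time
series for each subject under several cognitive states. The question this
package addresses is: which *pipeline* — dependency measure, temporal
filter, regularization — best discriminates those states, when every scan is
summarized as a network matrix (netmat) and classified across subjects?

The pipeline is: extract node time series from voxel data (parcel averaging
or spatial multiple regression), optionally band- or high-pass filter them,
compute a per-scan dependency summary (node variance "amplitude",
covariance, full correlation with Fisher z, or ridge-regularized partial
correlation), vectorize it, and classify states with a multiclass linear
SVM under leave-one-subject-out (LOSO) cross-validation. Pipelines are then
compared with McNemar's test (paired per-sample outcomes), Wilcoxon
signed-rank (paired accuracy lists), and Benjamini–Hochberg FDR.

Real recordings of this kind are not redistributable, so the package ships
a synthetic generator with exported ground truth; it is first-class, tested
code and the substrate for all study-scale validation.

## The measures

For a demeaned node-by-time matrix $X$ ($N \times T$):

* **Amplitude**: per-node unbiased variance, $\mathrm{var}(x_i)$ with a
  $T-1$ denominator.
* **Covariance**: $\hat\Sigma = \frac{1}{T-1} X X^\top$.
* **Full correlation**: $r_{ij}$, with the Fisher transform
  $z = \operatorname{atanh}(r)$ applied off-diagonally ($|r|$ clipped at
  $1 - 10^{-7}$ so features stay finite).
* **Ridge partial correlation**: the covariance is scaled to unit mean
  diagonal, $\tilde\Sigma = \hat\Sigma / \overline{\mathrm{diag}
  \hat\Sigma}$, so that the penalty is scale-free; then
  $P = (\tilde\Sigma + \lambda I)^{-1}$ and
  $\rho_{ij} = -P_{ij}/\sqrt{P_{ii} P_{jj}}$. At $\lambda = 0$ this equals
  the textbook partial correlation obtained by residualizing each pair on
  all remaining nodes (asserted to $10^{-8}$ in the tests). The default
  grid for $\lambda$ is 0 to 5 in steps of 0.1; `extend_to` can lengthen it
  when a parcellation needs heavier regularization. Fisher z for partial
  correlation is configurable and on by default (it stabilizes variance
  either way; whether to apply it is a genuinely open convention).

Partial correlation is the interesting case scientifically: it measures the
dependency between two nodes *after* removing the linear influence of all
others, so it distinguishes direct couplings from correlations induced by
indirect paths. The generator plants its state effects in precision space
precisely so that this distinction exists in the ground truth.

## Spectral machinery

Filtering uses digital Butterworth designs of prototype order 4 (a
band-pass therefore has 8 poles), applied forward and backward (zero
phase). Zero-phase application was chosen because connectivity measures are
phase-sensitive; its consequence — the effective magnitude response is
$|H(f)|^2$, i.e. half *power* at each nominal cutoff — is asserted in the
tests. Edge transients are controlled by odd-reflection padding of three
filter lengths plus steady-state initial conditions on each pass. The
"minimal filtering" pipeline is a 0.005 Hz high-pass (drift removal only),
and four canonical non-overlapping bands tile 0.005–0.385 Hz; at
TR = 1.3 s the top edge abuts Nyquist (0.3846 Hz) at printed precision.

Power spectra use Welch's overlapped-segment averaging: at most 8
Hamming-windowed, mean-detrended segments at 50% overlap, one-sided,
scaled so the rectangle-rule integral over frequency approximates the
series variance (Parseval; checked on white noise to within 10% over 50
draws). Segment length is the largest even integer whose eight
half-overlapping copies fit in $T$ (50 samples at $T = 230$).

## Classification

Features are the strict upper triangle of the netmat in fixed row-major
order (amplitude: the node vector). LOSO cross-validation holds out all
scans of one subject per fold. Within each training set, hyperparameters
are selected by an *inner* LOSO over training subjects: every
$(\lambda, C)$ pair is scored, ties resolved toward the smallest $\lambda$
(least shrinkage) and the largest $C$; features are then recomputed at the
selected $\lambda$ and a single model fit on the full training set. The C
grid is 8 log-spaced values spanning 0.001–1000 — the count and range are
fixed, log spacing is the natural 8-point choice. Because selection only
ever sees training subjects, the accuracy estimate is honest; a
`select_c = "max"` mode also reports the maximum over the C grid of the
aggregate LOSO accuracy, the more optimistic convention, for comparability.

The SVM is the libsvm linear machine (one-vs-one multiclass); votes are
aggregated in package code with ties broken by the larger summed decision
value, so the multiclass reduction is deterministic and testable. A
Euclidean k-NN (majority vote, ties to the smallest class index) is the
secondary classifier.

**Within-subject ratio normalization.** The study pipeline divides each
feature by the subject's mean of that feature across its states, removing
subject-level offsets. This is leakage-free by construction (it uses only
within-subject statistics; corrupting a held-out subject's data provably
never changes the selected hyperparameters — there is a test for this).
It is, however, *ill-conditioned when a feature's subject mean approaches
zero*: the ratio becomes heavy-tailed. Real dense FC matrices keep most
edges bounded away from zero, but honest synthetic partial-correlation
matrices do not — dense positive partial correlations are mathematically
bounded by roughly $1/(N-1)$, so at $T = 230$ estimation noise is
commensurate with the values themselves and normalized features develop
extreme tails (we observed magnitudes above $10^4$). The package therefore
keeps the normalization as the default pipeline (with the documented
guard: denominators below $10^{-12}$ of the feature scale yield 0 and a
flag), but the measure-contrast experiments below run unnormalized, with
subject heterogeneity injected explicitly as the nuisance the classifier
must generalize across. This is a property of the ratio itself worth
knowing before applying it to data whose features straddle zero.

## The synthetic generator

`simulation_config()` describes a study of `n_subjects` × `n_states` scans
of `n_nodes` × `n_timepoints` samples at TR `sampling_interval`; the
defaults (15 × 5 × 230 at 1.3 s, i.e. 75 scans of ~5 min) mirror the
steady-state design the pipeline was built for. Ground truth is a sparse
precision matrix per (state, band): a base support drawn at
`base_density`, negative off-diagonal entries in (0.15, 0.35) (so direct
couplings are positive partial correlations), diagonal set by dominance
plus multiplicative loading (×1.1, max 50 retries) to guarantee positive
definiteness deterministically. State effects add
$\pm\,$`edge_effect` × `band_effects[b]` to a designated half of the
support edges; amplitude effects scale node standard deviations by
$\exp(\pm\,$`amp_effect`$)$; subjects perturb support entries with Gaussian
noise of scale `subject_sd`; white measurement noise has scale `noise_sd`.
Band-limited series are generated by Cholesky-mixing i.i.d. Gaussian
vectors and filtering *after* mixing — the identical filter on every
channel preserves the cross-correlation structure of jointly Gaussian
channels exactly, so no spectral factorization is needed. Per-(subject,
state) random streams are derived from the master seed by a fixed
splitting rule, so enlarging the design never perturbs existing scans.

Default effect scales (`base_density` 0.3, `edge_effect` 0.25,
`amp_effect` 0.2, `subject_sd` 0.3, `noise_sd` 0.2) were chosen once as a
realistic regime: state effects well below the base coupling scale,
subject variability comparable to the couplings themselves (inter-subject
variance dominates state variance in real FC), and measurement noise a
minor term. All three effect channels (couplings, amplitudes, frequency
bands) are exposed as orthogonal knobs rather than asserting one mechanism,
because the data-generating mechanism behind real state differences is
unknown.

What the generator does *not* emulate: hemodynamic convolution,
physiological noise, head motion, spatial geometry. Passing tests
demonstrate the pipeline's statistical machinery and its sensitivity to
direct-edge, amplitude, and band-specific effects — not performance on
real BOLD data.

## Study-scale validation conditions

The acceptance-level checks run at these sizes (chosen as desk-scale
conditions; all seeds fixed or derived from one master seed):

* **Chance calibration**: 200 within-subject label permutations of a
  default 15 × 5 study (6 nodes); mean LOSO accuracy 20% ± 3%.
* **Direct-edge contrast** (partial vs full correlation): 20 studies,
  10 nodes, single 0.01–0.3 Hz band, `edge_effect` 0.25, `subject_sd` 0.3,
  `noise_sd` 0.2, amplitude effects off; partial correlation tuned by
  nested selection over λ ∈ {0.2, 0.5, 1, 2} with C = 1 for both measures
  (a single C keeps the contrast about the measure). Expected direction:
  tuned partial ≥ full correlation in mean accuracy.
* **Frequency specificity**: effects only in the 0.096–0.182 Hz band
  (`band_effects = c(0,1,0,0)`, `edge_effect` 0.35); features filtered to
  that band must beat features filtered to 0.298–0.385 Hz.
* **Null safety**: 20 zero-effect benchmarks of three measures against a
  correlation baseline; at least 95% of runs must show no cell
  significantly beating baseline after FDR.
* **McNemar level**: 2,500 replicates of paired 20% coin-flip errors on a
  common 400-sample prediction stream; rejection at α = 0.05 must land in
  5% ± 2%. At the 75-sample scale the prescribed variant (exact binomial
  below 25 discordant pairs, continuity-corrected χ² above) is
  conservative, rejecting at ≈3% — discreteness, not a defect; the level
  probe therefore uses the larger stream where the asymptotic level is
  identifiable.

## Numerical choices and degenerate inputs

* SPD enforcement: deterministic diagonal loading (×1.1, max 50), then a
  hard error — a pathological configuration should fail loudly.
* Fisher z clipping at $|r| = 1 - 10^{-7}$; zero-variance nodes are an
  error naming the node.
* λ = 0 with a singular covariance errors with advice to use λ > 0.
* Zero-variance paired differences (edge t-tests), all-zero Wilcoxon
  differences, and zero discordant McNemar counts all return p = 1 with a
  flag, never NaN — conservative and pipeline-safe.
* Wilcoxon signed-rank uses the exact sign-flip null (valid under midrank
  ties, via dynamic programming over doubled ranks) up to n = 25, then a
  tie-corrected normal approximation with continuity correction.
* Classifier tie-breaks are fully specified (summed decision values for
  the SVM vote; smallest class index for k-NN), making every prediction
  path deterministic.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_nodes = 10, seed = 1)
sim <- simulate_dataset(cfg)
sim$dataset
#> <study_dataset> 15 subjects x 5 states = 75 scans, 10 nodes x 230 timepoints, TR 1.30 s

tab <- dataset_features(sim$dataset, "correlation")
res <- run_loso(tab, classifier_config(c_grid = 1), normalize = FALSE)
res
#> <cv_result> 75 samples, 15 folds, accuracy 81.33%
```

## Known limitations

* The ratio normalization caveat above: with features near zero the
  normalized pipeline loses power; consider the unnormalized route or a
  variance-stabilizing offset when applying it to such data.
* Estimated accuracies on 75 samples have a binomial standard error of
  ≈5 percentage points; single-pipeline differences of that order are
  noise, which is why pipeline comparisons go through McNemar / Wilcoxon
  with FDR rather than raw rankings.
* The voxel stage is a generic linear forward model; registration,
  masking, and surface geometry are upstream concerns.
* Only L2 (ridge) regularization is provided; sparse (L1) precision
  estimation is deliberately out of scope.
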