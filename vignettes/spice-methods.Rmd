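---
title: "Permutation testing of intermodal correspondence: model, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation testing of intermodal correspondence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicetest)
```

## The hypothesis and the statistic

Suppose `n` subjects each contribute two aligned maps, `X_i` and `Y_i`,
observed at the same `V` locations (vertices of a common cortical surface
template, say). The SPICE null hypothesis is distributional: the intermodal
similarity `psi(X_i, Y_i)` between a subject's *own* two maps is distributed
no differently from the similarity `psi(X_i, Y_j)` between maps of two
*different* subjects. If the two modalities are genuinely coupled — through
anatomy, development, or function — a subject's own pair should be the more
similar one.

The observed statistic is the mean within-subject similarity,

$$A_0 = \frac{1}{n}\sum_{i=1}^n \hat\psi(X_i, Y_i),$$

with `psi` the sample Pearson correlation across locations by default;
`measure = "spearman"` substitutes the rank correlation (average ranks on
ties), which is invariant under any strictly monotone transform and hence
more sensitive to nonlinear but monotone coupling. A null distribution for
`A_0` is generated by randomly shuffling which subject's `Y` map is paired
with which `X` map: for permutation `k` the statistic `A_k` is the mean
similarity of the shuffled pairs. Permutations are drawn uniformly with
replacement from all `n!` orders; the identity can be re-drawn, and its
guaranteed contribution enters only once, through the estimator

$$p = \frac{1 + \#\{k : |A_0| \le |A_k|\}}{K + 1},$$

whose add-one terms represent the unpermuted arrangement compared against
itself. Consequences worth noting: `p` is bounded below by `1/(K+1)` (0.001
at the default `K = 999`), ties count toward the numerator, and under the
null `p` is uniform on the lattice `{1/(K+1), ..., 1}`. The default
comparison is two-sided via magnitudes; `sidedness = "greater"` gives the
one-sided "within exceeds between" variant for directional questions.

Because only subject labels are permuted, no spatial null model is ever
fitted: spatial autocorrelation is whatever the observed maps carry, and no
stationarity assumption or medial-wall rotation bookkeeping is needed. The
substantive assumption is that subjects are exchangeable under the null —
independent sampling from one population. Exchangeability *blocks* (e.g.
families, sites) are not yet supported; see Limitations.

## Parameters that matter

* `k` — permutation count. `K = 999` is the package default for a single
  test; the attainable p-value resolution is `1/(K+1)`. Simulation drivers
  default to `K = 199`, which resolves the 5% level adequately while keeping
  thousand-replicate studies fast. Note that with discrete p-values the
  attained level of "reject when `p < 0.05`" is `floor(0.05 (K+1)) / (K+1)`
  — 0.045 at `K = 199`, 0.049 at `K = 999` — slightly conservative, never
  anticonservative.
* `measure` — `"pearson"` (field convention) or `"spearman"`.
* `mask` — logical vector excluding non-cortical locations (medial wall).
  The same mask applies to both modalities, because a correlation is only
  meaningful over a common location set. The default is no mask.
* `seed` — every function that consumes randomness takes one explicitly; a
  test run without a seed draws one and records it in the result.

## The simulation model

`simulate_dataset()` implements a shared-signal generative model. Given a
pair of population mean maps `m1`, `m2` (length `V`, mutual correlation
`rho`), each subject draws a single scalar

$$a_i \sim \mathcal N(1,\ \sigma_a^2),$$

shared across both modalities, and the maps are

$$X_{iv} = a_i\, m_{1v} + E^{(1)}_{iv}, \qquad
  Y_{iv} = a_i\, m_{2v} + E^{(2)}_{iv},$$

with independent `N(0, sigma_e^2)` noise at every location. The mean of 1
for `a_i` is essential: it keeps simulated subjects near the population mean
maps, and it makes `sigma_a^2 = 0` the *exact* null — every subject then has
the same signal, so within- and between-subject similarities are identically
distributed. With `sigma_a^2 > 0` the shared `a_i` couples the two maps of
the same subject, and power rises with `sigma_a^2`, falls with
`sigma_e^2`, and rises with `n` and with `|rho|`.

`make_mean_maps()` synthesizes the mean-map pair rather than loading real
group averages: the test's operating characteristics depend on the mean maps
only through `V` and their mutual correlation, which are exactly the two
knobs exposed. Construction is residualize-and-recombine on two Gaussian
vectors, giving an *empirical* correlation equal to the target to ~1e-15.
The maps are standardized to zero mean and unit variance — a deliberate,
recorded choice: it makes `sigma_a^2` and `sigma_e^2` directly comparable
across settings (a map with variance 1 contributes signal variance
`E[a^2] = 1 + sigma_a^2` per location). An optional circular moving-average
`smoothness` parameter induces 1-D spatial autocorrelation; the default is
0 (rough maps), since the permutation test's validity does not depend on
smoothness.

What the generator deliberately does *not* emulate: cortical mesh geometry,
spatially heterogeneous (non-stationary) noise, heavy-tailed intensity
distributions, site or motion artifacts, and dependence between subjects.
Passing simulation suites therefore demonstrates calibration and power
*under the stated model*, not robustness to every pathology of real imaging
data — though the test itself only relies on subject exchangeability, which
none of those pathologies except inter-subject dependence violates.

### Study sizes

Simulation drivers default to desk-scale settings chosen once: `V = 500`
locations, 1,000 replicates per parameter cell, `K = 199`. A thousand
replicates give a binomial standard error of about 0.7 percentage points at
the 5% level, ample for calibration checks and power curves; `V = 10242`
(one fsaverage5 hemisphere) is available by passing a larger `v`. The
package's own acceptance checks use these sizes; the uniformity check uses
2,000 null replicates.

## Reproducibility and the seed-spawning scheme

A single master seed determines everything. Child streams are derived with
`spawn_seed(master, key)` — a Lehmer-style hash
`((master mod M) * 69069 + key) mod M`, `M = 2^31 - 1` — with documented
keys: replicate `r` of a rejection-rate run uses
`spawn_seed(spawn_seed(master, r), 1)` for data and `..., 2)` for
permutations; grid cell `i` uses `spawn_seed(master, i)`; region tests use
the region's integer label as the key. Two properties follow: any single
replicate, cell, or region can be recomputed in isolation, and a region's
result does not depend on which other regions were requested. A
whole-surface region therefore reproduces the global test exactly under the
same derived seed — a property the test suite asserts.

## Numerical choices

* **Correlation formula.** The standard sample Pearson correlation is used
  throughout (some published renderings of the across-location correlation
  formula contain typographical slips; the standard formula is the quantity
  intended).
* **One matrix, two uses.** Internally the test computes the `n x n`
  cross-similarity matrix `C[i, j] = psi(X_i, Y_j)` once — rows are
  rank-transformed for Spearman, then centred and scaled to unit sum of
  squares, so each entry is a dot product — and every permutation statistic
  is a mean of `n` entries of `C`. This is algebraically identical to
  re-scoring each permuted dataset, makes `K = 999` essentially free, and
  guarantees `A_0` and all `A_k` are computed by the same arithmetic, so
  the `<=` tie rule operates on exactly comparable numbers. Ties are
  compared in exact floating point (no tolerance): they arise structurally
  (the identity re-drawn), not from rounding.
* **Clamping.** Dot-product correlations are clamped to `[-1, 1]` to absorb
  last-bit rounding excursions.
* **Degenerate input.** A constant map (zero variance) is an error naming
  the subject and modality, raised before any permutation is scored —
  never a silent `NA`. Non-finite values inside the mask are likewise
  errors; outside the mask they are ignored.
* **Small `n`.** With `n` subjects there are only `n!` distinct
  permutations; at `n = 2` the attainable p-values are severely limited.
  The test remains valid (never anticonservative) but nearly powerless
  below `n ≈ 5`; the suite checks Monte-Carlo agreement with exhaustive
  enumeration up to that range.
* **File formats.** GIFTI data arrays are written as base64 little-endian
  32-bit floats (ASCII and gzip encodings are read); FreeSurfer
  morphometry uses the 0xFFFFFF-magic big-endian float32 format; `.annot`
  files use the version -2 colortable with the region label packed into the
  annotation color, so label partitions round-trip exactly while float maps
  round-trip to single precision (~1e-7 relative).

## Region-stratified testing and multiplicity

`spice_by_region()` restricts both modalities to one parcel or network at a
time and runs the full test per region — a major practical advantage of a
subject-permutation null: narrowing the location set requires no new spatial
model, so post-hoc localization is statistically identical to the global
test. Bonferroni correction is applied as a *threshold on raw p-values*
(`alpha / m`), not by inflating the p-values themselves; both the raw p and
the threshold are reported so users can substitute other corrections. The
comparison count `m` defaults to the number of regions actually tested, but
multiplicity is a study-design declaration — a study correcting across age
strata rather than regions should pass `m_comparisons` explicitly. The
threshold is kept at full precision internally (0.05/16 = 0.003125);
rounding to 0.003 is display-only. Regions with fewer than 3 usable
locations are reported as skipped with a reason, never dropped.

## Design decisions that were genuinely open

* **Permutations with replacement, fixed points allowed.** Plain uniform
  shuffles match the estimator's `k = 0..K` indexing and the add-one
  correction; derangement-restricted or without-replacement schemes would
  change the estimator's null distribution subtly and buy little.
* **Sidedness.** The two-sided magnitude comparison is the default because
  correspondence can be negative (thickness vs. sulcal depth correlate
  negatively); the one-sided option exists because the alternative of
  interest is directional ("within exceeds between").
* **Mean-map standardization.** Zero-mean unit-variance maps with an exact
  target correlation (see above); the alternative — raw-scale maps — would
  entangle the noise-variance grid with map units.
* **Rejection counting.** A replicate counts as rejected when `p < alpha`
  strictly, matching the estimator's discrete support.

## Limitations

* Subject exchangeability is assumed wholesale; block-structured
  exchangeability (families, scanners) is future work.
* The mean-similarity statistic tests one moment of the similarity
  distribution; distribution-level statistics (e.g. Kolmogorov–Smirnov
  across the per-subject similarities) and connectivity-specific distances
  are out of scope here.
* Volumetric (voxel) input and surface resampling are not provided; maps
  must already live in a common surface space.
* A Pearson-based `psi` measures linear coupling only; regions with known
  nonlinear structure–function relationships can fail to reject for that
  reason alone (the Spearman option mitigates monotone nonlinearity only).
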