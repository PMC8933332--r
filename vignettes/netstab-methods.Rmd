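---
title: "Methods: test-retest stability of resting-state fMRI metrics"
author: "netstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest stability of resting-state fMRI metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstab)
```

# Overview

`netstab` quantifies how reproducible resting-state fMRI measurements are
when the same subject is scanned twice (here: two sessions a week apart).
Two families of measures are covered:

* **voxel-wise spontaneous-activity metrics** — the amplitude of
  low-frequency fluctuations (ALFF), its fractional variant (fALFF),
  regional homogeneity (ReHo, Kendall's coefficient of concordance with the
  26 neighbors), and binarized degree centrality (DC);
* **region-level functional connectivity** in the triple-network model:
  15 regions assigned to the default mode (DMN, 4 ROIs), central executive
  (CEN, 4 ROIs) and salience (SN, 7 ROIs) networks.

Stability is measured per subject: voxel-based agreement of each metric map
across the two sessions with **Lin's concordance correlation coefficient**
(CCC), and rank agreement of each internetwork connectivity block with
**Spearman's correlation**.

# Temporal preprocessing

For each session the pipeline applies, in order:

1. **Initial-volume removal** (default 10 of 300 volumes at TR = 3 s,
   leaving 290) to discard pre-steady-state frames; motion tables are
   truncated identically.
2. **Nuisance regression**: ordinary least squares of each voxel on an
   intercept, the Friston 24-parameter motion expansion (6 rigid-body
   parameters, their one-frame lags — first row zero-filled, a convention
   whose constant fill is absorbed by the intercept — and both sets
   squared), and the mean white-matter and CSF signals. An intercept is
   always included so residualization removes the mean consistently; the
   design is checked for full column rank and the offending column is named
   on failure. Residuals are orthogonal to every regressor by construction,
   and the operation is idempotent.
3. **Framewise displacement (FD)** by the Power convention — the sum of
   absolute backward differences of the six parameters, rotations converted
   to arc length on a 50 mm sphere — since this is the convention under
   which the standard 0.2 mm scrubbing cut-off is defined. The first frame
   is 0.
4. **Gross-motion screening**: any session with a frame beyond 1.5 mm
   translation or 1.5 degrees rotation excludes the subject (motion files
   store radians; conversion happens inside the screen).
5. **Scrubbing**: frames with FD > 0.2 mm are removed and the kept frames
   concatenated in time order; nothing is imputed.
6. **Band-pass filtering** to 0.01-0.1 Hz for the correlation branch,
   realized as a zero-phase frequency-domain mask. This gives exact band
   edges with no filter-order choice, removes the mean exactly, and leaves
   on-grid pass-band tones untouched.

## Which branch sees which step

ALFF and fALFF are *spectral* metrics: band-passing first would make them
trivial, so they are computed on the nuisance-regressed, unfiltered
residuals. ReHo, DC and the ROI connectivity matrices are computed on the
band-passed series.

**Scrubbing and the spectral branch.** A discrete Fourier transform assumes
regular sampling. Concatenating the kept frames after scrubbing breaks the
phase continuity of every sinusoid and leaks a session-specific fraction of
in-band energy across bins; because the two sessions lose *different*
frames, this contaminates amplitude metrics with variance unrelated to the
underlying signal (in synthetic experiments it also destroys the expected
ordering of stability with session fidelity). The package therefore
defaults to computing ALFF/fALFF on the **unscrubbed** residual series,
while the correlation branch — where frame deletion is well defined — keeps
scrubbing. `run_config(scrub_spectral = TRUE)` restores strict
scrub-then-transform behavior for comparison.

# Voxel-wise metrics

* **ALFF** — per voxel: demean, DFT, one-sided amplitude `2|X_k|/n`, summed
  over bins with `0.01 <= f <= 0.1` Hz. The `2/n` scaling makes a pure
  on-bin tone's ALFF equal its sinusoid amplitude; any fixed scaling
  cancels in fALFF and after z-scoring.
* **fALFF** — in-band amplitude sum divided by the sum over *all* positive
  bins up to Nyquist (the zero bin is removed by demeaning). Flat series
  get an `NA` sentinel and are excluded downstream.
* **ReHo** — Kendall's W over the voxel plus its in-mask neighbors (27-voxel
  cube by default): with K series of n frames ranked over time,
  `W = 12 S / (K^2 (n^3 - n))` where S is the squared deviation of the
  frame-wise rank sums from their mean. Ties get average ranks without a
  denominator tie correction (exact ties have measure zero in band-passed
  data). At mask edges only in-mask neighbors are used (K < 27 allowed,
  K >= 2 required) — padding would fabricate data.
* **DC** — the count of other in-mask voxels with Pearson r > 0.25 (strict;
  self excluded). The conventional joint criterion "r > .25, p <= .001" is
  implemented as the r-threshold alone because at the frame counts targeted
  here (about 230+ frames) r > 0.25 implies p far below 0.001; a
  `p_threshold` option enforces the joint rule for short series.
  Zero-variance voxels contribute zero correlations and are flagged `NA`.

Maps are then **z-scored** (in-mask mean 0, SD 1) and **smoothed** with a
3 mm FWHM Gaussian, in that order (standardize, then smooth). Smoothing is
separable with per-axis sigma `FWHM / (voxel * 2 sqrt(2 ln 2))` and is
renormalized over the mask, so constants are preserved exactly and no
intensity bleeds in from outside the brain. Whether the voxel-based CCC is
computed on smoothed or merely standardized maps is configurable
(`ccc_on_smoothed`, default `TRUE`).

# Connectivity and stability statistics

ROI mean series (unweighted voxel means on the band-passed branch) give a
15 x 15 Pearson correlation matrix per session, Fisher r-to-z transformed
off-diagonal with |r| clipped at `1 - 1e-12` so degenerate correlations
stay finite. Internetwork blocks (DMN x CEN = 16 values,
DMN x SN = CEN x SN = 28) are vectorized in fixed row-major atlas order.

**Lin's CCC** with population (1/n) moments:

$$\rho_c = \frac{2\sigma_{yx}}{\sigma_x^2 + \sigma_y^2 + (\mu_y-\mu_x)^2}
         = \chi_a \, \rho, \qquad
  \chi_a = \frac{2}{\varpi + 1/\varpi + v^2}, \quad
  \varpi = \sigma_y/\sigma_x, \quad
  v^2 = \frac{(\mu_y-\mu_x)^2}{\sigma_x\sigma_y}$$

The decomposition into accuracy (distance from the identity line) times
precision (Pearson correlation) is verified to 1e-10 on every call. The
sample counterpart computed through Pearson's r uses the same 1/n variance
normalization — with n-1 variances the unscaled mean-shift term in the
denominator would break the algebraic identity between the two routes.
Confidence intervals use the Fisher z transform of the estimate with Lin's
(1989) asymptotic standard error, back-transformed; the default two-sided
level is the Bonferroni-adjusted 0.05/192 = 0.00026 arising from 16
subjects x 4 metrics x 3 networks.

**Spearman internetwork stability** correlates a network pair's Fisher-z
block across the two sessions (Spearman rather than Pearson because the
blocks hold only 16-28 values; note Spearman is invariant under the
monotone atanh map, so raw r gives the identical coefficient). P-values use
the two-sided t approximation, with an exact permutation option for blocks
of 10 or fewer tie-free values; multiplicity is controlled by
Benjamini-Hochberg FDR at q = 0.01.

Coefficients are labeled on the conventional magnitude scale (< .40 weak,
.40-.69 moderate, .70-.99 strong, 1.00 perfect), applied to the rounded
2-decimal magnitude; negative coefficients are labeled by magnitude with
the sign carried in the estimate. Group summaries report mean, SD (n-1),
and range per network x metric; rounding happens only at report time
(half-even, 2 decimals).

# The synthetic two-session generator

`synthetic_spec()` + `generate_dataset()` emulate the acquisition the
pipeline targets: per subject two sessions of 300 volumes at TR = 3 s on a
desk-scale 16 x 16 x 10 voxel grid (3 mm voxels) — small enough that the
full 16-subject pipeline runs in seconds while each default ROI keeps 27
voxels.

* **Latent band-limited signals.** All signals are sums of sinusoids on the
  DFT frequency comb inside 0.01-0.1 Hz with *Gaussian* random amplitudes
  and phases (i.e. a stationary Gaussian process restricted to the comb;
  expected variance 1). Exact band control avoids filter edge effects. The
  Gaussian amplitudes matter: with fixed-modulus random-phase sinusoids the
  between-session variability of realized spectral amplitude would be
  proportional to the interference term `2 sqrt(f(1-f))` — largest at
  fidelity 0.5 and zero at both extremes — whereas Gaussian coefficients
  give realized-power correlation `f^2`, monotone in fidelity, which is
  what a fidelity parameter must produce. An optional `1/f` in-band
  spectral shape is available (`spectrum = "one_over_f"`); the flat comb is
  the default since the band is narrow (one decade) and nothing downstream
  depends on the within-band shape.
* **Spatial structure.** Fifteen disjoint spheres (radius 1.8 voxels) on a
  4-voxel lattice carry the 15 ROI signals, drawn with a known 15 x 15
  correlation matrix via Cholesky factorization (1e-8 diagonal jitter for
  borderline-PSD inputs; genuinely non-PSD matrices are rejected naming the
  offending eigenvalue). Each ROI voxel carries
  `sqrt(0.7) x (ROI signal) + sqrt(0.3) x (voxel-local signal)`: regional
  coherence explains only part of a voxel's spontaneous variance in vivo,
  and the fidelity parameter is defined at the voxel level, which requires
  voxel-level signal to exist. Background brain voxels get purely local,
  independent signals, keeping DC ground truth interpretable. A per-subject
  amplitude map (uniform in 0.8-1.2) scales every voxel and is shared
  across sessions.
* **Session fidelity.** Every latent component (ROI, local, background,
  nuisance) of session s is `sqrt(f) x shared + sqrt(1-f) x session-unique`.
  Motion traces are mixed by the same rule: at fidelity 1 the generator
  reproduces the identical acquisition — including motion, hence identical
  scrubbing and nuisance regressors — so the processed maps and therefore
  all stability coefficients equal 1 exactly, which is the defining limit
  of the parameter. White measurement noise (SD 0.3) is always
  session-unique.
* **Nuisance and motion.** A global out-of-band (0.11-0.15 Hz) oscillation
  with amplitude 0.1 (about 1% of signal power, so noise-free voxels keep
  at least 95% of their power in band) mimics aliased physiological signal.
  Motion is a slow random walk plus occasional one-frame 0.3 mm spikes
  (rate 0.03/frame) that exceed the 0.2 mm FD threshold and exercise
  scrubbing.
* **Determinism.** One master seed; per-subject/per-session streams are
  derived by fixed counter offsets, so identical specs reproduce
  bit-identical datasets.

What the generator does *not* emulate: scanner physics, distortion,
spatially correlated or non-Gaussian noise, true physiological waveforms,
spatial preprocessing (the pipeline starts after alignment), and realistic
anatomy — masks are boxes and spheres. Passing tests therefore demonstrate
the correctness and internal consistency of the measurement chain, not its
behavior on real tissue contrast.

# Numerical choices and degenerate inputs

* Band-pass and spectral metrics require at least one DFT bin in band; the
  error reports the bin spacing.
* fALFF of a flat series, ReHo of an isolated voxel (K < 2), and DC of a
  zero-variance voxel produce `NA` sentinels (never silent zeros) and are
  excluded from CCC pairing; fewer than 10 usable voxels in a network is an
  error.
* CCC with both vectors constant is rejected; with exactly one constant it
  is 0 by convention with a warning. Fisher-z clipping bound: 1 - 1e-12.
* The pipeline refuses empty intermediate products (zero kept frames, empty
  ROIs, all subjects screened out) with named errors.

# Problem sizes

The test suite and the acceptance script run the full study size the
package emulates — 16 subjects, 16 x 16 x 10 grid, 290 retained volumes —
for the parameter-recovery checks (a few minutes in total), and scaled-down
grids (e.g. 10 x 10 x 6 with 4096 volumes) where a property needs long
series, such as recovering the latent connectivity to within +-0.1.

# Known limitations

* The CCC confidence interval follows Lin's asymptotic method; small-n
  coverage is approximate and no bootstrap alternative is provided.
* ReHo stability in the synthetic world is dominated by the static
  ROI-edge geometry of the binary spherical masks, so its fidelity
  sensitivity, while strictly monotone, is compressed near 1.
* Scrubbed series feed the correlation branch as a plain concatenation;
  no Lomb-Scargle or gap-aware spectral estimator is implemented.
* The atlas is an input; no spatial normalization or warping is performed.
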