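---
title: "Shot-noise based identification and localization of single emitters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shot-noise based identification and localization of single emitters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snsmlm)
```

## The problem

Single-molecule localization microscopy (SMLM; PALM, dSTORM and relatives)
reconstructs a super-resolution image from thousands of wide-field or TIRF
frames in which only a sparse, random subset of fluorophores emits at a
time. The central difficulty is step two of the workflow: deciding which
local intensity fluctuations are genuine single-emitter signals and which
are background noise. This package makes that decision from the physics of
the noise itself. Photoelectron counts on an EMCCD are Poisson distributed
(shot noise), so the expected fluctuation of a background of $N_{bg}$
photoelectrons is $F\sqrt{N_{bg}}$, where $F$ is the camera's excess-noise
factor ($\sqrt 2$ at high electron-multiplying gain). Everything downstream
— candidate scoring, the acceptance threshold, the quality histograms — is
expressed in units of that fluctuation.

## The model and the pipeline

Raw intensities are first converted to photoelectrons,
$N_e = (I - I_{bias}) / G_{\mathrm{eff}}$, clamped at zero (counts cannot
be negative; readout noise can push readings below the bias). The optics
enter through two derived lengths, the Airy (Rayleigh) radius
$R_{airy} = 0.61\,\lambda M / (\mathrm{NA}\,\mu)$ and the Gaussian-PSF
approximation width $\sigma_{PSF} = 0.21\,\lambda M / (\mathrm{NA}\,\mu)$,
both in camera pixels ($\mu$ = sensor pixel size, $M$ = magnification).

Per frame the pipeline then:

1. smooths lightly (Gaussian, $\sigma = 1$ px by default — below
   $\sigma_{PSF}$, so the spot shape survives while single-pixel noise is
   suppressed);
2. estimates a per-pixel local background (below);
3. takes every pixel that is the strict maximum within $R_{airy}$ as a
   candidate, and discards candidates closer than $R_{airy}$ to one
   another — overlapping PSFs are not analyzable as single emitters and
   multi-emitter deconvolution is out of scope;
4. forms a region of interest (ROI): pixels within
   $\lceil\sigma_{PSF}\rceil$ of the peak whose smoothed value exceeds the
   local background;
5. scores each candidate with
   $SNR_{\mathrm{eff}}$ (the ROI mean of the per-pixel SNR
   $S/(F\sqrt{N_{bg}})$),
   $CNR_{\mathrm{eff}}$ (the summed ROI signal over the aggregate noise of
   the *full* theoretical PSF disk, $\sum S / (F\sqrt{\sum_{disk} N_{bg}})$),
   and the quality metric $Q = \min(SNR_{\mathrm{eff}}, CNR_{\mathrm{eff}})$.
   A needle-like single-pixel spike has high SNR but low CNR; an over-broad
   blob has high CNR but low SNR; neither looks like a single emitter, and
   the minimum penalizes both;
6. accepts candidates with $CNR_{\mathrm{eff}} > 3$ (the Rose criterion,
   fixed) and $Q \ge$ the user's threshold — the one genuinely free
   parameter of the method;
7. localizes accepted candidates by Levenberg–Marquardt least-squares
   fitting of a 2D Gaussian on the *raw* photoelectron frame, with three
   model variants (1: width fixed at $\sigma_{PSF}$; 2: one fitted width;
   3: independent $\sigma_x, \sigma_y$), and filters the fits by width
   (models 2–3: every $\sigma \in [0.5\,\mathrm{px},\ PWT \cdot
   \sigma_{PSF}]$) and by the Pearson correlation between model and data
   ($r \ge 0.5$ by default).

The scoring stage runs on the smoothed frame (smoothing precedes scoring
in the workflow); the fit uses the raw photoelectron data so the noise
statistics of the fit residuals are untouched.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `q_threshold` | user-chosen (2 is a good start) | noise SDs | the only free parameter; trades false negatives against false positives |
| `rose_cnr_min` | 3 (fixed) | noise SDs | detectability floor; not meant to be tuned |
| `model` | 1 | – | 1 for in-focus (TIRF) data; 2–3 when defocus matters |
| `pwt` | 3 | × $\sigma_{PSF}$ | upper width bound for models 2–3 |
| `smooth_sigma_px` | 1 | px | noise reduction before scoring |
| `r_min` | 0.5 | – | goodness-of-fit floor |
| `excess_noise_factor` | $\sqrt2$ | – | EMCCD excess noise; 1 for an ideal amplifier |

## Local background estimation

The SNR analysis stands or falls with the local background map. The
estimator here is deliberately simple and purely spatial: each pixel is
clipped at its local median (window of radius
$\lceil R_{airy}\rceil$) plus three shot-noise standard deviations,
$\min(x, \mathrm{med} + 3\sqrt{\mathrm{med}})$, and the clipped frame is
smoothed with a heavy Gaussian ($\sigma = 4 R_{airy}$). The clip removes
PSF-shaped spots (which are far above the local median) without touching
ordinary Poisson fluctuations, so the estimate is unbiased on emitter-free
frames — a plain min-with-median rule would sit several percent low,
because $E[\min(X, \mathrm{med}(X))] < E[X]$ for any non-degenerate
distribution. The map is floored at $10^{-3}$ e⁻ so SNR divisions are
always defined. Temporal (across-frame) background estimation is a known
alternative but out of scope; the estimator sits behind the single
`estimate_background()` interface so it can be swapped.

## The synthetic-data generator

`sim_regime()` reproduces three benchmark imaging regimes: emitters with
on average 500 signal photons on a uniform background of 10 photons/pixel
(high SNR) or 50 photons/pixel (low SNR), the latter optionally with a
broad Gaussian-profile background superimposed (peak 50 photons, FWHM =
half the frame) to mimic uneven wide-field/TIRF illumination. Optics are
64 nm pixels, 665 nm emission, NA 1.49; about 40 emitters per frame
(Poisson-drawn), uniformly placed with a 3$\sigma_{PSF}$ edge margin,
overlaps allowed.

Noise model: each emitter's photon count is Poisson-drawn around 500 and
every photon lands at a position drawn from the Gaussian PSF — the count
plus the random placement *is* the signal's shot noise, realized photon by
photon. The background is added as a single Poisson draw on its
expectation. The "width of half size of full image" of the inhomogeneous
background is read as its FWHM (so $\sigma_{bg} = 0.5\,\mathrm{frame}/2.355$).
Gain is applied as a plain multiplication, without stochastic
electron-multiplication, as in the benchmark datasets the regimes emulate;
detection therefore runs with the slightly conservative $F=\sqrt2$ noise
model against single-Poisson data.

What the generator does *not* emulate: emitter blinking kinetics and
photobleaching, non-Gaussian (Airy/vectorial) PSF tails, defocus, sCMOS
pixel-to-pixel gain variation, drift, and readout noise. Tests passing on
this generator therefore validate the algorithmic contracts — conversion,
scoring, thresholds, fitting, matching — not performance on any particular
real microscope.

## Evaluation and rendering

Reconstructions are scored against ground truth with within-frame greedy
nearest-pair matching: the globally closest unmatched (truth, found) pair
within the tolerance is matched repeatedly, each record used once. From the
resulting TP/FP/FN counts: Jaccard $= TP/(TP+FP+FN)$, precision, recall,
and RMSD over matched pairs. The default tolerance is twice the
sample-plane pixel (128 nm for the 64 nm simulations); it is reported with
every result because scores at different tolerances are not comparable.
Rendering bins accepted localizations into 10 nm pixels (histogram mode) or
splats unit-integral Gaussians (default 20 nm); `line_profile()` projects
localizations in a band onto the axis perpendicular to a segment, the
standard width measurement for filament-like structures, normalized to the
profile maximum.

## Numerical choices and degenerate inputs

* Smoothing uses reflective boundaries (zero padding would create dark rims
  that inflate SNR at frame edges) and a kernel truncated at $3\sigma$ and
  renormalized, so the frame total is conserved.
* Local-maxima ties on flat plateaus are resolved by keeping the
  lexicographically smallest coordinate — a deterministic rule that makes
  the stage reproducible and testable against a brute-force scan.
* The Rose constraint is strict (`> 3`), following "detectable if larger
  than three".
* Candidates closer than $\lceil\sigma_{PSF}\rceil + 1$ px to a border are
  rejected (neither ROI nor fit window fits); empty ROIs score zero.
* The fit window is a square of half-size $\lceil 2\sigma_{PSF}\rceil$
  (>95% of the PSF mass, limited neighbour contamination). Convergence is
  a relative parameter change below $10^{-6}$, capped at 200 iterations;
  non-convergence and singular Jacobians are statuses, not errors. The fit
  offset is a free parameter initialized at the local background, so
  background-map bias cannot shift positions. Plain (unweighted) least
  squares is used; the residual function is isolated so Poisson-weighted
  fitting could be added.
* Position initialization uses the background-subtracted centroid over the
  fit window (the ROI disk alone truncates the PSF asymmetrically and
  biases the centroid by ~0.07 px at typical sub-pixel offsets).
* A Thompson-style per-localization precision estimate
  $\sigma_{loc}^2 = (\sigma^2 + a^2/12)/N + 8\pi\sigma^4 b^2/(a^2N^2)$ is
  exported but not used as a filter.
* Zero matches in evaluation give `NaN` RMSD with a message, not an error;
  empty stacks and empty localization tables propagate as empty outputs.

## Problem sizes used in the test suite

The packaged tests validate the pipeline at desk scale: oracle-equivalence
property tests on hundreds of random 32×32 frames, parameter recovery on
2,000 simulated single spots, and an end-to-end reconstruction of 500
frames of the high-SNR regime at 256×256 px (~20,000 emitters), where the
Jaccard index exceeds 0.85 and RMSD stays below 30 nm at a 128 nm matching
tolerance — a conservative floor for this regime, chosen so the check is
robust to seed variation. Full-scale benchmark datasets (≈5,000 frames,
200,000 emitters) are a single `sim_regime()` call away but not exercised
in the default test run.

## Known limitations

* Overlapping emitters are discarded, not deconvolved; at high activation
  density recall drops by design.
* The quality scores are computed on the smoothed frame; very small
  `smooth_sigma_px` values make SNR_eff noisier and Q thresholds less
  transferable between datasets.
* 2D only: no astigmatic or biplane z-estimation (models 2–3 expose the
  widths such methods would need).
* The background estimator assumes emitters are sparse within the median
  window; dense quasi-uniform labeling will inflate the background and
  depress sensitivity.
* Streaming is per-frame in structure (results are frame-independent and
  order-invariant), but the TIFF reader decodes whole files, so memory
  scales with stack size at desk scale.
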