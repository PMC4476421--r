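# snsmlm — shot-noise based single-molecule identification and localization

`snsmlm` identifies and localizes single fluorescent emitters in
single-molecule localization microscopy (SMLM: PALM, dSTORM, …) image
stacks. Its premise is that the decision "is this blob a single molecule or
a background fluctuation?" should be made in units of the noise the camera
physically produces: photoelectron counts on an EMCCD are Poisson
distributed, so a background of *N*<sub>bg</sub> photoelectrons fluctuates
by *F*·√*N*<sub>bg</sub> (excess-noise factor *F* = √2 at high EM gain).

Each candidate spot (a local maximum within the Airy radius
*R*<sub>airy</sub> = 0.61 λM/(NA·μ), isolated from its neighbours) is
scored over its region of interest with

* **SNR**<sub>eff</sub> — the ROI mean of the per-pixel SNR
  *S*/(F·√*N*<sub>bg</sub>),
* **CNR**<sub>eff</sub> — summed signal over the aggregate shot noise of
  the full theoretical PSF disk, Σ*S* / (F·√Σ<sub>disk</sub>*N*<sub>bg</sub>),
* **Q = min(SNR<sub>eff</sub>, CNR<sub>eff</sub>)** — single-pixel spikes
  have high SNR but low CNR, over-broad blobs the reverse; neither is a
  single emitter, and the minimum penalizes both.

Acceptance requires CNR<sub>eff</sub> > 3 (the Rose criterion, fixed) and
Q ≥ a user threshold — the method's only free parameter. Accepted spots are
localized to sub-pixel precision by Levenberg–Marquardt 2D-Gaussian fitting
(fixed-width, symmetric, or elliptical model, with a PSF-width-tolerance
band and a Pearson goodness-of-fit filter).

The package also ships the pieces that make the pipeline verifiable without
microscope data: a ground-truth simulator for three benchmark regimes
(500 photons/emitter on uniform background 10 or 50 photons/pixel,
optionally plus a Gaussian-profile background peaking at 50 photons), the
Jaccard/precision/recall/RMSD evaluation protocol with distance matching,
and super-resolution rendering with line-profile width measurement.

## Worked example

```r
library(snsmlm)

cam <- camera_config(bias_offset = 100, effective_gain = 30,
                     pixel_size_nm = 64, numerical_aperture = 1.49,
                     emission_wavelength_nm = 665)
cam
#> camera_config:
#>   bias offset        100 counts
#>   effective gain     30 counts/e-
#>   excess noise F     1.414
#>   pixel size         64 nm (sample plane 64 nm)
#>   NA 1.49, lambda 665 nm
#>   Airy radius        4.254 px, PSF sigma 1.464 px

cfg <- sim_regime("high_snr", n_frames = 50, seed = 11)   # ~2000 emitters
st  <- simulate_stack(cfg)

res <- localize_stack(st$frames,
                      pipeline_config(camera = cam, q_threshold = 2,
                                      model = 1))
head(res$localizations[, c("frame", "x_nm", "y_nm", "photons_e",
                           "pearson_r", "q")], 3)
#>   frame      x_nm      y_nm photons_e pearson_r        q
#> 1     0 7240.3136  491.2021  461.6912 0.8945352 3.784328
#> 2     0 8228.4655 1170.0272  462.4485 0.9191685 3.724601
#> 3     0  507.1402 1192.9175  451.5718 0.9123314 3.834364

evaluate_localizations(st$truth, res$localizations, tolerance_nm = 128)
#> evaluation at 128 nm tolerance:
#>   TP 1940  FP 0  FN 45
#>   Jaccard 0.977  precision 1.000  recall 0.977  RMSD 14.3 nm
```

Of 1985 simulated emitters, 1940 are recovered with zero false positives;
the 45 misses are dominated by emitter pairs closer than the Airy radius,
which the isolation filter discards by design. The 14.3 nm RMSD is the
localization precision of ~460 detected photoelectrons per emitter against
the 64 nm pixel grid. Each localization carries its photon count, Pearson
goodness-of-fit, quality score Q, and a Thompson-style precision estimate.

A command-line front-end wrapping the same functions is installed at
`inst/cli/snsmlm` (`simulate`, `localize`, `evaluate`, `render`
subcommands); `vignettes/shot-noise-localization.Rmd` documents the model,
the estimator choices, and the generator's scope.

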