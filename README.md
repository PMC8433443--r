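# flimfg

Two-photon excitation (2PE) spectra, TCSPC lifetime fitting and neuron
counting for Fluoro-Gold imaging — with a synthetic-data generator for every
stage, so the whole pipeline can be validated against known ground truth.

Fluoro-Gold (FG) is a retrograde neuronal tracer. Imaged with two-photon
microscopy and time-correlated single-photon counting (TCSPC), its
fluorescence decay is bi-exponential with a very short component
(τ₁ ≈ 0.1 ns) and a long one (τ₂ ≈ 2.3 ns), giving an intensity-weighted
mean lifetime of about 1.4 ns — close to, but distinguishable from, the
≈ 1.35 ns mono-exponential autofluorescence background of brain tissue. That
lifetime contrast, plus the excitation-spectrum optimum, is what lets
FG-labeled neurons be mapped and counted in 3D.

## The model in one paragraph

A decay is d(t) = Σₖ aₖ e^(−t/τₖ) (Σ aₖ = 1) convolved *periodically* with a
Gaussian instrument response (default FWHM 100 ps) on a 12.5 ns / 256-bin
histogram (80 MHz excitation), plus a constant baseline; counts are Poisson.
The intensity-weighted mean lifetime is Σ aₖτₖ² / Σ aₖτₖ. Two-photon
fluorescence scales as F ∝ σ C P², and relative cross-sections come from a
reference dye via f_c(λ) = F_R/σ_R and σ_S = (F_S / f_c) · (C_R/C_S). See
`vignette("flimfg-methods")` for the full methods description.

## What's in the box

| Area | Key functions |
|---|---|
| Synthetic decays | `fg_decay()`, `background_decay()`, `make_irf()`, `simulate_decay()` |
| Decay fitting | `fit_biexponential()`, `fit_monoexponential()`, `fit_opts()` |
| FLIM maps | `scene_phantom()`, `simulate_flim_image()`, `fit_pixels()`, `lifetime_histogram()`, `lifetime_contrast()`, `contrast_spectrum()` |
| Spectra | `simulate_spectral_series()`, `correction_curve()`, `relative_cross_section()`, `spectral_peak()`, `power_exponent()` |
| Segmentation | `segment_cells()`, `count_cells()`, `connected_components()`, `place_cells()` |
| I/O + CLI | `write_decay_table()`, `write_stack()`, `write_label_volume()`, `flimfg_main()` (installed script `exec/flimfg`) |

## Worked example

Simulate a realistic FG acquisition (10⁶ photons, 100 ps IRF) and fit it:

```r
library(flimfg)
irf <- make_irf()                                   # 100 ps FWHM Gaussian
h   <- simulate_decay(fg_decay(), irf,
                      acquisition(total_photons = 1e6, seed = 42))
fit_biexponential(h, irf)
#> Decay fit (biexp, pearson weighting): converged
#> bi-exponential decay:
#>   a_1 = 0.9411  tau_1 = 0.09935 ns
#>   a_2 = 0.0589  tau_2 = 2.289 ns
#>   baseline = 3.65 counts/bin
#>   mean lifetime (intensity) = 1.392 ns
#>   IRF shift = 7.7e-06 ps, reduced chi^2 = 0.929 (df 250)
```

Both lifetimes, the 0.94/0.06 amplitude split and the 1.4 ns mean come back
from pure photon noise. Verifying the quadratic power dependence that marks
two-photon excitation:

```r
d <- simulate_power_series(powers = 1:10, exponent = 2,
                           noise_cv = 0.01, seed = 42)
power_exponent(d$power, d$intensity)$slope
#> slope 2.000, 95% CI [1.991, 2.009]
```

A full FLIM map works the same way: build a `scene_phantom()` with cells and
background, `simulate_flim_image()`, then `fit_pixels()` →
`lifetime_histogram()` / `lifetime_contrast()`. Cell counting is
`segment_cells()` + `count_cells()` on an intensity stack, optionally gated
by fitted lifetime.

The same recipes are scriptable without writing R:

```sh
flimfg simulate decay --seed 7 --out decay.tsv
flimfg fit decay --model biexp --in decay.tsv --out fit.json
flimfg segment --in stack.tif --out labels.tif --min-volume 100
```

Every `simulate` command writes a `<out>.config.json` with the fully resolved
parameters, and every output table/stack carries a JSON sidecar with its
metadata, so results are reproducible from the artifacts alone.

## License

MIT (see `LICENSE`).
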