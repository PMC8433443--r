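---
title: "Methods: synthetic two-photon Fluoro-Gold data and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic two-photon Fluoro-Gold data and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(flimfg)
```

`flimfg` models a two-photon excitation (2PE) microscope imaging brain tissue
labeled with the retrograde neuronal tracer Fluoro-Gold (FG), and implements
the standard analyses run on such data: time-correlated single-photon counting
(TCSPC) decay fitting, fluorescence-lifetime (FLIM) mapping, relative
two-photon cross-section spectroscopy, and 3D cell-body segmentation with
counting. This vignette documents the model, its parameters and their
rationale, and the numerical choices, so that results are interpretable
without reading the source.

## 1. The decay model

A pulsed laser (default repetition period $T = 12.5$ ns, i.e. 80 MHz) excites
the sample; emitted photons are histogrammed into $n = 256$ bins of width
$T/n \approx 48.8$ ps. The fluorescence impulse response is a sum of
exponentials,

$$ d(t) = \sum_k a_k \, e^{-t/\tau_k}, \qquad \sum_k a_k = 1 , $$

and the measured curve is its *periodic* convolution with the instrument
response function (IRF), plus a constant baseline from uncorrelated
background. Periodicity matters: a 2.3 ns component retains
$e^{-12.5/2.3} \approx 0.4\%$ of its intensity at the end of the period, so
each excitation inherits a tail from previous pulses. `periodic_decay_curve()`
accounts for this exactly with the per-component wrap factor
$1/(1 - e^{-T/\tau_k})$, and `model_decay()` performs the convolution with an
FFT on the circular time axis, which is the natural group for a periodic
train. Photon number is conserved exactly: the expected curve sums to the
requested photon count plus baseline.

### FG and background defaults

`fg_decay()` is bi-exponential with $\tau_1 = 0.1$ ns and $\tau_2 = 2.3$ ns.
The amplitude split is not free: it is solved by
`amplitude_for_mean_lifetime()` so that the *intensity-weighted* mean
lifetime,

$$ \bar\tau_\mathrm{int} = \frac{\sum_k a_k \tau_k^2}{\sum_k a_k \tau_k}, $$

equals 1.4 ns, giving $a_1 \approx 0.941$. The intensity weighting is the
package default for `mean_lifetime()` because it is what a photon-counting
histogram actually measures — each component contributes in proportion to the
photons it emits ($a_k\tau_k$), not to its amplitude. The amplitude-weighted
convention remains available as `mode = "amplitude"`.

`background_decay()` is mono-exponential with $\tau = 1.35$ ns, emulating
autofluorescent structures (lipofuscin-like granules) whose lifetime sits
close to, but below, the FG mean — which is exactly what makes
lifetime-based separation of tracer from background a quantitative question
rather than a triviality.

### The IRF

`make_irf()` samples a Gaussian of given full width at half maximum (default
100 ps, a typical hybrid-detector system response) at the bin centers and
normalizes to unit sum. Requests with FWHM below half a bin width are refused
("not resolvable") rather than silently aliased. `measure_fwhm()` measures
the width of any sampled kernel with linear interpolation of the two
half-maximum crossings; on a 1 ps grid it reproduces the constructed 100 ps
width to better than 0.01 ps, and on the native 48.8 ps grid to within one
bin.

## 2. Decay simulation and fitting

`simulate_decay()` draws independent Poisson counts around the expected curve
(default $10^6$ total photons, a realistic acquisition for a bright decay
curve) under `withr::with_seed()`, so every dataset is reproducible from its
recorded seed and metadata.

`fit_monoexponential()` / `fit_biexponential()` fit the same forward model by
Levenberg–Marquardt (`minpack.lm::nls.lm`) with box constraints. Choices, all
recorded in `fit_opts()`:

* **Weighting.** Default is Pearson weighting $1/\max(E_i, 1)$ — weighted
  least squares against the *model* counts, the convention of commercial
  TCSPC packages, and well-behaved in nearly empty bins. A Poisson
  maximum-likelihood option (`weighting = "mle"`, deviance minimized with
  L-BFGS-B) is provided for low-count work.
* **Nuisance parameters.** A constant baseline and an IRF "color shift"
  (fractional-bin circular translation, bounded at ±5 bins) are free by
  default; real systems always have both.
* **Initialization.** The long lifetime comes from the log-slope of the tail,
  the short one starts at 50 ps, and the amplitude split from extrapolating
  the tail component back to the peak. All are overridable via `opts$init`,
  which the FLIM layer uses to seed pixel fits from a global fit.
* **Identifiability guards.** Fits that land on a lifetime bound are marked
  non-converged; two-component fits whose lifetimes agree within 5% or whose
  minor amplitude is below $10^{-4}$ collapse to the mono model with an
  explicit warning; lifetimes longer than the excitation period are flagged
  as poorly identifiable (the periodic curve becomes flat in that limit).
* **Goodness of fit.** `reduced_chi_squared()` excludes bins with expected
  counts below 1 (where the Pearson statistic is meaningless) and divides by
  used bins minus free parameters. For a correctly specified model it sits
  near 1; values up to 2 are accepted as adequate in practice.

## 3. FLIM maps

`scene_phantom()` builds a voxel scene (z, y, x order) of ellipsoidal "cells"
with chosen decay, brightness and position over a uniform background, and
`simulate_flim_image()` attaches a photon histogram to every pixel.
`fit_pixels()` then:

1. optionally box-sums photons over $(2b+1)^2$ neighborhoods
   (`spatial_binning`, default $b=1$, i.e. 3×3) — the standard FLIM trick for
   trading spatial resolution for photon statistics;
2. fits the pooled global histogram once and uses the result to initialize
   each pixel fit;
3. refuses pixels below `min_photons` (default 500, roughly the minimum for a
   stable mean-lifetime estimate with these lifetimes) and errors if *no*
   pixel qualifies.

`lifetime_histogram()` summarizes a map with 250 bins over 0–5 ns (0.02 ns
resolution) and reports the mode, the natural summary for a peaked,
asymmetric lifetime distribution. `lifetime_contrast()` compares median
lifetimes between two disjoint masks; the default definition is the absolute
difference $|\tau_\mathrm{fg} - \tau_\mathrm{bg}|$ (invariant to a common
additive shift), with a normalized variant available.
`contrast_spectrum()` repeats this across datasets acquired at different
excitation wavelengths and reports the wavelength of maximum contrast,
breaking ties toward the shorter wavelength.

## 4. Excitation spectra and cross-sections

Two-photon fluorescence scales with the *square* of excitation power:
$F \propto \sigma \, C \, P^2$ for cross-section $\sigma$, concentration $C$.
`power_exponent()` verifies the exponent by ordinary least squares of
$\log F$ on $\log P$ (with its 95% CI), and `normalize_by_power()` divides
the quadratic term out of a measured series.

Everything wavelength-dependent that is *not* the fluorophore (laser
spectrum, optics, detector) is absorbed into one instrument curve via a
reference dye of known cross-section $\sigma_R(\lambda)$ measured under
identical conditions:

$$ f_c(\lambda) = \frac{F_R(\lambda)}{\sigma_R(\lambda)}, \qquad
   \sigma_S(\lambda) = \frac{F_S(\lambda)}{f_c(\lambda)}\cdot
   \frac{C_R}{C_S}. $$

`correction_curve()` and `relative_cross_section()` implement exactly these
quotients; wavelengths where $\sigma_R = 0$ are dropped and reported rather
than producing infinities, and mismatched wavelength grids are an error — the
package never resamples silently. `spectral_peak()` reports the argmax
together with `is_boundary`, because a maximum at the edge of the tuning
range (e.g. at a 720 nm lower limit of a Ti:sapphire laser) means the true
optimum may lie outside the measured window and must not be over-interpreted.

The generator `simulate_spectral_series()` produces sample and reference
series sharing one instrument curve and one power profile, with optional
multiplicative noise — sufficient to validate the correction algebra
end-to-end. It does not attempt to model detector saturation, bleaching, or
wavelength-dependent focal volume.

## 5. Segmentation and counting

Labeled cell bodies in a 3D stack are bright, blob-like and sparse, so a
classical pipeline is an adequate stand-in for learned methods and has the
advantage of being fully auditable:

Gaussian smoothing (`sigma` in voxels, default 2) → global Otsu threshold
(256-bin, scale-invariant) → optional hole filling → removal of components
below `min_volume` (default 100 µm³, well under the volume of a 5 µm-radius
soma) → optional watershed-style splitting of touching cells seeded at
Euclidean-distance-transform maxima separated by at least
`watershed_min_sep` voxels. An optional `lifetime_gate` restricts the
foreground to voxels whose fitted lifetime lies in a window, which is how
lifetime contrast turns into tracer-specific counting.

The 3D primitives (26/6-connectivity components, hole filling, separable
Gaussian, exact squared EDT, watershed growing) are implemented in-package
because the established image packages available here are 2D-oriented; each
primitive is tested against brute-force reference implementations.

`place_cells()` samples non-overlapping cells with a minimum surface gap
(`min_gap`, default 5 µm) emulating the neuropil that separates real somata;
without a gap, smoothing at the default `sigma` merges adjacent cells and the
count no longer reflects the scene.

## 6. Problem sizes and reproducibility

Defaults throughout are package choices sized so that every pipeline is
exercisable in seconds to a few minutes on one core: 256-bin histograms,
$10^6$ photons per decay, 64×64 FLIM fields at 5000 photons/pixel, tissue
blocks of order $48 \times 96 \times 96$ voxels with 10–20 cells. All
stochastic generators require a seed and run under `withr::with_seed()`, so
no call disturbs the caller's RNG state and every artifact is reproducible
from its metadata, which is preserved through the TSV/TIFF+JSON round trips
in the I/O layer (`write_decay_table()`, `write_stack()`, …) and by the
`flimfg` command-line interface (`flimfg_main()`).
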