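---
title: "Methods: time-domain diffuse optical sensing of deep tissue"
author: "lungtdos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-domain diffuse optical sensing of deep tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtdos)
```

## The problem

Time-domain diffuse optical spectroscopy (TD-DOS) injects picosecond laser
pulses into tissue and histograms the arrival times of single re-emitted
photons (a distribution of times of flight, DTOF). Photons detected after
several nanoseconds have diffused deep — a few centimetres — before
returning to the surface, which makes TD-DOS a candidate for sensing the
lung through the chest wall. `lungtdos` implements the computational
machinery such a feasibility study needs: a forward model and inverse
fitter for DTOFs, a trajectory-resolved Monte Carlo transport kernel for
layered media, broadband spectral analyses, gated-contrast analysis of
paced-breathing protocols, and a synthetic-data generator that emulates
the acquisition statistics so every stage is testable without
measurements.

## Forward model: diffusion with an extrapolated boundary

`trReflectance()` evaluates the time-resolved reflectance of a
homogeneous semi-infinite medium from the time-dependent diffusion
equation with the extrapolated boundary condition: the fluence is forced
to zero on a plane a distance $z_e = 2AD$ outside the surface, where
$D = 1/(3\mu_s')$ and the boundary factor $A$ captures internal
reflection at the refractive-index mismatch (Groenhuis polynomial
approximation; $A \approx 3.25$ for tissue against air at $n = 1.4$). A
single image-source pair (an isotropic source at $z_0 = 1/\mu_s'$ and its
negative mirror about the extrapolated plane) realises the condition;
further image pairs matter only for slabs, not for reflectance from a
semi-infinite medium, so one dipole is used for simplicity and speed.

Two structural properties of this solution are load-bearing and are
asserted in the tests to machine precision:

* causality — the curve is identically zero for $t \le 0$;
* Beer–Lambert factorisation — with $D$ defined scattering-only,
  $R_{\mu_a}(t) = R_0(t)\,e^{-\mu_a v t}$ exactly.

The refractive index of tissue is taken as $n_{in} = 1.4$ (standard soft
tissue, configurable), the exterior as air; all time/path conversions use
$v = c/n_{in}$. The model amplitude is arbitrary: fits carry a free scale.

Measured DTOFs are the convolution of the physical reflectance with the
instrument response function (IRF). `convolveIRF()` performs the discrete
causal convolution on the shared channel grid (FFT-based, with the IRF's
$t = 0$ channel as the origin), so that a unit-count IRF at $t = 0$
reproduces the model and total counts factorise.

## Monte Carlo transport with trajectory storage

`runMC()` is a layered-slab, time-resolved photon transport kernel
(compiled, as is standard for photon Monte Carlo) with three deliberate
design choices:

* **No absorption during transport** (microscopic Lambert–Beer): each
  detected photon stores its per-layer geometric path lengths $L_j$, exit
  time, exit radius and maximum visited depth. Any absorption vector is
  applied afterwards as the weight $w = \exp(-\sum_j \mu_{a,j} L_j)$
  (`applyAbsorption()`). One transport run therefore serves every
  absorption state, and perturbation contrasts computed from the same
  records (`perturbationContrast()`, correlated sampling) have variance
  far below independent runs. Scattering perturbations do require a
  second, ideally paired-seed, run (`independentRunContrast()`), which
  carries full independent-run noise — the methods make that distinction
  explicit.
* **Isotropic scattering by default** ($g = 0$, $\mu_s = \mu_s'$): by the
  similarity relation, time-resolved reflectance at these scales is
  insensitive to the anisotropy once $\mu_s'$ is fixed; $g$ is
  configurable (Henyey–Greenstein) for sensitivity studies.
* **Annular detection** at $\rho \pm 0.25$ cm, or accept-all-exits for
  depth statistics, which are rigorously independent of detection radius
  and absorption in a homogeneous medium.

Photons launch at the origin heading into the medium; free paths are
sampled as optical depth consumed across layers (exact for exponential
free paths); the top surface applies unpolarized Fresnel
reflection/refraction. Trajectories are abandoned beyond a configurable
recording time (default 10 ns). An exact pruning rule removes photons
that can no longer reach any detectable exit within the remaining path
budget — this is a pure efficiency device and provably does not bias the
detected set. The internal RNG is a xoshiro256++ stream seeded from the
user's integer seed, so identical (seed, parameters) reproduce identical
results bit for bit.

`meanMaxDepthCurve()` summarises probing depth: the unweighted mean of
the per-photon maximum visited depth, binned by arrival time. Because a
homogeneous absorption multiplies every weight in a narrow arrival-time
bin by (nearly) the same factor $e^{-\mu_a v t}$, the mean is invariant
under absorption reweighting — asserted numerically in the tests.

## Inverse problem: fitting DTOFs

`determineFitRange()` implements the standard fitting window: from the
channel on the leading edge where counts first exceed 80% of the peak
(scanning back from the peak) to the last channel on the falling edge
still above 1% of the peak, taken at the first downward crossing so that
noisy tails do not re-enter the window. Both thresholds are relative, so
the range is invariant under count rescaling.

`fitHomogeneous()` minimises the Pearson chi-square (model-based
variance, the Poisson-appropriate weighting) between the measured counts
and the amplitude-scaled, time-shifted, IRF-convolved model over that
window, with Levenberg–Marquardt under bounds
$\mu_a \in [0, 2]$ cm$^{-1}$, $\mu_s' \in [1, 50]$ cm$^{-1}$ and a time
shift bounded to $\pm 100$ ps. The shift absorbs residual offset between
the IRF peak (the nominal $t = 0$) and the true injection instant — the
data cannot distinguish a small shift from a bias in $\mu_s'$, so the
bound is deliberately tight. Three multi-starts run only when the first
fit does not converge; a stalled optimizer returns `converged = FALSE`
rather than raising, so per-acquisition failures never abort a series
(`fitTimeseries()` additionally warm-starts each acquisition at its
predecessor's result).

## Broadband spectroscopy

Absorption spectra are decomposed by non-negative least squares over five
absorbers — deoxy- and oxy-hemoglobin (per µM), water, lipid and collagen
(per g/cm³) — via `fitComposition()`; non-negativity is the only
regularisation. Reduced scattering spectra follow the empirical power law
$\mu_s'(\lambda) = a(\lambda/600\,\mathrm{nm})^{-b}$, fitted by linear
regression in log–log space (`fitPowerLaw()`), which is exact on
noiseless power-law input.

The bundled chromophore table is **synthetic**: smooth spectra anchored
at literature-order values (near-infrared hemoglobin extinctions, the
975 nm water and 930 nm lipid bands, a broad rising collagen background).
No published compilation is redistributed, and composition results are
always basis-dependent; accordingly every composition test in this
package is self-consistent — spectra are generated from the bundled basis
and recovered with it. Absolute concentrations from real data would
require substituting a laboratory-validated basis, which the
`ChromophoreBasis` container accepts directly.

## Breathing-protocol analysis

The paced protocols alternate suspended full inspiration (IN) and
expiration (OUT): Prot10 is 5 repetitions of 10 s phases; Prot5 is 10
repetitions of 5 s phases preceded by one normal-breathing repetition
used as a reference. At the default cadence of 1 acquisition/s (the
cadence is configuration, not a measured fact) these yield 100 and 110
acquisitions respectively.

`gatedContrast()` computes, per acquisition and time gate
$[t, t + \Delta t)$, the relative contrast
$C = (\int_{gate} R - \int_{gate} R_0)/\int_{gate} R_0$ with the
reference $R_0$ the element-wise mean count-rate curve over the whole
exercise (the normal-breathing prefix excluded by default). Gates with a
zero reference integral are flagged undefined, never silently zero. The
default gate family is $t \in \{0.5, \dots, 4.5\}$ ns with
$\Delta t = 0.5$ ns. `foldingAverage()` averages across repetitions at
matched within-cycle offsets; folding is applied after the contrast,
whose reference remains the unfolded whole-exercise mean.
`phasePlateauSummary()` reports per-gate IN/OUT plateau means and their
difference, excluding a 2 s transient at each phase start — "plateau" is
not defined by the protocol itself, and 2 s drops the
inhalation/exhalation transitions at both cadences.

`estimateTmax()` gives the latest usable gate: the largest gate start
whose 0.5 ns gate still collects more than 10,000 counts/s (1% shot
noise), the practical limit for late-gate analysis.

## The synthetic-data generator

The generator produces every input the analyses consume, each with its
ground truth attached:

* `generateIRF()` — Gaussian-rise/exponential-tail instrument response,
  default 150 ps FWHM (plausible for SiPM/hybrid detectors; the width is
  configurable), peak at $t = 0$, Poisson-sampled.
* `generateDTOF()` — forward model × IRF, scaled to a 1 Mcounts/s
  operating point (the single-photon-statistics regime of TCSPC
  electronics) for the configured acquisition time, per-channel Poisson
  counts, optional uniform background (default 0).
* `generateSpectralSeries()` — a broadband series (default 600–1100 nm
  in 10 nm steps, 4 s per wavelength, $\rho = 3$ cm) from a tissue
  composition and power-law scattering truth.
* `generateProtocolSeries()` — the two-layer chest+lung scenario: chest
  wall $\mu_s' = 7$ cm$^{-1}$ over lung $\mu_s' = 12$ cm$^{-1}$
  (inside the plausible range for lung, whose scattering hardly affects
  the contrast), baseline $\mu_a = 0.15$ cm$^{-1}$ in both layers (the
  midpoint of chest-wall values measured around 800 nm), lung roof at
  3 cm, $\rho = 6$ cm, and a 10% reduction of lung absorption during IN
  phases mimicking the density drop on inhalation. One absorption-free
  transport run per distinct scattering state is reused across all
  acquisitions via Lambert–Beer reweighting, so a 100-acquisition series
  costs one Monte Carlo run.

What the generator does *not* emulate — and hence what passing tests do
not show about real chests: anatomical heterogeneity (ribs, muscle
layering), the pleural membranes and any light-guiding they may cause,
subject motion, detector afterpulsing, and nonlinear scattering changes
with lung inflation. The two-layer slab is an idealisation; results on
real data depend on factors the model deliberately omits.

## Numerical choices and problem sizes

* Channel width 10 ps; generator axes run from −1 to 9 ns so the IRF
  rise is captured; histogram axes for Monte Carlo output run 0–10 ns.
* Transport runs use $10^5$–$2\times10^5$ detected photons for headline
  depth/contrast numbers and $10^3$–$5\times10^4$ inside the test suite;
  correlated reweighting keeps contrast estimates stable at these
  budgets, and the statistical tests state their tolerances in the
  corresponding counting noise.
* The exact pruning bound (straight-line distance to the nearest
  detectable exit vs remaining path budget) typically cuts transport
  cost severalfold at large $\rho$ without touching the detected set.
* NNLS via an active-set solver; bounded Levenberg–Marquardt for curve
  fits; FFT convolution with brute-force fallback below 64 channels.
* Degenerate inputs are rejected with specific messages: all-zero curves
  (no fit range), negative counts (file I/O names the row), empty gates
  (flagged undefined), exhausted launch budgets (partial result plus
  warning flag).

## Worked example

A miniature end-to-end run of the three workflows (reduced problem sizes;
the full-scale conditions are in `scripts/acceptance.R`):

```{r example, eval = FALSE}
cfg <- runConfig(wavelengths = seq(700, 1060, 120),
                 nDetectedProtocol = 1500, nDetectedZmax = 4000, seed = 7)
bundle <- runPipeline(cfg)
bundle$spectroscopy$composition   # recovered chromophore concentrations
bundle$protocol$plateau           # per-gate IN/OUT plateau contrast
bundle$depth$meanMaxDepth_cm      # probing depth at the configured time
```

## Known limitations

* The homogeneous inverse model applied to layered media is a
  deliberate simplification: fitted $\mu_a$ tends toward the deep layer
  at late times while $\mu_s'$ reflects the superficial layer, so the
  fitted time series during a breathing task mixes the two.
* Contrast magnitudes from the two-layer scenario depend linearly on the
  assumed baseline absorption, which real chests only constrain to a
  range; the package's defaults state one point in that range.
* Scattering-perturbation contrasts carry independent-run Monte Carlo
  noise and need photon budgets an order of magnitude larger than
  absorption perturbations for the same precision.
* The analytic solver covers the semi-infinite homogeneous geometry
  only; layered media are handled by Monte Carlo, not by a two-layer
  analytic inverse.
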