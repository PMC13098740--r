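---
title: "Multi-layer look-up-table inverse models for FD-NIRS and DCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer look-up-table inverse models for FD-NIRS and DCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Frequency-domain near-infrared spectroscopy (FD-NIRS) measures the amplitude
attenuation and phase delay of intensity-modulated light after it has
diffused through tissue, and from them the absorption coefficient
$\mu_a$ and reduced scattering coefficient $\mu_s'$. Diffuse correlation
spectroscopy (DCS) measures the temporal intensity autocorrelation
$g_2(\tau)$ of multiply scattered coherent light and, through it, a blood
flow index (BFi, mm$^2$/s). Muscle measurements are made through skin and
adipose whose optical properties vary with skin pigmentation and whose
thickness varies between subjects; a homogeneous ("single-layer") inverse
model silently attributes part of the signal to those upper layers and
biases the recovered muscle properties. `mldos` implements subject-specific
three-layer look-up-table (LUT) inverse models that fix the upper layers
from a skin-tone class (via the individual typology angle, ITA) and a
measured adipose thickness, and recover only the bottom-layer (muscle)
properties.

This vignette records the model, its assumptions, the numerical choices,
and what the synthetic validation does and does not demonstrate.

## Layered Monte Carlo engine

The forward model is a layered-slab Monte Carlo (`run_layered_mc()`,
compiled C++). A pencil beam enters at the origin normal to the surface
($z$ positive downward); layers are horizontal slabs over a semi-infinite
bottom layer. Scattering uses the Henyey–Greenstein phase function with
per-layer anisotropy $g$ and $\mu_s = \mu_s'/(1-g)$; unpolarized Fresnel
reflection/refraction is applied at the surface and at internal
index-mismatched interfaces, with the specular entry loss deducted from the
launch weight. Detection is an annulus centred on the source at the
source–detector separation (25 mm by default) with configurable half-width
(0.5 mm default; the heavier validation pipelines use 2 mm, which only
changes the radial averaging window and is applied identically to forward
data and LUTs). For every detected photon the engine records per-layer
pathlengths $L_j$ and per-layer dimensionless momentum transfer
$Y_j=\sum(1-\cos\theta)$ over the scattering events in layer $j$.

Transport is *white in absorption for every layer*: photons propagate with
$\mu_a = 0$ and absorption is applied afterwards as Beer–Lambert weights
$w = \exp(-\sum_j \mu_{a,j} L_j)$ on the recorded pathlengths. Because
scattering paths are independent of absorption, a single photon set serves
the entire absorption axis of a LUT — and, for tissue presets whose
upper-layer scattering does not depend on pigmentation, every skin-tone
class at a given wavelength. A baked-in absorption mode exists for
validation; with Russian roulette disabled the two modes traverse identical
trajectories and agree to machine precision (this is asserted in the
tests).

Two variance-reduction devices keep the zero-absorption random walk
affordable on one CPU:

* **Reference survival absorption** (`mua_ref`, default 0.005 mm$^{-1}$):
  each photon draws an exponential absorption path at rate `mua_ref` and
  terminates there; detected weights are compensated by
  $e^{+\mu_{a,\mathrm{ref}} L}$. This is an unbiased importance-sampling
  scheme for any downstream per-layer $\mu_a$, and variance-optimal near
  $\mu_a = \mu_{a,\mathrm{ref}}$; every absorption value used by the
  presets and axes is at or above the default, so compensated weights never
  grow along a path.
* **Similarity-relation deep zone** (`similarity_depth`, default 2
  transport mean free paths): beyond that depth inside the bottom layer,
  transport switches to the transport-equivalent reduced medium
  ($\mu_s \to \mu_s'$, $g \to 0$), preserving pathlength and
  momentum-transfer statistics at diffusion scale with roughly ten-fold
  fewer scattering events for $g = 0.9$. The mean momentum transfer per
  unit path, $\mu_s(1-g) = \mu_s'$, is invariant; the first-order effect on
  $g_1$ is therefore nil, and the diffusion-oracle agreement tests bound
  the residual.

The RNG is xoshiro256++ seeded by splitmix64; every simulation stream is a
pure function of one integer seed, and repeat simulations for LUT nodes use
seeds derived deterministically from (base seed, node, repeat), so pooled
batches are reproducible and independent.

Termination: total pathlength cap 3000 mm (contributions beyond it are
suppressed by at least $e^{-0.005 \cdot 3000}$ under the reference
absorption); Russian roulette (threshold $10^{-4}$, survival 0.1) applies
only in baked-absorption mode.

## Forward models

* **FD-NIRS**: photon arrival times $t = \sum_j n_j L_j / c$ are binned
  into a time-of-flight histogram (10 ps bins to 12 ns by default; weight
  is conserved under rebinning) and Fourier-transformed at the modulation
  frequency, $R(\omega) = \sum w\, e^{-i\omega t}$. Reported phase is
  $-\mathrm{Arg}\,R$, so phase is positive and increases with modulation
  frequency, scattering, and distance. The LUT builder uses the same
  bin-midpoint quantization, so LUT values and forward "measurements" are
  numerically commensurable. Amplitudes are normalized per launched
  photon.
* **DCS**: Brownian dynamics with per-layer mean-square displacement
  $\langle\Delta r^2\rangle = 6\,\mathrm{BFi}_j\,\tau$ gives
  $G_1(\tau) = \sum_s w_s \exp(-2\tau \sum_j k_{0,j}^2 Y_{sj}
  \mathrm{BFi}_j)$ with $k_{0,j} = 2\pi n_j/\lambda$ evaluated with each
  layer's own refractive index; $g_1 = G_1/G_1(0)$ (the normalization
  cancels any launch-weight convention) and the Siegert relation
  $g_2 = 1 + \beta g_1^2$ applies the instrument coherence factor
  ($\beta = 0.45$ for the phantom configuration, $\approx 0.35$ in vivo).
  The DCS wavelength is 850 nm while the preset optical properties are
  tabulated at 730/830 nm; the forward model maps the 830 nm properties to
  the DCS wavelength (the wavenumber uses 850 nm), a stated approximation
  configurable per call.

## Diffusion oracles

Two independent closed forms validate the engine: the extrapolated-boundary
semi-infinite frequency-domain solution (`diffusion_fd_semi_infinite()`,
with annulus averaging for like-for-like detector comparison) and its
correlation-diffusion counterpart via
$\mu_a \to \mu_a + 2\mu_s' k_0^2 \mathrm{BFi}\,\tau$. For layered media the
package carries an N-layer Hankel-space solution
(`diffusion_fd_nlayer()`): an admittance recursion through the stack with
Gauss–Legendre panels between Bessel zeros for the oscillatory inversion —
naive quadrature loses the answer to catastrophic cancellation at 25 mm.
For homogeneous media at the preset separations the Monte Carlo engine
matches the closed forms within 5% in amplitude and 1° in phase, and
$g_1$ within 0.02 RMS; these are the core correctness gates.

## Look-up tables and inversion

LUT axes follow the study design: bottom-layer $\mu_s'$ is simulated at a
coarse 0.1 mm$^{-1}$ step over 0.1–1.0 mm$^{-1}$ (ten simulations pooled
per node) and densified by *linear interpolation of the complex reflectance*
(real and imaginary parts separately — interpolating amplitude/phase was
the alternative; the complex choice follows the stated "linear
interpolation on the complex FD reflectance") to 0.001 mm$^{-1}$ for
FD-NIRS and 0.05 mm$^{-1}$ for $g_2$. The absorption axis
(0.01–0.2 mm$^{-1}$) is evaluated densely (0.001 mm$^{-1}$) by Beer
reweighting, which is exact and cheap. The BFi axis is 121 log-spaced
nodes over 0.1–40 × 10$^{-6}$ mm$^2$/s; BFi enters $g_1$ analytically, so
the DCS LUT stores $g_1^2$ (with $\beta$ applied at query time) and the
fit refines continuously between nodes. LUTs persist to version-stamped
full-precision JSON with payload checksums; loading a tampered or truncated
file fails loudly.

FD inversion is a dense grid search minimizing
$\chi^2 = (\Delta\ln A/\sigma_A)^2 + (\Delta\phi/\sigma_\phi)^2$ with
unweighted defaults ($\sigma_A = \sigma_\phi = 1$); with one modulation
frequency per wavelength the data are two observables for two unknowns, so
any objective with an attainable zero finds the same minimum and the
weights only matter for inconsistent (model-mismatched or noisy) data.
Ties break toward smaller $\mu_a$, then smaller $\mu_s'$; minima on an axis
edge set boundary flags rather than failing. DCS inversion is least squares
over the BFi axis inside the delay window where the measured correlation
exceeds the noise floor ($g_2 - 1 > 0.01\beta$), with $\beta$ fixed or
fitted linearly. The single-layer comparison model is the same machinery
run on a homogeneous-medium LUT. For liquid-phantom processing the known
bottom optical properties can be supplied to the DCS fit directly, which is
how the phantom validation is scored; in vivo the FD-recovered properties
at the matched wavelength are used.

Calibration: synthetic pipelines operate directly in model space; for
instrument data a complex phantom-reference factor
(`calibration_factor()`) maps measurements into it.

## Hemodynamics

Chromophores come from the 2×2 Beer–Lambert system at 730/830 nm after
subtracting fixed water (62.5%) and lipid (20%) background absorption.
The bundled extinction table (packaged CSV, swappable) uses base-10 molar
extinction coefficients, with the $\ln 10$ conversion applied once in the
solver — the classic 2.303× pitfall is confined to one line and one test.
Negative concentrations are flagged, never clipped.
$\mathrm{StO_2} = 100\,\mathrm{oxy}/\mathrm{total}$, and
$\mathrm{MRO_2} = \mathrm{HGB} \times \mathrm{BFi} \times
(\mathrm{SpO_2} - \mathrm{StO_2}) / (\mathrm{venous\ ratio} \times
\mathrm{mw_{Hb}})$ with defaults HGB 16 (male) / 14 (female) g/dL,
SpO$_2$ 0.98, venous ratio 0.75, mw 64,500 g/mol. MRO$_2$ is reported in
the pseudo-units mol·mm$^2$·L$^{-1}$·s$^{-1}$ that the BFi factor carries.

## Sensitivity analysis

Eight upper-layer assumptions (skin/adipose thickness, $\mu_a$, $\mu_s'$,
BFi) are perturbed one at a time by their tabulated population
variabilities (10–75%), the perturbed medium is forward-modelled, inverted
with the *unperturbed* multi-layer LUTs, and scored as
$((\mathrm{recovered}-\mathrm{truth})/\mathrm{truth}\times 100\%)/
\mathrm{perturbation}\%$ at 1 mm adipose. Perturbations are one-sided
positive by default (the tabulated magnitudes carry no signs); a
`direction` argument enables two-sided evaluation. Each sensitivity is a
mean over seed replicates (three by default) with its standard error.
Under white-absorption transport, perturbations of upper-layer $\mu_a$ or
BFi cannot change photon paths, so they are evaluated by exact reweighting
of a shared unperturbed forward batch — a variance-reduction choice that
removes Monte Carlo noise from those rows entirely.

## Synthetic data

The generators make every pipeline stage testable without hardware.
Phantom-stack bundles mirror the physical validation design: skin-tone
phantom (1 mm) + adipose phantoms (1–6 mm) over either a static silicone
muscle or a Brownian intralipid muscle (BFi 1.05 × 10$^{-6}$ mm$^2$/s),
with $\beta = 0.45$ and embedded ground truth. Breathing-protocol series
use baseline (60 s) / load (60 s) / recovery at 0.5 Hz; muscle chromophore
and BFi trajectories deviate along a smoothed trapezoid (10 s ramps)
during load and are forward-modelled through the subject's three-layer
medium frame by frame. Defaults place the subject near the cohort centre:
baseline oxy 90 µM, deoxy 30 µM (StO$_2$ 75%), BFi 2 × 10$^{-6}$
mm$^2$/s, load deviations −20 µM oxy, +12 µM deoxy, +1.5 × 10$^{-6}$
mm$^2$/s BFi. The noise model is phenomenological: 1% multiplicative
amplitude noise, 2 mrad phase noise, and additive $g_2$ noise shrinking
with delay as $(\tau_{\min}/\tau)^{1/4}$; amplitude–phase independence is
assumed and stated. Time-series summaries take the baseline as the mean of
the first 50 s and the perturbation magnitude as the largest absolute
deviation from baseline inside the load window.

Because the study's muscle truth is a range, not a point, the default
muscle layer is a fixed documented choice within it:
$\mu_a$ 0.030/0.025 mm$^{-1}$, $\mu_s'$ 0.75/0.70 mm$^{-1}$ (730/830 nm),
BFi 2 × 10$^{-6}$ mm$^2$/s, $g = 0.9$, $n = 1.38$ — a representative
resting skeletal muscle. The ambient refractive index defaults to 1.0
(air); the probe face is not modelled.

## Problem sizes

The test suite runs reduced problem sizes chosen for a single CPU: LUT
nodes pooled from 3 × 70–120k photons, forward runs of 3–6 × 10$^5$
photons, oracle comparisons at 2 × 10$^6$ photons, and a reduced LUT
scattering axis (0.4–1.0 mm$^{-1}$) for the multi-layer round trips. The
acceptance script rebuilds everything at larger budgets (2 × 10$^5$ per
repeat per node, 8 × 10$^5$ per forward run, three seed replicates and all
three skin tones for the sensitivity table). At these sizes the remaining
Monte Carlo noise on recovered parameters is at the percent level, which
is the dominant uncertainty on the reported sensitivities.

## Known limitations

* The stack forward model is idealized: perfectly planar layers in optical
  contact, no lateral boundaries, no probe face, no fibre numerical
  aperture. Real stacked-phantom measurements include coupling and finite
  geometry effects that this model deliberately omits. The multi-layer
  round trips are self-consistency checks; agreement with an independent
  N-layer diffusion solution is the external check.
* Diffusion-based oracles are marginal for thin, low-scattering,
  strongly absorbing skin layers; cross-engine comparisons there use
  phases and ratios, not absolute amplitudes.
* Brownian dynamics only; no random-ballistic or hybrid $g_1$ models.
* Skin tone enters through three discrete classes, not continuous ITA.
* The DCS wavelength mapping (830 nm properties at 850 nm) is an
  approximation, configurable but not eliminated.
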