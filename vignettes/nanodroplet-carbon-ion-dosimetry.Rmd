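---
title: "Ultrasound-assisted carbon-ion dosimetry with superheated nanodroplets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound-assisted carbon-ion dosimetry with superheated nanodroplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ndvap)
```

`ndvap` simulates and quantifies a dosimetry concept in which superheated
perfluorobutane (PFB) nanodroplets dispersed in a tissue-mimicking phantom
are vaporized by carbon ions at the Bragg peak, and the resulting
microbubble contrast in B-mode ultrasound images is used to measure dose
and verify the beam range. This vignette documents the models, the
assumptions behind them, the tunable parameters, and the design decisions
taken where the published account leaves the construction open.

## 1. Nucleation physics of the superheated core

A liquid held above its boiling point is metastable; the degree of
superheat

$$s = \frac{T - T_b}{T_c - T_b}$$

normalizes the operating temperature $T$ between the boiling point $T_b$
and the critical temperature $T_c$. PFB (C₄F₁₀, $T_b = -2$ °C,
$T_c = 113.2$ °C) gives $s = 0.34$ at body temperature — superheated enough
that a sufficiently dense energy deposition nucleates a vapor embryo, yet
stable against homogeneous nucleation.

The thermal-spike model treats a single ion track as a line source of heat.
Vaporization requires that the energy deposited along twice the critical
embryo radius exceeds the energy of forming that embryo:

* critical radius (mechanical equilibrium):
  $R_c = 2\sigma(T) / (p_v(T) - p_0)$,
* nucleation energy: $W_\mathrm{tot} = 4\pi R_c^2 \sigma(T) +
  \tfrac{4}{3}\pi R_c^3 \rho_v h_{fg}(T)$,
* LET threshold: $\mathrm{LET}_{th} = W_\mathrm{tot} / (2 R_c)$.

The surface plus latent-heat composition is the package default; an
expansion-work term $\tfrac43 \pi R_c^3 (p_v - p_0)$ can be switched on
(`nucleation_energy(..., include_expansion_work = TRUE)`); it contributes
only a few percent here.

**Property closures.** Only the boiling point of PFB is fixed by the
application; the remaining thermophysics come from standard literature
constants shipped in `inst/extdata/pfc_properties.csv` and turned into
temperature correlations by `pfc_properties()`:

* vapor pressure: two-point Clausius–Clapeyron through the normal boiling
  point and the critical point (this pins $p_v(T_b)$ to 1 atm exactly);
* surface tension: Guggenheim–Katayama $\sigma_0 (1 - T/T_c)^{11/9}$
  anchored at 9.4 mN/m (25 °C);
* latent heat: Watson correlation from 96.2 kJ/kg at the boiling point;
* vapor density: ideal-gas law at $p_v(T)$ — a documented approximation;
  PFB vapor near 4 bar deviates from ideality by roughly 10%, which is well
  inside the model's other uncertainties.

With these closures the PFB threshold at 37 °C and 1 atm evaluates to
about 138 keV/µm, within ~5% of the published estimate of 145 keV/µm —
agreement is expected only within the tolerance of the property choices.
The threshold falls steeply with temperature (about 430 keV/µm at 25 °C),
which is why the droplets respond to primary carbon ions at physiological
temperature but not at room temperature. The ideal-gas liquid→gas radius
expansion factor is ≈5.5 at 37 °C; the frequently quoted "factor of 10"
can be imposed via the `override` argument of `expansion_factor()`.

## 2. Beam model

The package does not transport particles. `pristine_bragg()` builds an
analytic stand-in for a measured carbon-ion depth-dose curve: a
continuous-slowing-down rise $\propto 1/\sqrt{R - z}$ convolved with a
Gaussian range-straggling kernel, peak-normalized, with a constant
fragmentation tail (default 5% of peak) beyond the distal edge. The kernel
width is solved numerically so the curve's distal W₈₀ (full width at 80%
of peak) equals a requested value; the reference widths are the measured
2.72 mm (50 mm range) and 3.04 mm (180 mm range), linearly interpolated
for intermediate ranges by `reference_w80()`. The default grid step of
0.05 mm is ten times finer than the 0.3 mm range-accuracy claims being
tested.

Spread-out Bragg peaks are weighted sums of pristine peaks
(`sobp()`); `sobp_weights()` solves non-negative least squares for a flat
plateau, which yields the expected distal-heavy weighting. Dose converts
to fluence linearly, anchored at 0.1 Gy ↔ 1.25×10⁶ C-ions/cm²
(`dose_to_fluence()`), valid for the fixed reference beam quality.

**Depth-LET surrogate.** `let_profile()` supplies the track-averaged LET
the vaporization gate needs without a transport calculation. Its only
contractual property is its threshold crossing: the proximal branch is a
power law pinned so the LET crosses the nucleation threshold exactly where
the dose first reaches 60% of its peak — the empirically observed
vaporization onset. Distally the LET decays as a Gaussian with twice the
straggling sigma: near the end of range it is the surviving fluence, not
the per-track LET, that collapses, so the gate must stay open through the
distal dose R50 (with a shorter decay the simulated vaporization zone was
truncated proximal of R50 and could not reproduce the observed
sub-millimetre fall-off agreement). The peak LET (default 400 keV/µm) is a
free parameter; it only needs to exceed the threshold comfortably, and the
onset calibration absorbs its exact value.

## 3. Synthetic phantom and vaporization events

`phantom_spec()` fixes the container geometry (inner 54 × 26 × 31 mm,
2 mm front wall — the wall thickness is not printed and 2 mm of PMMA was
chosen once), the entrance position along the beam axis (144, 154 or 20 mm
depending on the experiment) and the 37 °C operating temperature.

Droplets are uniformly dispersed with truncated log-normal diameters
(median 700 nm, geometric SD 1.3, truncated to 200–1000 nm; the resulting
sample mean is ≈690 nm, matching the reported 700 ± 100 nm).
`sample_droplets()` instantiates only droplets inside the three imaged
elevational slabs (importance sampling — the full 43 ml phantom at
4×10⁶ ND/ml would be 1.7×10⁸ droplets, of which all but the imaged slabs
are irrelevant); the count in each slab is Poisson with the exact
concentration × volume expectation, so concentration semantics are
preserved.

Two stochastic vaporization channels produce bubbles:

* `spontaneous_vaporization()` — independent Bernoulli per droplet with
  probability $\min(1, p_0 e^{(d - d_\mathrm{ref})/d_\mathrm{scale}})$,
  increasing with diameter because large droplets are least stabilized by
  Laplace pressure. The default $p_0 = 10^{-5}$ yields a few tens of
  isolated bright spots per frame, the qualitative pre-irradiation
  appearance.
* `irradiate()` — a one-hit superheated-detector model: at beam-axis depth
  $z$ a droplet of diameter $d$ vaporizes with probability
  $p = 1 - \exp(-\varepsilon\, \sigma_{geo}(d)\, \Phi(z))$ wherever
  $\mathrm{LET}(z)$ meets the threshold, and never elsewhere.
  $\sigma_{geo} = \pi (d/2)^2$ is the geometric cross-section and
  $\Phi(z)$ scales the peak fluence by the local relative dose, emulating
  the thinning of the stopping-ion population. The response depends only
  on total fluence, never on delivery rate — the observed dose-rate
  independence holds by construction and is verified as an invariant.

The efficiency scalar $\varepsilon$ (default 0.07) is a free parameter of
the one-hit model: it aggregates the probability that a geometric hit
deposits its energy close enough to the track core to nucleate. It was
calibrated jointly with the imaging parameters (Section 4) so that the
rendered images reproduce the reported behaviours: a clearly
super-background but unsaturated 1 Gy peak, saturation emerging at 2 Gy
and above, and an integral response linear below ~1–2 Gy.

## 4. B-mode synthesis

`render_frame()` renders one 8-bit frame per elevational slab (rows =
probe depth, columns = lateral position along the beam; the beam enters at
the left edge):

1. bubble echo amplitudes $\propto r^3$ (Rayleigh scattering regime),
   binned onto the pixel grid and spread by an anisotropic Gaussian PSF
   (lateral σ 0.05 mm, axial σ 0.04 mm);
2. logistic saturation of the accumulated blob density,
   $S = S_\mathrm{max} B / (B_{1/2} + B)$ — dense clusters cannot scatter
   proportionally more;
3. acoustic shadowing: pixels below accumulated echo mass are attenuated
   exponentially (`shadow_coef`), darkening the region under dense bubble
   clouds;
4. iid Rayleigh speckle added to the envelope;
5. log compression to 8 bits with the gain anchored to the saturated echo
   envelope, and the speckle scale solved so the pure-background mean grey
   equals `speckle_mean` (default 10).

Gain is fixed across pre- and post-irradiation frames by construction, and
rendering refuses mechanical indices ≥ 0.4, the acoustic-droplet-
vaporization threshold. `scan_phantom()` images three slabs evenly spaced
across the phantom width with the probe centered on the container's inner
mid-length.

**What the renderer does and does not emulate.** It reproduces the
features the quantification depends on — speckle background with sparse
bright spots, a confined hyperechoic vaporization zone whose intensity
saturates with bubble density, and shadowing below dense clouds. It does
not model wave propagation, beamforming, speckle spatial correlation
beyond the PSF, frequency-dependent attenuation, or multiple scattering.
The PSF here is an *effective* splat kernel: its footprint, together with
the one-hit efficiency, sets the blob coverage of the image and therefore
where the contrast-versus-dose curve leaves its linear range. The default
footprint is smaller than a physical 7.5 MHz resolution cell; it was
chosen jointly with $\varepsilon$ so the contrast transfer reproduces the
reported linear range, and it under-represents speckle-scale correlation.
Consequently, passing tests demonstrate that the *quantification pipeline*
recovers dose and range from images with the reported statistical
structure — not that the renderer predicts real echo amplitudes.

## 5. Profile pipeline

The quantification follows the published image-processing chain:

1. `default_threshold()` — iterative intermeans (isodata) threshold;
   pixels at or below it are zeroed. On a pure-speckle pre-irradiation
   frame the iteration settles inside the speckle mode (retaining the
   bright speckle tail), while a post-irradiation frame with a bright
   vaporization zone settles at the bimodal split and suppresses the
   speckle entirely — the same asymmetry an ImageJ default threshold
   produces on such pairs. A configuration switch
   (`us_config(threshold_profiles = FALSE)`) disables thresholding.
2. `extract_profile()` — per-column mean grey over the full probe depth.
3. `subtract_background()` — post minus pre at profile level, clipped at
   zero (profile-level subtraction avoids pre/post registration
   artifacts).
4. `calibrate_positions()` — window positions map to beam-axis mm through
   the probe-center convention: probe center ↔ entrance position + front
   wall + half the inner length.
5. `average_profiles()` — pointwise mean over the 3 frames × 2 phantoms
   (n = 6) of a condition.
6. `fit_peak()` — least-squares Gaussian plus constant baseline
   (Levenberg–Marquardt via minpack.lm), initialized at the profile
   argmax with the width from the full second central moment of the
   baseline-subtracted profile (stable for sparse low-dose bands) and the
   baseline from the proximal-quartile median; convergence tolerance
   10⁻¹⁰ on the relative parameter change, at most 500 iterations.
   Derived metrics: FWHM, W₈₀, analytic area $A\sigma\sqrt{2\pi}$, r²,
   onset (first proximal sample above baseline + 3 background SD, the
   configurable `k_onset`), plateau-to-peak ratios, and — against a
   reference curve — the 50%-drop shift.
7. `distal_fall50()` — the paper's range coordinate: the midpoint between
   the extreme grey values, returned as the most distal interpolated
   downward crossing.

`x_end` is not defined in the published account; here it is the distal
position where the fitted curve decays to baseline + 10% of amplitude,
flagged as such in the documentation. Ties among distal 50% crossings are
broken to the most distal crossing, matching "distal fall-off" semantics.

## 6. Dose response

`integrate_peak()` uses the analytic Gaussian area. `fit_dose_response()`
adopts a four-parameter logistic
$y = \mathrm{floor} + (\mathrm{ceiling} - \mathrm{floor}) /
(1 + (\mathrm{ed50}/D)^{\mathrm{slope}})$ with the floor constrained
non-negative as the canonical saturating form (the original saturating
equation is in supplementary material not reproduced here; the 4PL is the
standard choice for such data). `linear_range_fit()` restricts an OLS fit
to doses below a cutoff; r² is $1 - SS_\mathrm{res}/SS_\mathrm{tot}$
without adjustment throughout.

## 7. Experiment runner, seeds, problem sizes

`run_experiment()` reproduces the evaluation matrix: dose effect (0.1–4 Gy),
concentration effect (0.8–8×10⁶ ND/ml at 1 Gy), dose-rate halving, a 10 mm
phantom displacement, SOBP irradiation (pristine peaks 160–180 mm; the
published span and the quoted 10 mm thickness are inconsistent, so the
constituent ranges are exposed as configuration), a 50 mm range change,
and both negative controls. Every stochastic operation takes an explicit
seed; per-phantom and per-frame streams are derived as stable offsets from
the master seed, so every reported number is reproducible from the
configuration and seed recorded in the output bundle (a config hash is
written alongside).

Default problem sizes keep a full reference condition (two phantoms, three
frames each, ≈4×10⁶ ND/ml in the imaged slabs ≈ 2×10⁶ instantiated
droplets per phantom, 300 × 230 px frames) at a few seconds per phantom on
one CPU; the complete dose sweep runs in about 90 s and the
range-verification replicate study in about three minutes.

## 8. Known limitations

* The LET surrogate is calibrated, not transported; only its
  threshold-crossing depth is contractual. Fragment spectra, secondary
  protons/neutrons and lateral scattering are not modelled (their
  contribution to vaporization is reported to be negligible, and the
  simulation reproduces the absence of distal contrast by construction of
  the gate).
* Shell mechanics (thickness, elasticity) are not part of the nucleation
  threshold; size polydispersity enters only through the geometric
  cross-section and the spontaneous-vaporization rate.
* The concentration sweep reproduces the qualitative broadening at twice
  the reference concentration, but multiple scattering — the mechanism the
  original account holds responsible for overestimated broadness — is only
  mimicked by saturation plus shadowing; amplitudes at 8×10⁶ ND/ml still
  grow mildly where the real system was fully saturated.
* Droplet diffusion, buoyancy and in-vivo transport are out of scope.
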