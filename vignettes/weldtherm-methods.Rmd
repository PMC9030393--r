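---
title: "weldtherm: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{weldtherm: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-frequency electric welding (electrosurgical vessel sealing) clamps a
vessel wall between two electrodes and passes an RF current through it.
Joule heat denatures collagen; between roughly 40 °C and 60 °C the
denatured chains re-crosslink into a seal, while above ~60 °C accumulated
heat damages the tissue. The tissue under the electrodes — where the weld
forms — is invisible to an infrared camera, so its temperature must be
inferred: a coupled electro-thermal simulation is validated against IR
measurements of the *exposed* edge area and then trusted in the covered
centre. `weldtherm` implements that workflow end to end, together with the
downstream analyses that link temperature to weld quality: T-peel strength
statistics, Raman amide-III band ratios, and phase classification.

## The coupled model

Temperature obeys the Pennes bioheat equation

$$\rho c \,\partial T/\partial t = \nabla\!\cdot\!(k \nabla T) + q_g + Q_{bio},$$

with the perfusion/metabolic source $Q_{bio} = \rho_b C_{p,b}\omega_b (T_b - T) + Q_{met}$
carried in the model but disabled by default (ex-vivo tissue). The heat
source is quasi-static Joule dissipation $q_g = \sigma |\nabla V|^2$ with
$\nabla\!\cdot\!(\sigma \nabla V) = 0$, the upper electrode at the applied
voltage and the lower grounded. Tissue properties follow affine laws about
$T_0 = 25$ °C:

$$k(T) = k_0 + 0.0013\,(T - T_0), \qquad
  \sigma(T) = \sigma_0\,[1 + 0.02\,(T - T_0)],$$

with $k_0 = 0.462$ W/m·K and $\sigma_0 = 0.24567$ S/m; copper electrode
properties are constant. Temperatures are carried in °C throughout — every
formula in the model uses temperature *differences*, so no Kelvin
conversion is ever required. Out-of-range temperatures that would drive a
conductivity non-positive raise errors instead of being clamped, so solver
instabilities cannot hide. An optional Haemmerich-style damage cutoff
(σ/10⁴ above a damage temperature) is exposed but off by default, since
the underlying experiments did not state using it.

### Discretisation and numerics

The grid is a regular voxel grid: a 20 × 10 × 0.958 mm tissue slab
(dx = dy = 0.2 mm, 8 layers through the thickness) with 3 mm-footprint
copper electrode blocks pressed on both faces. Finite volumes with
harmonic-mean face conductivities make the fluxes conservative across the
copper–tissue interface; the same face form is used for the Joule source
(each face dissipates $g\,\Delta V^2$, split between its cells), which
makes the discrete power balance exact: total dissipation equals applied
voltage times electrode current, to solver tolerance.

Each step (default dt = 0.05 s) re-evaluates $k(T)$ and $\sigma(T)$ at the
lagged temperature, re-solves the potential, and advances the temperature
by one backward-Euler step (unconditionally stable; the copper block has a
diffusion CFL far beyond any explicit scheme). Both linear systems are
symmetric positive definite and solved by SSOR-preconditioned conjugate
gradients warm-started from the previous step. The default relative
residual tolerance is 1e-6 — per-step temperature errors of order 1e-5 °C,
three orders below the time-discretisation error — while oracle and
conservation tests run at 1e-12–1e-13. The RF carrier is not resolved: a
square wave of amplitude $V$ and duty cycle $D$ enters as its thermally
equivalent constant voltage $V\sqrt{D}$, justified because the thermal
time constant (seconds) exceeds the electrical period (µs) by six orders
of magnitude.

### Boundary conditions and the electrode block

Exposed tissue faces lose heat by natural convection
(h = 10 W/m²·K to 25 °C air — an order-of-magnitude default, configurable).
The electrodes start at 20 °C and are coupled to the instrument body by a
sink coefficient `h_sink` on their outer faces. The electrode *block
thickness* deserves a note: the geometry models the thermally
participating contact plate of the forceps jaw as ~0.96 mm of copper
(8 cells). This was fixed from two considerations: (i) physically, the
jaw plate in contact with tissue is of millimetre scale; (ii) the
calibration contract below is only satisfiable when the electrode's own
thermal mass supplies a realistic early-time heat drain — a 0.48 mm block
reaches 40 °C ~0.6 s too early relative to the anchors at any
`h_sink ≥ 0`, while beyond ~1 mm the effect saturates (copper equilibrates
internally much faster than it exchanges with tissue).

### Drive calibration

The instrument's output voltage, frequency and duty cycle are not
observable, so the model is anchored instead: `calibrate_drive()` fits
(amplitude, `h_sink`) so the simulated *maximum* tissue temperature
crosses 40.0 °C at 11.5 s and 60.0 °C at 23.5 s (±0.2 s). "Temperature
reaches 40/60 °C" is ambiguous between the central mean and maximum; the
package uses the maximum, matching how peak temperatures are reported in
the underlying experiments. The search is nested: the inner loop exploits
$q \propto V^2$ (crossing times scale approximately as $1/V^2$) for a
fast fixed-point fit of the amplitude to the hotter anchor; the outer
loop bisects `h_sink` on the earlier anchor. In the default geometry the
outer optimum sits at `h_sink = 0` — the electrode mass alone provides
the early drain — and a final minimax amplitude polish balances the two
residuals (±0.15 s at default settings).

## IR profile comparison

Profiles are temperature vs distance from the electrode edge, sampled
along the heat-spread axis on the top tissue surface. The agreement
metric, called the *fitting degree*, is not given a formula in the
literature this package follows; it is implemented as the coefficient of
determination in percent, $100(1 - SS_{res}/SS_{tot})$, restricted to
x ≥ 1 mm — the only definition consistent with reported values near 98 %
alongside a visible near-electrode mismatch (the electrode heat sink
displaces the measured maximum outward within the first millimetre). A
normalised-RMSE alternative is available behind a switch. Comparison
always interpolates the simulation onto the measurement grid: the
measurement is ground truth. The thermal diffusion width is the
contiguous band beside the electrode more than ε = 0.5 °C above the
25 °C ambient, with the outer crossing interpolated linearly; the
isotherm z-deviation locates an isotherm on the top and bottom tissue
surfaces and reports their horizontal displacement.

## Raman pipeline

Spectra are smoothed (Savitzky–Golay, window 11, order 3 — defaults
chosen since none are stated in the source workflow, exposed in the API),
baseline-corrected by an iterative polynomial scheme (degree 5, 10
iterations; points above the current fit are clipped to it before the
next fit, the modified-polyfit limit of down-weighting), cropped to the
800–2000 cm⁻¹ fingerprint window, and calibrated with pseudo-Voigt peaks:
height-normalised additive Gauss–Lorentz profiles with shared FWHM and a
free mixing fraction η per peak — the standard reading of a
"Gauss–Lorentz function" in Raman practice. Peak *intensity* means fitted
height (not area), matching the magnitudes of the reference peak table.
Fitting is deterministic least squares (PORT/`nlminb` with analytic
gradients and per-parameter scaling; box constraints keep η in [0, 1]).
The amide-III ratio divides the height of the peak nearest 1247 cm⁻¹ by
that nearest 1325 cm⁻¹, with a ±40 cm⁻¹ assignment window that absorbs
the denaturation-induced shifts (1247 → 1266, 1325 → 1305 cm⁻¹).

## Strength and phases

T-peel strength is normalised to the F-unit (peak force / weld width,
N/mm); samples with no weld or a damaged weld are excluded before group
statistics, mirroring the exclusion rule of the bench protocol. Change
rates are computed from unrounded means. Phase classification uses
thresholds at 40 °C (denaturation onset) and 60 °C (damage onset) with a
half-open upward convention — a temperature exactly at a threshold
belongs to the higher phase; the source material writes "(40–60 °C)"
without specifying inclusivity, and the upward convention keeps
`classify_phase` monotone with strict inequalities only on one side.
Phase boundary times are linear-interpolated first crossings.

## What the synthetic generators emulate — and what they do not

* **IR sequences**: a 30 Hz camera over the slab, additive i.i.d.
  Gaussian sensor noise (sd 0.05–0.2 °C, motivated by the ±0.1 °C rated
  accuracy), optional Gaussian blob artefacts standing in for adipose
  residue. Frames default to 96 × 128 pixels for test speed; the real
  384 × 512 sensor is one argument away. Not emulated: emissivity
  variation, dead pixels, optical blur, tissue curling at the edge.
* **Raman spectra**: pseudo-Voigt peaks + polynomial baseline + Gaussian
  noise on a 1 cm⁻¹ grid. Not emulated: cosmic rays, wavelength
  miscalibration, fluorescence photobleaching dynamics.
* **Strength samples**: per-group F-unit from a normal truncated at zero
  (forces are non-negative; at the reference mean/sd scales the
  truncation bias is < 0.1 %), widths near 5 mm, and a failure
  probability concentrated in the 30 s group where welds burn out.

A green test on synthetic data therefore establishes that the pipeline
recovers known ground truth under the stated noise model — not that the
physical instruments behave like the generators.

## Numerical choices and degenerate inputs

* Linear-solver tolerances: 1e-6 (simulation default), 1e-10 (standalone
  potential solves), 1e-12/1e-13 in conservation and oracle tests.
* Crossing times and phase boundaries: linear interpolation between
  0.05 s steps; calibration tolerance ±0.2 s.
* Ties and boundaries: phase thresholds half-open upward; band
  assignment takes the nearest peak and errors if both bands resolve to
  the same peak; `diffusion_width` returns 0 when the edge is already at
  ambient and the full profile length when nowhere below threshold.
* Degenerate grids (single tissue layer, full-coverage footprint with an
  empty edge area) are supported and tested.
* Errors, not clamps: non-finite temperatures, non-positive
  conductivities, empty crop windows, constant measured profiles
  (fitting degree undefined), absent isotherms, and zero-width welds all
  raise informative errors.

## Known limitations

* No tissue dehydration or shrinkage: σ(T) keeps rising affinely, so the
  late-time heating rate is, if anything, slightly optimistic; the
  impedance rise and steam pop of real electrosurgery are out of scope.
* Contact impedance between electrode and tissue is not modelled; the
  calibrated amplitude absorbs it, so the fitted voltage is an
  *effective* drive, not the instrument's display value.
* The electrode is a passive copper block with a lumped sink; no active
  temperature regulation.
* Perfusion is implemented but untested against in-vivo data.
* The fitting-degree values reported for real IR recordings cannot be
  reproduced (recordings unreleased); the metric is validated on
  synthetic data only.
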