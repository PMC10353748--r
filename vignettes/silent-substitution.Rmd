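---
title: "Designing photoreceptor-isolating stimuli with silsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing photoreceptor-isolating stimuli with silsub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silsub)
```

## The problem

The retina's photoreceptor classes — S, M and L cones (`sc`, `mc`, `lc`),
rods (`rh`) and melanopsin-expressing ipRGCs (`mel`) — have broadly
overlapping spectral sensitivities, so changing a light's spectrum normally
changes the activation of all of them at once. Silent substitution exploits
the principle of univariance (a photoreceptor's output depends only on its
total quantum catch, not on which wavelengths delivered it): two spectra that
produce the same α-opic irradiance for a receptor class are, to that class,
the same light. Given a multiprimary device with at least as many primaries
as receptors under consideration, one can therefore find a *background* and a
*modulation* spectrum whose exchange modulates targeted receptors while
leaving the silenced ones untouched.

Everything reduces to the α-opic projection

$$E_\alpha = \sum_{\lambda=380}^{780} E(\lambda)\, S_\alpha(\lambda)\,
\Delta\lambda,$$

evaluated on a canonical grid of 380–780 nm at 1 nm (401 samples). The grid
is a hard convention: loaders resample finer-sampled inputs linearly onto it
(and reject anything coarser than 5 nm, where linear quadrature error becomes
unacceptable), while all other operations raise an alignment error on
mismatched grids rather than resampling silently.

## Observer model

`build_observer(age, field_size)` produces the five action spectra. Two
prereceptoral filters reshape the underlying pigment sensitivities:

* **Lens.** The crystalline lens yellows with age; its optical density is
  largest at short wavelengths and scales up with age (valid range 20–80
  years; outside it the function refuses rather than extrapolates, because no
  extrapolation rule is defined). Consequences: older observers' effective
  peak sensitivities shift toward longer wavelengths, and short-wavelength
  sensitivity drops.
* **Macular pigment.** A yellow carotenoid spot over the fovea with peak
  density near 460 nm. Its peak optical density decreases with stimulus
  field size as $0.485\,e^{-F/6.132}$; beyond 10° it is negligible, so
  larger fields are clamped to 10° (with a notice). It is applied to the
  cones only: rods are absent from the fovea and ipRGCs lie above the
  pigment layer, so `rh` and `mel` are bitwise invariant to field size.

Two backends are available. The **template** backend is fully self-contained:
pigments are Gaussians in log wavelength (width 0.08 log units ≈ 100 nm FWHM
for a mid-wave pigment), and the lens/macular densities are analytic
surrogates satisfying the same monotonicity contracts as the standard
formulations. The **cie-tables** backend evaluates the two-component lens
formula, the field-size-dependent peak axial pigment densities, and the lens
re-adjustment of the rhodopic/melanopic standard curves from *user-supplied*
base tables; no standard tables are bundled, and numerical equality with
published tabulations is only meaningful at the precision of the tables the
user provides. The lens function used to correct `rh`/`mel` is exposed as a
swappable argument (`mel_lens_fn`) because reference standards use a slightly
different density function there; equivalence with any particular standard is
unverified unless its tables are supplied.

All action spectra are **peak-normalised to 1**. Absolute α-opic calibration
constants are out of scope; every solver quantity is a contrast (a ratio), so
the solutions are invariant to per-receptor rescaling.

## Device model

A device is defined entirely by its calibration: per primary, an ordered
ladder of native settings with a measured spectrum each, including the
minimum (0 = ambient) and maximum (resolution) of every primary. Predictions
interpolate this ladder linearly, wavelength-wise, along the setting axis —
exact (bitwise) at calibrated settings, never extrapolating. A multiprimary
prediction sums ambient-subtracted primary predictions and adds ambient back
once, so the all-zeros prediction is the ambient measurement, not n copies of
it; this convention preserves both additivity of increments and the
all-zeros identity, and is stated explicitly because other implementations
may differ.

Numerical conventions worth knowing:

* Weights are settings divided by resolution; the inverse rounds **half away
  from zero** (documented because half-even rounding changes settings by one
  count: weight 0.5 on an 8-bit primary gives 128, not 127).
* Negative calibration values (spectrometer noise floor) are clipped to zero
  at load, with a count, never at predict time.
* The ambient (setting-0) rows of all primaries must agree within 5%
  (relative to the peak ambient value) by default.
* Gamma correction is defined on the *integrated* ambient-subtracted output
  of each primary, not per wavelength, because primaries may shift
  spectrally with drive level; spectral shift is the optimiser's job (below).
  The gamma table must be non-decreasing; dips beyond 1% of the output range
  raise a calibration-quality error, smaller ones are flattened.
* Gamut means every weight in [0, 1] within a slack of 1e-9.

## Solvers

Both solvers consume a `problem_spec()`: a partition of the observer's
receptors into *target*, *silence* and *ignore* (pairwise disjoint, jointly
exhaustive — unassigned receptors are an error, not a guess), a contrast
request, a mode, and optionally a background and per-primary bounds.
Ignoring receptors (e.g., rods in the photopic range, or the missing cone
class of a dichromat) frees contrast for the targets; ignored receptors are
dropped from the equations but always *reported*, so the contrast they
absorb is visible.

**Linear algebra.** With a known background and numeric contrast, the device
is linearised about the background: the rows of $P_{bg}$ are the per-primary
spectral slopes $\partial\,\mathrm{spd}_p/\partial w_p$ through the
calibration interpolant (central finite difference, $\delta = 10^{-3}$ in
weight units; on a linear device this is exactly the ambient-subtracted
full-drive spectrum). Then $A = P_{bg} \cdot S_\alpha$ over the non-ignored
receptors, the requested modulation is $\beta_r = C \cdot E_r(bg)$ for
targets and 0 for silenced receptors, and $\alpha_{sc} = \beta A^{-1}$
(square) or $\beta A^{+}$ (Moore–Penrose, giving least-squares /
minimum-norm semantics otherwise). The modulation weights are
$\alpha_{bg} + \alpha_{sc}$. A condition number above $10^{10}$ raises a
degenerate-system error — beyond that, solutions amplify calibration noise
past any plausible measurement precision. Requests that leave the gamut
raise an error reporting the largest attainable contrast along the solution
direction; contrast is never silently clipped.

Michelson (bipolar) requests are converted to a positive Weber arm of the
same magnitude; the stored modulation is the positive arm and the negative
arm is its reflection through the background, $2\,bg - mod$, so on a linear
device the Michelson contrast of the two arms equals the request exactly and
sinusoid generation needs only one stored vector.

**Constrained optimisation.** `optim_solve()` evaluates contrasts through
the calibration interpolant itself, so it stays valid where linearisation
fails — e.g., when a primary's spectrum shifts with drive level. It
minimises the squared deviation of the targeted contrasts from the request
(or the negative absolute targeted contrast for `contrast = "max"`), subject
to equality constraints pinning every silenced contrast at zero and box
bounds on the weights, using SLSQP. When no background is given it becomes
part of the optimisation variables. Global mode is a seeded
basin-hopping-style loop: the first start is anchored near the background
(the sought modulation is an excursion about it), subsequent starts perturb
the incumbent (step SD 0.3 in weight units) or draw fresh, and the loop
stops early once a feasible solution meets the objective tolerance.

Two deliberate regularisations:

* **Minimum-excursion ridge.** With more primaries than constrained
  receptors the solution set is a family of metamers; the achieved contrasts
  on *ignored* receptors differ across that family. A tiny penalty
  ($10^{-6}\,\lVert mod - bg\rVert^2$) selects the minimum-excursion member,
  matching the pseudo-inverse's minimum-norm choice, so the two solvers
  return the same solution on linear devices (they agree to ~$10^{-9}$ in
  contrast). The ridge perturbs the achieved target contrast by an amount
  far below the $10^{-4}$ constraint tolerance.
* **Finite landscape.** Near an all-dark background the Weber denominator
  vanishes; the optimiser's evaluation path floors the denominator and caps
  non-finite contrasts at $\pm 10^{6}$ so the search can move away instead
  of aborting. The *reported* contrasts are always recomputed through the
  strict forward-model path.

Defaults: constraint tolerance $10^{-4}$ contrast units (a solution whose
recomputed silenced contrast exceeds it is rejected with an infeasibility
error reporting the best residual), objective tolerance $10^{-8}$, 100
iterations per local solve, 30 global restarts, and a numeric target missed
by more than $10^{-3}$ is declared infeasible rather than silently clipped.
Every solve is seeded and the seed is recorded in the solution metadata;
fixed seed means bit-reproducible solutions.

The solution's native settings come from weight quantisation
(round-half-away); `validate_solution()` then recomputes everything from
those integer settings and reports the achieved contrasts, the
quantisation-induced error per receptor, and the gamut margins —
report-only, since validation of a hand-made solution should describe it,
not reject it. `make_sinusoidal_waveform()` samples
$w(t) = bg + \sin(2\pi f t)(mod - bg)$ and gamma-corrects each sample to
native settings; `sinpi()` makes the first and last samples equal the
background exactly.

## Synthetic fixtures and what they do (not) show

`make_gaussian_device()` builds calibration ladders from a closed-form
generator: primary $p$ at setting $s$ measures
$\mathrm{ambient} + (s/R)^{\gamma_p}\, \mathrm{max}_p\,
G(\lambda;\ \mathrm{peak}_p + \mathrm{shift}_p\, s/R,\ \mathrm{fwhm}_p)$,
optionally with seeded multiplicative log-normal noise (signal-proportional,
like spectrometer noise, and nonnegative by construction). Gaussian primaries
were chosen over measured LED shapes because the closed form provides exact
oracles: a linear recipe (γ = 1, shift 0, no noise) satisfies superposition
to machine precision, a γ-recipe has a known integrated-output law, and a
shift-recipe moves its peak by a known amount. Defaults emulate a plausible
5-primary LED device: peaks equally spaced 430–630 nm, 35 nm FWHM, 8-bit
resolution, six calibration levels, zero ambient.

Two template observers are used in testing. The *human-like* layout
(sc 420, mc 530, lc 560, rh 500, mel 480 nm, width 0.08) reproduces the
field's qualitative geometry — and its hard reality: with five same-shape
templates this close together, the maximum melanopsin Weber contrast a
mid-gamut 5-primary device can deliver is only a few percent, because the
isolating direction lies along the A-matrix's smallest singular value. Real
observers are more favourable (action spectra differ in shape, not just
position). For solver demonstrations that need sizeable in-gamut contrasts,
the tests therefore use a *separable* observer whose five peaks are spread
across the device span (425–625 nm, width 0.05), giving a condition number
of ~3 and a maximum melanopic Weber contrast of ~0.64 at the half-power
background. Random solver problems draw device and observer jointly this way
and request a contrast at a fixed fraction of the maximum feasible along the
solution direction, so "within gamut" holds by construction.

What passing these tests does *not* show: that any particular physical
device is linear enough for `linalg_solve` (validate with measurements), that
real calibration noise is log-normal, or that template observers numerically
match standards-based action spectra — for that, supply the base tables or
your own spectra.

## Design choices where the design was open

* **Normalisation** of action spectra: peak = 1 (conventional for cone
  fundamentals); all contrast mathematics is invariant to the choice.
* **A-matrix linearisation**: rows of $P_{bg}$ are *slopes* at the
  background rather than the raw primary spectra at background settings.
  The two coincide (up to scale per primary) only on linear zero-ambient
  devices; the slope form is the one that makes "add $\alpha_{sc}$ to the
  background weights" deliver exactly the requested α-opic increment, and
  is exact on linear devices.
* **Ambient in mixtures**: subtract-then-add-once (see above).
* **Interpolation**: linear only; splines can overshoot below zero.
* **β construction**: Weber increments relative to the background's α-opic
  vector; bipolar requests become symmetric ±C Weber arms.
* **Exit codes** (CLI): 0 success, 2 validation, 3 gamut/infeasibility —
  chosen for scriptability in experiment pipelines; each solve also writes a
  run manifest whose hash covers the inputs (not the timestamp), so equal
  manifests imply equal solution JSON.

## Problem sizes used in the test-suite

Property tests run 50 random solver problems (5–7 primaries, 5 receptors)
for each solver, 100 random spectra for the quadrature cross-check, a
3×4 non-square system for the pseudo-inverse semantics, 3^5 perturbations
for the quantisation envelope, and seven ages × six field sizes for the
observer monotonicity suite. These sizes make the whole suite run in a few
minutes on one CPU while keeping every check at full numerical stringency
(silencing at 1e-8, quadrature at 1e-12, cross-solver at 1e-4).

## Known limitations

* Silencing at the pigment level does not guarantee silence at the level of
  receptor *output*: horizontal-cell feedback means cone responses are not
  functions of quantum catch alone. Validation measurements of delivered
  spectra remain essential.
* No background luminance/chromaticity constraints; no conversion between
  photon and energy sensitivity systems (photon-unit calibrations must be
  converted before loading); no opsin polymorphism modelling.
* `linalg_solve` requires a known background and a numeric contrast by
  design; use the optimiser otherwise.
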