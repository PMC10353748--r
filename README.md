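# silsub

Silent substitution is the standard technique for stimulating one class of
retinal photoreceptor while holding the others constant. The human retina
contains rods, three cone classes (S, M, L), and melanopsin-expressing
intrinsically photosensitive retinal ganglion cells (ipRGCs); their spectral
sensitivities overlap heavily, so almost any light stimulates all of them.
With a spectrally calibrated multiprimary device, however, one can exchange a
*background* spectrum for a *modulation* spectrum chosen so that the quantum
catch changes only for the targeted receptor class — the others are
"silenced". `silsub` is an R toolbox for computing such stimuli: for vision
scientists, chronobiologists, and clinical electrophysiologists who need
photoreceptor-directed contrast from LED ganzfelds, projectors, or displays.

## The model

Given a device spectrum in energy units, the activation of receptor class
α is its α-opic irradiance

```
E_α = Σ_λ  E(λ) · S_α(λ) · Δλ          (380–780 nm, Δλ = 1 nm)
```

where `S_α(λ)` is the receptor's action spectrum. The package has three
layers:

* **Observer** — `build_observer(age, field_size)` constructs `sc`, `mc`,
  `lc`, `rh`, `mel` action spectra for ages 20–80 and field sizes 1°–10°.
  Cones are corrected for lens *and* macular pigment; the rhodopic and
  melanopic members receive only the lens correction (rods are absent from
  the fovea; ipRGCs sit above the pigment layer). Custom observers — mice,
  vessel-shadowed cones — load from CSV via `load_action_spectra()`.
* **Device** — `load_device()` reads a calibration CSV (rows = spectral
  measurements per primary per setting; header `Primary,Setting,380,…,780`)
  plus a JSON config, and predicts the spectrum and α-opic irradiances of any
  settings vector by input-wise linear interpolation
  (`predict_multiprimary_spd()`, `predict_aopic()`), with gamma correction
  and gamut checks.
* **Problem** — `problem_spec()` names which receptors to target, silence,
  and ignore, the contrast (Weber for unipolar pulses, Michelson for bipolar
  modulations) and optionally a background and bounds. `linalg_solve()`
  inverts the A-matrix `A = P_bg · S_α` (Moore–Penrose pseudo-inverse for
  non-square systems); `optim_solve()` runs bounded SLSQP with the silenced
  contrasts as equality constraints, which remains valid when the device is
  nonlinear (gamma, spectral shift with drive level) and can maximise
  contrast (`contrast = "max"`) or optimise the background itself.

Synthetic fixtures (`fixture_recipe()`, `make_gaussian_device()`,
`make_template_observer()`) generate fully controlled devices and observers,
so everything can be exercised — and is tested — without calibration
hardware.

## Worked example

```r
library(silsub)

# a linear 5-primary device (Gaussian primaries, 430-630 nm, 8-bit)
device   <- make_gaussian_device(fixture_recipe(seed = 42))
# a synthetic 5-receptor observer with well-separated action spectra
observer <- make_template_observer(
  c(sc = 425, mel = 475, rh = 525, mc = 575, lc = 625), log_width = 0.05
)

spec <- problem_spec(
  target = "mel", silence = c("sc", "mc", "lc", "rh"),
  contrast = 0.2, mode = "weber", background = rep(0.5, 5)
)
solution <- linalg_solve(device, observer, spec)
solution
#> <silent substitution solution (linalg, weber contrast) on 'synthetic 5-primary gaussian device'>
#> background weights:  0.5000 0.5000 0.5000 0.5000 0.5000
#> modulation weights:  0.4802 0.6564 0.4480 0.5192 0.4929
#> # A tibble: 5 x 3
#>   receptor role     contrast
#>   <chr>    <chr>       <dbl>
#> 1 sc       silence  0
#> 2 mel      target   2.00e- 1
#> 3 rh       silence  1.45e-16
#> 4 mc       silence -1.33e-16
#> 5 lc       silence -1.50e-16
#> max |silenced contrast| = 1.5e-16
```

The modulation raises melanopic irradiance by exactly 20% (Weber) while the
recomputed contrast on every silenced receptor is at numerical zero — the
reported contrasts always come from pushing the solution back through the
device forward model, never from the solver's own bookkeeping.
`validate_solution(solution, device, observer)` additionally reports the
contrast error introduced by quantising to native 8-bit settings, and
`make_sinusoidal_waveform()` turns a bipolar solution into a settings time
series. `tidy()`/`glance()` give per-receptor and one-row summaries;
`autoplot()` draws the spectra.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/silsub.R solve --config device.json \
  --target mel --silence sc,mc,lc,rh --contrast 0.2 --mode weber \
  --background 0.5,0.5,0.5,0.5,0.5 --solver linalg --out solution.json
```

(exit 0 on success, 2 on validation errors, 3 on gamut/infeasibility).

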