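---
title: "From layered-tissue photon transport to blood-pressure algorithm sensitivity: the synthetic PPG workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From layered-tissue photon transport to blood-pressure algorithm sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgsim)
```

## The problem this package addresses

Photoplethysmography (PPG) devices estimate hemodynamic parameters — most
ambitiously blood pressure — from the small pulsatile component of light
reflected by perfused tissue. The recorded waveform depends not only on
physiology but on who is being measured (age, skin tone) and on what is
measuring them (LED wavelength, ADC resolution, filter chain). Clinical
waveform archives rarely document these factors, so their influence on
downstream feature extraction and prediction algorithms is hard to isolate.
`ppgsim` builds the whole chain synthetically, so every factor is a knob:

1. **Tissue model** — a six-layer volar fingertip (epidermis, four dermal
   sublayers, subcutis) whose geometry and optical coefficients depend on
   age, melanosome volume fraction (VFM, a proxy for skin tone) and
   wavelength.
2. **Photon transport** — weighted Monte Carlo through the layer stack with
   an LED-type source and an annular detector, yielding the baseline (DC)
   and pulsatile (AC) detected amplitudes.
3. **Waveform synthesis** — three-Gaussian pulse templates tiled into
   continuous records at a set heart rate and sampling frequency, scaled by
   the Monte Carlo amplitudes, with optional sinusoidal interference.
4. **Device simulation** — Butterworth / inverse-Chebyshev filter chains,
   ADC quantization, amplitude rescaling.
5. **Pulse wave analysis** — fiducial detection (onset, systolic peak,
   dicrotic notch) and a 38-feature registry (widths, ratios, areas,
   timings).
6. **Sensitivity harness** — a model-agnostic regression interface whose
   sensitivity metric is the standard deviation of a trained model's
   predictions across the synthetic cohort.

## The tissue model and its parameters

The dermis thins linearly with age: total thickness
$T(\mathrm{age}) = 0.75\,\mathrm{mm} + (61 - \mathrm{age}) \times
0.0044\,\mathrm{mm/yr}$, anchored at a 61-year-old reference cohort. (The
source material prints the thinning rate as 0.00044 mm/yr, which cannot
reproduce its own thickness table; read as 0.00044 cm/yr the table is
reproduced to its printed precision, and that interpretation is adopted.)
The four dermal sublayers are fixed fractions of the total: papillary
8.2%, upper blood net 4.37%, reticular 81.97%, deep blood net 5.46%. One
tabulated cell (upper blood net at 55 y, printed 0.033 mm) appears
truncated rather than rounded (the model gives 0.0339 mm); tests therefore
check agreement within one unit in the last printed digit of each cell.

Epidermal absorption mixes a melanosome power law
$\mu_{a,\mathrm{mel}}(\lambda) = 6.6\times10^{10}\,\lambda^{-3.33}$
cm$^{-1}$ ($\lambda$ in nm) with a baseline back-solved from the tabulated
VFM = 0.03 cell at each wavelength, so the shipped table remains the
calibration authority:
$\mu_a = \mathrm{VFM}\,\mu_{a,\mathrm{mel}} + (1-\mathrm{VFM})\,
\mu_{a,\mathrm{base}}$.

The cardiac pulse enters as an increased dermal blood volume. The
multiplier falls with age (1.124 at 23 y to 1.073 at 55 y, linear in
between) as vessel compliance declines. The printed "pulsed" absorption
coefficients correspond to the youngest tabulated age (the largest
multiplier); for other ages the blood-borne share of each sublayer's rest
absorption — calibrated from the printed rest/pulsed pair — is scaled by
the age's multiplier. Scattering does not pulsate (the source material
modifies absorption only, and we follow it).

Anisotropy ($g = 0.9$) and refractive index ($n = 1.4$ tissue / 1.0
ambient) are not tabulated; the adopted values are the standard choices
for skin Monte Carlo work and are exposed as arguments.

```{r tissue}
build_tissue_model(age = 23, vfm = 0.03, wavelength = 515, state = "rest")
```

## Photon transport: estimator and numerics

Layers are laterally infinite slabs (all structures in the model are
laterally uniform). The engine implements the standard weighted scheme:
optical-path step sampling $-\ln \xi$, Henyey–Greenstein scattering,
absorption weighting ($w \mapsto w\,\mu_s/\mu_t$ per interaction), Fresnel
reflection at the top tissue/air interface with deterministic weight
splitting (the transmitted fraction exits and is detected if it lands in
the detector annulus), an absorbing bottom boundary, and Russian roulette
(default threshold $10^{-4}$, survival 0.1). Roulette's signed
weight creation/retirement is folded into the absorbed fraction, so
`detected + escaped + absorbed = 1` holds to floating-point accuracy on
every run — a per-run conservation test, not just an expectation.

Randomness comes from a xoshiro256++ stream seeded through splitmix64;
one master seed expands into per-run substreams
(`mc_substream_seed()`), and `mc_rng_stream()` exposes the raw uniforms so
an independently coded single-photon loop can replay a simulation number
for number (the test suite does exactly this and requires equality at
$10^{-12}$).

**AC/DC estimation.** DC is the rest-state detected fraction. AC is rest
minus pulse; stated verbally the pulse state *absorbs more and detects
less*, so this magnitude convention keeps AC positive. Because the pulse
perturbs only absorption, the pulse detected fraction can be computed from
the *same* photon paths as the rest run by exact reweighting
($\exp(-\sum_\ell \Delta\mu_{a,\ell} L_\ell)$ per detected path, with
$L_\ell$ the path length in layer $\ell$). This correlated (perturbation)
estimator is the strongest form of common-random-number pairing: it is
unbiased, it halves the cost of a pair, and the AC difference converges
orders of magnitude faster than independent runs. A two-run shared-seed
mode is available for comparison (`run_pulse_pair(method = "paired")`).

**Convergence rule.** `converge_pulse_pair()` repeats triplicate pairs
with a growing photon count until the coefficient of variation of AC
across the triplicate falls below 10% (the study's criterion), and flags
the best attempt if the photon budget is exhausted.

**Source and detector geometry.** The emitter is a 1 mm square with a
top-hat near field and a Lambertian far field. The nominal half angle of
2.4 rad exceeds $\pi/2$ and is clamped to $\pi/2$ with a warning (a
Lambertian far field cannot emit beyond the forward hemisphere). The
nominal annular detector radii (0.0071/0.0091 mm) subtend near-zero area
*inside* the emitter footprint and would detect essentially nothing at
desk-scale photon counts; grid work therefore defaults to
`mc_detector_annulus()`, the physically consistent 0.2 mm ring just
outside the square source's circumscribed radius ($\sqrt{2}/2$ mm). Both
geometries are plain configuration objects. This choice was fixed before
any trend results were inspected and was not revisited.

**Problem sizes.** The reference workflow ran $5\times10^8$–$10^{11}$
photons per simulation on a GPU over weeks. The package's test suite runs
the same physics at desk scale: $10^5$–$10^6$ photons for property checks
and $5\times10^6$ per wavelength (correlated pairing, roulette threshold
$10^{-2}$ for these long-path runs) for the wavelength-trend check, where
the correlated AC estimates carry about 1% Monte Carlo error.
Those sizes keep the full suite in the minutes range on one core.

**What desk scale can and cannot reproduce.** Signs and ordering of the
wavelength trend are robust: AC drops sharply from 515 nm to 660 nm and
partially recovers at 880 nm. The *absolute* percent changes are not
recoverable from the printed optical table: the pulsed-minus-rest
absorption differences at 660/880 nm are differences of one or two units
in the table's last printed digit (e.g. 0.5249 → 0.5250 cm$^{-1}$), which
constrains the AC at those wavelengths only to within roughly ±50%. The
package reports what the printed constants imply (about −93% and +51%
for the two steps, versus −59% and +107% reported from the full-scale
runs) and the corresponding acceptance check on the bands is expected to
fail while the sign/ordering checks pass.

## Waveform synthesis

Templates are additive sums of three Gaussians
$y(t) = \sum_i a_i \exp(-((t-b_i)/c_i)^2)$ — note the *free-width*
spreadsheet-solver convention: no factor 2 in the denominator and no
normalization constant. The shipped parameter tables are only meaningful
under this form. Four age templates (23, 34.4, 44.8, 55 years) on a 0.8 s
period are shipped; older templates progressively lose the dicrotic notch
and diastolic peak.

`fit_ppg_template()` replaces the original spreadsheet
generalized-reduced-gradient fits with bounded multi-start
Levenberg–Marquardt least squares on relative residuals (the residual
denominator is floored at 5% of the waveform maximum so near-zero tails do
not dominate). Fits are summarized by the median relative error, the
measure that is robust to tail blow-ups; round-trip tests require
parameter recovery to 5% per parameter up to component permutation.

Records are synthesized by evaluating the template at each sample's phase
within the beat (time-axis scaling maps the 0.8 s template onto the
60/hr period) and tiling by concatenation — no cross-beat additive
overlap; the small step discontinuity at the beat junction is accepted as
part of the repetition construction. When the samples-per-beat count is
integral (e.g. 96 at 120 Hz / 75 bpm) one beat is built and repeated
exactly, which keeps the junction bitwise identical across beats. The
record is affinely scaled so its minimum is DC and its span is AC. Noise
is a bank of sinusoids scaled by the AC amplitude, by default 20/40/60 Hz
at 38/59/59% of AC; at 120 Hz sampling the 60 Hz tone sits exactly at
Nyquist, so its default phase is $\pi/2$ (phase 0 would sample only zero
crossings). Noise is added after AC/DC scaling, consistent with defining
its amplitude relative to AC.

## Device simulation

Three filter chains plus a pass-through control: a 0.1–7 Hz Butterworth
bandpass, a 0.1–7 Hz inverse-Chebyshev (type II, 40 dB stopband) bandpass
with a 10-sample trailing moving average, and a 7 Hz type II lowpass with
the same moving average. (A variant caption in the source material prints
"0.1–0.7 Hz"; that band would remove the 1.25 Hz cardiac fundamental and
contradict the usable features reported downstream, so 0.1–7 Hz is
adopted.) Filtering is causal — forward only, as a device DSP would run —
and implemented as cascaded second-order sections because the order-8
transfer functions at the 0.1 Hz edge are too ill-conditioned in direct
form (the linearity property test at $10^{-9}$ fails in direct form and
passes in cascade form).

The ADC maps a sample in detected-fraction units to a photocurrent
$i = 10 \times \mathrm{value} \times P_\mathrm{LED} \times A_\mathrm{PD}$
and to an integer code $\lfloor i \cdot 2^{\mathrm{bits}} /
I_\mathrm{ref}\rfloor$, saturated to $[0, 2^\mathrm{bits}-1]$ — a
floor-with-saturation quantizer, with the conversion constants (reference
current 32 µA, LED power 50 mW, photodiode area defaulting to the
detector annulus area) taken literally from the device description.
`resolution_sweep()` reports the median percent difference against a
25-bit reference, filtering both signals identically before comparison
(the device chain is filter-then-digitize; the reverse order is exposed as
an option). Records from one parameter combination are finally rescaled
jointly to the range 0.5–2.7, the amplitude range of the training data
used downstream.

## Pulse wave analysis

Systolic peaks come from an adaptive-threshold rolling-mean detector (a
self-contained re-implementation of the approach popularized by the
Python heart-rate toolkits): candidate thresholds raise a 0.75 s rolling
mean by a ladder of percentages, and the setting minimizing the
beat-interval standard deviation among plausible pulse rates wins. Onsets
are the preceding local minima. The dicrotic notch is located on the
Savitzky–Golay-smoothed (window 11, order 3), rescaled second derivative:
within each beat's decay (excluding the final 15% before the next onset,
whose upstroke curvature would dominate), the strongest local curvature
maximum is taken as the notch. A 30 s window is accepted when more than
90% of the expected `duration*hr/60` peaks are found and fewer than 10%
are rejected.

Fiducial times and values are refined to sub-sample precision: parabolic
(three-point) interpolation for peaks and onsets, linear interpolation
for threshold crossings. At 120 Hz a sample is 8.3 ms — as large as the
reported precision of the width features — so sub-sample refinement is
not cosmetic; it is what makes the width ratios reproducible.

Width conventions, fixed before any comparison and then left alone: with
the pulse amplitude referenced to the onset value, the systolic width at
p% is the time from the rising p%-amplitude crossing to the peak, the
diastolic width from the peak to the falling crossing;
`x{p}WidthTime` is their sum and `X{p}DivWidthTime` the
diastolic/systolic ratio. The p-grid is {10, 25, 33, 50, 66, 75} — only
10 and 75 are directly evidenced in the reported feature values; the rest
fill out the 38-feature registry and are configurable. Per-window feature
values are means across accepted beats.

```{r features}
rec <- synthesize_ppg(ppg_pulse_template(23), hr = 75, fs = 120,
                      duration = 30, ac = 2.2, dc = 0.5)
fid <- detect_fiducials(rec, expected_hr = 75)
window_qc(fid, duration = 30, hr = 75)
feats <- compute_ppg_features(rec, fid)
round(unlist(feats[c("x10WidthTime", "X10DivWidthTime",
                     "x75WidthTime", "pulseRate")]), 3)
```

## The sensitivity harness and its synthetic training generator

Training on the clinical archive used by the original study is out of
scope (external data, unpublished splits), so the harness ships a
synthetic generator: features uniform on $[0,1]$ (the post-rescaling range
of the extraction pipeline) and blood pressures linear in the features
plus Gaussian noise, with the planted truth recorded. That makes the
preprocessing rules and the harness testable offline — coefficient
recovery to $10^{-6}$ at zero noise, residual-sd recovery at
$n = 10^4$ — while making no claim of physiological realism: the
generator emulates the *shape* of a training table (ranges, noise,
filterable violations), not the joint distribution of real PPG features
and pressures, so passing tests certify the machinery, not clinical
validity.

Preprocessing follows the study's order: discard windows whose
within-window systolic/diastolic range exceeds 20/12 mmHg, remove
per-feature 3-standard-deviation outliers (iterated to a fixed point so
the operation is idempotent), then min-max rescale features to $[0,1]$.
Models plug in behind a `fit`/`predict` contract; reference adapters wrap
kernel SVM regression (Gaussian kernel, kernel scale 1.5), bagged
regression trees (a random forest with `mtry = p`), and a
single-hidden-layer network with 100 hidden units — reading the study's
"100 hidden layers" as the standard fitting-app configuration of 100
hidden *units*. Their behavior when trained on the original clinical data
is explicitly not reproducible here. `evaluate_split()` reports held-out
mean error and error standard deviation (the summary pair of the
automated-sphygmomanometer standard, which references < 5 mmHg and
8 mmHg); `sensitivity_analysis()` reports the population standard
deviation of predictions over the synthetic cohort — population rather
than sample, because the cohort *is* the set of conditions under study,
which also makes the metric exactly invariant to duplicating the cohort.

## Design decisions on genuinely open points

* **Interface shape.** The package is a pipeline of small, composable
  functions over lightweight classed objects rather than one monolithic
  model-fitting call; the one true estimator in the workflow
  (`fit_ppg_template()`) follows the classic fitted-object idiom with
  `coef`/`predict`/`fitted`/`residuals`/`plot` methods. The spec'd
  command-line surface is covered by a thin `inst/cli/ppgsim` Rscript
  over these functions.
* **Detected quantity.** Weight-based reflectance (summed surviving
  weight), not photon counts.
* **Quantizer.** Floor with saturation (mid-tread variants were not
  specified; the 1-LSB bound and monotone-fidelity properties hold
  regardless).
* **Tiling.** Concatenation, accepting the junction step; beat-period
  changes rescale the template's time axis, preserving shape.
* **Feature means.** One value per window = mean over accepted beats;
  beats lacking a notch contribute to all non-notch features and are
  excluded from notch-dependent ones.

## Known limitations

* The dermal blood-volume fractions behind the rest-state absorption
  values are not derivable from the shipped table; the printed values are
  used verbatim, and pulse scaling at untabulated ages rests on the
  youngest-age calibration.
* Lateral structures (vessels, inhomogeneities) are absent by
  construction; the slab geometry cannot express source–detector effects
  that depend on them.
* The synthetic cohort records differ from real PPG in beat-to-beat
  variability, baseline wander and motion artifacts; sinusoidal
  interference is the only noise model shipped.
* Absolute wavelength-trend percentages are limited by the printed
  precision of the pulsed absorption table, as quantified above.
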