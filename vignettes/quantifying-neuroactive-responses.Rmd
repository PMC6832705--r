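---
title: "Quantifying neuroactive drug responses: RSH, dose-inhibition and calcium MGV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuroactive drug responses: RSH, dose-inhibition and calcium MGV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dumpharm)
```

`dumpharm` implements a three-pronged quantification workflow for the
pharmacology of octopaminergic DUM (dorsal unpaired median) neurons — the
spontaneously firing pacemaker cells of the insect terminal abdominal
ganglion — together with seeded synthetic-data generators that emulate the
three raw data modalities. The scientific question the workflow serves is
whether menthol potentiates the carbamate insecticide bendiocarb through
octopamine receptors and the PKA pathway; the package's job is the
*quantification*: turning raw voltage traces, microplate absorbances and
fluorescence images into the summary statistics on which that question is
decided.

This vignette documents the models, the tunable parameters, the calibration
of the shipped presets, the numerical choices, and the limits of what the
synthetic data can show.

## 1. The RSH statistic on voltage traces

DUM neurons fire rhythmic action potentials at about 2 Hz around a −50 mV
interspike potential. A hyperpolarizing drug response silences spiking and
drives the potential tens of millivolts below baseline for some seconds.
The workflow quantifies such responses with the **relative size of
hyperpolarization (RSH)**: the deviation of the membrane potential from the
pre-application baseline, integrated over the duration of the response,

$$\mathrm{RSH} = \int_{t_0}^{t_1} \left(V(t) - V_\text{base}\right)\,dt
\quad [\mathrm{mV\cdot s}],$$

i.e. the signed *area* of the response. Deviations of both signs are
included: in control traces the after-hyperpolarization (AHP) phase of each
action potential makes RSH slightly negative even though no drug response
occurs, which is exactly the behaviour of the reference control cohorts.
When no hyperpolarization episode is detected, the statistic is evaluated
over a conventional 15-s window starting at the application time.

The per-trace pipeline is:

1. **Baseline** (`estimate_baseline()`): median of the pre-application
   samples after masking (−20 ms, +300 ms) around each detected spike. The
   asymmetric mask covers the AHP undershoot; without it the estimate is
   dragged below the true interspike potential. The median is robust to any
   residual spike contamination. The pre-application segment must be at
   least 1 s.
2. **Spikes** (`detect_spikes()`): local maxima above baseline + 20 mV,
   thinned to a 50-ms refractory interval.
3. **Response window** (`detect_response_window()`): the first
   post-application excursion below baseline − 5 mV that, after bridging
   above-criterion gaps shorter than 0.3 s (the gaps between AHP undershoots
   riding on the episode edges), lasts at least 0.5 s. Below-criterion runs
   shorter than 50 ms are discarded before bridging, so isolated noise
   crossings cannot seed or glue an episode while the ~130-ms AHP dips still
   can. The window ends where the potential re-crosses the criterion for
   good — operationally the end of the bridged run, which avoids unbounded
   windows under noise. No crossing ⇒ 15-s fallback window.
4. **RSH** (`compute_rsh()`): trapezoidal integration of the deviation over
   the window; `rsh = mean_deviation × duration` holds by construction.
5. **Cohort summary** (`summarize_cohort()`): mean, SE = sd/√n, n, mean
   detected duration, and the number of fallback windows.

The depth criterion (5 mV), minimal duration (0.5 s), bridging gap (0.3 s)
and minimal run (50 ms) are package defaults, not values inherited from any
protocol; they are exposed in the pipeline configuration. The choice of a
signed *integral* rather than a single depth × duration product follows from
the response-surface reading of the statistic and from the fact that a
nonzero control RSH requires contributions from the AHP phases; a
depth-times-duration product of a silent 15-s window would be zero.

### The trace generator and its calibration

`simulate_voltage_trace()` builds a trace as baseline + Gaussian recording
noise (0.3 mV) + a jittered 2-Hz train of template action potentials + an
optional programmed response episode + a small depolarizing saline-application
artifact (≤ 2 mV, ≤ 3 s in every shipped preset). The spike template is a
raised-cosine depolarization (80 mV, 4 ms) followed by a raised-cosine AHP
undershoot; both have closed-form areas (amplitude × width / 2), so the AHP
parameters could be *solved* rather than tuned: with 30 spikes in a 15-s
window and the artifact area, the control preset's AHP (12 mV, 241.4 ms)
makes the expected control RSH equal −35.65 mV·s, the reference control
value. A ~240-ms slow AHP at 2 Hz is physiologically reasonable for these
pacemaker cells.

The response episode is a plateau at `response_depth` with exponential
onset (τ = 0.5 s) and offset (τ = 2 s) ramps; spiking is suppressed while
the programmed deviation is more than 1 mV below baseline. The plateau
duration is drawn per trace from a truncated normal. The reference episode
duration is reported as 19.27 ± 4.5 s; since the methods declare summaries
as mean ± SE the ±4.5 is ambiguous (SE would imply a per-trace SD of
±14 s, implausibly wide), so the presets use 4.5 s as the *per-trace* SD and
document it as a knob. Because the ramps make the *detected* window longer
than the programmed plateau (the offset tail needs ~2 ln(depth/5) ≈ 4.5 s to
re-cross the 5-mV criterion), the menthol preset's plateau parameters
(−49.44 mV, 14.82 s) were solved with the package's own detector on
noiseless traces so that the *measured* episode averages 19.27 s and the
measured RSH −793.39 mV·s — the presets encode the reported summaries as
recoverable ground truth, which is what the acceptance suite checks
end-to-end. The octopamine preset scales the depth by the ratio of the
reported cohort RSH values; the phentolamine preset keeps a shallow
(−4.4 mV) residual deviation below the detection criterion, and the
PKA-inhibitor preset is identical to control.

## 2. Ellman/Bradford reduction and dose-inhibition fitting

Acetylcholinesterase (AChE) activity is measured by the Ellman method: the
hydrolysis product reacts with DTNB to give TNB, read at 406 nm; protein is
read at 595 nm against a Bradford standard series fitted per plate
(`fit_bradford()`). `reduce_plate()` converts each sample well to a specific
activity

$$a = \frac{(A_{406} - A_\text{blank})\; v}{\varepsilon\, \ell\, m}
\quad [\mu\mathrm{mol\, / \, mg\ protein}],$$

with ε = 13,600 M⁻¹cm⁻¹ (TNB), path length ℓ = 0.28 cm (90 µL in a
0.32 cm² flat-bottom well), well volume v = 90 µL and protein mass m from
the well's own Bradford read. Activities are per total 30-min incubation,
matching the µmol/mg unit convention without a time divisor. The generator
inverts exactly this formula, so a noiseless plate round-trips to the true
activity to machine precision; read noise is additive Gaussian (0.01 AU) on
every absorbance. The tissue-solution protein concentration (0.3 mg/mL) was
chosen once so that, with 0.01 AU read noise through the Bradford inverse,
per-well activity CV is ≈ 4% — a plausible precision for a microplate
Bradford at the middle of its standard range.

`percent_of_control()` normalizes activities to the mean of the same-run
control wells; `fit_log_logistic()` fits

$$I(x) = \frac{I_\text{max}}{1 + (e/x)^{b}}$$

by unweighted nonlinear least squares (Levenberg–Marquardt) with
multi-start initialization over a grid of I~max~ ∈ [50, 100] (5 points),
b ∈ [0.5, 4] (8 points) and e log-spaced over the dose range (10 points);
replicates enter individually. The lower bound is fixed at 0 and the upper
asymptote is *fitted* because the maximal observed inhibition (≈ 89% at
1 µM) stays below 100%. The ED50 is the model parameter e — the
concentration of half-*maximal* inhibition — not the concentration of 50%
absolute inhibition. `ed50_shift()` reports 100·(e_a − e_b)/e_a; for the
reference values 0.10 → 0.074 µM this is a 26% decrease (the shift is always
computed from the ED50s themselves).

The per-arm inhibition truths shipped with the generator are log-logistic
parameter sets solved from the reference summaries. For the
bendiocarb-alone arm the four published anchors (ED50, inhibition at 1 µM,
percent activity at 0.5 µM, inhibition at 0.05 µM) are mutually
inconsistent with any single three-parameter log-logistic; the shipped truth
reproduces the ED50 (0.10 µM), the 1-µM inhibition (88.76%) and the 0.5-µM
percent activity (18.87%) — the quantities the downstream comparisons use —
and consequently predicts ≈ 34% rather than 8.4% inhibition at 0.05 µM.
The menthol + bendiocarb anchors *are* mutually consistent and the truth
(I~max~ 96.3, b 1.27, e 0.074 µM) reproduces all of them.

## 3. Calcium-indicator MGV quantification

Fluorescence of a calcium indicator in single cells is quantified as the
**mean gray value (MGV)**: the mean pixel intensity over the segmented cell
mask — the per-µm² mean in arbitrary units, with the µm/pixel calibration
recorded alongside. Background subtraction (modal intensity outside the
mask) is available but off by default.

`segment_cell()` smooths with a Gaussian (σ = 2 px), thresholds at half of
the foreground dynamic range above the background median, keeps the largest
connected component and fills holes. Two properties motivate the
half-maximum threshold: for a blurred step edge the half-maximum crossing
sits on the true boundary (so the mask is unbiased to ≈ half a pixel,
keeping MGV accurate), and for a membrane-bright cell the ring itself
crosses the threshold while the dimmer interior is recovered by hole
filling. An image with no foreground above four robust SDs of the smoothed
background raises a "no cell" error.

The generator draws a disk-shaped cell (radius 25 µm at 0.5 µm/px) with a
3-µm membrane ring three times brighter than the interior — emulating the
membrane-proximal indicator signal — on a background of 2 intensity units,
scales the cell so the mask mean equals the per-image target before adding
pixel noise (SD 1), and records the true mask and MGV. The per-image target
is drawn around the cohort target with a mean-preserving lognormal of
CV 12%. That between-cell variability is needed jointly by two cohort-level
facts the generator must reproduce: the PKA-inhibitor cohort
(target 6.93 MGV) must be statistically *indistinguishable* from control
(6.65 MGV) in the Tukey comparison — impossible with near-zero within-group
variance — while the 15-image cohort mean must remain a stable estimate of
the target. CV 12% (within-group SD ≈ 0.8 MGV at control intensities)
satisfies both and is a moderate figure for cell-to-cell indicator loading;
the much larger spread implied by the reference SEs (CV ≈ 40%) would mostly
reflect biological heterogeneity that the geometric phantom makes no claim
to model.

`radial_profile()` bins mask pixels by distance from the mask centroid;
on ring presets the profile peaks at the membrane (≈ 23.5 µm for the
default geometry), the quantitative counterpart of "signal near the
membrane".

## 4. Group statistics

`one_way_anova()` is the classical fixed-effects decomposition (df =
k − 1, N − k; no Welch correction, matching the original analysis);
`tukey_hsd()` uses the studentized range with the Tukey–Kramer correction
under unequal group sizes, plus a compact letter display computed as the
maximal cliques of the non-significance graph (groups share a letter iff
their adjusted p > α, with α = 0.05). Degrees of freedom are always those
of the package's own data; published F-statistics with irreconcilable dfs
are not forced. `summarize_groups()` reports mean ± SE with `NA` SE for
singleton groups. `build_report()` assembles the three sections with
provenance (package version, seed, configuration hash) and no timestamps,
so a rerun with the same configuration is byte-identical.

## 5. Problem sizes, determinism and runtime

The documented study design — 10 traces per electrophysiology arm (60 s at
10 kHz, application at 30 s), 3 plates per assay arm (5 concentrations × 3
replicates plus in-plate controls, standards and blanks), 15 images per
imaging cohort (256² px) — is what `run_all()` executes and what the
acceptance script re-measures; the whole pipeline completes in well under a
minute per modality. All generators take explicit seeds, cohort member i
uses `seed + i − 1`, and the global RNG state of the caller is saved and
restored, so identical preset + seed is bit-identical and the end-to-end
report is deterministic.

## 6. What the synthetic data do and do not show

The generators emulate the *measurement process*: waveform geometry, read
noise, optical constants, segmentation-relevant image structure. Passing
the recovery suite therefore demonstrates that the detection, reduction,
fitting and statistical machinery is unbiased and correctly calibrated on
data whose ground truth is known. It does not validate the biology: traces
are template spike trains, not conductance-based membrane models; episode
shape is a fixed plateau-with-ramps; plates have Gaussian read noise but no
pipetting gradients, edge effects or enzyme-kinetic time courses; images
are single-plane geometric phantoms without optics, bleed-through or
ratiometric calibration to absolute calcium concentration. Real recordings
with drifting baselines, multi-phasic responses, or cells that deviate
strongly from disk-with-ring geometry will need threshold adjustments that
the configuration exposes but the synthetic cohorts cannot certify.
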