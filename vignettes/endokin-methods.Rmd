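---
title: "Quantifying endocytosis and fusion-pore closure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endocytosis and fusion-pore closure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endokin)
library(dplyr)
```

# Overview

`endokin` quantifies vesicle endocytosis and fusion-pore closure from four
measurement modalities — whole-cell membrane capacitance, synapto-pHluorin
bouton imaging, three-channel fusion-spot time series, and EM vesicle
tables — and ships seeded generators for each modality so that every
estimator can be validated by parameter recovery without access to raw
recordings. This vignette explains the underlying models, the tunable
parameters and their defaults, the numerical choices, and what the
simulations do and do not establish about real data.

# Capacitance kinetics

## Model

Membrane capacitance Cm is proportional to membrane area, so a
depolarization-evoked jump ΔCm_peak measures net exocytosis, and the
subsequent decay measures endocytosis. The decay is modeled as

- mono-exponential: `Cm(t) = plateau + A e^(−t/τ)`,
- bi-exponential: `Cm(t) = plateau + A₁ e^(−t/τ₁) + A₂ e^(−t/τ₂)` with
  τ₁ < τ₂ and rapid weight `w₁ = A₁/(A₁+A₂)`,
- or, for overshoot endocytosis, a mono-exponential recovery to a plateau
  below baseline, so total retrieval exceeds the jump.

Two rate statistics summarize the decay without committing to a model:
`Rate_decay`, minus the least-squares slope of Cm over a fixed early
window (0.5–4 s after a single 20 ms step, which evokes slow endocytosis;
0.5–1.5 s after a 10 × 20 ms train at 10 Hz, which adds a rapid
component), and `Rate_decay_n = Rate_decay / ΔCm_peak`, the fraction of
the jump retrieved per second. For a mono-exponential decay with
τ = 10.2 s, the companion identity `1 − e^(−1/τ)` says ~9% of the jump is
retrieved in the first second, which is the interpretive anchor for
`Rate_decay_n` values near 0.09/s.

## The artifact window and the jump estimator

The first 0.25 s of capacitance after stimulation is contaminated by the
stimulus artifact. The simulator emits those samples flagged
`masked = TRUE` rather than dropping them, so the analyzers — not the
generator — own the exclusion rule. This creates a genuine estimation
problem for ΔCm_peak: the earliest clean sample is already 0.25 s into
the decay, so a plain average of the first 0.25 s of clean trace
underestimates the jump by roughly `1 − e^(−0.375/τ)` (≈7% at τ = 5 s).
`measure_delta_cm_peak()` therefore fits a line through the first 0.25 s
of clean samples and takes its intercept at stimulus end; for exponential
decays with τ ≥ 5 s the residual bias of this back-extrapolation is below
0.5%. The plain window mean remains available as `method = "window_mean"`
for sensitivity checks. For the same reason, fitted exponential
amplitudes are back-extrapolated to stimulus end
(`A·e^(offset/τ)`), so the reported amplitudes and weights describe the
full jump, not the post-artifact remainder.

## Fitting

Decay fits use bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with τ constrained to (0.01, 10 × window].
Starting values are derived deterministically: plateau from the tail mean,
the slow component from a log-linear fit to the tail, and (for the
bi-exponential) the rapid component from the log-linear fit of the peeled
early residual. If a start lands exactly on the optimum (noiseless
traces), the zero-residual gradient test in the underlying machinery can
report a spurious singularity; the fitter retries once from a nudged
start. Non-convergence is never silent: the fit is returned with
`model = "unfit"` and `converged = FALSE`, and a time constant whose 95%
CI spans the fitting window is flagged `tau_uncertain` (the expected
outcome on pure noise).

## Mode classification and boundaries

Cells are classified by their decay into five modes with this precedence:
overshoot (total decay > 130% of the jump), no-endocytosis (< 30%), and
otherwise by dominant time constant — ultrafast (τ < 0.6 s), fast
(0.6 s ≤ τ ≤ 6 s, both boundaries inclusive), slow (τ > 6 s). Total decay
is measured at 60 s after stimulus end (or record end if sooner), using
the mean of the final second of trace; where the boundary values
themselves fall is documented and tested (exactly 30% or 130% falls
through to the τ classes; τ exactly 0.6 or 6 s is fast). A recording with
an intermediate decay and no usable τ is `unclassified` rather than an
error. The dominant τ of a bi-exponential fit is the component with the
larger amplitude weight. Calcium-current peaks are binned into
160–360, 400–900 and 1000–1800 pA groups; magnitudes in the gaps are
`out_of_bin` rather than forced into the nearest bin.

# Synapto-pHluorin quantification

Bouton fluorescence is normalized so the pre-stimulus mean is 100%, and
boutons are averaged unweighted into an experiment trace. Exocytosis is
the peak rise ΔF/F over baseline, searched from stimulus onset to 5 s
after train end because the fluorescence peak can lag the last stimulus.
Endocytosis is the normalized initial decay rate: minus the least-squares
slope over a window starting at the post-stimulus peak, divided by ΔF/F.
The window length is configurable within 4–10 s with a default of 6 s —
the measurement is specified as covering the first seconds of decay
without a unique prescription, so the package exposes the choice and
keeps the mono-exponential fit (`fit_syph_decay()`) as an alternative
initial-rate route. The decay is measured from the trace peak rather than
from stimulus end for the same lag reason.

Being a maximum over frames, the ΔF/F estimator carries a positive noise
bias, bounded in practice by about twice the frame noise SD of the
experiment-average trace (with 20 boutons at 3% per-bouton noise, that
bound is ~1.3%, under 1% of a 161% signal). The bias bound is part of the
tested contract, and the normalized decay rate inherits it (scaled by
rate/ΔF/F) through its denominator.

# Fusion-spot classification

## Detection physics encoded in the generator

The generator reproduces the optical logic of the three-channel assay.
The bath dye (F_655) is strongly excited: while a pore connects the
vesicle lumen to the bath, bleached dye exchanges freely and the spot
stays bright; once the pore closes, the trapped dye bleaches toward
background with time constant `a655_bleach_tau_s` (default 0.3 s). The
membrane label (F_PH) is weakly excited and reports membrane geometry: it
holds after pore closure and decays only when the vesicle pinches off and
leaves the imaging plane, `ph_delay_s` (default 1.5 s) after dye dimming.
Vesicular content (F_FFN) decays exponentially from fusion onset with the
release time constant. Spot size is emitted as a Gaussian FWHM in nm; in
shrink-fusion, size and both fluorescence channels decay exponentially in
parallel to zero. Frame intervals are constrained to the 0.04–0.08 s
range of the imaging protocol (default 0.05 s).

## Decision rules

Fusion onset requires the joint appearance of F_PH and F_655 (both above
baseline mean + 4 SD within the same 3-frame window) with a sustained
F_FFN decline starting within ±2 frames — single-channel rises are
rejected as artifacts. Classification then proceeds in a fixed order on
lightly smoothed (5-frame rolling mean), baseline-subtracted channels:

1. **shrink-fusion** — both channels decline below `phi_sustain` (0.7) of
   their post-onset peaks, the declines are parallel (Pearson r ≥ 0.9
   over the decline segment), and the spot size shows a net decrease
   above 20%. The correlation is computed from the first sustained drop
   below 90% of peak until both channels reach 10% of peak; extending it
   over the post-decay noise floor would dilute r toward zero at
   realistic noise. The size criterion is what separates a shrinking spot
   from a closed vesicle whose membrane label later decays.
2. **close-fusion** — the dye dims below `theta_dim` (0.5) of its peak
   while the membrane label still holds at ≥ `phi_sustain` of its own
   peak, or the membrane-label decline lags the dye decline by at least
   `min_delay_frames` (3). The lag is measured between the two channels'
   sustained crossings of the same fractional level, which is far more
   noise-robust than comparing decline onsets. The closure time is the
   onset-to-half-dimming interval; for the generator's kinematics this
   equals the true closure time plus `a655_bleach_tau · ln 2`.
3. **stay-fusion** — both channels end ≥ `phi_sustain` of their peaks;
   the event is censored when the record ends less than 30 s after
   onset, since pore closure is observed up to ~30 s after fusion.
4. anything else is `ambiguous` — a value, not an error.

All thresholds are exposed as arguments with the defaults above; the
qualitative rules they implement do not prescribe numbers, so the
defaults were chosen once to keep the noiseless canonical traces exactly
separable and verified (not tuned) against the ≥95%-accuracy property at
10% channel noise. Pre-existing spots use the same dimming/sustain logic
against their initial levels. Multiple sequential fusions at one spot are
out of scope: only the first event per spot is counted.

The release-time statistic T_FFN is the 20–80% decay time of F_FFN with
span measured from pre-onset plateau to post-decay floor and crossings
linearly interpolated; it equals `τ·ln 4` for exponential release and 0.6
of the ramp duration for a linear decay. The floor is the mean of the
final 0.5 s, so the record must outlast the release by several time
constants; a trace still declining at record end (final-second slope
steeper than 2% of span per second) is censored rather than measured.
Per-cell summaries report the close-fusion probability among fusion
events, the pore-closure probability among pre-existing spots (NA when a
cell has none), and the mean T_FFN over non-censored events; cells with
fewer than five fusion events are flagged excluded to avoid
small-denominator bias, but retained in the output.

# EM morphometry

Bulk endosomes are defined by size: diameter ≥ 80 nm, or cross-section
area exceeding that of an 80 nm vesicle (π·(0.04 μm)² ≈ 0.005 μm²).
Either criterion suffices; the diameter boundary is assigned to bulk,
consistent with the area clause being a strict "more than". HRP(+)
regular-vesicle densities exclude bulk endosomes (they are reported
separately), and by default only HRP(+) bulk endosomes enter the area
density, since unlabeled large structures were not formed during the
labeling epoch; both choices are configurable. Densities are per μm² of
profile cross-section and aggregate over profiles as mean ± s.e.m., the
synaptic profile being the unit of analysis.

The EM generator is structural plumbing rather than a calibrated model:
profile areas are gamma-distributed around 0.35 μm² (typical bouton
cross-sections), vesicle counts are Poisson with per-μm² rates, regular
diameters are normal around 42 ± 5 nm (safely below the 80 nm rule), and
bulk diameters are 80 nm plus a log-normal excess.

# Group statistics

Summaries are mean ± s.e.m. (`sd/√n`, n−1 variance; undefined for a
single value). Comparisons are unpaired two-tailed Student's t-tests with
equal variances, because that is the named test of the reporting
convention this package serves; Welch's correction is available behind
`var_equal = FALSE`. No multiple-testing correction is applied, matching
the same convention. Significance stars are p < 0.05 (\*), p < 0.01
(\*\*), p < 0.001 (\*\*\*). The unit of analysis varies by modality
(cell, experiment, profile), so aggregation level is the caller's
explicit responsibility rather than being inferred.

# Synthetic data: what it does and does not establish

The generators reproduce the statistical structure the estimators assume:
stimulus-locked jumps with exponential recovery and Gaussian sampling
noise at 100 Hz (60 s records, giving ≥5τ coverage up to τ ≈ 12 s);
10 Hz bouton traces with linear stimulus-locked rise, constant-rate or
exponential decay, multiplicative bouton heterogeneity (CV 0.2) and
additive frame noise; canonical channel kinematics per fusion mode; and
Poisson vesicle counts. Default control parameters are the
control-condition values of the system the package models: 531 fF jump
with τ = 10.2 s for the single 20 ms step; 1565 fF jump with rapid
τ = 1.6 s (31% amplitude) and slow τ = 15.5 s for the train; 161% ΔF/F
decaying at 3.9%/s for the pHluorin experiments; fusion-pore closure
0.05–30 s after onset.

Passing parameter recovery on these inputs shows the estimators are
correct and well-calibrated for data that meet their assumptions. It does
not validate them against what the generators deliberately omit: baseline
drift and rundown, intra-train exocytosis kinetics (the jump is
instantaneous at stimulus end), non-Gaussian or correlated imaging noise,
focus drift, overlapping or sequential fusion events at one spot, and
segmentation error upstream of the per-frame measurements (ROI extraction
is out of scope throughout).

# Reproducibility

Every generator takes an explicit seed and restores the caller's RNG
state, so a fixed seed yields byte-identical tables. `run_pipeline()`
fans one global seed out to per-modality seeds as seed + 100/200/300/400
(capacitance / pHluorin / fusion / EM), so any modality can be re-run in
isolation, and writes its fully resolved configuration beside the outputs.
The test suite runs the cohort sizes used throughout this vignette
(11 capacitance traces per protocol, 20 pHluorin experiments, 200 spot
traces per fusion mode, 120 EM profiles per group, 10,000 null
replicates for the t-test calibration), which keeps a full run around a
minute on one core while leaving the recovery checks well-powered.

```{r example}
recs <- simulate_cm_cohort(
  11, cm_truth(jump_fF = 531, decay_model = "mono", tau_s = 10.2,
               noise_sd_fF = 10),
  cm_protocol("depol_20ms"), seed = 1)
kin <- bind_rows(lapply(recs, analyze_cm))
summarise(kin, tau = mean(tau_s), jump = mean(delta_cm_peak_fF),
          rate_n = mean(rate_decay_n_per_s))
```

# Known limitations

- The capacitance analyzers assume a stable baseline; rundown correction
  is out of scope.
- The decay-window rate statistics are window-dependent by construction;
  comparing values across protocols requires matching windows.
- The fusion classifier operates on per-frame spot measurements and
  assumes channels are time-aligned; it neither detects spots in images
  nor resolves overlapping events.
- Lock-in computation of capacitance from raw admittance is upstream of
  this package and not reimplemented.
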