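# endokin

Quantification of endocytosis kinetics and fusion-pore closure from
whole-cell capacitance recordings, synapto-pHluorin imaging, three-channel
fusion-spot time series, and electron-microscopy vesicle tables.

## What this package is for

Synapses and neuroendocrine cells retrieve fused vesicle membrane by
several endocytic routes — slow and fast clathrin-associated endocytosis,
ultrafast retrieval, bulk endocytosis, and direct closure of Ω-shaped
membrane intermediates ("kiss-and-run"). Each route leaves a distinct
signature in a different measurement modality, and each modality needs its
own quantification:

- **Membrane capacitance** (`analyze_cm()` and friends). A depolarizing
  step evokes a capacitance jump ΔCm_peak (exocytosis) followed by a decay
  (endocytosis). The package measures the jump, fits mono- or
  bi-exponential decays `Cm(t) = plateau + Σ Aᵢ e^(−t/τᵢ)`, computes the
  initial decay rate Rate_decay (least-squares slope over a
  protocol-dependent window: 0.5–4 s after a single 20 ms step, 0.5–1.5 s
  after a 10 × 20 ms train at 10 Hz) and its normalized form
  Rate_decay_n = Rate_decay / ΔCm_peak, classifies each cell into the
  five endocytic modes (no-endo < 30% decay; overshoot > 130%; otherwise
  ultrafast τ < 0.6 s, fast 0.6–6 s, slow > 6 s), and bins cells by peak
  calcium current (160–360 / 400–900 / 1000–1800 pA). The first 0.25 s
  after stimulation is treated as capacitance artifact and excluded.
- **Synapto-pHluorin imaging** (`analyze_syph()`). Bouton fluorescence is
  normalized to a 100% pre-stimulus baseline and averaged; exocytosis is
  the peak rise ΔF/F and endocytosis the normalized initial decay rate
  (% of ΔF/F lost per second over a 4–10 s post-peak window).
- **Fusion-spot classification** (`classify_fusion_table()`). Three-channel
  confocal spot traces (membrane label F_PH, bath dye F_655, vesicular
  content F_FFN) are searched for fusion onsets and classified into
  close-fusion (pore closes 0.05–30 s after fusion: F_655 bleaches while
  F_PH holds or decays with a delay), stay-fusion (both sustained), and
  shrink-fusion (parallel decline with shrinking spot size); pre-existing
  spots are tested for pore closure the same way. Release time is the
  20–80% decay time of F_FFN (T_FFN = τ·ln 4 for exponential release).
  Cells with fewer than five fusion events are flagged excluded.
- **EM morphometry** (`em_profile_densities()`). Per synaptic profile,
  HRP(+) vesicle counts per μm² and bulk-endosome area per μm², with bulk
  endosomes defined as diameter ≥ 80 nm or cross-section >
  π·(0.04 μm)² ≈ 0.005 μm².
- **Group statistics** (`t_test_groups()`, `compare_groups()`): mean ±
  s.e.m. and unpaired two-tailed Student's t-tests with the usual star
  thresholds (p < 0.05/0.01/0.001).

Because raw recordings of this kind are rarely deposited, the package
ships seeded generators (`simulate_cm_recording()`,
`simulate_syph_experiment()`, `simulate_spot_trace()`,
`simulate_em_tables()`) that produce every input modality with known
ground truth, so every estimator is validated by parameter recovery; and
`run_pipeline()` runs simulate → analyze → report end to end,
reproducibly from one seed.

All user-facing functions take data frames and return tibbles, so results
chain with the pipe; fitted objects have `tidy()`/`glance()` methods and
the main types have `autoplot()` displays.

## Worked example

```r
library(endokin)
library(dplyr)

# Eleven simulated control cells: 531 fF jump decaying with tau = 10.2 s,
# 10 fF recording noise, single 20 ms depolarization.
recs <- simulate_cm_cohort(
  11, cm_truth(jump_fF = 531, decay_model = "mono", tau_s = 10.2,
               noise_sd_fF = 10),
  cm_protocol("depol_20ms"), seed = 1)

kin <- bind_rows(lapply(recs, analyze_cm))
summarise(kin,
          tau = mean(tau_s), jump = mean(delta_cm_peak_fF),
          rate_n = mean(rate_decay_n_per_s))
#> # A tibble: 1 × 3
#>     tau  jump rate_n
#>   <dbl> <dbl>  <dbl>
#> 1  10.2  528. 0.0795
```

The fitted time constant recovers the generating 10.2 s; the measured
jump recovers 531 fF to within its sampling error; and the normalized
decay rate of ~0.08/s sits just under the 1 − e^(−1/10.2) ≈ 9.3%
first-second retrieval implied by a 10.2 s mono-exponential decay (a
finite-window slope is slightly shallower than the instantaneous initial
rate). `autoplot(recs[[1]])` shows the trace with the artifact window
greyed out, and `autoplot(fit_cm_decay(recs[[1]]))` overlays the fit.

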