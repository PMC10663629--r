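# pupildoc

Pupillometry and ERP markers of covert cognition in disorders of
consciousness, built around the auditory "local–global" oddball paradigm.

## The problem

Patients with a disorder of consciousness (DoC) — the vegetative state /
unresponsive wakefulness syndrome (VS/UWS) and the minimally conscious state
(MCS) — cannot report what they perceive, so clinicians look for
physiological markers of residual cognitive processing. The local–global
paradigm crosses two auditory regularities: on each trial five 50-ms tones
(low `A` or high `B`, 150 ms onset asynchrony) either repeat (`AAAAA`, a
*local standard*) or end deviantly (`AAAAB`, a *local deviant*); across
trials, one series is presented frequently (~80%) and establishes a *global*
regularity that rare alternative series violate. Violations of the local
rule evoke a mismatch negativity (MMN) automatically; violations of the
global rule evoke a P3b and — in pupillometry — an event-related pupil
dilation response (PDR) only when the subject consciously tracks the rule.
That asymmetry makes the *global effect* a candidate bedside marker of
conscious processing, and the *maximal violation effect* (MVE: doubly
deviant `LDGD` trials vs doubly standard `LSGS` trials) a higher-contrast
variant of it.

`pupildoc` implements the full analysis chain:

* **Paradigm** — generation of labelled stimulus schedules (4 blocks × 30
  trials, 4–7 global deviants per block, each followed by a standard, 3 s
  trial asynchrony, 90 s per block), with BIDS-events-like TSV I/O.
* **Pupil preprocessing** — dilation-speed / blink artifact detection
  (median + 16·MAD speed criterion with a 50-ms guard), linear gap
  interpolation, zero-phase 10 Hz low-pass, epoching (−0.5 to +3 s at
  120 Hz), trial rejection (>25% interpolated), dataset grading
  (poor >25%, excluded >50% rejected trials), most-reactive-eye selection,
  baseline correction.
* **Pupil statistics** — sample-wise Student t-tests (one-sample vs
  baseline, paired, pooled two-sample) with Benjamini–Hochberg FDR over the
  analysis window; per-patient labels (significant at q ≤ 0.05, trend at
  q ≤ 0.10) for the generic, local, global and MVE contrasts.
* **ERP pipeline** — 0.5–45 Hz zero-phase band-pass, epoching (−0.2 to
  +1.344 s at 250 Hz), iterative channel and epoch rejection (100 µV
  amplitude rules, four variance-Z>4 passes), spline interpolation of bad
  channels, average reference, 800-ms pre-fifth-sound baseline, and the
  triple-threshold effect criterion: Welch t-tests per channel and sample,
  significant only over ≥5 consecutive samples on ≥10 contiguous
  electrodes inside the component's expected window.
* **Diagnostics** — 2×2 contingency tables of marker positivity against
  diagnosis (MCS vs VS/UWS) or six-month recovery, sensitivity /
  specificity / predictive values with exact Clopper–Pearson intervals,
  Fisher exact and Mann–Whitney tests, and a packaged 24-patient cohort
  table.
* **Synthetic data** — pupil recordings (unit-peak gamma dilation kernel
  `k(t) = (t/t_p)^s e^{s(1 - t/t_p)}`, AR(1) noise, blinks), EEG sessions
  (MMN/P3b-like components on a planar montage with explicit adjacency,
  bad channels, artifact epochs) and whole cohorts, so every stage runs
  and is testable without any clinical recording.

## Worked example

Simulate one MCS-like patient (a generic 1-px response to every trial plus
a 0.8-px dilation to global deviants, AR(1) noise of 0.5 px), run the full
pupil pipeline, and classify their effects:

```r
library(pupildoc)

sched  <- build_session(seed = 42)                      # 120 trials, 360 s
params <- pupil_sim_params(amp_generic = 1, amp_global = 0.8, noise_sd = 0.5)
sim    <- simulate_pupil_session(sched, params, seed = 42)
pat    <- pupil_pipeline(sim$recording, sched)

pat$quality
#> <pupil_quality> correct (rejection rate 0.8%)
classify_patient_effects(pat)
#> # A tibble: 1 × 5
#>   quality sound       mve         local global
#>   <chr>   <chr>       <chr>       <chr> <chr>
#> 1 correct significant significant ns    significant
```

The patient shows a generic auditory PDR, a global effect and an MVE, and
no local effect — the signature expected when only the consciously
mediated across-trial rule is being tracked.

Marker performance on the packaged cohort (the PDR MVE against clinical
diagnosis; trends count as positive for this marker):

```r
rec <- doc_patients()
tab <- build_contingency(rec, "pdr_mve", "significant_or_trend", "diagnosis_mcs")
tidy(tab)
#> # A tibble: 1 × 7
#>   marker  truth         positive                tp    fp    fn    tn
#> 1 pdr_mve diagnosis_mcs significant_or_trend     6     1     8     9
diag_metrics(tab)
#>   metric estimate ci_low ci_high k  n
#> 1     se     42.9   17.7    71.1 6 14
#> 2     sp     90.0   55.5    99.7 9 10
#> 3    ppv     85.7   42.1    99.6 6  7
#> 4    npv     52.9   27.8    77.0 9 17
fisher_exact_2x2(tab)
#> [1] 0.1717807
```

So the MVE marker identifies MCS with 43% sensitivity and 90% specificity
in this cohort. `patient_report(rec)` assembles the same summary for every
marker and both reference truths at once, and `autoplot()` methods exist
for epochs, effect results and metric tables.

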