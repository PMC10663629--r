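---
title: "Methods: pupillometry and ERP analysis of the local-global paradigm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometry and ERP analysis of the local-global paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupildoc)
```

This vignette documents the models, conventions and numerical choices
behind `pupildoc`: what each stage assumes, which parameters matter and why
their defaults are what they are, what the synthetic-data generators do and
do not emulate, and where the underlying study left the design genuinely
open.

## The paradigm

Each trial is a series of five tones (50 ms each, 150 ms onset asynchrony),
so the fifth tone starts 600 ms after trial onset and the series ends at
650 ms. A trial is a **local deviant (LD)** when the fifth tone differs
from the first four, otherwise a local standard (LS). Within a block, one
series is frequent (~80% of trials) and defines the global regularity;
trials repeating it are **global standards (GS)**, the rare alternative
series are **global deviants (GD)**. Four block types — one per possible
frequent series — cross the two factors fully: a block whose frequent
series is `AAAAB`, for instance, makes LD the *standard* and LS the
*deviant*, which is what lets the analysis separate stimulus acoustics from
rule violations.

Structural rules enforced by `build_block()`: 30 trials per block; the
first `n_habituation` trials present the frequent series to establish the
rule; the number of deviants is drawn uniformly from {4, 5, 6, 7}; deviant
positions are drawn uniformly among placements in which every deviant is
immediately followed by a standard (hence never last, never adjacent).

Three timing/structure points were underdetermined and are resolved as
package conventions, all configurable via `paradigm_config()`:

* **Trial asynchrony.** The sounds of a trial end 650 ms after its onset,
  yet 30 trials fill 90 s; the stated 3000-ms interval is therefore
  implemented as *onset-to-onset* asynchrony (30 × 3 s = 90 s, 360 s per
  session), not as a gap after the last sound.
* **Habituation count.** Described variously as four or five block-initial
  repetitions; the default is 5. Habituation trials are labelled GS and
  kept in analysis epochs (`include_habituation = FALSE` drops them), since
  nothing indicates they were excluded from the pupil averages.
* **Block order** within a session is uniformly shuffled per seed.

## Synthetic data

The generators exist so that every downstream stage is exercisable and
testable without clinical recordings. They emulate the *statistical
structure* the pipeline assumes, not the biophysics.

**Pupil.** The dilation response to a trial is a unit-peak gamma kernel
$k(t) = (t/t_p)^s \exp\{s(1 - t/t_p)\}$ with peak latency $t_p = 1.3$ s and
shape $s = 2$ — a conventional event-related pupil impulse response on the
timescale of the 3-s analysis window; the true kernel in DoC patients is
unknown, and these are conventions, not claims. Each trial adds
$(a_\text{generic} + a_\text{local}\,1[\text{LD}] +
a_\text{global}\,1[\text{GD}])\,k(t - t_\text{onset})$ pixels to a 50-px
baseline. Noise is stationary AR(1) (default sd 0.5 px, lag-1 correlation
0.9 at 120 Hz). Blinks arrive as a Poisson process (default 4/min): a
linear fall over 50 ms to ~2% of baseline, a plateau whose duration is
drawn around 300 ms, and a linear recovery over 150 ms, shared between the
two eyes; the ground truth lists every blink interval. An optional
`drift_amp` adds a CNV-like anticipatory ramp from trial onset to the fifth
sound as a nuisance; no CNV statistic is computed anywhere. Recordings
start 2 s before the first trial so the first baseline window exists. Not
emulated: gaze-dependent foreshortening, luminance responses, pink-noise
spectra, partial lid closures.

**EEG.** 250 Hz, default 32 channels on a 4 × 8 planar grid with rook
adjacency (an explicit, serialisable graph; `grid_montage()` can build
other sizes). LD trials receive an MMN-like negativity (Gaussian in time,
default latency 150 ms after the fifth sound, sd 50 ms) and GD trials a
P3b-like positivity (400 ms, sd 100 ms), each scaled by a spatial Gaussian
(sd 2.5 grid units) centred front-centre and back-centre respectively. Bad
channels get 20× noise; artifact epochs get a 150-µV 4-Hz burst on all
channels — both chosen to be unambiguous instances of what the rejection
rules define. Not emulated: realistic dipole topographies, the geodesic
net's geometry, ocular artifacts.

**Cohorts.** `simulate_cohort()` draws group membership (default 10 VS/UWS
+ 14 MCS), true effect flags from per-group prevalences, CRS-R-like
subscale scores from group-typical ranges, and a six-month outcome whose
recovery probability increases when a true global effect is present — the
structure needed to exercise the diagnostics module end to end.

Because the generators share the pipeline's own effect model, passing
recovery tests show internal consistency and correct implementation of the
stated rules; they cannot show that the pipeline is robust to real-world
violations of the model (non-stationary noise, drifting baselines,
asymmetric eyes, agitation artifacts).

## Pupil preprocessing

Artifact detection flags (i) missing, non-positive, or near-zero samples
(below 10% of the median valid diameter — device blink coding), and
(ii) dilation-speed outliers, where speed is the larger absolute
neighbouring difference per sampling interval and the threshold is
median + 16 × MAD of the speed distribution. Flagged regions grow by a
50-ms guard on each side. The 16 and 50 ms follow the conventions of
standard eye-tracking artifact-removal tools; the study names the method
but not its constants, so both are parameters. Two degenerate cases are
defined explicitly: a zero-MAD speed distribution flags nothing, and a
fully masked trace is an error rather than an all-interpolated fabrication.

Gaps are filled linearly between nearest valid neighbours; leading and
trailing gaps take the nearest valid value (a documented choice — linear
extrapolation can produce negative diameters). Filtering is a zero-phase
(forward–backward) 3rd-order Butterworth low-pass at 10 Hz; zero-phase so
that effect latencies are not shifted, with odd-reflection padding so edge
transients fall outside the data and a constant trace passes through
unchanged.

Epochs span −0.5 to +3.0 s around the first sound (420 samples at 120 Hz).
The −0.5–0 s baseline must exist, which is why the epoch starts at −500 ms
even though one part of the study's description mentions epochs from
"200 ms"; we read that as a typo, and the window is configurable. A trial
is rejected when its interpolated fraction exceeds 25% (strictly), a
dataset is *poor* above 25% rejected trials and *excluded* above 50%
(strictly; these thresholds are also reported inconsistently in the source
— 75% appears in one passage — so both are parameters and the defaults
follow the methods text). Eye selection: the more reactive eye when the
light reflex is asymmetric, otherwise the eye with fewer rejected trials,
ties to the right eye by convention.

## Pupil statistics

All contrasts are evaluated sample by sample. At the individual level the
generic response is a one-sample t of baseline-corrected LSGS trials
against zero; local ({LDGD, LDGS} vs {LSGS, LSGD}), global ({LSGD, LDGD}
vs {LSGS, LDGS}) and MVE (LDGD vs LSGS) are pooled-variance two-sample
Student t-tests across trials. At the group level each patient contributes
one mean trace per condition and the tests are paired across patients.
"Student" is read as the pooled-variance form at the pupil stage because
the study reserves Welch's correction explicitly for the ERP stage.
Zero-variance samples get p = 1 when the means agree and p = 0 otherwise.

P-values are corrected with the Benjamini–Hochberg step-up rule over the
samples of one contrast's analysis window (0–3 s by default) — one FDR
family per contrast, never pooled across contrasts. The per-patient
decision rule is: **significant** if any sample survives at q ≤ 0.05,
**trend** if any survives at q ≤ 0.10 but none at 0.05, else **ns**; an
optional minimum-run-length parameter (default 1 sample) tightens this.
The study reports one p per patient per effect without stating how the
sample-wise map was reduced; this any-sample convention mirrors its group
criterion and is declared rather than inferred. Under the null the
"significant" rate of this rule is close to, and bounded by, the nominal
5% because FDR control over a positively correlated family is conservative
for the global null; the test suite measures it at ~4%.

Power conventions used by the test suite (and nothing else): the
"documented strong effect" for parameter recovery is a 0.8-px global
amplitude against 0.5-px AR(1) noise at the paradigm's ~24 GD vs ~96 GS
trials, which yields >80% detection; the null calibration runs the same
pipeline with a zero global amplitude. These sizes (100 and 200 simulated
patients) were chosen a priori as the smallest runs giving stable rates.

## ERP pipeline

Preprocessing follows the conventional order: 0.5–45 Hz zero-phase
band-pass; epoching −0.200 to +1.344 s (386 samples at 250 Hz; the source's
"+1.344 ms" is read as a ms/s typo for +1344 ms); channel rejection;
spline interpolation of bad channels; epoch rejection; average reference;
baseline correction over the 800 ms ending at the fifth-sound onset
(−0.2 to +0.6 s).

Rejection rules, all strict inequalities: a channel is removed when |V|
exceeds 100 µV in more than 50% of epochs (absolute voltage; a
peak-to-peak variant is available by argument), then four passes remove
channels whose voltage variance has Z > 4 across the currently valid
channels — variances recomputed each pass, removed channels staying
removed. Epochs: removed when |V| > 100 µV on more than 10% of valid
electrodes, then four variance-Z passes. The loop is deterministic and
always terminates in exactly `n_iter` passes. Bad channels are rebuilt by
thin-plate-spline interpolation over the valid channels — the planar
analogue of spherical-spline scalp interpolation, exact for constant and
linear fields — and a channel with fewer than 3 valid neighbours is left
invalid rather than extrapolated. A dataset is *correct* with ≥75% valid
channels and ≥30% valid epochs.

The **triple-threshold criterion** for an individual-level effect: Welch
t-tests at every (channel, sample); p < 0.05 must hold on at least 5
consecutive samples (20 ms) over at least 10 electrodes that form a
connected subgraph of the montage adjacency, inside the component's
expected window. The default reading is strict — the same channel set must
be significant throughout the run — with a relaxed
spatio-temporal-component mode (`mode = "component"`) available. Each
electrode is tested independently before clustering. Expected windows are
anchored to the fifth-sound onset (+0.6 s): local effects from 0.7 s to
the epoch end, global/MVE from 0.8 s; the source quotes windows anchored
to the *first* sound ("from 100 ms"), which is physiologically odd for a
deviance response that cannot begin before the fifth sound — both the
anchoring and the windows are arguments, so the literal-text windows can be
reproduced by passing them. Group-level ERP contrasts are provided as
patient-mean paired t-tests with FDR in time at a caller-chosen channel
set, since the study does not state its channel selection.

On pure-noise simulations the triple threshold's false-positive rate is
low; the suite measures it over 100 runs at 32 channels and asserts it
stays below 20%. End-to-end recovery is verified at a documented
strong-effect setting (MMN 8 µV, P3b 12 µV peak amplitudes against 4-µV
sensor noise on the 32-channel grid), where ~90% of simulated patients
show both effects; the acceptance-grade detection checks instead inject a
flat 3-σ effect on exactly 12 adjacent electrodes for 200 ms, so the
criterion's three thresholds are each probed by construction (4-sample and
9-electrode variants of the same effect must fail).

## Diagnostics

Markers are dichotomised per patient and crossed with one of two reference
truths: clinical diagnosis (MCS positive) or recovery of consciousness at
six months (outcome "Conscious"; death, VS/UWS and MCS± count as
non-recovery; missing outcomes are excluded pairwise). Positivity follows
the study's own usage: the PDR maximal-violation contrast counts trends
(q ≤ 0.10) as positive — stated explicitly in its results — while ERP
markers count only significant effects, since their table is binary.

Sensitivity, specificity, PPV and NPV come with exact Clopper–Pearson
intervals by default, which reproduce the study's printed Se/Sp intervals
to their printed precision (one printed lower bound, 56 for 9/10, reflects
intermediate rounding of the exact 55.5). The printed PPV/NPV intervals
follow an unidentified method; a logit-based (Mercaldo) alternative is
provided (`ci_method = "logit"`), and the mismatch is documented rather
than patched. One further source inconsistency is preserved as-is: the
ERP-global NPV is printed as 43% although the underlying counts give
8/17 = 47%, and the package reports the count-derived value. The Fisher
exact test sums hypergeometric probabilities of all tables with the
observed margins that are no more probable than the observed one (the
conventional two-sided definition, with a 1e-7 tie tolerance); the
Mann–Whitney U is delegated to `wilcox.test` (exact for small untied
samples, tie-corrected normal approximation otherwise). Percentages are
kept at full precision in all returned objects; only report *display*
rounds to integers.

The packaged cohort table transcribes the study cohort: 24 patients
(10 VS/UWS, 14 MCS), demographics, aetiology, CRS-R subscales, per-marker
labels and six-month outcomes. `crs_r_total` is recomputed as the sum of
the six subscales — the table's own invariant; one transcribed row (patient
13) prints a total inconsistent with its subscales, and the sum wins.

## Problem sizes and limitations

The default test suite uses 1000 seeds for paradigm invariants, 100/200
simulated patients for pupil power and null calibration, 100 pure-noise
runs for the ERP false-positive rate, and single fixed-seed sessions for
end-to-end regressions — sizes chosen so the whole suite completes in a
few minutes while keeping Monte-Carlo error well inside the asserted
margins. Known limitations: the synthetic generators share the analysis
model (see above); the 32-channel grid makes the 10-contiguous-electrode
rule proportionally much stricter than on a 256-channel net, which is why
end-to-end ERP detection needs generous amplitudes there; and the
individual-level "any surviving sample" decision rule is one defensible
reduction of a sample-wise map among several — alternatives are reachable
through `min_run` and the alpha parameters.
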