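---
title: "Methods: simulating and screening a week of digital phenotyping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and screening a week of digital phenotyping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Passive sensing from a wrist wearable and a smartphone yields, for every
participant-day, a small set of behavioural summaries: staged sleep, sleeping
heart rate, step counts, GPS mobility, touchscreen tapping speed, messaging
activity and screen time. In a psychosis outpatient cohort these daily digital
measures are aggregated to one visit-level *digital marker* per measure over
the week after the baseline clinical assessment and screened pairwise against
baseline symptom, functioning and cognition scales. `digiphen` implements
that pipeline end to end, together with a synthetic-cohort generator with
known ground truth, so that every stage — extraction, windowing, validity
rules, completeness accounting and the regression screen — is testable
without access to any participant data.

## Pipeline model

**Daily measures.** Twelve measures are extracted per local date
(`daily_measures()`): six sleep fields (total asleep hours summing light,
deep and REM over all segments assigned to the date, wake hours, the three
stage totals, and main-segment efficiency), mean sleeping heart rate
(samples inside assigned segments but outside wake bouts), daily steps
(vendor totals passed through), distance travelled (haversine sum over
accuracy-filtered GPS fixes, dropping implied speeds above 150 km/h and
displacements under 30 m), the modal intertap interval over a trailing
7-day window (50 ms bins, gaps within 5 s typing sessions, non-game taps),
messages sent (both channels pooled), and screen time (matched
screen-on/screen-off sessions intersected with the local day). A sleep
segment belongs to the local date of its **end** — the wake-up date — which
is the wearable vendor's reporting convention. Days run at a single fixed
UTC offset (+8 by default); no daylight-saving transitions are modelled.

**Zero versus missing.** Phone count features are `0` on a day the phone
reported (ambient-light stream present) and `NA` on a day it did not;
without that distinction non-compliance would masquerade as social
withdrawal. Wearable features go missing mechanically (no segments, no
samples, no step record).

**Weekly markers.** The window is the 7 days strictly after baseline. Every
measure except the intertap mode takes the mean of its non-null daily values
and requires at least 4 of them (`weekly_marker()`). The intertap mode is
already a trailing 7-day statistic, so the marker takes its **last valid**
value; we guard it with a minimum of one valid window statistic rather than
the 4-day rule, and expose `intertap_min_valid` to re-impose the stricter
behaviour. This was a genuinely open corner of the aggregation contract;
both behaviours are tested.

**Standardization.** `log(1+x)` is applied to distance travelled and
messages sent (both strongly right-skewed) before z-scoring. Every marker
and clinical column is standardized across the population with the sample
SD (ddof = 1), complete-case per column. SOFAS enters as
`100 - rating` and the BACS composite negated, so higher is always worse.
Age is standardized too, which puts "mean age" at exactly zero in the
design — the reported digital coefficient is then directly the effect at
mean age for own-phone participants.

**Completeness.** The wearable collection rate is the fraction of the 168
hour-long windows after the first post-baseline local midnight containing at
least one heart-rate sample; the phone rate uses the ambient-light stream.
One sample saturates a window. Study-phone vs own-phone rates are compared
with a Mann–Whitney U test: midranks for ties, the exact tie-free null
distribution when `n1*n2 <= 400`, otherwise a normal approximation with
tie-corrected variance and 0.5 continuity correction.

**Association screen.** For each of the 12 × 15 (marker, clinical) pairs an
OLS regression of the standardized clinical measure on the standardized
marker is fitted without an intercept, with standardized age and a
marker-by-age interaction; phone-derived markers additionally carry an
unstandardized study-phone indicator (own = 0) and its interaction.
Interaction columns are products of the standardized mains and are not
re-standardized, preserving the interpretation of the marker coefficient at
age = 0. Inference uses `t` with `n - p` degrees of freedom (no intercept,
so no intercept correction). p-values are reported raw: the screen is
exploratory and deliberately applies no multiple-testing correction.
Whether the original analysis entered age raw or standardized cannot be
determined from reported coefficients alone; we standardize (the cleaner
interpretation) and the choice only rescales the age terms, not the marker
coefficient.

## The synthetic cohort: what it states, and what it does not

`cohort_config()` defaults *are* the stated world: 99 participants, 7
post-baseline days, hourly wearable presence 0.91, phone presence 0.91
(study phones, 39/99 of the cohort) and 0.77 (own phones) — the mixture,
0.825, reproduces the published 82% overall phone rate — nightly asleep
time 8.76 (SD 2.13) h, main-segment efficiency 0.93 (SD 0.03), sleeping
heart rate 69.94 (SD 10.06) bpm, daily steps 9186.91 (SD 5413.21), screen
time 4.74 (SD 3.64) h/day, messages 38.02/day, modal intertap 596 ms, age
29.88 (SD 6.72), and the published clinical-scale moments truncated to
instrument ranges.

Choices the calibration source does not determine, made once:

* **Between/within split.** Each daily quantity's variance is split 80/20
  between stable participant differences and day-to-day noise
  (`between_var_frac = 0.8`). Weekly averaging then shrinks marker SDs only
  mildly, keeping them near the published visit-level SDs.
* **Distribution families.** Gaussian for sleep, heart rate, efficiency
  (truncated to [0, 1]); zero-truncated Gaussian for steps and screen time;
  lognormal for daily distance; a lognormal-Poisson mixture for messages;
  lognormal intertap intervals. Distance and messages were noted as
  particularly skewed, which motivates the multiplicative families; the
  rest are unstated and Gaussian is the neutral choice.
* **Mean-matched truncation.** Truncating `N(9186.91, 5413.21)` at zero
  inflates the realized mean by roughly 12%. Because the configuration
  states the moments *of the generated data*, the generator solves for the
  latent location of the truncated normal whose post-truncation mean equals
  the configured mean (`rtnorm_target()`). The configured SD applies at the
  latent level, so realized SDs of truncated quantities sit slightly below
  their configured values; the calibration tests assert SD recovery only
  for non-truncated quantities.
* **Hypnogram structure.** Per night, stage proportions are drawn from a
  Dirichlet centred on the configured fractions (concentration 60), and the
  time in bed is tiled exactly: half the wake time at sleep onset, half at
  final waking, the asleep time as four light/deep/REM cycles. Naps (15% of
  days) carve their asleep time out of the day's total, so daily asleep
  hours keep their configured moments. A night is recorded only if the
  wearable was worn for at least half its hour-windows.
* **Presence granularity.** Wear and phone presence are independent
  Bernoulli draws per hour-window — exactly the granularity of the
  completeness statistic. Heart rate is sampled 1/min during sleep and
  every 5 min while awake; phone streams are emitted only in phone-present
  hours/days.
* **Latent coupling.** Every participant carries one standard-normal trait
  per digital measure. A planted effect `(scale -> measure, rho)` makes the
  clinical scale `rho * trait + sqrt(1 - rho^2) * noise`: the population
  correlation between the scale and the participant-level digital mean is
  `rho`, so a standardized no-intercept regression recovers `rho` directly.
  Weekly averaging attenuates this by
  `sqrt(0.8 / (0.8 + 0.2/7))` (about 0.98) — visible only below the
  recovery tolerances.

**What a green test does not establish.** The generator's streams are
schematic: GPS paths are straight lines at constant speed (so the haversine
sum recovers the planted distance exactly — real trajectories would not),
tapping sessions are homogeneous lognormal bursts, message timing is
uniform within present hours, and compliance is independent across hours
rather than bursty. Passing the calibration suite shows the *pipeline* is
correct and unbiased under the stated world; it says nothing about
classifier quality of the upstream devices, nor about real-world
missingness mechanisms, which are surely not missing-completely-at-random.

## Numerical choices and degenerate inputs

* Stage tilings are exact by construction (cumulative boundaries); the
  tests assert closure to 1 ms.
* Intertap gaps are rounded to 1 µs before binning: epoch-scale double
  timestamps resolve to ~0.4 µs, and an exact-millisecond gap must not
  straddle a bin edge. Ties between modal bins go to the lowest bin.
* The truncated-normal sampler works through the inverse CDF with the
  Mills ratio evaluated on the log scale, and snaps the rare
  probability-clamped draw back to the support.
* OLS is solved by QR; the test oracle re-solves every design by explicit
  normal equations. Rank-deficient designs raise an error naming the
  collinear columns; designs with fewer than `p + 2` complete rows return a
  soft `insufficient` result so one empty marker cannot sink the screen.
* A pooled sample with all values identical short-circuits the U test to
  `p = 1`.
* Unterminated screen sessions are capped at 4 h; a second `screen_on`
  restarts the session and caps the first at the restart.
* Clinical scores are truncated (clamped) to instrument ranges after the
  Gaussian draw; with the published moments the clamping is rare enough not
  to disturb planted couplings measurably.

## Known limitations

* The stage-level sleep means published alongside the total are mutually
  inconsistent (the rows have different denominators); the generator's
  stage fractions are normalized from the stage rows, so stage-hour means
  are internally consistent but do not reproduce every published stage row
  simultaneously.
* Completeness SDs are interpreted as across-participant; hourly presence
  with a common probability cannot reproduce an across-participant SD of
  22% — that would require participant-level compliance heterogeneity,
  which the presence model deliberately keeps simple (means, not SDs, are
  the recovery targets).
* Single time zone, no travel across zones, no daylight saving.
* No longitudinal structure beyond the one analysed week.
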