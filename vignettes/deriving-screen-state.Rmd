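---
title: "Deriving objective smartphone screen-state from ON/OFF event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving objective smartphone screen-state from ON/OFF event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Smartphone screen time is usually measured by asking people how long they
spend on their phones. Self-report is cheap but biased: recall over a
"typical day" compresses dozens of short pickups into a guess. Modern
sensing apps offer an alternative — the operating system emits an event
every time the screen turns ON or OFF, and the sum of ON→OFF intervals is
an objective measure of screen exposure, here called *screen-state* to
distinguish it from self-reported *screen time*.

The raw event stream is not usable as-is. Three error modes dominate:

* **auto-notification blips** — the screen lights up for a few seconds
  because a notification arrived, with no one looking at it;
* **stuck-screen artifacts** — a device error leaves the screen ON for
  hours, inflating a day by an implausible amount;
* **day-scale outliers** — days whose recorded total is so large (over
  10 h) that it is unclear whether they are heavy use or accumulated
  error.

None of these has a single correct threshold, so the package implements a
*sensitivity grid* rather than one cleaning rule, and reports how the
objective-vs-subjective comparison behaves across the whole grid.

## The pipeline

`sessionize()` pairs events per participant in time order: an ON opens a
session, the next OFF closes it. Real streams are imperfect, so the
pairing policy is explicit: a second ON while a session is open is
ignored (`keep_first`), an OFF with no open session is dropped, and an ON
never closed before the stream ends is dropped rather than imputed —
closing it at stream end would fabricate duration, and the logged drop
lets coverage checks flag the gap instead. At equal instants OFF sorts
before ON, so a re-opening transition never swallows the close that
precedes it. All drops are counted and attached to the result.

Filters operate on whole sessions, in a fixed order:

1. **notification cut-point** `c` ∈ {0, 5, 10, 15, 20} s: retain sessions
   with duration strictly greater than `c`. A session lasting exactly the
   cut-point is treated as a notification; cut-point 0 ("no filter")
   therefore still removes zero-duration blips.
2. **continuous-usage cap** `K` ∈ {6, 5, 4, 3, 2, 1} h or none
   (no-threshold): remove sessions longer than `K` entirely. Removal —
   rather than truncation to `K`, or exclusion of the whole participant —
   treats the offending session as invalid device data while keeping the
   participant's other records; it also lets the per-cell sample size
   drop naturally when a tighter cap empties someone's days, which is the
   behaviour visible in the published sensitivity tables. Whether the
   original analysis truncated instead cannot be determined, so numeric
   agreement with the original cohort is not claimed.
3. **day-boundary split**: sessions are cut at local midnight *after* the
   cap is applied, because midnight does not interrupt actual continuous
   use; fragments sum exactly to the parent duration.
4. **daily rule**: either keep all participant-days or exclude those with
   more than 600 min (a day of exactly 10 h is kept).

Both session-level filters are pure per-session predicates, so they
commute; the order above matters only for interpretability.

`daily_totals()` produces one record per participant per local calendar
day *with at least one retained session*. Days without data are absent,
never zero-filled: a silent day is indistinguishable from an unobserved
one, and zero-filling would bias participant means downward. A
consequence, documented and tested, is that inclusion (below) can depend
on the grid cell.

**Inclusion criteria**: a participant enters a comparison with
screen-state data on at least 2 weekdays and at least 1 weekend day, and
without an "app off" gap — operationalized as any gap between consecutive
events longer than 24 h (configurable), since the design criterion
("did not turn off the app") names no detection rule. Weekday means
Monday–Friday in the participant's configured timezone; weekend is
Saturday–Sunday.

## The comparison layer

Subjective smartphone screen time is scored from an adapted 14-item
sedentary behaviour questionnaire as the sum of the smartphone-specific
items — by default Q3 (internet/general work on a smartphone), Q5
(smartphone/handheld gaming), Q6 (texting) and Q9 (smartphone e-reading).
Talking on the phone (Q11) is excluded because a call does not require
the screen to be on; the set is fully configurable because the original
item subset was never enumerated. A respondent with every item of the set
missing contributes no subjective value and drops out of the pair.

Per grid cell, paired participants are compared with:

* **Wilcoxon signed rank** (primary test; zero differences removed, mid
  ranks for ties). The p-value is exact — equivalent to enumerating all
  2^m sign assignments — when at most 25 tie-free nonzero differences
  remain, exact by direct enumeration up to m = 16 when magnitudes tie,
  and a tie- and continuity-corrected normal approximation otherwise.
* **paired t**, reported alongside because the published table footnotes
  flag significance from paired t-tests while the analysis text names
  Wilcoxon; both are reported and neither is silently preferred.
* **Spearman's rank correlation** (Pearson on mid-ranks, asymptotic t
  p-value) with Pearson's r alongside.

All tests are two-sided at α = 0.05. The discrepancy is recorded as
objective − subjective, so a positive value means under-reporting.
"Borderline" flags cover 0.05 ≤ p < 0.10 — the published tables use a
borderline marker without defining it, and this band is the conventional
reading. No multiple-testing correction is applied across the 70 cells
per day type, matching the original presentation; `p.adjust`-style
correction is deliberately left to the caller.

## The synthetic cohort generator

Because the motivating study deposited no data, `simulate_cohort()`
provides a cohort with known ground truth. Its defaults are fixed study
conditions, not tuning knobs:

* 54 participants (the original final sample) observed for 8 consecutive
  days from Wednesday 2017-04-05 — inside the original spring pilot
  window, giving 6 weekdays and 2 weekend days — in `America/Regina`
  (the study region; a DST-free zone, so every local day is 24 h);
* ~40 true usage sessions per participant-day (Poisson), with lognormal
  durations (meanlog = log 2.5 min, sdlog = 1): right-skewed, median
  2.5 min, mean ≈ 4.1 min, ≈ 165 min/day of true screen-state — the
  scale of the published weekday means;
* ~30 notification blips/day, uniform 1–15 s, below the largest
  notification cut-point;
* a stuck-screen artifact on 2% of participant-days, uniform 3–12 h;
* self-reports equal to 0.8 × the participant's true mean daily usage
  (under-reporting, the direction of the original finding) plus Gaussian
  recall noise (SD 20 min), floored at zero, generated separately for
  weekdays and weekends and spread at random over the smartphone items.

Sessions are placed uniformly at random without overlap by rejection
sampling (longest interval first, so multi-hour artifacts find room);
evening sessions may cross midnight, which exercises the day splitter,
but nothing extends past the final study day — the recording window is
finite. The generator is fully deterministic given its seed and restores
the caller's RNG state.

What the simulator does *not* emulate: circadian structure (sessions are
uniform over the 24 h day), app-level content, duplicate or missing
events (streams are clean ON/OFF pairs; dirty-stream handling is tested
with separately constructed streams), and between-participant variance in
usage rates. Passing recovery tests therefore demonstrates correctness of
the *derivation machinery*, not behavioural realism.

## Numerical and degenerate-input choices

* Durations are carried in seconds as doubles; daily totals are exact
  sums of fragment seconds divided by 60. Conservation is asserted to
  1e-9 s in tests (sub-microsecond; POSIXct arithmetic is the limit).
* Timestamps are stored in UTC and written with microsecond precision;
  calendar attribution uses the configured Olson zone. Local dates are
  resolved per 15-minute UTC bin (every real offset and transition falls
  on a 15-minute boundary), which keeps day attribution exact across DST
  transitions at a fraction of the per-timestamp cost.
* A session ending exactly at local midnight belongs wholly to the
  earlier day; zero-duration sessions are retained by the sessionizer
  and removed by every notification cut-point.
* Degenerate comparisons never kill a grid: all-zero differences yield a
  degenerate Wilcoxon (no p-value, flagged `ns`), zero-variance paired t
  and constant-vector correlations are reported as `NA` in a cell, while
  the standalone functions raise errors as their contracts state.
* Empty cells (no surviving pairs) report `n = 0` with `NA` statistics.

## Problem sizes

The test suite validates oracle equivalence on 100 random instances of up
to ~400 events, full-grid brute-force agreement on three 3-participant
cohorts, and power/size of the weekday Wilcoxon cell on 200 simulated
50-participant cohorts per arm; the acceptance script uses one
54-participant cohort for the grid and 100 replicates per power arm.
These sizes give Monte-Carlo error well inside the asserted bands while
keeping a full run in minutes on one core.

## Known limitations

* Inclusion counts are computed after filtering (per cell); a pre-filter
  convention would give different per-cell n. The original convention is
  not stated.
* The app-off rule is a heuristic; a 23 h silent gap passes it.
* Weekend questionnaire items are accepted as given; the original
  instrument printed only weekday wording, and no weekend phrasing is
  invented here.
* Timezone handling assumes one zone per cohort; travelling participants
  are out of scope.
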