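---
title: "Survey power analysis from automated acoustic monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey power analysis from automated acoustic monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveypower)
```

## The problem

Short nighttime listening surveys are the standard tool for concluding
presence or absence of chorusing anurans at a site, and for endangered
species that conclusion carries regulatory weight: an absence call made
with too little effort risks "take" of an undetected population. The
adequacy of any survey prescription depends on the per-survey detection
probability $p$, which in turn depends on when surveys are allowed to
happen — the months, the hours, and the weather conditions a protocol
demands.

Continuous recordings from automated recording devices (ARDs) make $p$
measurable. If a recorder ran all season, every 5-minute interval is a
potential human survey whose outcome is known. `surveypower` resamples
simulated surveys from such interval data under alternative scheduling
rules, estimates $p$ as a function of survey duration, converts it to the
minimum number of surveys for a stated confidence in absence, and searches
for the environmental conditions that make surveys most efficient.

## From recordings to intervals

The unit of analysis is the 5-minute interval with a binary detection
flag. Verified detection events (site, start time, duration) are binned by
`bin_events_to_intervals()` under these conventions:

- **Clock-aligned, half-open bins.** Bins start at hh:00, hh:05, … and
  cover `[start, start + 5 min)`, so they are identical across sites and
  days. An event overlapping a bin boundary marks *both* bins — a listener
  present in either window would have heard the call — and an event
  crossing midnight contributes to both calendar dates.
- **Minimum event duration.** Events with duration ≤ `min_event_s`
  (default 3 s, strict) are discarded entirely before binning; in
  classifier output, very short detections are dominated by false
  positives.
- **Explicit coverage.** The caller enumerates every (site, date, bin) the
  recorder actually ran (`recording_coverage()`). Only covered bins are
  emitted, so recorder downtime never masquerades as silence. Events
  falling wholly outside coverage are dropped with a warning and counted.
- **Calendar-date attribution.** An interval belongs to the date
  containing its bin start; a night therefore spans two dates. This
  matches how date-based eligibility rules are applied in practice, where
  the decision to survey is made per calendar date.

## Environmental features and date eligibility

Hourly station weather (temperature °C, relative humidity %, wind km/h,
barometric pressure in the station's native unit, hourly precipitation mm)
is read by `read_hourly_environment()`; missing hours are gaps, not
zeros. Pressure is carried opaquely in whatever unit the station reports —
every pressure threshold downstream is expressed in that same unit, so no
conversion is ever applied.

`derive_env_features()` adds two change features:

- `pressure_change_24h(t)` = pressure(t) − pressure(t − 24 h), defined
  when the observation exactly 24 h earlier exists;
- `cum_precip_24h(t)` = total precipitation over the *previous* 24 hours,
  the window $[t-24\mathrm{h}, t)$. The current hour's own rainfall is not
  part of "the previous 24 h", so the cumulative value can be smaller than
  the concurrent hourly value. The feature additionally requires at least
  18 of the 24 hourly slots (75%) to be observed; with fewer it is
  missing, and a threshold on a missing value evaluates false. This guards
  against gappy station records producing spurious dry signals.

Surveys are scheduled in advance from forecasts, so eligibility is
deliberately coarse: a calendar date is surveyable when its rules are met
*at any point within the date* (`eligible_dates()`). By default all rules
must hold at the same hourly observation — that is the condition a
surveyor would actually experience — but `simultaneous = FALSE` offers the
looser reading in which each rule is met at some, possibly different,
hour. Moon illumination is constant within a date and its protocol
threshold (< 0.5) is a *fraction* of full illumination; reading it as
0.5 % would leave almost no night surveyable, which is plainly not the
protocol's intent.

Three scenarios ship as presets: `scenario_random()` (peak season and
night window only: February–April, bins starting at/after 18:00 or before
06:00), `scenario_usfws()` (the federal protocol conditions: temperature
> 14 °C, relative humidity > 70 %, wind < 24 km/h, moon < 0.5), and
`scenario_optimized()` (temperature > 16 °C, positive 24-h precipitation,
24-h pressure fall below −0.07 — the combination the threshold search
identifies as maximising survey success on the motivating dataset).

`summarize_detection_conditions()` reports the six-number summary of each
weather variable over all hourly observations on detection-positive dates
(moon in percent, one value per date). Full-day rather than night-only
records are summarised: conditions like a sub-zero daily minimum on an
otherwise active date are part of what a scheduler sees. All quantiles in
the package use linear interpolation between order statistics (R type 7),
configurable globally via `options(surveypower.quantile_type = )`.

## The survey simulator

`simulate_surveys(pool, k)` estimates the detection probability of a
survey lasting $k$ 5-minute bins:

1. A valid survey position is $k$ *consecutive* bins at one site within
   one date, with no recording gap (`enumerate_survey_starts()`). A human
   surveyor stays at one listening post for the duration, so longer
   surveys are contiguous windows rather than $k$ independent spot checks;
   the alternative mechanism is available as `contiguous = FALSE` for
   comparison.
2. Within a permutation, **one** position is drawn uniformly per date —
   no date contributes two surveys, reflecting how real surveys are
   scheduled. Where both sites have positions on a date the draw is over
   their union, i.e. a site is chosen with probability proportional to its
   number of positions, consistent with pooling detection data across
   sites.
3. The permutation's estimate is the fraction of dates whose survey
   window contained a detection; every estimate is therefore a multiple of
   $1/D$ for $D$ surveyed dates. Repeating 1,000 times under a seeded
   generator gives the distribution summarised by its mean and 2.5/97.5 %
   quantiles.

Dates that cannot host a $k$-bin survey (short or fragmented coverage)
are dropped from that duration's simulation with a warning rather than
padded. The closed-form expectation of the same draw — the mean over dates
of the fraction of positive positions — is exposed as `analytic_mean()`
and serves as the simulator's independent oracle in the test suite: the
permutation mean must agree with it within Monte-Carlo error, and it must
be non-decreasing in $k$, since enlarging a window can only add positive
bins.

## Minimum survey effort

If each survey independently detects a present population with probability
$p$, then $N$ surveys all fail with probability $(1-p)^N$, and

$$N_{\min} = \left\lceil \frac{\log(1-C)}{\log(1-p)} \right\rceil$$

is the minimum number of surveys for confidence $C$ (default 0.95) in
absence. The ceiling implements the "at least $N$ surveys" semantics: the
returned integer is the smallest with $(1-p)^N \le 1-C$. `effort_table()`
evaluates the simulator over a scenario × duration grid and maps the mean
and both quantiles of $p$ through `min_surveys()` — the effort bound
`n_high` pairs with the *lower* probability quantile. Because the bounds
are computed from rounded quantiles of $p$, an effort bound can differ by
±1 survey from a value computed from the unrounded probability; the
package always reports the ceiling of whatever probability it actually
estimated. A degenerate quantile of exactly 0 (possible on very sparse
pools) yields `NA` with a warning rather than an error, since absence can
never be confirmed at $p = 0$.

## The environmental threshold search

`grid_search()` asks which scheduling thresholds make the surveyable pool
richest in detections. Candidates per variable are its unique observed
values (optionally decimated to evenly spaced quantile points via
`resolution`), each in both directions; every combination of one rule per
variable is evaluated by the same eligibility machinery as the scenarios,
and ranked by the detection:non-detection ratio of the resulting pool.
The objective maximises the *density* of detections among surveyable
intervals, subject to a floor `min_dates` on how many dates remain — the
guard prevents degenerate optima that leave a handful of perfect nights.
Ties are broken by larger positive count, then more dates, then the
canonical rule text, making the ranking a deterministic total order
(verified against exhaustive enumeration in the tests).

Two caveats are inherent to the design and flagged here deliberately: the
search is evaluated on the same data it was fit to (no train/test split),
so its advantage is optimistic for future seasons; and conditions meeting
aggressive thresholds can be rare in a given year, which may leave too few
surveyable dates to reach $N_{\min}$ at all. The synthetic module supports
out-of-sample evaluation (search on one simulated campaign, evaluate on
another seed) for exactly this reason.

## The synthetic study system

`generate_dataset()` produces inputs with the statistical structure the
analysis assumes: two sites recorded continuously January–July for four
years (2015–2018 by default), with per-site-per-day recorder failure
(probability 0.25). The weather model combines:

- temperature: seasonal sinusoid (annual mean 19.5 °C, half-range
  9.5 °C, coldest mid-January) + diel sinusoid (half-range 4 °C, warmest
  15:00) + AR(1) noise ($\phi = 0.98$, innovation SD 0.35 °C);
- precipitation: each day carries a rain event with probability 0.15,
  with gamma-distributed totals (shape 0.8, scale 10 mm) spread over a few
  consecutive hours — sparse, right-skewed, like convective rain;
- pressure: a mean-reverting random walk (mean 29.5, reversion 0.02,
  step SD 0.02) on the inches-of-mercury scale typical of US station
  feeds, giving 24-h swings of roughly ±0.1–0.3;
- humidity: diel cycle (most humid pre-dawn) plus a boost after recent
  rain; wind: gamma-distributed hourly speeds (mean ≈ 7 km/h);
- moon: a deterministic 29.53-day illumination cycle.

Chorus activity is generated per site-night: initiation follows a logistic
model in the night's temperature, 24-h cumulative precipitation and 24-h
pressure change (evaluated at 21:00), with coefficients
$\beta_0 = -3.5$, $\beta_T = 0.3$/°C, $\beta_P = 0.2$/mm,
$\beta_{\Delta B} = -8$ per pressure unit, minus a quadratic seasonal
availability penalty centred on day-of-year 75 (scale 20 days) that
encodes breeding phenology beyond weather. An initiated night produces
1–3 contiguous bouts (expected extra bouts 2 × 0.7) of geometric length
(mean 60 bins) with per-bin detection probability 0.85 inside a bout.
Bouts being *contiguous runs* matters: it is what makes longer surveys
genuinely more powerful within a night, rather than just more draws from
independent noise.

These defaults were calibrated by simulation so that, in expectation,
roughly 4 % of recorded bins are detection-positive, positives fall on
about 30 % of dates, and ≥ 95 % of positives occur February–April —
the gross structure of a multi-year campaign for a spring-breeding toad.
What the generator does *not* emulate: spatial correlation between sites
beyond shared weather, observer effects (the simulated surveyor hears
exactly what the recorder heard), classifier errors surviving manual
review, within-season population turnover, and multi-year trend. Passing
tests on synthetic data therefore demonstrate the pipeline's statistical
correctness under known structure, not field realism of any particular
number.

## Numerical and testing choices

- Determinism: every stochastic entry point takes a seed; the pipeline
  splits one root seed across stages, and reruns of `run_pipeline()` with
  the same config are byte-identical.
- The test suite runs the simulator oracle checks at 1,000 permutations
  and the planted-signal recovery at five seeds of a two-year, two-site
  synthetic campaign with 300-permutation effort grids and a
  quantile-decimated (resolution 4) threshold search — sizes chosen to
  keep the full suite at a couple of minutes while leaving Monte-Carlo
  margins wide.
- Degenerate inputs are first-class: empty pools error, dates unable to
  host a survey are dropped and counted, empty rule sets mean "every
  covered date", perfect threshold separation yields an infinite ratio
  flag, and an all-zero pool cannot produce an effort figure (absence
  unconfirmable).

## Limitations

The simulation treats human and recorder detection as exchangeable within
an interval; if surveyors disturb chorusing animals, field detection
probabilities will be lower. Interval data from a high-abundance site
yield optimistic $p$ for marginal populations, so effort numbers derived
from rich sites should be read as lower bounds. Finally, the threshold
search's in-sample bias (above) means its scenario should be re-validated
on independent seasons before being adopted as protocol.
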