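---
title: "Methods: processing rules, the geometric-mean-ratio model, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: processing rules, the geometric-mean-ratio model, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigortrend)
```

## Scope

`vigortrend` estimates how vigorous-intensity physical activity (VPA) changes
with age in youth cohorts measured with count-based accelerometers, and
compares it with moderate-intensity activity (MPA). It covers four stages:
a synthetic cohort generator, epoch-level processing, log-linear
geometric-mean-ratio regression with interactions and sensitivity analyses,
and extrapolation/reporting. It does **not** model raw acceleration, bouts
of MVPA, maturation or seasonality, and it fits cross-sectional models only
(first measurement per participant).

## Processing rules

All processing operates on 60-s epochs; shorter epochs are summed into
60-s blocks first (`reintegrate()`), dropping a trailing partial block with
a warning because an incomplete minute would bias counts-per-minute.

**Non-wear.** A non-wear bout is ≥ 60 min of zero-count epochs, allowing at
most 2 nonzero interruption epochs. The rule as published leaves several
details open; the package fixes them as follows:

* an interruption is a *single isolated* epoch — two consecutive nonzero
  epochs always terminate a bout;
* interruptions are counted *cumulatively* within a bout (not only when
  consecutive), and a third one terminates the bout;
* bouts start and end on zero epochs (an interruption cannot be terminal);
* scanning is greedy left-to-right; bout length includes absorbed
  interruption epochs;
* interruption magnitude is uncapped by default. Some count-threshold
  implementations cap it (e.g. at 100 cpm); this is exposed as
  `processing_params(interrupt_max_cpm = )`, default off, because the rule
  this package follows states no cap.

One consequence worth knowing: under greedy scanning with a cumulative
interruption budget, *adding* activity counts can occasionally **increase**
total detected non-wear, because an extra interruption early in the series
can re-segment the bouts so that a later zero run, previously stranded
below 60 min, joins a qualifying bout. The test suite pins a concrete
example (150 min becoming 209 min after one added count). Monotonicity does
hold for the interruption-free rule, and is tested there.

**Day and person summaries.** Only epochs with clock time in [07:00, 24:00)
count; wear time is window time outside detected bouts; intensity minutes
use the Evenson cut-points (sedentary < 100, light [100, 2296), moderate
[2296, 4012), vigorous ≥ 4012 cpm, all boundaries inclusive on the left).
Sedentary + light + moderate + vigorous always partitions wear time. A day
is valid at ≥ 500 wear min (inclusive); a person is included at ≥ 1 valid
day (inclusive); person outcomes are unweighted means over valid days.
Multi-day traces are split at midnight, so a bout spanning midnight must
qualify within each day separately — immaterial in practice because the
wear window excludes 00:00–07:00.

## The model

Person-level mean daily VPA is winsorized at the sample 99th percentile
(quantile type 7, i.e. linear interpolation of order statistics — the choice
is configurable but matters little at n in the thousands), then
log-transformed with an additive offset:

\[ \log(\mathrm{VPA}_i + c) = \alpha + \beta\,\mathrm{age}_i +
   \gamma\,\mathrm{wear}_i + \sum_s \delta_s\,\mathrm{study}_{is} +
   \varepsilon_i \]

`exp(β)` is the per-year ratio of geometric means; `(exp(β) − 1) × 100` the
percent change per year of age. Confidence intervals and p-values use the
normal approximation (the method targets samples of tens of thousands; no
clustering or robust correction is applied because the emulated analysis
used none). The VPA model is optionally further adjusted for log MPA to ask
whether the vigorous decline is independent of the moderate one.

**Zero offset `c`.** The emulated analysis does not state its handling of
zero VPA means. The default is `c = 0.5` min (half of one epoch's
resolution), configurable, and `log_transform()` refuses zeros when
`c = 0`. The offset is a device for admitting zeros, not a free parameter:
when the data contain no zeros it should be 0, because a positive offset
applied to a zero-free sample introduces a Jensen-type slope bias of order
`c · |β| · E[1/λ]` (≈ 0.005 on the ratio at these parameter values, which is
~2 standard errors at n = 2000 and would invalidate CI coverage while
saying nothing about the estimator). This is why the parameter-recovery and
self-consistency tests run with `zero_offset = 0` (their generative world
produces no zero person-means) while pipeline defaults keep 0.5.

**Interactions.** `test_interaction()` adds age-by-level terms for one
moderator (reference levels: male, white, high school, normal weight, UK),
reports a Wald p per non-reference level and a joint Wald test, and refits
within levels when significant at 0.05. Both per-level and joint tests are
reported because the emulated tables are ambiguous about which was used for
multi-level moderators. When studies are nested in regions the region main
effects are aliased with study indicators; `lm()` drops the aliased columns
and the interaction terms remain estimable.

**Linearity check.** `age_band_check()` swaps linear age for 2-year band
indicators ([5,7), …, [15,17), [17,18]); under log-linearity adjacent
full-width band coefficients differ by ≈ 2β (1.5β for the terminal 1-year
band, via band centres).

**Sensitivity.** `leave_one_study_out()` refits per omitted study and flags
sign changes of β — the diagnostic that exposed a single study driving a
positive regional trend in the emulated analysis.

## Extrapolation and reporting

`extrapolate(ratio, mean, years = 13)` computes
`ratio^13 × mean − mean`, the implied absolute change from the 5.0–5.9 y
baseline band (half-open [5.0, 6.0)) to age 18; `predict_at_age()` gives the
end value. Reports round ratios to 3 dp, percents to 1 dp, changes to 2 dp;
unrounded values are always retained. When reproducing published tables the
printed 3-dp ratio is used (`reproduce_published_tables()`); in pipeline
mode the unrounded fitted ratio is used. Two published rounding quirks are
handled explicitly rather than papered over: the headline "7.9 min
decrease" arises as baseline − (predicted value rounded to 1 dp), since the
unrounded change (−7.85) rounds to 7.8 at 1 dp (`narrative_prediction()`
implements exactly that); and one stratified row (Australia) prints a
change computed from an unrounded ratio, so its 3-dp reproduction is off by
one 2-dp step and is flagged, not forced.

## The synthetic cohort

The generator's defaults state one fixed world, patterned on the pooled
consortium sample the methods emulate, and are not tuned per test:

| parameter | default | basis |
|---|---|---|
| ages | uniform on [5, 18] | design range |
| baseline VPA / MPA at age 5 | 12.97 / 41.32 min/day | published baseline means |
| per-year ratios VPA / MPA | 0.931 / 0.940 | published pooled ratios |
| person noise (log SD) | 0.5 | gives right-skewed min/day distributions with median/IQR of realistic magnitude |
| day jitter | Poisson on class minutes | mean-preserving, integer, overdispersion-free stand-in |
| days per person | 7 | one monitoring week |
| wear time | Normal(770, 88.6), truncated [500, 960] | published wear mean (SD) |
| sedentary | 349 min/day | published sedentary mean |
| study/region mix | 7 studies over 5 regions, shares ≈ 0.41/0.18/0.29/0.02/0.10 | published regional shares |
| subgroup mixes | sex 44.7/55.3; ethnicity 52.3/20.4/20.6/6.7; maternal education 52.6/16.6/30.8; weight 89.8/10.2 | published descriptives |

Expected daily VPA for person *i* of age *a* is
`B · r^(a−5) · exp(z_i)`, `z_i ~ N(0, 0.5²)` shared between VPA and MPA;
day minutes are Poisson around that expectation (or deterministically
rounded in `day_jitter = "none"` mode, used by the exact self-consistency
checks). Baselines and ratios may instead be supplied per level of one
moderator (`ratio_moderator = "sex"` etc.) to plant interaction effects.

Trace rendering places the requested class minutes at random positions in a
wear block anchored at 07:00, with counts drawn uniformly within each
cut-point band (vigorous capped at 8000 cpm) — band membership, not count
magnitude, drives everything downstream. Zeros are reserved for non-wear;
sedentary wear epochs draw from [1, 100). Anchoring the wear block at 07:00
with length ≤ 960 min guarantees the trailing zero run to midnight is ≥ 60
min, so scheduled wear is *exactly* recoverable by the non-wear rule — a
deliberate construction that makes round-trip tests sharp.

**What a green test does not establish.** The generator produces no device
noise, no triaxial signal, no within-day activity autocorrelation, no
weekday/weekend structure, no missing covariates, and its day-to-day
variability model (Poisson) is a stand-in chosen for mean-preservation, not
an inference about real children. Green recovery tests certify the
estimator and the processing arithmetic, not the realism of any particular
variance structure. The published ratios themselves were fitted on ~24k
real participants and are not reproducible from synthetic data; they enter
only as generative inputs and as printed arithmetic inputs.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere (winsorization, IQR displays).
* CIs: normal quantiles, not t (n is large in the intended use).
* `summarize_person()` returns `NULL` for excluded participants — exclusion
  is a state, not an error; `build_analysis_dataset()` logs counts at every
  filter and reports summaries lacking metadata instead of dropping them.
* Empty inputs: empty cohorts, empty bout specs and empty series are legal
  and return empty results; an empty baseline band, a single-level
  moderator, a single study, or a single distinct age are errors.
* Determinism: one integer seed fixes a cohort byte-for-byte; all
  acceptance simulations derive their seeds from fixed offsets.

## Known limitations

* Non-wear bouts cannot span midnight (split at day boundaries).
* The greedy bout scan is the only supported segmentation; an optimal
  (maximum-coverage) segmentation would differ on contrived series.
* 60-s epochs understate vigorous activity relative to shorter epochs in
  real data; the generator does not emulate that distortion.
* The winsorization threshold is recomputed per analysis sample, so
  stratified fits inherit the full-sample cap only through their data.
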