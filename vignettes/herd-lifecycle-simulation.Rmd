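---
title: "Modelling the dairy cow life cycle in herdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dairy cow life cycle in herdsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdsim)
```

## The model

`herdsim` is a stochastic, individual-based Monte-Carlo simulator of the
dairy cow life cycle on a daily time step. Each animal is an agent carrying
its full state (age, weight, reproductive state, lactation state, culling
fate); every day each animal passes through a fixed pipeline —

1. age and body-weight update,
2. reproduction (ovulation, heat detection, insemination, pregnancy day),
3. calving and calf generation,
4. lactation and dry-off,
5. culling checks —

and every discrete life event (birth, heat, insemination, diagnosis, loss,
calving, dry-off, cull, exit) is appended to an event log from which herd
summaries are recomputed. Because future performance is uncertain, the model
propagates that uncertainty: every rate and duration is drawn from a
configured distribution, and replicated runs report a distribution of herd
outcomes rather than a single trajectory.

## Life-cycle parameters

The default configuration (`default_config()`) is the exemplar Holstein
estrus-detection/artificial-insemination protocol:

| parameter | default | units | meaning |
|---|---|---|---|
| `birth_weight` | 40.8 | kg | calf weight at birth |
| `average_daily_gain` | 0.9 | kg/d | linear growth rate (to `mature_weight_cap`) |
| `female_prob_by_semen$sexed` | 0.90 | — | P(female calf), sexed semen |
| `puberty_base_age` | 400 | d | start of the first-ovulation clock |
| `first_ovulation_delay_mean/sd` | 19 / 11 | d | lognormal delay past 400 d |
| `cycle_length_mean/sd` | 21 / 4 | d | estrus cycle length, normal |
| `heat_detection_prob` | 0.60 | — | per-estrus detection probability |
| `conception_first_service` | 0.339 | — | first-service conception rate |
| `conception_decrement_per_service` | 0.026 | — | absolute drop per extra service |
| `diagnosis_days` | 32, 91, 200 | d | scheduled pregnancy checks |
| `daily_loss_rates` | 0.0096, 0.0017 | 1/d | daily loss in each inter-diagnosis window |
| `gestation_mean/sd` | 278 / 6 | d | gestation length, normal |
| `heifer_cull_age` | 650 | d | cull for a never-pregnant open heifer |
| `cow_cull_dim` | 300 | d | cull an open cow once DIM exceeds this |

Male calves are sold at birth and never enter the herd. Six stochastic
culling reasons (lameness, injury, mastitis, other diseases, udder problems,
unknown) are evaluated once at animal creation by comparing a U(0,1) draw
with each reason's lifetime probability; an assigned fate receives its
culling age by inverse-transform sampling of an empirical culling-age CDF.

### Conventions and numerical choices

These points were genuinely open design choices; the conventions below are
the package's and are pinned by tests:

* **`N(m, s)` means mean and standard deviation**, not variance — the usual
  convention in the herd-simulation literature.
* **The first-ovulation delay is lognormal in its arithmetic moments.** The
  mean-19/SD-11 pair is moment-matched to the log scale
  (`sdlog^2 = log(1 + (11/19)^2)`, `meanlog = log(19) - sdlog^2/2`), because a
  delay distribution with arithmetic mean 19 d past a 400 d base is the only
  reading that produces biologically plausible ages at first ovulation.
  A mean-19/SD-11 reading *on the log scale* would put first ovulation at
  implausible ages (e^19 days).
* **The conception decrement is absolute**: 0.339, 0.313, 0.287, ... with a
  configurable floor (default 0), rather than a 2.6% *relative* decay.
* **Pregnancy-loss windows are half-open**: hazard 0.0096/d on gestation
  days (32, 91], 0.0017/d on (91, 200], zero before day 33 (early losses are
  considered absorbed in the conception rate) and zero after day 200.
* **A loss is latent until the next scheduled diagnosis.** The animal is
  managed as pregnant until the diagnosis reveals it open, at which point she
  re-enters a fresh full-length cycle starting the next day. She is not
  re-bred during the latent interval.
* **Heat is detectable only on the single ovulation day** of each cycle; the
  0.60 probability applies once per cycle.
* **Cull boundaries**: the heifer cull fires the day age reaches 650 d; the
  open-cow cull fires on the first day DIM exceeds 300 (i.e. at DIM 301), so
  the largest DIM attained while in the herd is exactly 300.
* **Day counts are whole days**: continuous draws are rounded to the nearest
  day with a floor of 1; cycle lengths are resampled while nonpositive and
  gestation lengths while not exceeding the last diagnosis day.
* **The calving day is DIM 1** (the first milking day).
* Within a day animals update in ascending id order; this choice only fixes
  log ordering, since animals never share random draws (below).

### Non-normative defaults

The protocol above fixes reproduction and the two rule-based culls but not
the remaining inputs, which ship as clearly labelled placeholders intended
for testing, to be overridden with herd-specific values: the culling-reason
probabilities (0.02–0.08 each), the synthetic logistic-shaped culling-age
CDF over 700–3800 d, the Wood lactation parameters by parity class, the
60 d dry period, and the 700 kg mature-weight cap.

## Reproducibility

All randomness flows through L'Ecuyer-CMRG streams (`rng_stream()`): each
replicate takes an independent stream derived from the root seed, and each
animal draws exclusively from its own substream keyed by animal id. Two
consequences are tested directly: the same (seed, config, horizon) gives
byte-identical logs, and adding animals to a herd never perturbs the
trajectories of existing animals.

## Lactation and growth

Milk yield follows either Wood's gamma-type curve
\(y(t) = a\,t^{b}e^{-ct}\) or the MilkBot model
\(M(t) = a\,(1 - e^{(c-t)/b}/2)\,e^{-dt}\) (clipped at zero), per breed and
parity class (1, 2, 3+). Both closed forms are pinned by oracle tests
(the Wood peak at `b/c`, MilkBot values against an independent
re-evaluation). Body weight is linear in age at the breed ADG up to a cap;
dry-off is scheduled `dry_period_length` days before expected calving from
the drawn gestation length.

## Least-cost ration formulation

The nutrition option formulates the classic least-cost diet LP: minimize
\(\sum_f c_f x_f\) subject to nutrient minima (and optional maxima), a
dry-matter-intake window, and per-feed inclusion/availability bounds.
Requirements are assembled linearly from a user-supplied coefficient table
(`requirements_from_production()`): feeding-system equations are
deliberately not shipped, since they are external standards, not part of
this model. The LP is solved by an in-package dense two-phase simplex with
Bland's anti-cycling rule — ration problems are small (a handful of feeds
and nutrients), so a dense exact tableau is appropriate — and every shipped
toy problem is cross-checked against brute-force vertex enumeration in the
test suite. Tests assert the optimal *cost*, which is unique, never the
diet vector, which may be degenerate.

## What the tests do and do not show

Statistical recovery tests run the generators at the study scale
(50,000–100,000 draws or pregnancies; 2-standard-error acceptance bands) and
the herd engine at small scale (single animals to a few dozen cows over
1–7 simulated years), chosen so the whole suite runs in about a minute.
Per-day pregnancy-loss rates are estimated from a vectorized cohort
simulator that applies the identical daily hazard rule as the per-animal
update; the two routes are checked against each other statistically.

Passing tests show that the simulator reproduces its *configured*
distributions and thresholds exactly or within Monte-Carlo error. They do
not show that the defaults describe any particular herd: the synthetic
culling-age CDF and lactation parameters are placeholders, and the model
omits seasonality and heat stress, health-event dynamics, voluntary waiting
periods and synchronization protocols, twinning, genetics, intake-driven
milk prediction, and economics. Those are extension points, not modelled
behavior.
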