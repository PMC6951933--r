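#' Sample age at first ovulation
#'
#' The first-ovulation clock starts at `puberty_base_age` (default 400 d);
#' the delay beyond it is lognormal with arithmetic mean
#' `first_ovulation_delay_mean` (19 d) and arithmetic SD
#' `first_ovulation_delay_sd` (11 d), moment-matched to the underlying
#' normal scale: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`. Draws are rounded to whole days and
#' floored at one day past the base age.
#'
#' @param cfg a `herd_config`.
#' @param n number of draws.
#' @param rng a `herd_stream` or NULL for the session RNG.
#' @return integer ages in days, all `>= puberty_base_age + 1`.
#' @export
sample_first_ovulation_age <- function(cfg, n = 1L, rng = NULL) {
  m <- cfg$first_ovulation_delay_mean
  s <- cfg$first_ovulation_delay_sd
  if (s <= 0) {
    delay <- rep(round(m), n)
  } else {
    sdlog2 <- log(1 + (s / m)^2)
    meanlog <- log(m) - sdlog2 / 2
    delay <- with_stream(rng, round(stats::rlnorm(n, meanlog, sqrt(sdlog2))))
  }
  as.integer(cfg$puberty_base_age + pmax(delay, 1))
}

#' Sample estrus cycle length
#'
#' Normal draw with mean `cycle_length_mean` (21 d) and SD `cycle_length_sd`
#' (4 d), resampled while nonpositive, then rounded to the nearest whole
#' day with a floor of 1.
#'
#' @inheritParams sample_first_ovulation_age
#' @return integer days, all `>= 1`.
#' @export
sample_cycle_length <- function(cfg, n = 1L, rng = NULL) {
  draw_positive_normal(cfg$cycle_length_mean, cfg$cycle_length_sd, n, rng,
                       lower = 0)
}

#' Sample gestation length
#'
#' Normal draw with mean `gestation_mean` (278 d) and SD `gestation_sd`
#' (6 d), rounded to a whole day and resampled until it exceeds the last
#' scheduled pregnancy-diagnosis day, so every pregnancy that escapes loss
#' reaches its third diagnosis before calving.
#'
#' @inheritParams sample_first_ovulation_age
#' @return integer days, all `> max(diagnosis_days)`.
#' @export
sample_gestation_length <- function(cfg, n = 1L, rng = NULL) {
  draw_positive_normal(cfg$gestation_mean, cfg$gestation_sd, n, rng,
                       lower = max(cfg$diagnosis_days))
}

# Rounded normal draw resampled until strictly greater than `lower`.
draw_positive_normal <- function(mean, sd, n, rng, lower) {
  if (sd <= 0) {
    x <- rep(round(mean), n)
    if (any(x <= lower))
      stop("degenerate draw ", round(mean), " does not exceed lower bound ", lower)
    return(as.integer(pmax(x, 1)))
  }
  with_stream(rng, {
    x <- round(stats::rnorm(n, mean, sd))
    bad <- which(x <= lower)
    while (length(bad)) {
      x[bad] <- round(stats::rnorm(length(bad), mean, sd))
      bad <- bad[x[bad] <= lower]
    }
    as.integer(pmax(x, 1))
  })
}

#' Bernoulli heat-detection draw
#'
#' Heat is detectable only on the single ovulation day of each cycle; each
#' such day is detected with probability `heat_detection_prob` (0.60).
#'
#' @inheritParams sample_first_ovulation_age
#' @return logical vector of length `n`.
#' @export
heat_detected <- function(cfg, n = 1L, rng = NULL) {
  with_stream(rng, stats::runif(n) < cfg$heat_detection_prob)
}

#' Conception probability by service number
#'
#' First service conceives with probability `conception_first_service`
#' (0.339); each later service subtracts the absolute decrement
#' `conception_decrement_per_service` (0.026), clipped below at
#' `conception_floor`: 0.339, 0.313, 0.287, ...
#'
#' @param service_number integer vector of service numbers, all `>= 1`.
#' @param cfg a `herd_config`.
#' @return numeric probabilities.
#' @export
conception_probability <- function(service_number, cfg) {
  if (any(service_number < 1))
    stop("service_number must be >= 1")
  pmax(cfg$conception_floor,
       cfg$conception_first_service -
         (service_number - 1) * cfg$conception_decrement_per_service)
}

#' Simulate conception outcomes for a vector of services
#'
#' Draws one Bernoulli outcome per entry of `service_number` at the
#' service-dependent conception probability. This is the single conception
#' mechanism of the package: [attempt_insemination()] calls it for one
#' animal, and dose-response experiments (e.g. regressing realized
#' conception frequency on service number) call it in bulk.
#'
#' @inheritParams conception_probability
#' @param rng a `herd_stream` or NULL.
#' @return logical vector: TRUE where conception occurred.
#' @export
sample_conception <- function(service_number, cfg, rng = NULL) {
  p <- conception_probability(service_number, cfg)
  with_stream(rng, stats::runif(length(p)) < p)
}

#' Attempt insemination of a cycling animal in detected heat
#'
#' Increments the service count, emits an INSEMINATION event, and with the
#' service-dependent conception probability moves the animal to `pregnant`
#' (days_pregnant 0, gestation length drawn); otherwise the animal re-enters
#' a fresh estrus cycle.
#'
#' @param state an animal state list (see [generate_calf()]).
#' @param cfg a `herd_config`.
#' @param rng a `herd_stream` or NULL.
#' @param sim_day simulation day for the event log.
#' @return list with elements `state` and `events`.
#' @export
attempt_insemination <- function(state, cfg, rng = NULL, sim_day = state$age) {
  if (identical(state$repro_state, "pregnant"))
    stop("attempt_insemination called on a pregnant animal")
  state$services <- state$services + 1L
  events <- list(event_row(sim_day, state$animal_id, "INSEMINATION",
                           age = state$age, service = state$services))
  if (sample_conception(state$services, cfg, rng)) {
    state$repro_state <- "pregnant"
    state$ever_pregnant <- TRUE
    state$days_pregnant <- 0L
    state$latent_loss <- FALSE
    state$gestation_length_drawn <- sample_gestation_length(cfg, 1L, rng)
  } else {
    state <- enter_new_cycle(state, cfg, rng)
  }
  list(state = state, events = events)
}

# Begin a fresh full-length cycle: next ovulation one cycle length from now.
enter_new_cycle <- function(state, cfg, rng) {
  state$repro_state <- "cycling"
  state$day_in_cycle <- 0L
  state$cycle_length <- sample_cycle_length(cfg, 1L, rng)
  state
}

# Daily pregnancy-loss hazard at `days_pregnant = d` (after incrementing):
# daily_loss_rates[i] inside the half-open window
# (diagnosis_days[i], diagnosis_days[i+1]]; zero before the first and after
# the last diagnosis.
loss_hazard <- function(d, cfg) {
  dd <- cfg$diagnosis_days
  h <- numeric(length(d))
  for (i in seq_along(cfg$daily_loss_rates)) {
    h[d > dd[i] & d <= dd[i + 1]] <- cfg$daily_loss_rates[i]
  }
  h
}

#' Advance a pregnant animal by one day
#'
#' Increments `days_pregnant`. In the window between the first and second
#' diagnoses (gestation days 33-91) a latent pregnancy loss occurs with
#' daily probability 0.0096, and between the second and third (92-200) with
#' 0.0017; a latent loss is revealed only at the next scheduled diagnosis
#' day (32, 91, 200), where DIAGNOSIS_OPEN and PREGNANCY_LOSS are emitted
#' and the animal resumes cycling with a fresh cycle starting the next day.
#' An intact pregnancy gets DIAGNOSIS_PREGNANT at each diagnosis day, and a
#' CALVING event when `days_pregnant` reaches the drawn gestation length
#' (parity increments, lactation starts at DIM 0, services reset).
#'
#' @inheritParams attempt_insemination
#' @return list with elements `state`, `events`, and `calved` (logical).
#' @export
daily_pregnancy_update <- function(state, cfg, rng = NULL, sim_day = state$age) {
  stopifnot(identical(state$repro_state, "pregnant"))
  state$days_pregnant <- state$days_pregnant + 1L
  d <- state$days_pregnant
  events <- list()
  calved <- FALSE

  if (!state$latent_loss) {
    h <- loss_hazard(d, cfg)
    if (h > 0 && with_stream(rng, stats::runif(1)) < h) {
      state$latent_loss <- TRUE
      state$latent_loss_day <- d
    }
  }

  di <- match(d, cfg$diagnosis_days)
  if (!is.na(di)) {
    if (state$latent_loss) {
      events <- c(events, list(
        event_row(sim_day, state$animal_id, "PREGNANCY_LOSS",
                  age = state$age, value = state$latent_loss_day),
        event_row(sim_day, state$animal_id, "DIAGNOSIS_OPEN",
                  age = state$age, diagnosis = di)))
      state$days_pregnant <- 0L
      state$latent_loss <- FALSE
      state$latent_loss_day <- NA_integer_
      state$gestation_length_drawn <- NA_integer_
      state <- enter_new_cycle(state, cfg, rng)
      return(list(state = state, events = events, calved = FALSE))
    }
    events <- c(events, list(
      event_row(sim_day, state$animal_id, "DIAGNOSIS_PREGNANT",
                age = state$age, diagnosis = di)))
  }

  if (d >= state$gestation_length_drawn) {
    calved <- TRUE
    state$parity <- state$parity + 1L
    state$life_stage <- "cow"
    state$lactating <- TRUE
    state$dim <- 0L
    state$services <- 0L
    state$days_pregnant <- 0L
    state$gestation_length_drawn <- NA_integer_
    events <- c(events, list(
      event_row(sim_day, state$animal_id, "CALVING",
                age = state$age, parity = state$parity)))
    state <- enter_new_cycle(state, cfg, rng)
  }
  list(state = state, events = events, calved = calved)
}

#' Reproductive-failure culling check
#'
#' Signals a cull when a never-pregnant heifer reaches
#' `heifer_cull_age` (650 d), or when an open cow's days in milk first
#' exceed `cow_cull_dim` (i.e. at DIM 301 under the default 300). Pregnancy
#' exempts the animal from both rules.
#'
#' @param state an animal state list.
#' @param cfg a `herd_config`.
#' @return the string "reproductive_failure" if the cull fires, else NULL.
#' @export
check_reproductive_cull <- function(state, cfg) {
  pregnant <- identical(state$repro_state, "pregnant")
  if (state$parity == 0L && !state$ever_pregnant && !pregnant &&
      state$age >= cfg$heifer_cull_age)
    return("reproductive_failure")
  if (state$parity >= 1L && !pregnant &&
      !is.na(state$dim) && state$dim > cfg$cow_cull_dim)
    return("reproductive_failure")
  NULL
}

#' Vectorized Monte-Carlo of a cohort of pregnancies
#'
#' Simulates `n` pregnancies from conception to diagnosis-revealed loss or
#' calving, applying the identical daily hazard rule as
#' [daily_pregnancy_update()] but over the whole cohort at once (one
#' Bernoulli column per at-risk gestation day). Used to estimate per-day
#' loss rates by window from large cohorts.
#'
#' @param n number of pregnancies.
#' @param cfg a `herd_config`.
#' @param rng a `herd_stream` or NULL.
#' @return a data.frame with per-pregnancy `gestation_length` and
#'   `loss_day` (NA when the pregnancy reached calving).
#' @export
simulate_pregnancy_cohort <- function(n, cfg, rng = NULL) {
  gest <- sample_gestation_length(cfg, n, rng)
  loss_day <- rep(NA_integer_, n)
  dd <- cfg$diagnosis_days
  with_stream(rng, {
    for (w in seq_along(cfg$daily_loss_rates)) {
      h <- cfg$daily_loss_rates[w]
      if (h <= 0) next
      for (d in (dd[w] + 1L):dd[w + 1L]) {
        at_risk <- which(is.na(loss_day) & gest >= d)
        if (!length(at_risk)) next
        hit <- at_risk[stats::runif(length(at_risk)) < h]
        loss_day[hit] <- d
      }
    }
  })
  data.frame(gestation_length = gest, loss_day = loss_day)
}

#' Estimate per-day pregnancy-loss rates by diagnosis window
#'
#' Tallies losses and pregnant-animal at-risk days inside each
#' inter-diagnosis window of a simulated cohort (the loss day itself counts
#' as at risk) and returns the maximum-likelihood daily rate
#' losses / at-risk-days per window.
#'
#' @param cohort output of [simulate_pregnancy_cohort()].
#' @param cfg a `herd_config`.
#' @return data.frame with columns `window`, `losses`, `at_risk_days`,
#'   `daily_rate`.
#' @export
estimate_loss_rates <- function(cohort, cfg) {
  dd <- cfg$diagnosis_days
  out <- lapply(seq_along(cfg$daily_loss_rates), function(w) {
    lo <- dd[w]; hi <- dd[w + 1L]
    # pregnancies lost in an earlier window never reach this one
    entered <- is.na(cohort$loss_day) | cohort$loss_day > lo
    last_day <- ifelse(is.na(cohort$loss_day), hi, pmin(cohort$loss_day, hi))
    days <- sum(pmax(last_day[entered] - lo, 0))
    losses <- sum(!is.na(cohort$loss_day) &
                    cohort$loss_day > lo & cohort$loss_day <= hi)
    data.frame(window = w, losses = losses, at_risk_days = days,
               daily_rate = losses / days)
  })
  do.call(rbind, out)
}
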