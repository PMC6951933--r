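test_that("first-ovulation age collapses to 419 d when the delay SD is zero", {
  cfg <- default_config()
  cfg$first_ovulation_delay_sd <- 0
  expect_equal(sample_first_ovulation_age(cfg, 10), rep(419L, 10))
})

test_that("first-ovulation delay matches the moment-matched lognormal", {
  cfg <- default_config()
  x <- sample_first_ovulation_age(cfg, 1e5, rng_stream(101))
  # closed-form oracle: arithmetic mean 19 on top of the 400 d base;
  # SE of the mean = 11 / sqrt(n), doubled, plus rounding slack
  expect_equal(mean(x), 419, tolerance = 0.2 / 419)
  expect_equal(sd(x - 400), 11, tolerance = 0.05)
  expect_true(all(x >= 401))
})

test_that("cycle length sampling recovers N(21, 4) truncated to whole positive days", {
  cfg <- default_config()
  cfg$cycle_length_sd <- 0
  expect_equal(sample_cycle_length(cfg, 5), rep(21L, 5))
  cfg <- default_config()
  x <- sample_cycle_length(cfg, 1e5, rng_stream(102))
  expect_lt(abs(mean(x) - 21), 0.05)
  expect_true(all(x >= 1))
})

test_that("gestation length sampling recovers N(278, 6) above the last diagnosis day", {
  cfg <- default_config()
  cfg$gestation_sd <- 0
  expect_equal(sample_gestation_length(cfg, 5), rep(278L, 5))
  cfg <- default_config()
  x <- sample_gestation_length(cfg, 1e5, rng_stream(103))
  expect_lt(abs(mean(x) - 278), 0.1)
  expect_true(all(x > 200))
})

test_that("heat detection is Bernoulli at the configured probability", {
  cfg <- default_config()
  cfg$heat_detection_prob <- 1
  expect_true(all(heat_detected(cfg, 100)))
  cfg$heat_detection_prob <- 0
  expect_false(any(heat_detected(cfg, 100)))
  cfg$heat_detection_prob <- 0.60
  expect_lt(abs(mean(heat_detected(cfg, 1e5, rng_stream(104))) - 0.60), 0.005)
})

test_that("conception probability declines by the absolute decrement and clips at the floor", {
  cfg <- default_config()
  expect_equal(conception_probability(1, cfg), 0.339)
  expect_equal(conception_probability(2, cfg), 0.313)
  expect_equal(conception_probability(3, cfg), 0.287)
  expect_equal(conception_probability(100, cfg), 0)
  expect_error(conception_probability(0, cfg), "service_number")
  # nonincreasing and bounded over a long service range
  p <- conception_probability(1:60, cfg)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= cfg$conception_floor & p <= cfg$conception_first_service))
})

test_that("insemination outcomes follow the forced and stochastic conception rates", {
  cfg <- degenerate_config()   # conception 1
  st <- cycling_state(cfg)
  out <- attempt_insemination(st, cfg, rng_stream(1))
  expect_equal(out$state$repro_state, "pregnant")
  expect_equal(out$state$services, 1L)
  expect_equal(out$state$days_pregnant, 0L)
  expect_equal(out$state$gestation_length_drawn, 278L)
  expect_equal(vapply(out$events, `[[`, "", "event"), "INSEMINATION")

  cfg0 <- degenerate_config(conception_first_service = 0)
  out0 <- attempt_insemination(cycling_state(cfg0), cfg0, rng_stream(2))
  expect_equal(out0$state$repro_state, "cycling")
  expect_equal(out0$state$services, 1L)

  expect_error(attempt_insemination(out$state, cfg, rng_stream(3)), "pregnant")

  # realized first-service conception over 50,000 animals
  cfg <- default_config()
  s <- rng_stream(105)
  base <- cycling_state(cfg)
  hits <- vapply(seq_len(5e4), function(i) {
    attempt_insemination(base, cfg, s)$state$repro_state == "pregnant"
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.339), 0.006)
})

test_that("pregnancy survival through the first diagnosis window matches the geometric closed form", {
  cfg <- default_config()
  coh <- simulate_pregnancy_cohort(5e4, cfg, rng_stream(106))
  surv_w1 <- mean(is.na(coh$loss_day) | coh$loss_day > 91)
  expect_lt(abs(surv_w1 - 0.9904^59), 0.005)   # (1 - 0.0096)^59 = 0.566
  # hazard is zero outside (32, 200]
  ld <- coh$loss_day[!is.na(coh$loss_day)]
  expect_true(all(ld > 32 & ld <= 200))
})

test_that("per-animal daily pregnancy updates agree statistically with the cohort route", {
  cfg <- default_config()
  s <- rng_stream(107)
  n <- 4000
  lost_w1 <- logical(n)
  for (i in seq_len(n)) {
    st <- cycling_state(cfg)
    st$repro_state <- "pregnant"; st$ever_pregnant <- TRUE
    st$days_pregnant <- 0L; st$latent_loss <- FALSE
    st$gestation_length_drawn <- 278L
    for (d in 1:91) {
      res <- daily_pregnancy_update(st, cfg, s)
      st <- res$state
      if (!identical(st$repro_state, "pregnant")) break
    }
    lost_w1[i] <- !identical(st$repro_state, "pregnant")
  }
  p_loss <- 1 - 0.9904^59
  se <- sqrt(p_loss * (1 - p_loss) / n)
  expect_lt(abs(mean(lost_w1) - p_loss), 4 * se)
})

test_that("losses are revealed only at the next diagnosis and zero loss means calving at the drawn length", {
  cfg <- degenerate_config()
  st <- cycling_state(cfg)
  st$repro_state <- "pregnant"; st$ever_pregnant <- TRUE
  st$days_pregnant <- 0L; st$latent_loss <- FALSE
  st$gestation_length_drawn <- 278L
  evs <- list()
  for (d in 1:278) {
    res <- daily_pregnancy_update(st, cfg, NULL, sim_day = d)
    st <- res$state
    evs <- c(evs, res$events)
  }
  codes <- vapply(evs, `[[`, "", "event")
  days <- vapply(evs, `[[`, 1L, "sim_day")
  expect_equal(days[codes == "DIAGNOSIS_PREGNANT"], c(32L, 91L, 200L))
  expect_equal(days[codes == "CALVING"], 278L)
  expect_equal(st$parity, 1L)
  expect_true(st$lactating)

  # a forced latent loss surfaces at the next scheduled diagnosis only
  cfg91 <- degenerate_config(daily_loss_rates = c(1, 0))
  st <- cycling_state(cfg91)
  st$repro_state <- "pregnant"; st$ever_pregnant <- TRUE
  st$days_pregnant <- 0L; st$latent_loss <- FALSE
  st$gestation_length_drawn <- 278L
  evs <- list()
  for (d in 1:100) {
    res <- daily_pregnancy_update(st, cfg91, NULL, sim_day = d)
    st <- res$state
    evs <- c(evs, res$events)
    if (identical(st$repro_state, "cycling")) break
  }
  codes <- vapply(evs, `[[`, "", "event")
  days <- vapply(evs, `[[`, 1L, "sim_day")
  expect_equal(days[codes == "PREGNANCY_LOSS"], 91L)  # loss on day 33, revealed day 91
  expect_equal(days[codes == "DIAGNOSIS_OPEN"], 91L)
  expect_equal(st$repro_state, "cycling")
})

test_that("reproductive-failure culling triggers at the documented boundaries", {
  cfg <- default_config()
  heifer <- cycling_state(cfg, age = 650L)
  expect_equal(check_reproductive_cull(heifer, cfg), "reproductive_failure")
  heifer$age <- 649L
  expect_null(check_reproductive_cull(heifer, cfg))

  cow <- cycling_state(cfg, age = 1000L)
  cow$parity <- 1L; cow$ever_pregnant <- TRUE
  cow$lactating <- TRUE; cow$dim <- 300L
  expect_null(check_reproductive_cull(cow, cfg))
  cow$dim <- 301L
  expect_equal(check_reproductive_cull(cow, cfg), "reproductive_failure")
  cow$repro_state <- "pregnant"; cow$dim <- 400L
  expect_null(check_reproductive_cull(cow, cfg))
})

test_that("loss-rate estimation recovers the configured window rates within two standard errors", {
  cfg <- default_config()
  coh <- simulate_pregnancy_cohort(1e5, cfg, rng_stream(108))
  est <- estimate_loss_rates(coh, cfg)
  for (w in 1:2) {
    p <- cfg$daily_loss_rates[w]
    se <- sqrt(p * (1 - p) / est$at_risk_days[w])
    expect_lt(abs(est$daily_rate[w] - p), 2 * se)
  }
})
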