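test_that("calf generation follows the semen-type sex ratio and exit contract", {
  cfg <- default_config()
  cfg$female_prob_by_semen$sexed <- 1
  for (i in 1:20)
    expect_equal(generate_calf(cfg, rng_stream(i))$state$sex, "female")

  cfg0 <- default_config()
  cfg0$female_prob_by_semen$sexed <- 0
  res <- generate_calf(cfg0, rng_stream(1))
  expect_equal(res$state$sex, "male")
  expect_true(res$state$exited)
  expect_equal(vapply(res$events, `[[`, "", "event"),
               c("BIRTH", "MALE_SOLD", "EXIT"))

  cfg_bad <- default_config(); cfg_bad$semen_type <- "nonexistent"
  expect_error(generate_calf(cfg_bad, rng_stream(1)), "semen")

  # sex-ratio recovery under the default sexed semen
  s <- rng_stream(301)
  cfgd <- default_config()
  fem <- vapply(seq_len(2e4), function(i)
    generate_calf(cfgd, s, animal_id = i)$state$sex == "female", logical(1))
  expect_lt(abs(mean(fem) - 0.90), 2 * sqrt(0.9 * 0.1 / 2e4))
})

test_that("stepping an empty herd is a no-op", {
  herd <- herdsim:::new_herd(rng_stream(1))
  res <- step_day(herd, default_config(), 1L)
  expect_length(res$events, 0)
  expect_equal(res$milk, 0)
  expect_length(herd$animals, 0)
})

test_that("a cow on her last gestation day calves and a calf is born the next step", {
  cfg <- degenerate_config()
  herd <- herdsim:::new_herd(rng_stream(5))
  invisible(herdsim:::herd_add_calf(herd, cfg, 0L, force_female = TRUE))
  a <- herd$animals[["1"]]
  a$age <- 500L; a$repro_state <- "pregnant"; a$ever_pregnant <- TRUE
  a$days_pregnant <- 277L; a$gestation_length_drawn <- 278L
  a$latent_loss <- FALSE
  herd$animals[["1"]] <- a
  res <- step_day(herd, cfg, 1L)
  codes <- vapply(res$events, `[[`, "", "event")
  expect_true("CALVING" %in% codes)
  expect_true("BIRTH" %in% codes)
  expect_length(herd$animals, 2)
})

test_that("identical seeds give byte-identical logs and summaries", {
  cfg <- default_config()
  r1 <- run_simulation(cfg, 800, list(type = "newborn_females", n = 3), seed = 9)[[1]]
  r2 <- run_simulation(cfg, 800, list(type = "newborn_females", n = 3), seed = 9)[[1]]
  expect_identical(r1$events, r2$events)
  expect_identical(r1$summary, r2$summary)
})

test_that("per-animal substreams insulate trajectories from herd composition", {
  cfg <- no_cull_config()
  rA <- run_simulation(cfg, 700, list(type = "newborn_females", n = 1), seed = 77)[[1]]
  rB <- run_simulation(cfg, 700, list(type = "newborn_females", n = 2), seed = 77)[[1]]
  evA <- rA$events[rA$events$animal_id == 1, ]
  evB <- rB$events[rB$events$animal_id == 1, ]
  expect_identical(evA, evB)
})

test_that("replicates use independent reproducible streams", {
  cfg <- default_config()
  rr <- run_simulation(cfg, 600, list(type = "newborn_females", n = 2),
                       replicates = 3, seed = 13)
  expect_length(rr, 3)
  # replicate streams differ from one another but are each reproducible
  expect_false(identical(rr[[1]]$events, rr[[2]]$events))
  again <- run_simulation(cfg, 600, list(type = "newborn_females", n = 2),
                          replicates = 3, seed = 13)
  expect_identical(rr[[2]]$events, again[[2]]$events)
})

test_that("the daily herd ledger balances and matches the event-log recomputation", {
  cfg <- default_config()
  for (r in run_simulation(cfg, 900, list(type = "newborn_females", n = 5),
                           replicates = 2, seed = 31)) {
    s <- r$summary
    expect_true(all(diff(s$herd_size) == (s$entries - s$exits)[-1]))
    led <- summarize(r$events, n_days = 900)
    expect_equal(led$herd_size, s$herd_size)
  }
})

test_that("realized gestation lengths in full herd runs recover the configured mean", {
  cfg <- no_cull_config()
  gest <- c()
  for (r in run_simulation(cfg, 900, list(type = "fresh_cows", n = 20),
                           replicates = 3, seed = 55)) {
    ev <- r$events
    for (id in unique(ev$animal_id)) {
      e <- ev[ev$animal_id == id, ]
      ai <- e$sim_day[e$event == "INSEMINATION"]
      cv <- e$sim_day[e$event == "CALVING"]
      for (cd in cv) {
        conc <- max(ai[ai < cd])         # the conceiving insemination
        gest <- c(gest, cd - conc)
      }
    }
  }
  expect_gt(length(gest), 30)
  expect_lt(abs(mean(gest) - 278), 2 * 6 / sqrt(length(gest)) + 0.5)
})

test_that("event times are per-animal nondecreasing and nothing follows an exit", {
  cfg <- default_config()
  r <- run_simulation(cfg, 2500, list(type = "newborn_females", n = 4), seed = 8)[[1]]
  ev <- r$events
  for (id in unique(ev$animal_id)) {
    e <- ev[ev$animal_id == id, ]
    expect_true(all(diff(e$sim_day) >= 0))
    ex <- which(e$event == "EXIT")
    expect_lte(length(ex), 1)
    if (length(ex)) expect_equal(ex, nrow(e))
  }
})

test_that("summaries from raw logs are idempotent and count events correctly", {
  empty <- summarize(herdsim:::events_to_table(list()), n_days = 3)
  expect_equal(empty$entries, rep(0L, 4))
  expect_equal(empty$herd_size, rep(0L, 4))

  rows <- list(
    herdsim:::event_row(2, 1, "BIRTH"), herdsim:::event_row(2, 2, "BIRTH"),
    herdsim:::event_row(2, 3, "BIRTH"),
    herdsim:::event_row(3, 1, "EXIT", reason = "injury"))
  log <- herdsim:::events_to_table(rows)
  s1 <- summarize(log, n_days = 4)
  expect_equal(s1$entries[s1$sim_day == 2], 3)
  expect_equal(s1$exits_injury[s1$sim_day == 3], 1)
  expect_equal(s1$herd_size, c(0, 0, 3, 2, 2))
  expect_identical(s1, summarize(log, n_days = 4))

  bad <- data.frame(sim_day = 1, animal_id = 1, event = "NOT_AN_EVENT")
  expect_error(summarize(bad), "row 1")
  expect_error(summarize(data.frame(sim_day = 1)), "missing column")
})
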