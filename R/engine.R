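#' Generate a newborn calf
#'
#' Emits a BIRTH event; sex is drawn with the female probability of the
#' configured semen type (default sexed semen, 90% female). Male calves
#' are sold at birth (MALE_SOLD + EXIT the same day) and never enter the
#' herd; female calves are initialized prepubertal at birth weight, with
#' their age at first ovulation and their stochastic lifetime cull fate
#' both assigned at creation from the calf's own random stream.
#'
#' @param cfg a `herd_config`.
#' @param rng the calf's `herd_stream` (or NULL for the session RNG).
#' @param sim_day day of birth in simulation time.
#' @param animal_id integer id for the calf.
#' @param force_female bypass the sex draw (used when seeding a herd with
#'   newborn females).
#' @return list with `state` (the animal, `$exited = TRUE` for males) and
#'   `events`.
#' @export
generate_calf <- function(cfg, rng = NULL, sim_day = 0L, animal_id = 1L,
                          force_female = FALSE) {
  p_female <- cfg$female_prob_by_semen[[cfg$semen_type]]
  if (is.null(p_female))
    stop("unknown semen type: ", cfg$semen_type)
  female <- force_female || with_stream(rng, stats::runif(1)) < p_female
  state <- list(
    animal_id = as.integer(animal_id),
    sex = if (female) "female" else "male",
    breed = cfg$breed_name,
    age = 0L,
    weight = cfg$birth_weight,
    life_stage = "calf",
    repro_state = "prepubertal",
    day_in_cycle = NA_integer_,
    cycle_length = NA_integer_,
    first_ovulation_age = NA_integer_,
    services = 0L,
    days_pregnant = 0L,
    latent_loss = FALSE,
    latent_loss_day = NA_integer_,
    gestation_length_drawn = NA_integer_,
    parity = 0L,
    dim = NA_integer_,
    lactating = FALSE,
    ever_pregnant = FALSE,
    cull_fate = NULL,
    exited = FALSE
  )
  events <- list(event_row(sim_day, animal_id, "BIRTH", age = 0L,
                           value = cfg$birth_weight))
  if (!female) {
    state$exited <- TRUE
    events <- c(events, list(
      event_row(sim_day, animal_id, "MALE_SOLD", age = 0L),
      event_row(sim_day, animal_id, "EXIT", age = 0L, reason = "male_sold")))
    return(list(state = state, events = events))
  }
  state$first_ovulation_age <- sample_first_ovulation_age(cfg, 1L, rng)
  state$cull_fate <- assign_cull_fate(cfg, rng)
  list(state = state, events = events)
}

# life stage refresh: calf until weaning age (60 d, non-normative), heifer
# until first calving, cow thereafter.
refresh_life_stage <- function(state) {
  state$life_stage <-
    if (state$parity >= 1L) "cow" else if (state$age < 60L) "calf" else "heifer"
  state
}

# Ovulation-day logic: one heat-detection chance; detected heat leads to
# insemination, otherwise the animal starts the next cycle.
ovulation_day_update <- function(state, cfg, rng, sim_day) {
  events <- list()
  if (heat_detected(cfg, 1L, rng)) {
    events <- c(events, list(event_row(sim_day, state$animal_id,
                                       "HEAT_DETECTED", age = state$age,
                                       service = state$services + 1L)))
    res <- attempt_insemination(state, cfg, rng, sim_day)
    state <- res$state
    events <- c(events, res$events)
  } else {
    state <- enter_new_cycle(state, cfg, rng)
  }
  list(state = state, events = events)
}

# Advance one animal one day through the fixed pipeline:
# age -> reproduction -> calving flag -> lactation/dry-off -> culling.
advance_animal <- function(state, cfg, rng, sim_day) {
  events <- list()
  calved <- FALSE

  # (1) age and weight
  state$age <- state$age + 1L
  state$weight <- body_weight(state$age, cfg)
  state <- refresh_life_stage(state)

  # (2) reproduction
  if (state$sex == "female") {
    rs <- state$repro_state
    if (rs == "prepubertal") {
      if (state$age >= state$first_ovulation_age) {
        events <- c(events, list(event_row(sim_day, state$animal_id,
                                           "FIRST_OVULATION",
                                           age = state$age)))
        state$repro_state <- "cycling"
        res <- ovulation_day_update(state, cfg, rng, sim_day)
        state <- res$state; events <- c(events, res$events)
      }
    } else if (rs == "cycling") {
      state$day_in_cycle <- state$day_in_cycle + 1L
      if (state$day_in_cycle >= state$cycle_length) {
        events <- c(events, list(event_row(sim_day, state$animal_id,
                                           "OVULATION", age = state$age)))
        res <- ovulation_day_update(state, cfg, rng, sim_day)
        state <- res$state; events <- c(events, res$events)
      }
    } else if (rs == "pregnant") {
      res <- daily_pregnancy_update(state, cfg, rng, sim_day)
      state <- res$state; events <- c(events, res$events)
      calved <- res$calved
    }
  }

  # (4) lactation and dry-off (calving day counts as DIM 1)
  milk <- 0
  if (isTRUE(state$lactating)) {
    state$dim <- if (is.na(state$dim)) 1L else state$dim + 1L
    milk <- daily_production(state, cfg)$milk_yield
    if (dry_off_due(state, cfg)) {
      events <- c(events, list(event_row(sim_day, state$animal_id, "DRY_OFF",
                                         age = state$age, dim = state$dim,
                                         parity = state$parity)))
      state$lactating <- FALSE
      state$dim <- NA_integer_
      milk <- 0
    }
  }

  # (5) culling
  cull_events <- apply_culling(state, cfg, sim_day)
  if (!is.null(cull_events)) {
    state$exited <- TRUE
    events <- c(events, cull_events)
  }

  list(state = state, events = events, calved = calved, milk = milk)
}

# A herd is a mutable environment: animals keyed by id, one RNG substream
# per animal derived from the replicate stream.
new_herd <- function(rep_stream) {
  h <- new.env(parent = emptyenv())
  h$animals <- list()
  h$streams <- list()
  h$next_id <- 1L
  h$rep_stream <- rep_stream
  class(h) <- "herd"
  h
}

# Seed the herd with a first-parity cow that calved on day 0 (its calf is
# not part of the herd). Used by the "fresh_cows" initial-herd option.
herd_add_fresh_cow <- function(herd, cfg, age) {
  id <- herd$next_id
  herd$next_id <- id + 1L
  st <- substream(herd$rep_stream, id)
  state <- generate_calf(cfg, st, 0L, id, force_female = TRUE)$state
  state$age <- as.integer(age)
  state$weight <- body_weight(state$age, cfg)
  state$parity <- 1L
  state$life_stage <- "cow"
  state$ever_pregnant <- TRUE
  state$lactating <- TRUE
  state$dim <- 0L                     # first milking day is tomorrow's DIM 1
  state <- enter_new_cycle(state, cfg, st)
  key <- as.character(id)
  herd$animals[[key]] <- state
  herd$streams[[key]] <- st
  list(event_row(0L, id, "ENTRY", age = state$age, dim = 0L, parity = 1L))
}

herd_add_calf <- function(herd, cfg, sim_day, force_female = FALSE) {
  id <- herd$next_id
  herd$next_id <- id + 1L
  st <- if (is.null(herd$rep_stream)) NULL else substream(herd$rep_stream, id)
  res <- generate_calf(cfg, st, sim_day, id, force_female)
  if (!res$state$exited) {
    key <- as.character(id)
    herd$animals[[key]] <- res$state
    herd$streams[[key]] <- st
  }
  res$events
}

#' Advance a herd by one simulated day
#'
#' Applies the fixed daily pipeline (age/weight, reproduction, calving,
#' lactation/dry-off, culling) to every live animal in ascending id order,
#' generating a newborn calf for every calving, and removes animals that
#' exited. Each animal draws exclusively from its own substream, so herd
#' composition never perturbs an individual's trajectory.
#'
#' @param herd a herd environment (see [run_simulation()]).
#' @param cfg a `herd_config`.
#' @param sim_day current simulation day.
#' @return list with `events` (list of rows) and `milk` (total kg that
#'   day); the herd is updated in place.
#' @export
step_day <- function(herd, cfg, sim_day) {
  events <- list()
  milk_total <- 0
  ids <- as.integer(names(herd$animals))
  for (key in as.character(sort(ids))) {
    state <- herd$animals[[key]]
    res <- advance_animal(state, cfg, herd$streams[[key]], sim_day)
    events <- c(events, res$events)
    milk_total <- milk_total + res$milk
    if (res$calved)
      events <- c(events, herd_add_calf(herd, cfg, sim_day))
    if (res$state$exited) {
      herd$animals[[key]] <- NULL
      herd$streams[[key]] <- NULL
    } else {
      herd$animals[[key]] <- res$state
    }
  }
  list(events = events, milk = milk_total)
}

count_stages <- function(herd) {
  stages <- vapply(herd$animals, `[[`, "", "life_stage")
  lact <- vapply(herd$animals, function(a) isTRUE(a$lactating), logical(1))
  c(n_calf = sum(stages == "calf"), n_heifer = sum(stages == "heifer"),
    n_cow = sum(stages == "cow"), n_lactating = sum(lact))
}

#' Run the Monte-Carlo herd simulation
#'
#' Drives [step_day()] for `n_days` over `replicates` independent
#' replicates. Replicate k draws from the k-th L'Ecuyer stream derived
#' from `cfg$seed` (or the `seed` argument), and each animal from its own
#' substream, so the whole output is a deterministic function of
#' (seed, config, n_days) and replicate streams are mutually independent.
#'
#' @param cfg a `herd_config`.
#' @param n_days number of simulated days, `>= 1`.
#' @param initial_herd_spec one of
#'   `list(type = "newborn_females", n = ...)` — n newborn females enter on
#'   day 0; `list(type = "calf_schedule", arrival_days = c(...))` —
#'   calves (sex drawn) arrive on the given days; or
#'   `list(type = "fresh_cows", n = ..., age = ...)` — n first-parity cows
#'   enter on day 0 having calved that day (ENTRY event; default entry age
#'   700 d).
#' @param replicates number of replicate runs.
#' @param seed root seed; default `cfg$seed`.
#' @param daily_states if TRUE, also record one end-of-day snapshot row per
#'   live animal (id, age, dim, repro_state, parity) — intended for small
#'   herds.
#' @return list of replicates; each has `events` (data.table), `summary`
#'   (data.table: sim_day, herd_size, stage counts, lactating count,
#'   milk_kg, entries, exits), `replicate`, `seed`, and optionally
#'   `states`.
#' @export
run_simulation <- function(cfg, n_days,
                           initial_herd_spec = list(type = "newborn_females",
                                                    n = 1L),
                           replicates = 1L, seed = cfg$seed,
                           daily_states = FALSE) {
  assert_valid_config(cfg)
  stopifnot(n_days >= 1, replicates >= 1)
  spec_type <- initial_herd_spec$type
  if (is.null(spec_type) ||
      !spec_type %in% c("newborn_females", "calf_schedule", "fresh_cows"))
    stop("initial_herd_spec$type must be 'newborn_females', 'calf_schedule'",
         " or 'fresh_cows'")
  if (spec_type %in% c("newborn_females", "fresh_cows") &&
      (is.null(initial_herd_spec$n) || initial_herd_spec$n < 1))
    stop("initial_herd_spec$n must be >= 1")

  root <- rng_stream(seed)
  lapply(seq_len(replicates), function(r) {
    rep_stream <- next_stream(root, r - 1L)
    herd <- new_herd(rep_stream)
    all_events <- list()
    snaps <- list()
    summ <- vector("list", n_days + 1L)

    day0_events <- list()
    if (spec_type == "newborn_females") {
      for (i in seq_len(initial_herd_spec$n))
        day0_events <- c(day0_events,
                         herd_add_calf(herd, cfg, 0L, force_female = TRUE))
    } else if (spec_type == "fresh_cows") {
      age <- if (is.null(initial_herd_spec$age)) 700L else
        as.integer(initial_herd_spec$age)
      for (i in seq_len(initial_herd_spec$n))
        day0_events <- c(day0_events, herd_add_fresh_cow(herd, cfg, age))
    } else if (0 %in% initial_herd_spec$arrival_days) {
      for (i in seq_len(sum(initial_herd_spec$arrival_days == 0)))
        day0_events <- c(day0_events, herd_add_calf(herd, cfg, 0L))
    }
    all_events <- c(all_events, day0_events)
    summ[[1]] <- summary_row(0L, herd, day0_events, milk = 0)

    for (day in seq_len(n_days)) {
      day_events <- list()
      if (spec_type == "calf_schedule" &&
          day %in% initial_herd_spec$arrival_days) {
        for (i in seq_len(sum(initial_herd_spec$arrival_days == day)))
          day_events <- c(day_events, herd_add_calf(herd, cfg, day))
      }
      res <- step_day(herd, cfg, day)
      day_events <- c(day_events, res$events)
      all_events <- c(all_events, day_events)
      summ[[day + 1L]] <- summary_row(day, herd, day_events, res$milk)
      if (daily_states && length(herd$animals))
        snaps[[length(snaps) + 1L]] <- snapshot_rows(day, herd)
    }

    out <- list(replicate = r, seed = seed,
                events = events_to_table(all_events),
                summary = data.table::rbindlist(summ))
    if (daily_states)
      out$states <- if (length(snaps)) data.table::rbindlist(snaps) else
        data.table::data.table()
    out
  })
}

summary_row <- function(day, herd, day_events, milk) {
  codes <- vapply(day_events, `[[`, "", "event")
  stages <- count_stages(herd)
  data.table::data.table(
    sim_day = day, herd_size = length(herd$animals),
    n_calf = stages[["n_calf"]], n_heifer = stages[["n_heifer"]],
    n_cow = stages[["n_cow"]], n_lactating = stages[["n_lactating"]],
    milk_kg = milk,
    entries = sum(codes %in% c("BIRTH", "ENTRY")),
    exits = sum(codes == "EXIT"))
}

snapshot_rows <- function(day, herd) {
  data.table::rbindlist(lapply(herd$animals, function(a)
    data.table::data.table(sim_day = day, animal_id = a$animal_id,
                           age = a$age, dim = a$dim,
                           repro_state = a$repro_state, parity = a$parity,
                           lactating = isTRUE(a$lactating))))
}

#' Daily tallies from an event log
#'
#' Recomputes, from the raw event rows alone, the per-day entry and exit
#' counts (exits split by reason) and the running herd size
#' (cumulative entries minus cumulative exits). Idempotent; the result is
#' independent of row order within a day.
#'
#' @param events an event-log data.frame/data.table with the columns of
#'   [event_columns()].
#' @param n_days pad the summary out to this many days (default: last day
#'   seen in the log).
#' @return data.table with sim_day, entries, exits, exits_<reason>...,
#'   herd_size.
#' @export
summarize <- function(events, n_days = NULL) {
  events <- data.table::as.data.table(events)
  need <- c("sim_day", "animal_id", "event")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("malformed event log: missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(events) && any(!events$event %in% EVENT_CODES)) {
    bad <- which(!events$event %in% EVENT_CODES)[1]
    stop("malformed event log row ", bad, ": unknown event '",
         events$event[bad], "'")
  }
  last <- if (is.null(n_days)) {
    if (nrow(events)) max(events$sim_day) else 0L
  } else n_days
  out <- data.table::data.table(sim_day = 0L:as.integer(last))
  sim_day <- event <- NULL  # data.table NSE
  ent <- events[event %in% c("BIRTH", "ENTRY"), .N, by = sim_day]
  ext <- events[event == "EXIT", .N, by = sim_day]
  out$entries <- ent$N[match(out$sim_day, ent$sim_day)]
  out$exits <- ext$N[match(out$sim_day, ext$sim_day)]
  out$entries[is.na(out$entries)] <- 0L
  out$exits[is.na(out$exits)] <- 0L
  if (nrow(events)) {
    for (rsn in sort(unique(events[event == "EXIT"]$reason))) {
      reason <- NULL
      byday <- events[event == "EXIT" & reason == rsn, .N, by = sim_day]
      col <- paste0("exits_", rsn)
      out[[col]] <- byday$N[match(out$sim_day, byday$sim_day)]
      out[[col]][is.na(out[[col]])] <- 0L
    }
  }
  out$herd_size <- cumsum(out$entries) - cumsum(out$exits)
  out[]
}
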