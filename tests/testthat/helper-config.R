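# Shared fixtures: configs with collapsed stochasticity, and a brute-force
# LP vertex enumerator used as the independent oracle for the simplex path.

# Default config with every random element made deterministic, overridable
# field by field: degenerate_config(heat_detection_prob = 0, ...).
degenerate_config <- function(...) {
  cfg <- default_config()
  cfg$first_ovulation_delay_sd <- 0
  cfg$cycle_length_sd <- 0
  cfg$gestation_sd <- 0
  cfg$heat_detection_prob <- 1
  cfg$conception_first_service <- 1
  cfg$conception_decrement_per_service <- 0
  cfg$daily_loss_rates <- c(0, 0)
  cfg$female_prob_by_semen$sexed <- 1
  cfg$culling_reason_probs <- lapply(cfg$culling_reason_probs, function(x) 0)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

# Default config with stochastic culling disabled only.
no_cull_config <- function(...) {
  cfg <- default_config()
  cfg$culling_reason_probs <- lapply(cfg$culling_reason_probs, function(x) 0)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

# A cycling female on her ovulation day, for repro-operation unit tests.
cycling_state <- function(cfg, age = 420L) {
  st <- generate_calf(cfg, rng_stream(99), sim_day = 0L, animal_id = 1L,
                      force_female = TRUE)$state
  st$age <- as.integer(age)
  st$repro_state <- "cycling"
  st$day_in_cycle <- 0L
  st$cycle_length <- 21L
  st
}

# Brute-force LP oracle: enumerate every basic point formed by intersecting
# n constraints (nutrient/DMI rows taken as equalities plus coordinate
# planes), keep the feasible ones, return the minimum cost. Independent of
# the package's simplex implementation.
enumerate_lp_min_cost <- function(cost, A_le = NULL, b_le = NULL,
                                  A_ge = NULL, b_ge = NULL) {
  n <- length(cost)
  rows <- rbind(if (!is.null(A_le)) matrix(A_le, ncol = n),
                if (!is.null(A_ge)) matrix(A_ge, ncol = n),
                diag(n))
  rhs <- c(b_le, b_ge, rep(0, n))
  feasible <- function(x) {
    ok <- TRUE
    if (!is.null(A_le)) ok <- ok && all(matrix(A_le, ncol = n) %*% x <= b_le + 1e-8)
    if (!is.null(A_ge)) ok <- ok && all(matrix(A_ge, ncol = n) %*% x >= b_ge - 1e-8)
    ok && all(x >= -1e-8)
  }
  best <- Inf
  for (combo in utils::combn(nrow(rows), n, simplify = FALSE)) {
    M <- rows[combo, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, rhs[combo])
    if (feasible(x)) best <- min(best, sum(cost * x))
  }
  best
}
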