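#' Default simulation configuration
#'
#' Returns the exemplar Holstein estrus-detection/AI configuration used
#' throughout the package: birth weight 40.8 kg, average daily gain 0.9 kg/d,
#' 90% female calves under sexed semen, first-ovulation clock starting at
#' 400 d with a lognormal delay of arithmetic mean 19 d and SD 11 d, estrus
#' cycle length N(21, 4), heat-detection probability 0.60 per estrus,
#' first-service conception 0.339 decreasing by 0.026 (absolute) per
#' additional service, pregnancy diagnoses on gestation days 32, 91 and 200
#' with daily pregnancy-loss probabilities 0.0096 and 0.0017 in the two
#' inter-diagnosis windows, gestation length N(278, 6), reproductive-failure
#' culling of open heifers at 650 d and of open cows past 300 days in milk.
#'
#' Values the exemplar protocol does not fix — culling-reason probabilities,
#' the empirical culling-age CDF, lactation-curve parameters, the dry-period
#' length (60 d) and the mature-weight cap — are shipped as documented
#' NON-NORMATIVE defaults intended for testing, and should be overridden
#' with herd-specific values for any real application.
#'
#' All `N(m, s)` parameters are normal with mean `m` and standard deviation
#' `s`; the first-ovulation delay is lognormal with *arithmetic* moments
#' (19, 11), moment-matched internally to (meanlog, sdlog).
#'
#' @return an object of class `herd_config` (a validated named list).
#' @examples
#' cfg <- default_config()
#' cfg$conception_first_service  # 0.339
#' cfg$diagnosis_days            # 32 91 200
#' @export
default_config <- function() {
  cfg <- structure(list(
    breed_name = "Holstein",
    birth_weight = 40.8,                 # kg
    average_daily_gain = 0.9,            # kg/d
    mature_weight_cap = 700,             # kg, non-normative
    semen_type = "sexed",
    female_prob_by_semen = list(sexed = 0.90, conventional = 0.49),
    puberty_base_age = 400,              # d
    first_ovulation_delay_mean = 19,     # d, arithmetic mean of lognormal delay
    first_ovulation_delay_sd = 11,       # d, arithmetic SD
    cycle_length_mean = 21,              # d
    cycle_length_sd = 4,                 # d
    heat_detection_prob = 0.60,
    conception_first_service = 0.339,
    conception_decrement_per_service = 0.026,  # absolute points per service
    conception_floor = 0,
    diagnosis_days = c(32, 91, 200),     # gestation days of pregnancy checks
    daily_loss_rates = c(0.0096, 0.0017),  # per-day loss, one per window
    gestation_mean = 278,                # d
    gestation_sd = 6,                    # d
    heifer_cull_age = 650,               # d, open-heifer cull
    cow_cull_dim = 300,                  # DIM; cull on first day dim > 300
    # NON-NORMATIVE: lifetime probabilities per reason, evaluated in order
    culling_reason_probs = list(
      lameness = 0.06, injury = 0.02, mastitis = 0.08,
      other_diseases = 0.06, udder_problems = 0.03, unknown = 0.05),
    culling_age_cdf = default_culling_cdf(),   # NON-NORMATIVE placeholder
    lactation = default_lactation_table(),     # NON-NORMATIVE placeholder
    dry_period_length = 60,              # d, non-normative
    seed = 20260924L
  ), class = "herd_config")
  stopifnot(length(validate_config(cfg)) == 0L)
  cfg
}

# Smooth placeholder culling-age CDF over 700-3800 d (non-normative fixture):
# a logistic ramp, renormalized so the terminal mass is exactly 1.
default_culling_cdf <- function() {
  age <- seq(700, 3800, by = 100)
  p <- stats::plogis(age, location = 1900, scale = 420)
  p <- (p - p[1]) / (p[length(p)] - p[1])
  p[length(p)] <- 1
  data.frame(age_days = age, cumulative_probability = p)
}

# Placeholder Wood parameters by parity class (non-normative, testing only).
default_lactation_table <- function() {
  data.frame(
    breed = "Holstein",
    parity_class = c("1", "2", "3+"),
    form = "WOOD",
    a = c(15, 19, 21),          # kg/d scale
    b = c(0.20, 0.22, 0.23),    # dimensionless rise
    c = c(0.0026, 0.0030, 0.0032),  # 1/d decay
    d = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of a `herd_config` and returns the
#' violations as a character vector of messages (empty when valid), each
#' naming the offending field. Violations are data, not errors, so a CLI
#' or config loader can report all of them at once.
#'
#' @param cfg a `herd_config`-shaped list.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  pos_fields <- c("birth_weight", "average_daily_gain", "mature_weight_cap",
                  "puberty_base_age", "first_ovulation_delay_mean",
                  "cycle_length_mean",
                  "gestation_mean", "heifer_cull_age", "cow_cull_dim",
                  "dry_period_length")
  for (f in pos_fields) {
    x <- cfg[[f]]
    if (!num1(x) || x <= 0) say(sprintf("%s: must be a single positive number", f))
  }
  nonneg_fields <- c("first_ovulation_delay_sd", "cycle_length_sd",
                     "gestation_sd")
  for (f in nonneg_fields) {
    x <- cfg[[f]]
    if (!num1(x) || x < 0) say(sprintf("%s: must be a single nonnegative number", f))
  }
  prob_fields <- c("heat_detection_prob", "conception_first_service",
                   "conception_decrement_per_service", "conception_floor")
  for (f in prob_fields) {
    x <- cfg[[f]]
    if (!num1(x) || x < 0 || x > 1) say(sprintf("%s: must be a probability in [0, 1]", f))
  }

  fp <- cfg$female_prob_by_semen
  if (!is.list(fp) || is.null(names(fp)) ||
      !all(vapply(fp, num1, logical(1))) ||
      !all(unlist(fp) >= 0 & unlist(fp) <= 1))
    say("female_prob_by_semen: must map semen types to probabilities in [0, 1]")
  else if (!is.null(cfg$semen_type) && !cfg$semen_type %in% names(fp))
    say("semen_type: not present in female_prob_by_semen")

  dd <- cfg$diagnosis_days
  if (!is.numeric(dd) || length(dd) < 1L || any(dd <= 0))
    say("diagnosis_days: must be positive gestation days")
  else if (any(diff(dd) <= 0))
    say("diagnosis_days: must be strictly increasing")
  lr <- cfg$daily_loss_rates
  if (!is.numeric(lr) || any(lr < 0) || any(lr > 1))
    say("daily_loss_rates: must be probabilities in [0, 1]")
  if (is.numeric(dd) && is.numeric(lr) && length(lr) != length(dd) - 1L)
    say("daily_loss_rates: length must equal length(diagnosis_days) - 1")

  cp <- cfg$culling_reason_probs
  if (!is.list(cp) || is.null(names(cp)) ||
      !all(vapply(cp, num1, logical(1))) ||
      !all(unlist(cp) >= 0 & unlist(cp) <= 1))
    say("culling_reason_probs: must map reasons to probabilities in [0, 1]")

  cdf_bad <- validate_cdf(cfg$culling_age_cdf)
  if (length(cdf_bad)) say(paste0("culling_age_cdf: ", cdf_bad))

  lt <- cfg$lactation
  if (!is.data.frame(lt) ||
      !all(c("breed", "parity_class", "form", "a", "b", "c") %in% names(lt)))
    say("lactation: must be a table with columns breed, parity_class, form, a, b, c[, d]")
  else {
    if (!all(lt$form %in% c("WOOD", "MILKBOT")))
      say("lactation: form must be WOOD or MILKBOT")
    if (any(!is.finite(lt$a) | lt$a <= 0)) say("lactation: a must be > 0")
  }

  if (!num1(cfg$seed)) say("seed: must be a single integer")
  v
}

# Returns "" -> no message; otherwise the defect description.
validate_cdf <- function(cdf) {
  if (!is.data.frame(cdf) ||
      !all(c("age_days", "cumulative_probability") %in% names(cdf)))
    return("must be a table with columns age_days, cumulative_probability")
  a <- cdf$age_days; p <- cdf$cumulative_probability
  if (nrow(cdf) < 1L || any(!is.finite(a)) || any(!is.finite(p)))
    return("entries must be finite")
  if (any(diff(a) <= 0)) return("age_days must be strictly increasing")
  if (any(diff(p) < 0)) return("cumulative_probability must be nondecreasing")
  if (p[1] < 0) return("cumulative_probability must start at or above 0")
  if (abs(p[length(p)] - 1) > 1e-9) return("cumulative_probability must end at 1")
  character(0)
}

#' @export
print.herd_config <- function(x, ...) {
  cat(sprintf("<herd_config> breed=%s semen=%s seed=%d\n",
              x$breed_name, x$semen_type, as.integer(x$seed)))
  cat(sprintf("  growth: %.1f kg + %.2f kg/d (cap %.0f kg)\n",
              x$birth_weight, x$average_daily_gain, x$mature_weight_cap))
  cat(sprintf("  repro : first ov %g d + logN(%g,%g); cycle N(%g,%g); heat %.0f%%\n",
              x$puberty_base_age, x$first_ovulation_delay_mean,
              x$first_ovulation_delay_sd, x$cycle_length_mean,
              x$cycle_length_sd, 100 * x$heat_detection_prob))
  cat(sprintf("  AI    : conception %.3f - %.3f/service; diagnoses d %s; loss %s\n",
              x$conception_first_service, x$conception_decrement_per_service,
              paste(x$diagnosis_days, collapse = "/"),
              paste(x$daily_loss_rates, collapse = "/")))
  cat(sprintf("  cull  : heifer %g d, cow >%g DIM, %d stochastic reasons\n",
              x$heifer_cull_age, x$cow_cull_dim,
              length(x$culling_reason_probs)))
  invisible(x)
}

# internal: stop with collected violations
assert_valid_config <- function(cfg) {
  v <- validate_config(cfg)
  if (length(v))
    stop("invalid herd_config:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}
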