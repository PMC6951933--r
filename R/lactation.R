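#' Body weight from age
#'
#' Linear growth at the breed average daily gain, from birth weight,
#' plateauing at the mature-weight cap:
#' `min(birth_weight + average_daily_gain * age, mature_weight_cap)`.
#'
#' @param age age in days (vectorized), `>= 0`.
#' @param cfg a `herd_config`.
#' @return body weight in kg.
#' @examples
#' body_weight(0, default_config())    # 40.8
#' body_weight(100, default_config())  # 130.8
#' @export
body_weight <- function(age, cfg) {
  if (any(age < 0)) stop("age must be nonnegative")
  w <- cfg$birth_weight + cfg$average_daily_gain * age
  cap <- cfg$mature_weight_cap
  if (!is.null(cap) && is.finite(cap)) w <- pmin(w, cap)
  w
}

#' Wood's lactation curve
#'
#' The three-parameter gamma-type curve `y(t) = a * t^b * exp(-c * t)`
#' with `t` the day in milk: `a` scales the whole curve (kg/d), `b`
#' governs the rise to peak, and `c` the exponential decline. The peak sits
#' at `t = b / c`.
#'
#' @param t_dim day in milk (vectorized), `>= 1`.
#' @param params list or one-row data.frame with `a`, `b`, `c`.
#' @return milk yield, kg/d.
#' @export
wood_yield <- function(t_dim, params) {
  if (any(t_dim < 1)) stop("t_dim must be >= 1")
  with(params, a * t_dim^b * exp(-c * t_dim))
}

#' MilkBot lactation curve
#'
#' The four-parameter model
#' `M(t) = a * (1 - exp((c - t) / b) / 2) * exp(-d * t)`, clipped below at
#' zero: `a` is the scale (kg/d), `b` the ramp (d) controlling the speed of
#' the rise, `c` the offset (d) shifting the curve along the time axis, and
#' `d` the decay (1/d).
#'
#' @param t_dim day in milk (vectorized), `>= 1`.
#' @param params list or one-row data.frame with `a`, `b`, `c`, `d`.
#' @return milk yield, kg/d, `>= 0`.
#' @export
milkbot_yield <- function(t_dim, params) {
  if (any(t_dim < 1)) stop("t_dim must be >= 1")
  if (params$b <= 0) stop("MilkBot ramp parameter b must be > 0")
  with(params, pmax(a * (1 - exp((c - t_dim) / b) / 2) * exp(-d * t_dim), 0))
}

# Parity 1 and 2 have their own curves; 3 and above share the "3+" class.
parity_class <- function(parity) ifelse(parity >= 3, "3+", as.character(parity))

# Look up the (breed, parity-class) row of the lactation table.
lactation_params <- function(breed, parity, cfg) {
  lt <- cfg$lactation
  row <- lt[lt$breed == breed & lt$parity_class == parity_class(parity), ]
  if (nrow(row) != 1L)
    stop(sprintf("no lactation parameters for breed '%s', parity %d",
                 breed, parity))
  as.list(row)
}

#' Milk yield of an animal on its current day in milk
#'
#' Dispatches to the configured curve family (Wood or MilkBot) at the
#' animal's (breed, parity-class) parameters; returns 0 for any
#' non-lactating animal. Day-in-milk 0 (the calving day itself) yields 0;
#' milking starts at DIM 1.
#'
#' @param state an animal state list.
#' @param cfg a `herd_config`.
#' @return list with `milk_yield` (kg/d) and `body_weight` (kg).
#' @export
daily_production <- function(state, cfg) {
  bw <- body_weight(state$age, cfg)
  if (!isTRUE(state$lactating) || is.na(state$dim) || state$dim < 1)
    return(list(milk_yield = 0, body_weight = bw))
  p <- lactation_params(state$breed, state$parity, cfg)
  y <- if (p$form == "WOOD") wood_yield(state$dim, p) else milkbot_yield(state$dim, p)
  list(milk_yield = y, body_weight = bw)
}

# Dry-off is due when a pregnant, lactating cow is dry_period_length days
# from expected calving (by the drawn gestation length).
dry_off_due <- function(state, cfg) {
  isTRUE(state$lactating) &&
    identical(state$repro_state, "pregnant") &&
    !is.na(state$gestation_length_drawn) &&
    (state$gestation_length_drawn - state$days_pregnant) <= cfg$dry_period_length
}
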