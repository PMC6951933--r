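#' Assign a stochastic lifetime cull fate at animal creation
#'
#' For each of the six culling reasons (lameness, injury, mastitis, other
#' diseases, udder problems, unknown), in the fixed order of
#' `cfg$culling_reason_probs`, a uniform U(0,1) draw is compared with the
#' reason's lifetime probability; the first reason whose draw falls below
#' its probability is assigned, and the age at which that cull fires is
#' then sampled by inverse transform from the empirical culling-age CDF.
#' If no draw hits, the animal carries no stochastic fate.
#'
#' First-hit-wins makes the marginal probability exact for the first reason
#' in the order and nested for later ones; reorder
#' `culling_reason_probs` to change precedence.
#'
#' @param cfg a `herd_config`.
#' @param rng a `herd_stream` or NULL.
#' @return NULL, or a list with `reason` and `scheduled_age` (days).
#' @export
assign_cull_fate <- function(cfg, rng = NULL) {
  probs <- unlist(cfg$culling_reason_probs)
  if (!length(probs)) return(NULL)
  with_stream(rng, {
    u <- stats::runif(length(probs))
    hit <- which(u < probs)
    if (!length(hit)) NULL
    else list(reason = names(probs)[hit[1]],
              scheduled_age = sample_cull_age(cfg$culling_age_cdf, 1L,
                                              rng = NULL))
  })
}

#' Inverse-CDF sampling of culling age
#'
#' Draws U(0,1) and returns the generalized inverse of the empirical
#' culling-age CDF: the smallest tabulated age whose cumulative probability
#' is greater than or equal to the draw.
#'
#' @param cdf data.frame with columns `age_days` (strictly increasing) and
#'   `cumulative_probability` (nondecreasing, ending at 1).
#' @param n number of draws.
#' @param rng a `herd_stream` or NULL.
#' @return integer ages in days.
#' @export
sample_cull_age <- function(cdf, n = 1L, rng = NULL) {
  bad <- validate_cdf(cdf)
  if (length(bad)) stop("malformed culling-age CDF: ", bad)
  u <- with_stream(rng, stats::runif(n))
  idx <- findInterval(u, cdf$cumulative_probability, left.open = TRUE) + 1L
  as.integer(cdf$age_days[pmin(idx, nrow(cdf))])
}

#' Daily culling check
#'
#' Fires on the first day any trigger holds — the animal's age reaches the
#' scheduled age of its stochastic fate, or the reproductive-failure rule
#' of [check_reproductive_cull()] signals — whichever comes first; emits a
#' CULLED event and a same-day EXIT with the reason in the payload. A
#' scheduled age already in the past (an animal entering mid-life) fires
#' immediately.
#'
#' @param state an animal state list.
#' @param cfg a `herd_config`.
#' @param sim_day simulation day for the event log.
#' @return NULL if no trigger fires, else list of two event rows
#'   (CULLED, EXIT).
#' @export
apply_culling <- function(state, cfg, sim_day = state$age) {
  reason <- check_reproductive_cull(state, cfg)
  if (is.null(reason) && !is.null(state$cull_fate) &&
      state$age >= state$cull_fate$scheduled_age)
    reason <- state$cull_fate$reason
  if (is.null(reason)) return(NULL)
  list(event_row(sim_day, state$animal_id, "CULLED", age = state$age,
                 dim = state$dim, parity = state$parity, reason = reason),
       event_row(sim_day, state$animal_id, "EXIT", age = state$age,
                 reason = reason))
}
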