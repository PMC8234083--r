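#' Configuration for a synthetic two-arm survival cohort
#'
#' Event times are exponential with an arm-specific hazard, administratively
#' censored at `censor_time_days`, then capped at `cap_days` (five years =
#' 1862 days by default) with the event flag cleared when capped — patients
#' surviving past five years count as surviving exactly five years.
#'
#' Arm names follow the infiltration grouping: the "high" infiltration arm
#' has the lower hazard (better prognosis).
#'
#' @param n_per_arm patients per arm.
#' @param hazard_high,hazard_low daily hazard of the high- and low-infiltration
#'   arms (both > 0).
#' @param censor_time_days administrative end of follow-up (>= 0).
#' @param cap_days follow-up cap; default 1862.
#' @param seed RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 40,
                          hazard_high = 1 / 1500,
                          hazard_low = 1 / 500,
                          censor_time_days = 2200,
                          cap_days = 1862,
                          seed = 1L) {
  if (hazard_high <= 0 || hazard_low <= 0) stop("hazards must be > 0")
  if (cap_days < 1) stop("'cap_days' must be >= 1")
  if (censor_time_days < 0) stop("'censor_time_days' must be >= 0")
  if (n_per_arm < 1 || n_per_arm != round(n_per_arm))
    stop("'n_per_arm' must be a positive integer")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 hazard_high = hazard_high, hazard_low = hazard_low,
                 censor_time_days = censor_time_days,
                 cap_days = cap_days, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic two-arm survival cohort
#'
#' @param config a [cohort_config()].
#' @return data.frame with sample_id, time_days, event (1 = death observed),
#'   group (`"high"`/`"low"` infiltration).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_per_arm
  draw_arm <- function(hazard, group, offset) {
    t_event <- rexp(n, rate = hazard)
    time <- pmin(t_event, config$censor_time_days)
    event <- as.integer(t_event <= config$censor_time_days)
    data.frame(sample_id = sprintf("%s_%03d", group, seq_len(n) + offset),
               time_days = time, event = event, group = group,
               stringsAsFactors = FALSE)
  }
  out <- rbind(draw_arm(config$hazard_high, "high", 0L),
               draw_arm(config$hazard_low, "low", n))
  cap_followup(out, cap_days = config$cap_days)
}
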