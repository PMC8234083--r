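#' Cap follow-up at a fixed horizon (five years = 1862 days)
#'
#' Times beyond `cap_days` are set to the cap with the event flag cleared:
#' patients surviving longer than the horizon are counted as surviving
#' exactly `cap_days` (administrative censoring at five years by default).
#' Times at exactly the cap are left unchanged.
#'
#' @param records data.frame with `time_days` and `event` columns.
#' @param cap_days cap in days (> 0), default 1862.
#' @return the records with times and events capped.
#' @export
cap_followup <- function(records, cap_days = 1862) {
  if (cap_days <= 0) stop("'cap_days' must be > 0")
  stopifnot(all(c("time_days", "event") %in% names(records)))
  over <- records$time_days > cap_days
  records$time_days[over] <- cap_days
  records$event[over] <- 0L
  records
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function, one curve per group.
#' Ties between events and censorings at the same time follow the standard
#' convention (events first). Computation is delegated to
#' [survival::survfit()]; this wrapper validates input and returns a tidy
#' per-group step table.
#'
#' @param records data.frame with `time_days`, `event` (1 = death observed)
#'   and `group` columns; `group` may be a single constant.
#' @return data.frame (class `km_curve`): group, time_days, n_risk, n_event,
#'   n_censor, survival.
#' @export
km_estimate <- function(records) {
  stopifnot(all(c("time_days", "event") %in% names(records)))
  if (is.null(records$group)) records$group <- "all"
  if (any(records$time_days < 0)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1))) stop("'event' must be 0/1")
  if (any(table(records$group) == 0L) || nrow(records) == 0L)
    stop("empty group")
  fits <- lapply(split(records, records$group), function(d)
    survival::survfit(survival::Surv(time_days, event) ~ 1, data = d))
  out <- do.call(rbind, lapply(names(fits), function(g) {
    f <- fits[[g]]
    data.frame(group = g, time_days = f$time, n_risk = f$n.risk,
               n_event = f$n.event, n_censor = f$n.censor,
               survival = f$surv, stringsAsFactors = FALSE)
  }))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test comparing survival between groups
#'
#' Standard log-rank test with hypergeometric variance, via
#' [survival::survdiff()]. Returns the chi-square statistic, degrees of
#' freedom, p-value and the per-group observed/expected event counts.
#'
#' @param records data.frame with `time_days`, `event`, `group`.
#' @return object of class `logrank_result`: list with statistic, df,
#'   p.value, observed, expected.
#' @export
logrank_test <- function(records) {
  stopifnot(all(c("time_days", "event", "group") %in% names(records)))
  groups <- unique(records$group)
  if (length(groups) < 2L) stop("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group,
                           data = records)
  df <- length(sd$n) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p.value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = setNames(as.numeric(sd$obs),
                                     sub("^group=", "", names(sd$n))),
                 expected = setNames(as.numeric(sd$exp),
                                     sub("^group=", "", names(sd$n)))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-sq = %.3f (df %d), p = %.4g\n",
              x$statistic, x$df, x$p.value))
  tab <- data.frame(group = names(x$observed), observed = x$observed,
                    expected = round(x$expected, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}
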