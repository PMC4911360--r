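#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function over the distinct event
#' times, computed through \code{survival::survfit}.
#'
#' @param time positive observed times.
#' @param event event indicators in \{0, 1\}.
#' @return An object of class `km_curve`: list with `event_times`
#'   (increasing), `survival` (non-increasing, in [0, 1]), `at_risk` and
#'   `n_events` aligned to `event_times`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0) stop("empty input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  structure(
    list(event_times = sf$time[keep],
         survival = sf$surv[keep],
         at_risk = sf$n.risk[keep],
         n_events = sf$n.event[keep]),
    class = "km_curve")
}

#' Two-sample log-rank test
#'
#' Standard two-sided log-rank chi-square test (1 df) comparing the survival
#' experience of two groups, via \code{survival::survdiff}.
#'
#' @param time positive observed times.
#' @param event event indicators in \{0, 1\}.
#' @param group vector with exactly two distinct values.
#' @return list with `chi2` (non-negative) and `p` (two-sided p-value).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("exactly two non-empty groups are required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- as.numeric(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
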