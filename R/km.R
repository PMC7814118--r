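#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate with Greenwood variance and log(-log)
#' confidence bands (so the bounds stay inside [0, 1]). The median is the
#' smallest time with S(t) <= 0.5; when no such time exists it is reported
#' as "not reached" (`NA`).
#'
#' @param times Survival/censoring times in months (> 0).
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @param conf_level Confidence level for the bands (default 0.95).
#' @return Object of class `mbs_km` with elements `time`, `n_risk`,
#'   `n_event`, `surv`, `greenwood_var`, `lower`, `upper`, `median_time`
#'   (`NA` = not reached), `n`, `n_events`, `conf_level`.
#' @export
#' @examples
#' km <- km_fit(c(1, 2, 3), c(1, 0, 1))
#' survival_at(km, 1)  # 2/3
km_fit <- function(times, events, conf_level = 0.95) {
  check_surv(times, events)
  fit <- survfit(Surv(times, events) ~ 1, conf.type = "log-log",
                 conf.int = conf_level)
  surv <- fit$surv
  # survfit std.err is the SE of log S (Greenwood sum); scale back to S
  gvar <- (surv * fit$std.err)^2
  gvar[!is.finite(gvar)] <- 0
  med <- fit$time[which(surv <= 0.5)[1L]]
  structure(list(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = surv, greenwood_var = gvar,
    lower = fit$lower, upper = fit$upper,
    median_time = if (length(med) && !is.na(med)) med else NA_real_,
    n = length(times), n_events = sum(events),
    conf_level = conf_level
  ), class = "mbs_km")
}

#' Survival probability at fixed horizons
#'
#' Evaluates the step function S(t) of a fitted curve at given times: the
#' estimate at the last observed time <= t, 1 before the first, and the last
#' available estimate beyond the end of follow-up (standard step-function
#' convention).
#'
#' @param km An `mbs_km` object.
#' @param t Numeric vector of horizons (months).
#' @param ci Return confidence bounds as well?
#' @return Numeric vector of S(t), or a `data.frame` with columns `time`,
#'   `surv`, `lower`, `upper` when `ci = TRUE`.
#' @export
survival_at <- function(km, t, ci = FALSE) {
  stopifnot(inherits(km, "mbs_km"))
  idx <- findInterval(t, km$time)
  s <- ifelse(idx == 0L, 1, km$surv[pmax(idx, 1L)])
  if (!ci) return(as.numeric(s))
  lo <- ifelse(idx == 0L, 1, km$lower[pmax(idx, 1L)])
  hi <- ifelse(idx == 0L, 1, km$upper[pmax(idx, 1L)])
  data.frame(time = t, surv = as.numeric(s),
             lower = as.numeric(lo), upper = as.numeric(hi))
}

#' @export
print.mbs_km <- function(x, ...) {
  cat(sprintf("<mbs_km> n = %d, events = %d, median OS = %s months\n",
              x$n, x$n_events,
              if (is.na(x$median_time)) "not reached"
              else format(x$median_time, digits = 4)))
  invisible(x)
}

#' k-sample log-rank test
#'
#' @param times Survival/censoring times (months).
#' @param events Event indicators (0/1).
#' @param groups Group labels (k >= 2 non-empty groups).
#' @return `mbs_test` with the chi-square statistic, k - 1 degrees of
#'   freedom and two-sided p-value.
#' @export
logrank <- function(times, events, groups) {
  check_surv(times, events)
  groups <- droplevels(factor(groups))
  if (length(groups) != length(times)) stop("length mismatch")
  if (anyNA(groups)) stop("missing group labels")
  if (nlevels(groups) < 2L) stop("log-rank test needs at least 2 groups")
  sd <- survdiff(Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  new_mbs_test(statistic = sd$chisq, df = df,
               p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
               method = "log-rank")
}

check_surv <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (anyNA(times) || anyNA(events)) stop("missing survival values")
  if (any(!is.finite(times) | times <= 0)) stop("times must be positive and finite")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  invisible(TRUE)
}

new_mbs_test <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = as.numeric(statistic),
                 df = if (is.null(df)) NA_real_ else as.numeric(df),
                 p_value = as.numeric(p_value), method = method, ...),
            class = "mbs_test")
}

#' @export
print.mbs_test <- function(x, ...) {
  cat(sprintf("<mbs_test> %s: statistic = %s, df = %s, p = %.4g\n",
              x$method, format(x$statistic, digits = 4),
              ifelse(is.na(x$df), "-", format(x$df)), x$p_value))
  invisible(x)
}
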