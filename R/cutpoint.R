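#' Optimal expression cutpoint for a survival marker
#'
#' Exhaustive scan over candidate thresholds — the midpoints between
#' consecutive sorted unique expression values — keeping only splits in
#' which both groups contain at least `floor(min_group_frac * n)` patients.
#' The returned cutpoint maximizes the chosen criterion:
#' \describe{
#'   \item{youden}{sensitivity + specificity - 1 of the induced indicator
#'     against the event label (orientation-free, i.e. |TPR - FPR|), the
#'     standard criterion of ROC-based cutpoint selection;}
#'   \item{concordance}{Harrell's C of the induced indicator against the
#'     censored survival outcome (orientation-free, max(C, 1 - C)).}
#' }
#' Ties are broken toward the more balanced split, then toward the smaller
#' cutpoint. The risk direction is set so that the dichotomized indicator's
#' univariate hazard ratio exceeds 1: `"high_is_risk"` when expression above
#' the cutpoint carries the excess hazard, `"low_is_risk"` otherwise
#' (low expression means at-or-below the cutpoint throughout the package).
#'
#' @param x Expression values of one gene.
#' @param times Survival/censoring times (months).
#' @param events Event indicators (0/1); at least one event, and at least
#'   one censored/surviving patient for the Youden criterion.
#' @param min_group_frac Minimum fraction of patients on each side of the
#'   cutpoint (default 0.10).
#' @param metric `"youden"` (default) or `"concordance"`.
#' @param gene Optional gene name carried into the result.
#' @return Object of class `mbs_cutpoint`: `gene`, `cutpoint`, `direction`,
#'   `metric`, `metric_value`, `n_high`, `n_low`, `n`.
#' @export
optimal_cutpoint <- function(x, times, events, min_group_frac = 0.10,
                             metric = c("youden", "concordance"),
                             gene = NA_character_) {
  metric <- match.arg(metric)
  check_surv(times, events)
  if (length(x) != length(times) || anyNA(x)) {
    stop("`x` must match `times` with no missing values")
  }
  n <- length(x)
  if (n < 20L) stop("cutpoint search needs at least 20 patients")
  ord <- order(x)
  xs <- x[ord]
  es <- events[ord]
  ux <- unique(xs)
  if (length(ux) < 2L) stop("uninformative marker: constant expression")
  cand <- (head(ux, -1L) + tail(ux, -1L)) / 2
  n_low <- findInterval(cand, xs)
  floor_n <- floor(min_group_frac * n)
  ok <- pmin(n_low, n - n_low) >= floor_n
  if (!any(ok)) stop("no admissible cutpoint under min_group_frac = ",
                     min_group_frac)
  cand <- cand[ok]
  n_low <- n_low[ok]

  if (metric == "youden") {
    ne <- sum(es)
    nn <- n - ne
    if (ne == 0L || nn == 0L) {
      stop("uninformative marker: Youden criterion needs both event labels")
    }
    cum_e <- cumsum(es)
    # TPR_high = events above cut / ne; FPR_high = non-events above cut / nn
    vals <- abs((ne - cum_e[n_low]) / ne -
                  (nn - (n_low - cum_e[n_low])) / nn)
  } else {
    vals <- vapply(cand, function(cc) {
      cidx <- as.numeric(harrell_c(times, events, as.numeric(x > cc)))
      max(cidx, 1 - cidx)
    }, numeric(1))
  }
  if (diff(range(vals)) < 1e-12) {
    stop("uninformative marker: criterion constant over all candidates")
  }
  best <- max(vals)
  tied <- which(vals >= best - 1e-12)
  if (length(tied) > 1L) {
    bal <- abs(n - 2 * n_low[tied])
    tied <- tied[bal == min(bal)]
    tied <- tied[which.min(cand[tied])]
  }
  cut <- cand[tied]
  z <- as.numeric(x > cut)
  beta <- suppressWarnings(
    coef(coxph(Surv(times, events) ~ z,
               control = coxph.control(eps = 1e-9)))[1L])
  direction <- if (!is.na(beta) && beta < 0) "low_is_risk" else "high_is_risk"
  structure(list(gene = gene, cutpoint = unname(cut), direction = direction,
                 metric = metric, metric_value = unname(vals[tied]),
                 n_high = as.integer(n - n_low[tied]),
                 n_low = as.integer(n_low[tied]), n = n),
            class = "mbs_cutpoint")
}

#' @export
print.mbs_cutpoint <- function(x, ...) {
  cat(sprintf(
    "<mbs_cutpoint> %s: cut = %.4g (%s), %s = %.4f, n_high/n_low = %d/%d\n",
    ifelse(is.na(x$gene), "marker", x$gene), x$cutpoint, x$direction,
    x$metric, x$metric_value, x$n_high, x$n_low))
  invisible(x)
}
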