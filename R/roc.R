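#' Harrell's concordance index for censored survival data
#'
#' Fraction of usable (comparable under right censoring) patient pairs in
#' which the higher-risk score belongs to the patient with the earlier
#' event; pairs tied on the score count one half. Scores are risk-oriented:
#' higher score = worse expected outcome.
#'
#' @param times Survival/censoring times (months).
#' @param events Event indicators (0/1).
#' @param score Numeric risk score (higher = higher risk).
#' @return Concordance in [0, 1], with the number of usable pairs attached
#'   as attribute `"pairs"`.
#' @export
harrell_c <- function(times, events, score) {
  check_surv(times, events)
  if (length(score) != length(times) || anyNA(score)) {
    stop("`score` must match `times` with no missing values")
  }
  cf <- concordance(Surv(times, events) ~ score, reverse = TRUE)
  cnt <- cf$count
  pairs <- unname(cnt["concordant"] + cnt["discordant"] + cnt["tied.x"])
  if (pairs == 0) stop("no comparable pairs under censoring")
  structure(as.numeric(cf$concordance), pairs = pairs)
}

#' ROC area under the curve with DeLong variance
#'
#' AUC of a score against a binary label, equal to the normalized
#' Mann-Whitney U statistic, with the DeLong structural-component variance
#' (via the pROC implementation of DeLong's algorithm).
#'
#' @param labels Binary labels (0/1); both classes must be present.
#' @param scores Numeric scores (higher = more label-1-like).
#' @return Object of class `mbs_auc` with `auc`, `delong_variance`,
#'   `n_pos`, `n_neg` and the underlying `roc` object.
#' @export
binary_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (anyNA(labels) || anyNA(scores)) stop("missing values in labels/scores")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both label classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  # DeLong variance is exactly 0 for a separating score; pROC warns about it
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  structure(list(auc = as.numeric(r$auc),
                 delong_variance = v,
                 n_pos = n_pos, n_neg = n_neg, roc = r),
            class = "mbs_auc")
}

#' @export
print.mbs_auc <- function(x, ...) {
  cat(sprintf("<mbs_auc> AUC = %.4f (DeLong SE %.4f), %d pos / %d neg\n",
              x$auc, sqrt(x$delong_variance), x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test comparing two AUCs
#'
#' Two-sided z-test for the difference of two correlated (paired, default)
#' or independent AUCs using DeLong covariance structure.
#'
#' @param a,b `mbs_auc` objects from [binary_auc()]. For a paired test they
#'   must score the same subjects.
#' @param paired Paired comparison (default `TRUE`).
#' @return `mbs_test` with fields `statistic`, `p_value` and `delta`
#'   (`a$auc - b$auc`).
#' @export
delong_test <- function(a, b, paired = TRUE) {
  stopifnot(inherits(a, "mbs_auc"), inherits(b, "mbs_auc"))
  delta <- a$auc - b$auc
  res <- tryCatch(
    pROC::roc.test(a$roc, b$roc, method = "delong", paired = paired),
    error = function(e) NULL)
  stat <- if (is.null(res)) NaN else unname(res$statistic)
  p <- if (is.null(res)) NaN else res$p.value
  if (!is.finite(stat) && isTRUE(all.equal(delta, 0))) {
    # identical scores: zero difference with zero variance
    stat <- 0; p <- 1
  }
  new_mbs_test(statistic = stat, df = NA, p_value = p,
               method = "DeLong AUC comparison", delta = delta)
}

# rank-based AUC (Mann-Whitney identity); fast path for bootstrap loops
auc_rank <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  n_neg <- length(labels) - n_pos
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
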