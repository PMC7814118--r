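#' Bootstrap tier-wise survival at fixed horizons with BCa intervals
#'
#' Each of `R` replicates resamples the `n` patients with replacement from
#' the whole cohort (unstratified, so tier sizes vary across replicates) and
#' recomputes the Kaplan-Meier survival of every tier at each horizon.
#' Intervals are bias-corrected and accelerated (BCa): the bias term `z0`
#' comes from the fraction of replicates below the original estimate and the
#' acceleration `a` from a leave-one-out jackknife of the original cohort.
#' A replicate in which a tier is absent is recorded as missing for that
#' tier's cells (counted, never an error); a tier present with zero events
#' contributes S = 1, and horizons beyond a replicate's last observed time
#' use the last available estimate (step-function convention, counted).
#'
#' A Kruskal-Wallis test across the tier-wise replicate distributions is
#' reported per horizon. Because replicates are resamples of one cohort and
#' not independent samples, that p-value is descriptive.
#'
#' @param cohort An `mbs_cohort` (healthy-donor rows excluded).
#' @param assignment An `mbs_risk` table from [score_patients()].
#' @param R Number of bootstrap replicates (default 1000; fewer than 100
#'   triggers a stability warning).
#' @param horizons Horizons in months (default 24 and 36: 2- and 3-year OS).
#' @param conf_level Interval level (default 0.95).
#' @param seed Integer seed; replicate streams follow a fixed per-replicate
#'   sub-seed schedule so results are reproducible from `(seed, R)`.
#' @return Object of class `mbs_bootstrap` with `$table` (per tier x horizon:
#'   original estimate, replicate mean, BCa interval, missing-replicate
#'   count), `$p_values` per horizon, and the resampling metadata.
#' @export
bootstrap_km <- function(cohort, assignment, R = 1000L,
                         horizons = c(24, 36), conf_level = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "mbs_cohort"), inherits(assignment, "mbs_risk"))
  R <- as.integer(R)
  if (R < 1L) stop("R must be positive")
  if (R < 100L) warning("R < 100: bootstrap intervals will be unstable")
  dat <- merge_assignment(cohort, assignment)
  tiers <- levels(droplevels(dat$tier))
  if (length(tiers) < 2L) stop("at least 2 tiers must be represented")
  n <- nrow(dat)
  cells <- expand.grid(tier = tiers, horizon = horizons,
                       stringsAsFactors = FALSE)
  est_cells <- function(idx) {
    d <- dat[idx, , drop = FALSE]
    out <- rep(NA_real_, nrow(cells))
    beyond <- 0L
    for (t in tiers) {
      rows <- d$tier == t
      if (!any(rows)) next
      sv <- km_step(d$os_time[rows], d$os_event[rows], horizons)
      out[cells$tier == t] <- sv$surv
      beyond <- beyond + sv$beyond
    }
    list(est = out, beyond = beyond)
  }
  orig <- est_cells(seq_len(n))$est

  reps <- matrix(NA_real_, nrow = R, ncol = nrow(cells))
  beyond_total <- 0L
  with_seed(seed, {
    sub_seeds <- sample.int(2147483646L, R)
    for (r in seq_len(R)) {
      set.seed(sub_seeds[r])
      idx <- sample.int(n, n, replace = TRUE)
      e <- est_cells(idx)
      reps[r, ] <- e$est
      beyond_total <- beyond_total + e$beyond
    }
  })

  # leave-one-out jackknife; removing patient i only perturbs i's own tier
  jack <- matrix(rep(orig, each = n), nrow = n)
  for (i in seq_len(n)) {
    t <- as.character(dat$tier[i])
    rows <- which(dat$tier == t)
    rows_i <- setdiff(rows, i)
    cols <- which(cells$tier == t)
    if (length(rows_i)) {
      jack[i, cols] <- km_step(dat$os_time[rows_i], dat$os_event[rows_i],
                               horizons)$surv
    } else {
      jack[i, cols] <- NA_real_
    }
  }

  tab <- cells
  tab$original <- orig
  tab$boot_mean <- colMeans(reps, na.rm = TRUE)
  ci <- t(vapply(seq_len(nrow(cells)), function(j) {
    rj <- reps[, j]; rj <- rj[!is.na(rj)]
    if (!length(rj) || is.na(orig[j])) return(c(NA_real_, NA_real_))
    bca_interval(rj, orig[j], jack[!is.na(jack[, j]), j], conf_level)
  }, numeric(2)))
  tab$lower <- ci[, 1L]
  tab$upper <- ci[, 2L]
  tab$n_missing <- colSums(is.na(reps))
  if (any(tab$n_missing > 0)) {
    message("bootstrap_km: ", sum(tab$n_missing),
            " missing tier cell(s) across replicates (tier absent)")
  }

  p_values <- vapply(horizons, function(h) {
    cols <- which(cells$horizon == h)
    groups <- rep(cells$tier[cols], each = R)
    vals <- as.vector(reps[, cols])
    keep <- !is.na(vals)
    kruskal.test(vals[keep], factor(groups[keep]))$p.value
  }, numeric(1))

  structure(list(table = tab,
                 p_values = data.frame(horizon = horizons,
                                       kruskal_p = p_values),
                 R = R, horizons = horizons, conf_level = conf_level,
                 seed = seed, n = n, n_beyond_horizon = beyond_total),
            class = "mbs_bootstrap")
}

# KM step-function survival at horizons; counts horizons beyond follow-up
km_step <- function(times, events, horizons) {
  fit <- survfit(Surv(times, events) ~ 1)
  idx <- findInterval(horizons, fit$time)
  surv <- ifelse(idx == 0L, 1, fit$surv[pmax(idx, 1L)])
  list(surv = as.numeric(surv),
       beyond = sum(horizons > max(times)))
}

# BCa interval over replicate values; reduces to the percentile interval
# when z0 = 0 and a = 0
bca_interval <- function(reps, theta, jack, conf_level = 0.95) {
  if (length(reps) == 0L) return(c(NA_real_, NA_real_))
  if (diff(range(reps)) == 0 && reps[1L] == theta) {
    return(c(theta, theta))
  }
  frac <- mean(reps < theta)
  R <- length(reps)
  frac <- min(max(frac, 1 / (2 * R)), 1 - 1 / (2 * R))
  z0 <- qnorm(frac)
  a <- 0
  if (length(jack) > 2L) {
    d <- mean(jack) - jack
    denom <- sum(d^2)^1.5
    if (is.finite(denom) && denom > 0) a <- sum(d^3) / (6 * denom)
  }
  alpha <- (1 - conf_level) / 2
  adj <- function(al) {
    zal <- qnorm(al)
    pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  }
  unname(quantile(reps, probs = c(adj(alpha), adj(1 - alpha)), type = 7,
                  names = FALSE))
}

merge_assignment <- function(cohort, assignment) {
  pat <- cohort_patients(cohort)$clinical
  dat <- merge(pat, as.data.frame(assignment)[, c("patient_id", "score",
                                                  "tier")],
               by = "patient_id", sort = FALSE)
  if (nrow(dat) == 0L) stop("assignment does not overlap the cohort")
  dat$tier <- factor(as.character(dat$tier), levels = .tier_levels)
  dat
}

#' @export
print.mbs_bootstrap <- function(x, ...) {
  cat(sprintf("<mbs_bootstrap> R = %d, n = %d, seed = %d\n", x$R, x$n,
              x$seed))
  tab <- x$table
  tab$original <- sprintf("%.1f%%", 100 * tab$original)
  tab$boot_mean <- sprintf("%.1f%%", 100 * tab$boot_mean)
  tab$ci <- sprintf("(%.1f-%.1f%%)", 100 * tab$lower, 100 * tab$upper)
  print(tab[, c("tier", "horizon", "original", "boot_mean", "ci",
                "n_missing")], row.names = FALSE)
  invisible(x)
}

#' Bootstrapped comparison of two risk scores' AUCs
#'
#' Computes the observed AUC of each score against the binary event label
#' and their difference `delta = auc_a - auc_b` (positive: score A performs
#' better). Each of `R` replicates resamples patients with replacement and
#' recomputes both AUCs on the same replicate; the percentile interval of
#' the replicate deltas gives the CI and the symmetric bootstrap tail
#' probability `2 * min(P(delta <= 0), P(delta >= 0))`, floored at `1/R`
#' and capped at 1, gives the p-value. Replicates with a single label class
#' are redrawn (counted, capped at `10 * R` total draws).
#'
#' @param cohort An `mbs_cohort` (labels are the patients' `os_event`), or a
#'   plain 0/1 label vector.
#' @param score_a,score_b Per-patient risk scores (higher = higher risk),
#'   defined for every patient.
#' @param R Number of replicates (default 10000).
#' @param conf_level Interval level.
#' @param seed Integer seed.
#' @return Object of class `mbs_auc_comparison`.
#' @export
compare_auc_bootstrap <- function(cohort, score_a, score_b, R = 10000L,
                                  conf_level = 0.95, seed = 1L) {
  labels <- if (inherits(cohort, "mbs_cohort")) {
    cohort_patients(cohort)$clinical$os_event
  } else {
    cohort
  }
  R <- as.integer(R)
  if (R < 1L) stop("R must be positive")
  if (length(score_a) != length(labels) || length(score_b) != length(labels)) {
    stop("scores must be defined for every patient")
  }
  if (anyNA(labels) || anyNA(score_a) || anyNA(score_b)) {
    stop("missing values in labels or scores")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L) {
    stop("labels must be 0/1 with both classes present")
  }
  n <- length(labels)
  auc_a <- auc_rank(labels, score_a)
  auc_b <- auc_rank(labels, score_b)
  delta <- auc_a - auc_b
  d <- numeric(R)
  redraws <- 0L
  with_seed(seed, {
    sub_seeds <- sample.int(2147483646L, R)
    for (r in seq_len(R)) {
      set.seed(sub_seeds[r])
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redraws <- redraws + 1L
        if (redraws > 10L * R) {
          stop("too many degenerate single-class replicates")
        }
      }
      d[r] <- auc_rank(labels[idx], score_a[idx]) -
        auc_rank(labels[idx], score_b[idx])
    }
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(d, probs = c(alpha, 1 - alpha), type = 7,
                        names = FALSE))
  p <- min(1, max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / R))
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 lower = ci[1L], upper = ci[2L], p_value = p,
                 R = R, conf_level = conf_level, seed = seed, n = n,
                 redraws = redraws, replicates = d),
            class = "mbs_auc_comparison")
}

#' @export
print.mbs_auc_comparison <- function(x, ...) {
  cat(sprintf(
    "<mbs_auc_comparison> AUC A = %.3f, AUC B = %.3f, delta = %.3f (95%% CI %.3f-%.3f), P = %.4g (R = %d)\n",
    x$auc_a, x$auc_b, x$delta, x$lower, x$upper, x$p_value, x$R))
  invisible(x)
}

#' Final multivariable model of risk tiers and confounders
#'
#' One Cox model with intermediate-versus-favourable and
#' adverse-versus-favourable tier indicators (reference level: favourable)
#' plus the clinical confounders, ranking covariates by their Wald
#' chi-square. A zero-event reference tier makes the tier coefficients
#' drift to infinity (monotone likelihood); such coefficients are flagged
#' and reported with a finite-side 95% profile-likelihood bound instead of
#' a Wald interval.
#'
#' @param cohort An `mbs_cohort`.
#' @param assignment An `mbs_risk` from [score_patients()].
#' @param confounders Subset of `c("age", "gender", "ipssr")`.
#' @param ties Tie handling for the Cox fit.
#' @return Object of class `mbs_multivariable` with `$fit` (an `mbs_cox`),
#'   `$ranking` (covariates sorted by Wald chi-square, descending),
#'   `$profile_bounds` for monotone-flagged coefficients, `$n`, `$n_dropped`.
#' @export
final_multivariable <- function(cohort, assignment,
                                confounders = c("age", "gender", "ipssr"),
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "mbs_cohort"), inherits(assignment, "mbs_risk"))
  if (length(confounders)) {
    confounders <- match.arg(confounders, c("age", "gender", "ipssr"),
                             several.ok = TRUE)
  }
  dat <- merge_assignment(cohort, assignment)
  if (!any(dat$tier == "favourable")) {
    stop("favourable tier is empty: no reference level")
  }
  conf <- build_confounders(dat, confounders)
  keep <- if (ncol(conf)) complete.cases(conf) else rep(TRUE, nrow(dat))
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message("final_multivariable: dropped ", n_dropped,
            " patient(s) with missing confounders")
  }
  dat <- dat[keep, , drop = FALSE]
  conf <- conf[keep, , drop = FALSE]
  covs <- cbind(data.frame(tier = droplevels(dat$tier)), conf)
  if (nlevels(covs$tier) < 2L) stop("fewer than 2 tiers after filtering")
  fit <- cox_fit(dat$os_time, dat$os_event, covs, ties = ties)
  ranking <- fit$terms[order(-fit$terms$wald_chisq),
                       c("term", "wald_chisq", "df", "p")]
  rownames(ranking) <- NULL
  flagged <- names(fit$monotone)[fit$monotone]
  profile_bounds <- NULL
  if (length(flagged)) {
    profile_bounds <- data.frame(
      term = flagged,
      bound = vapply(flagged, function(tm)
        tryCatch(cox_profile_bound(fit, tm), error = function(e) NA_real_),
        numeric(1)),
      side = vapply(flagged, function(tm) {
        b <- fit$terms$beta[fit$terms$term == tm]
        if (b > 0) "lower" else "upper"
      }, character(1)),
      stringsAsFactors = FALSE)
    rownames(profile_bounds) <- NULL
  }
  structure(list(fit = fit, ranking = ranking,
                 profile_bounds = profile_bounds,
                 n = nrow(dat), n_dropped = n_dropped),
            class = "mbs_multivariable")
}

#' @export
print.mbs_multivariable <- function(x, ...) {
  cat(sprintf("<mbs_multivariable> n = %d (%d dropped)\n", x$n, x$n_dropped))
  print(x$fit)
  cat("covariate ranking by Wald chi-square:\n")
  print(x$ranking, row.names = FALSE)
  if (!is.null(x$profile_bounds)) {
    cat("profile-likelihood bounds for monotone coefficients:\n")
    print(x$profile_bounds, row.names = FALSE)
  }
  invisible(x)
}
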