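#' Cox proportional-hazards fit
#'
#' Newton-type maximization of the Cox partial likelihood (via
#' [survival::coxph()] with a tight convergence tolerance), reporting per
#' coefficient the hazard ratio with Wald 95% CI `exp(beta +/- z * SE)`,
#' the Wald chi-square `(beta/SE)^2` and its p-value. Factor covariates are
#' expanded to reference-coded indicators; terms spanning several columns
#' additionally get a joint Wald test with matching degrees of freedom.
#'
#' Monotone partial likelihoods (complete separation: a coefficient drifting
#' to +/- infinity) are flagged per coefficient in `$monotone`, never
#' silently returned. Non-convergence within `max_iter` iterations is an
#' error whose condition carries the last iterate in `$last_beta`.
#'
#' @param times Survival/censoring times (months).
#' @param events Event indicators (0/1); at least one event required.
#' @param covariates Named `data.frame` (or numeric matrix with column
#'   names); no missing values — enforce complete cases upstream.
#' @param ties Tie handling: `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `mbs_cox`; see Details. `$terms` is the
#'   per-coefficient table, `$joint` the per-term joint Wald tests, `$fit`
#'   the underlying `coxph` object.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95, max_iter = 50L) {
  ties <- match.arg(ties)
  check_surv(times, events)
  if (sum(events) < 1L) stop("at least one event is required")
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  if (!is.data.frame(covariates) || is.null(names(covariates)) ||
      any(!nzchar(names(covariates)))) {
    stop("`covariates` must be a named data.frame or matrix")
  }
  if (nrow(covariates) != length(times)) stop("covariate length mismatch")
  if (anyNA(covariates)) {
    stop("missing covariate values; complete cases must be enforced upstream")
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  warns <- character(0)
  fit <- withCallingHandlers(
    coxph(as.formula(paste(
      "Surv(.time, .event) ~",
      paste(sprintf("`%s`", names(covariates)), collapse = " + "))),
      data = dat, ties = ties,
      control = coxph.control(eps = 1e-12, iter.max = max_iter)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  monotone <- detect_monotone(fit, warns)
  if (!any(monotone) && fit$iter >= max_iter) {
    cond <- structure(
      class = c("mbs_cox_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "Cox fit did not converge in %d iterations", max_iter),
        call = sys.call(-1), last_beta = coef(fit)))
    stop(cond)
  }
  s <- summary(fit, conf.int = conf_level)
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- beta / se
  terms <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = unname(exp(beta)),
    lower = unname(s$conf.int[, 3L]), upper = unname(s$conf.int[, 4L]),
    wald_chisq = unname(z^2), df = 1L,
    p = unname(2 * pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  joint <- joint_wald(fit)
  structure(list(
    terms = terms, joint = joint,
    loglik = unname(fit$loglik[length(fit$loglik)]),
    loglik_null = unname(fit$loglik[1L]),
    iterations = fit$iter, converged = TRUE, ties = ties,
    monotone = monotone, conf_level = conf_level,
    n = length(times), n_events = sum(events), fit = fit
  ), class = "mbs_cox")
}

# per-term joint Wald chi-square for terms spanning several columns
joint_wald <- function(fit) {
  assign <- fit$assign
  beta <- coef(fit)
  V <- vcov(fit)
  rows <- lapply(names(assign), function(nm) {
    idx <- assign[[nm]]
    b <- beta[idx]
    chisq <- tryCatch(as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE], b)),
                      error = function(e) NA_real_)
    data.frame(term = nm, wald_chisq = chisq, df = length(idx),
               p = pchisq(chisq, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

detect_monotone <- function(fit, warns) {
  beta <- coef(fit)
  flags <- setNames(rep(FALSE, length(beta)), names(beta))
  hit <- grep("coefficient may be infinite", warns, value = TRUE)
  for (msg in hit) {
    nums <- regmatches(msg, gregexpr("[0-9]+", msg))[[1L]]
    idx <- suppressWarnings(as.integer(nums))
    idx <- idx[!is.na(idx) & idx >= 1L & idx <= length(beta)]
    flags[idx] <- TRUE
  }
  # fall back on the usual numerical signature of a monotone likelihood
  se <- sqrt(diag(vcov(fit)))
  flags | (abs(beta) > 15 & se > 100)
}

#' @export
print.mbs_cox <- function(x, digits = 4, ...) {
  cat(sprintf("<mbs_cox> n = %d, events = %d, ties = %s, loglik = %.4f\n",
              x$n, x$n_events, x$ties, x$loglik))
  tab <- x$terms
  tab$hr <- round(tab$hr, digits); tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits); tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "hr", "lower", "upper", "wald_chisq", "p")],
        row.names = FALSE)
  if (any(x$monotone)) {
    cat("  monotone likelihood flagged for:",
        paste(names(x$monotone)[x$monotone], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Score test of each covariate's scaled Schoenfeld residuals against a
#' transform of time (default: the Kaplan-Meier transform), wrapping
#' [survival::cox.zph()]. A GLOBAL row tests all covariates jointly.
#'
#' @param fit An `mbs_cox` from [cox_fit()].
#' @param transform Time transform passed to `cox.zph` (default `"km"`).
#' @return `data.frame` of class `mbs_ph` with columns `term`, `chisq`,
#'   `df`, `p`.
#' @export
check_ph <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "mbs_cox"))
  if (fit$n_events < 3L) stop("proportional-hazards check needs >= 3 events")
  z <- cox.zph(fit$fit, transform = transform)
  tab <- as.data.frame(z$table)
  out <- data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
                    p = tab$p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mbs_ph", "data.frame")
  out
}

# 95% profile-likelihood bound for a coefficient with a monotone partial
# likelihood: the finite endpoint b where the profile log likelihood drops
# qchisq(level, 1)/2 below its supremum (the converged loglik).
cox_profile_bound <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "mbs_cox"))
  cox <- fit$fit
  X <- model.matrix(cox)
  j <- match(term, colnames(X))
  if (is.na(j)) stop("unknown term: ", term)
  y <- cox$y
  xj <- X[, j]
  others <- X[, -j, drop = FALSE]
  prof <- function(b) {
    off <- b * xj
    f <- if (ncol(others)) {
      coxph(y ~ others + offset(off), ties = fit$ties,
            control = coxph.control(eps = 1e-10, iter.max = 50))
    } else {
      coxph(y ~ offset(off), ties = fit$ties)
    }
    unname(f$loglik[length(f$loglik)])
  }
  target <- fit$loglik - qchisq(level, 1L) / 2
  d <- sign(coef(cox)[j])  # +1: profile increases in b, bound lies below
  if (d == 0) d <- 1
  g <- function(b) prof(b) - target
  b <- 0
  if (g(b) > 0) {
    while (g(b) > 0 && abs(b) < 60) b <- b - d
    if (abs(b) >= 60) return(-d * Inf)
    bracket <- sort(c(b, b + d))
  } else {
    while (g(b) < 0 && abs(b) < 60) b <- b + d
    if (abs(b) >= 60) return(-d * Inf)
    bracket <- sort(c(b - d, b))
  }
  uniroot(g, interval = bracket, tol = 1e-6)$root
}
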