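# Independent brute-force oracles used to cross-check the fast paths.

# gradient of the Cox partial log likelihood (no tied event times)
cox_pl_gradient <- function(beta, times, events, X) {
  X <- as.matrix(X)
  w <- as.numeric(exp(X %*% beta))
  g <- numeric(ncol(X))
  for (i in which(events == 1)) {
    at_risk <- times >= times[i]
    sw <- sum(w[at_risk])
    xbar <- colSums(X[at_risk, , drop = FALSE] * w[at_risk]) / sw
    g <- g + X[i, ] - xbar
  }
  g
}

# exhaustive O(n^2) pairwise concordance (continuous times assumed)
brute_concordance <- function(times, events, score) {
  n <- length(times)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (times[i] == times[j]) next
      a <- if (times[i] < times[j]) i else j
      b <- if (times[i] < times[j]) j else i
      if (events[a] != 1) next
      den <- den + 1
      num <- num + if (score[a] > score[b]) 1
        else if (score[a] == score[b]) 0.5 else 0
    }
  }
  num / den
}

# exhaustive cutpoint scan computing the Youden criterion directly
brute_cutpoint_youden <- function(x, events, min_group_frac = 0.10) {
  n <- length(x)
  ux <- sort(unique(x))
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  best <- NULL
  for (cc in cand) {
    n_low <- sum(x <= cc)
    if (min(n_low, n - n_low) < floor(min_group_frac * n)) next
    tpr <- mean(x[events == 1] > cc)
    fpr <- mean(x[events == 0] > cc)
    val <- abs(tpr - fpr)
    if (is.null(best) || val > best$val + 1e-12 ||
        (val >= best$val - 1e-12 &&
         (abs(n - 2 * n_low) < best$bal ||
          (abs(n - 2 * n_low) == best$bal && cc < best$cut)))) {
      best <- list(cut = cc, val = val, bal = abs(n - 2 * n_low))
    }
  }
  best
}

# small synthetic survival dataset with continuous times
random_surv_data <- function(n, censor_frac = 0.3) {
  t_death <- rexp(n, 0.1)
  t_cens <- if (censor_frac > 0) rexp(n, 0.1 * censor_frac / (1 - censor_frac))
            else rep(Inf, n)
  list(times = pmin(t_death, t_cens),
       events = as.integer(t_death <= t_cens))
}

# minimal risk assignment object for validate-stage tests
make_assignment <- function(patient_id, score) {
  tier <- ifelse(score == 0, "favourable",
                 ifelse(score == 1, "intermediate", "adverse"))
  structure(
    data.frame(patient_id = patient_id, score = as.integer(score),
               tier = factor(tier,
                             levels = c("favourable", "intermediate",
                                        "adverse")),
               stringsAsFactors = FALSE),
    class = c("mbs_risk", "data.frame"))
}

# cohort with given survival data and a dummy expression matrix
make_cohort <- function(times, events, extra = NULL) {
  n <- length(times)
  ids <- sprintf("P%04d", seq_len(n))
  expr <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("GENE1", "GENE2"), ids))
  clin <- data.frame(patient_id = ids, os_time = times,
                     os_event = events, stringsAsFactors = FALSE)
  if (!is.null(extra)) clin <- cbind(clin, extra)
  new_cohort(expr, clin)
}

# all-gene cutpoint list for a cohort, via the package's own search
panel_cutpoints <- function(cohort, metric = "youden") {
  pat <- cohort_patients(cohort)
  cl <- pat$clinical
  cuts <- list()
  for (g in rownames(pat$expression)) {
    cp <- tryCatch(
      optimal_cutpoint(pat$expression[g, ], cl$os_time, cl$os_event,
                       metric = metric, gene = g),
      error = function(e) NULL)
    if (!is.null(cp)) cuts[[g]] <- cp
  }
  cuts
}
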