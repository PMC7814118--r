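test_that("perfect separation yields Youden 1 between the clusters", {
  set.seed(1)
  expr <- c(runif(12, 3, 4), runif(12, 6, 7))
  events <- c(rep(0, 12), rep(1, 12))
  times <- c(runif(12, 50, 60), runif(12, 5, 10))
  cp <- optimal_cutpoint(expr, times, events)
  expect_equal(cp$metric_value, 1)
  expect_true(cp$cutpoint > 4 && cp$cutpoint < 6)
  expect_identical(cp$direction, "high_is_risk")
  expect_equal(cp$n_high, 12L)
})

test_that("cutpoint search equals the exhaustive-scan oracle", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    x <- if (i %% 3) rnorm(n) else sample(seq(0, 5, 0.5), n, TRUE)
    d <- random_surv_data(n)
    if (sum(d$events) == 0 || sum(d$events) == n) next
    cp <- tryCatch(optimal_cutpoint(x, d$times, d$events),
                   error = function(e) e)
    oracle <- brute_cutpoint_youden(x, d$events)
    if (inherits(cp, "error")) {
      # only legitimate for uninformative or inadmissible markers
      expect_true(is.null(oracle) || oracle$val < 1e-12)
      next
    }
    expect_equal(cp$cutpoint, oracle$cut, tolerance = 1e-12)
    expect_equal(cp$metric_value, oracle$val, tolerance = 1e-12)
  }
})

test_that("the induced partition is invariant to monotone transforms", {
  set.seed(6)
  x <- rnorm(50)
  d <- random_surv_data(50)
  cp1 <- optimal_cutpoint(x, d$times, d$events)
  cp2 <- optimal_cutpoint(exp(x), d$times, d$events)
  expect_identical(x > cp1$cutpoint, exp(x) > cp2$cutpoint)
  expect_identical(cp1$direction, cp2$direction)
})

test_that("concordance criterion agrees with a direct per-candidate scan", {
  set.seed(41)
  n <- 40
  x <- rnorm(n)
  d <- random_surv_data(n)
  cp <- optimal_cutpoint(x, d$times, d$events, metric = "concordance")
  ux <- sort(unique(x))
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  vals <- sapply(cand, function(cc) {
    n_low <- sum(x <= cc)
    if (min(n_low, n - n_low) < floor(0.1 * n)) return(NA_real_)
    ci <- as.numeric(harrell_c(d$times, d$events, as.numeric(x > cc)))
    max(ci, 1 - ci)
  })
  expect_equal(cp$metric_value, max(vals, na.rm = TRUE), tolerance = 1e-12)
})

test_that("degenerate markers and tiny cohorts are rejected", {
  d <- random_surv_data(30)
  expect_error(optimal_cutpoint(rep(1, 30), d$times, d$events),
               "uninformative")
  expect_error(optimal_cutpoint(rnorm(10), d$times[1:10], d$events[1:10]),
               "20 patients")
  expect_error(optimal_cutpoint(rnorm(30), d$times, rep(1, 30)),
               "uninformative")
})

test_that("stage-1 failures never reach stage 2 and gating is inclusive", {
  set.seed(77)
  sim <- simulate_cohort(simulation_config(n_patients = 250, seed = 77))
  coh <- sim$cohort
  truth <- sim$truth$prognostic
  cuts <- setNames(truth$cutpoint, truth$gene)
  # screen the 5 true genes plus 5 null genes at their medians
  nulls <- setdiff(mbs_gene_panel(), truth$gene)[1:5]
  for (g in nulls) cuts[g] <- median(coh$expression[g, ])
  sc <- suppressWarnings(screen_genes(coh, cuts))
  expect_s3_class(sc, "mbs_screening")
  gated <- !sc$failed & sc$p_uni > attr(sc, "alpha")
  expect_true(all(is.na(sc$hr_multi[gated])))  # never fitted in stage 2
  fitted2 <- !sc$failed & sc$p_uni <= attr(sc, "alpha")
  expect_true(all(!is.na(sc$p_multi[fitted2])))
  expect_true(all(sc$selected[!sc$failed] ==
                    (!is.na(sc$p_multi) & sc$p_multi <= 0.05)[!sc$failed]))
})

test_that("true prognostic genes are recovered at ground-truth cutpoints", {
  sim <- simulate_cohort(simulation_config(n_patients = 500, seed = 1))
  truth <- sim$truth$prognostic
  cuts <- setNames(truth$cutpoint, truth$gene)
  sc <- suppressWarnings(screen_genes(sim$cohort, cuts))
  expect_true(all(sc$selected[sc$gene %in% truth$gene]))
  # directions recovered from the multivariate hazard ratios
  m <- build_mbs(sc)
  comp <- m$components[m$components$gene %in% truth$gene, ]
  expect_identical(comp$direction,
                   truth$direction[match(comp$gene, truth$gene)])
})

test_that("null screening stays below the 37-alpha selection bound", {
  sel <- sapply(1:100, function(s) {
    coh <- simulate_null_cohort(120, seed = 3000 + s)
    cuts <- apply(coh$expression, 1, median)
    sc <- suppressWarnings(screen_genes(coh, cuts))
    sum(sc$selected)
  })
  expect_lt(mean(sel), 37 * 0.05)
})

test_that("tier percentages reproduce the published partition arithmetic", {
  pct <- tier_percentages(c(favourable = 28, intermediate = 60,
                            adverse = 71))
  expect_identical(unname(pct), c(18L, 38L, 44L))
  expect_identical(sum(pct), 100L)
  # generic property: always sums to 100
  set.seed(2)
  for (i in 1:20) {
    cnt <- sample(1:80, 3)
    expect_identical(sum(tier_percentages(cnt)), 100L)
  }
})

test_that("build_mbs maps multivariate hazard ratios to risk directions", {
  # the published five-gene screen: ANPEP/PKM hazardous when high,
  # ACLY/PANK1/SLC25A5 when low
  sc <- structure(data.frame(
    gene = c("PKM", "SLC25A5", "ACLY", "ANPEP", "PANK1", "GAD1"),
    cutpoint = c(7.1, 6.4, 6.5, 7.7, 6.3, 7.0),
    direction = NA_character_,
    n_high = 50L, n_low = 109L,
    hr_uni = c(2.24, 0.44, 0.38, 2.73, 0.42, 0.34),
    lower_uni = NA_real_, upper_uni = NA_real_,
    p_uni = c(0.01, 0.01, 0.002, 0.002, 0.01, 0.001),
    hr_multi = c(2.01, 0.49, 0.48, 2.16, 0.43, 0.73),
    lower_multi = NA_real_, upper_multi = NA_real_,
    p_multi = c(0.04, 0.05, 0.02, 0.02, 0.04, 0.47),
    selected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    failed = FALSE, stringsAsFactors = FALSE),
    class = c("mbs_screening", "data.frame"),
    alpha = 0.05, confounders = c("age", "gender", "ipssr"),
    n_used = 159L, n_dropped = 0L, ties = "efron")
  m <- build_mbs(sc)
  expect_equal(nrow(m$components), 5L)
  expect_identical(m$components$gene,
                   c("ACLY", "ANPEP", "PANK1", "PKM", "SLC25A5"))  # sorted
  expect_identical(
    setNames(m$components$direction, m$components$gene),
    c(ACLY = "low_is_risk", ANPEP = "high_is_risk", PANK1 = "low_is_risk",
      PKM = "high_is_risk", SLC25A5 = "low_is_risk"))

  # component order is independent of screening row order
  m2 <- build_mbs(sc[sample(nrow(sc)), ])
  expect_identical(m$components, m2$components)

  # degenerate single-component model warns about the unreachable tier
  sc1 <- sc
  sc1$selected <- sc1$gene == "PKM"
  expect_warning(m1 <- build_mbs(sc1), "unattainable")
  expect_equal(nrow(m1$components), 1L)

  sc0 <- sc
  sc0$selected <- FALSE
  expect_error(build_mbs(sc0), "cannot be built")
})

test_that("scoring counts risk factors and maps tiers deterministically", {
  comp <- data.frame(
    gene = c("ACLY", "ANPEP", "PANK1", "PKM", "SLC25A5"),
    cutpoint = rep(5, 5),
    direction = c("low_is_risk", "high_is_risk", "low_is_risk",
                  "high_is_risk", "low_is_risk"),
    stringsAsFactors = FALSE)
  model <- mbscore:::new_mbs_model(comp, alpha = 0.05)
  safe <- c(ACLY = 6, ANPEP = 4, PANK1 = 6, PKM = 4, SLC25A5 = 6)
  risky <- c(ACLY = 4, ANPEP = 6, PANK1 = 4, PKM = 6, SLC25A5 = 4)
  one <- safe; one["PKM"] <- 6
  expr <- cbind(P1 = safe, P2 = one, P3 = risky)
  clin <- data.frame(patient_id = c("P1", "P2", "P3"),
                     os_time = c(10, 20, 30), os_event = c(0, 1, 1))
  coh <- new_cohort(expr, clin)
  a <- score_patients(model, coh)
  expect_identical(a$score, c(0L, 1L, 5L))
  expect_identical(as.character(a$tier),
                   c("favourable", "intermediate", "adverse"))

  # boundary convention: expression exactly at the cutpoint is "low"
  at_cut <- safe; at_cut[c("ACLY", "ANPEP")] <- 5
  coh2 <- new_cohort(cbind(P1 = at_cut), clin[1, , drop = FALSE])
  a2 <- score_patients(model, coh2)
  expect_identical(a2$score, 1L)  # ACLY low (risk), ANPEP low (safe)

  # flipping any single component raises the score by exactly 1
  for (g in comp$gene) {
    flipped <- safe
    flipped[g] <- risky[g]
    cohf <- new_cohort(cbind(P1 = flipped), clin[1, , drop = FALSE])
    expect_identical(score_patients(model, cohf)$score, 1L)
  }
  expect_error(score_patients(model, make_cohort(c(1, 2), c(1, 0))),
               "absent")
})

test_that("tier survival curves are stochastically ordered at scale", {
  sim <- simulate_cohort(simulation_config(n_patients = 1000, seed = 99))
  truth <- sim$truth$prognostic
  model <- mbscore:::new_mbs_model(
    truth[, c("gene", "cutpoint", "direction")], alpha = 0.05)
  a <- score_patients(model, sim$cohort)
  dat <- merge(sim$cohort$clinical, a, by = "patient_id")
  s <- sapply(split(dat, dat$tier), function(d)
    survival_at(km_fit(d$os_time, d$os_event), c(24, 36)))
  tol <- 0.02
  expect_true(all(s[, "favourable"] >= s[, "intermediate"] - tol))
  expect_true(all(s[, "intermediate"] >= s[, "adverse"] - tol))
})
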