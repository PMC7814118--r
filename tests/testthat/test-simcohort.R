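test_that("identical configurations give byte-identical cohorts", {
  cfg <- simulation_config(n_patients = 60, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_null_cohort(30, seed = 9),
                   simulate_null_cohort(30, seed = 9))
})

test_that("no censoring means every patient has an observed event", {
  cfg <- simulation_config(n_patients = 100, censor_rate = 0,
                           admin_horizon = Inf, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$clinical$os_event == 1L))
})

test_that("degenerate and invalid configurations are caught", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  null_prog <- data.frame(gene = character(0), direction = character(0),
                          beta = numeric(0), quantile = numeric(0))
  expect_warning(simulate_cohort(
    simulation_config(n_patients = 30, prognostic = null_prog, seed = 1)),
    "null cohort")
  expect_error(simulation_config(
    n_patients = 10,
    prognostic = data.frame(gene = "PKM", direction = "high_is_risk",
                            beta = 0.5, quantile = 1.2)),
    "quantile")
})

test_that("null event fraction matches the exponential closed form", {
  # with no effects at all, P(event before T) = 1 - exp(-lambda0 * T)
  lam <- 0.02; horizon <- 48; n <- 2000
  cfg <- simulation_config(
    n_patients = n, baseline_hazard = lam, censor_rate = 0,
    admin_horizon = horizon, age_effect = 0, gender_effect = 0,
    ipssr_effects = rep(0, 5),
    prognostic = data.frame(gene = character(0), direction = character(0),
                            beta = numeric(0), quantile = numeric(0)),
    seed = 101)
  sim <- suppressWarnings(simulate_cohort(cfg))
  p <- 1 - exp(-lam * horizon)
  mc_se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(sim$cohort$clinical$os_event) - p), 3 * mc_se)
})

test_that("a single prognostic gene's log HR is recovered from true z", {
  cfg <- simulation_config(
    n_patients = 1000,
    prognostic = data.frame(gene = "PKM", direction = "high_is_risk",
                            beta = log(2), quantile = 0.5),
    age_effect = 0, gender_effect = 0, ipssr_effects = rep(0, 5),
    seed = 7)
  sim <- simulate_cohort(cfg)
  z <- unname(sim$truth$risk_count)  # single gene: count == indicator
  cl <- sim$cohort$clinical
  fit <- cox_fit(cl$os_time, cl$os_event, data.frame(z = z))
  expect_lt(abs(fit$terms$beta[1] - log(2)), 0.15)
})

test_that("stronger effects stochastically shorten risk-carriers' survival", {
  meds <- sapply(1:10, function(s) {
    sapply(c(0.4, 1.2), function(b) {
      cfg <- simulation_config(
        n_patients = 2000,
        prognostic = data.frame(gene = "PKM", direction = "high_is_risk",
                                beta = b, quantile = 0.5),
        censor_rate = 0, admin_horizon = Inf,
        age_effect = 0, gender_effect = 0, ipssr_effects = rep(0, 5),
        seed = s)
      sim <- simulate_cohort(cfg)
      carriers <- sim$truth$risk_count == 1L
      median(sim$cohort$clinical$os_time[carriers])
    })
  })
  # beta = 1.2 median below beta = 0.4 median in every seed
  expect_true(all(meds[2, ] < meds[1, ]))
})

test_that("null-cohort log-rank p-values are uniform", {
  pvals <- sapply(1:200, function(s) {
    coh <- simulate_null_cohort(100, n_genes = 5, seed = 1000 + s)
    g <- coh$expression[1 + (s %% 5), ]
    grp <- g > median(g)
    cl <- coh$clinical
    logrank(cl$os_time, cl$os_event, grp)$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("ground truth records population-quantile cutpoints", {
  cfg <- simulation_config(n_patients = 50, seed = 2)
  sim <- simulate_cohort(cfg)
  prog <- sim$truth$prognostic
  expect_equal(prog$cutpoint,
               7 + qnorm(prog$quantile))  # default gene mean 7, unit sd
  expect_true(all(sim$truth$risk_count >= 0 &
                    sim$truth$risk_count <= nrow(prog)))
})

test_that("healthy donors are appended with labels and shifted means", {
  cfg <- simulation_config(n_patients = 40, n_healthy = 17,
                           healthy_shift = c(PKM = -3), seed = 5)
  sim <- simulate_cohort(cfg)
  cl <- sim$cohort$clinical
  expect_equal(sum(cl$group_label == "healthy-donor"), 17L)
  expect_equal(n_patients(cohort_patients(sim$cohort)), 40L)
  hd <- cl$group_label == "healthy-donor"
  expect_lt(mean(sim$cohort$expression["PKM", hd]),
            mean(sim$cohort$expression["PKM", !hd]) - 1)
})

test_that("derived sub-seeds are deterministic, distinct and in range", {
  s1 <- derive_seed(42, "bootstrap-km")
  expect_identical(s1, derive_seed(42, "bootstrap-km"))
  expect_false(s1 == derive_seed(42, "delta-auc"))
  expect_false(s1 == derive_seed(43, "bootstrap-km"))
  big <- derive_seed(.Machine$integer.max, "delta-auc")
  expect_true(big >= 1 && big <= 2147483646)
})
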