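test_that("a tier without deaths bootstraps to 100% (100-100%)", {
  set.seed(8)
  n <- 90
  score <- rep(c(0, 1, 2), each = 30)
  times <- c(runif(30, 60, 100),                      # favourable: no deaths
             rexp(30, 0.02), rexp(30, 0.06))
  events <- c(rep(0, 30), rbinom(30, 1, 0.8), rbinom(30, 1, 0.9))
  coh <- make_cohort(times, events)
  a <- make_assignment(coh$clinical$patient_id, score)
  bs <- bootstrap_km(coh, a, R = 200, seed = 4)
  fav <- bs$table[bs$table$tier == "favourable", ]
  expect_true(all(fav$original == 1))
  expect_true(all(fav$boot_mean == 1))
  expect_true(all(fav$lower == 1 & fav$upper == 1))
  expect_true(all(bs$table$lower <= bs$table$boot_mean + 1e-12))
  expect_true(all(bs$table$upper >= bs$table$boot_mean - 1e-12))
  expect_true(all(bs$table$lower >= 0 & bs$table$upper <= 1))
})

test_that("BCa reduces to the percentile interval when z0 = 0 and a = 0", {
  # replicates symmetric around the original estimate, symmetric jackknife
  theta <- 0.5
  reps <- theta + c(-(50:1), 50:1) / 200
  jack <- theta + c(-(10:1), 10:1) / 100
  got <- mbscore:::bca_interval(reps, theta, jack, 0.95)
  expect_identical(got, unname(quantile(reps, c(0.025, 0.975), type = 7,
                                        names = FALSE)))
  # interval endpoints always lie within the replicate range
  set.seed(3)
  reps2 <- rbeta(500, 5, 2)
  jack2 <- rbeta(40, 5, 2)
  ci <- mbscore:::bca_interval(reps2, median(reps2) + 0.05, jack2, 0.95)
  expect_true(ci[1] >= min(reps2) && ci[2] <= max(reps2))
})

test_that("bootstrap summaries are reproducible and seed-stable", {
  set.seed(15)
  d <- random_surv_data(300)
  coh <- make_cohort(d$times, d$events)
  score <- sample(0:2, 300, TRUE)
  a <- make_assignment(coh$clinical$patient_id, score)
  b1 <- bootstrap_km(coh, a, R = 1000, horizons = c(5, 10), seed = 7)
  b2 <- bootstrap_km(coh, a, R = 1000, horizons = c(5, 10), seed = 7)
  expect_identical(b1$table, b2$table)
  b3 <- bootstrap_km(coh, a, R = 1000, horizons = c(5, 10), seed = 8)
  # different seed: intervals agree within Monte-Carlo jitter (< 2 points)
  expect_lt(max(abs(b1$table$lower - b3$table$lower), na.rm = TRUE), 0.02)
  expect_lt(max(abs(b1$table$upper - b3$table$upper), na.rm = TRUE), 0.02)
  expect_warning(bootstrap_km(coh, a, R = 50, seed = 1), "unstable")
})

test_that("delta-AUC self-comparison collapses to zero", {
  set.seed(5)
  labels <- rbinom(80, 1, 0.5); labels[1:2] <- c(0, 1)
  s <- rnorm(80)
  ac <- compare_auc_bootstrap(labels, s, s, R = 500, seed = 2)
  expect_equal(ac$delta, 0)
  expect_identical(c(ac$lower, ac$upper), c(0, 0))
  expect_equal(ac$p_value, 1)
})

test_that("delta-AUC separates a perfect score from noise", {
  set.seed(6)
  n <- 200
  labels <- rbinom(n, 1, 0.5); labels[1:2] <- c(0, 1)
  perfect <- labels + runif(n, 0, 0.5)
  noise <- rnorm(n)
  ac <- compare_auc_bootstrap(labels, perfect, noise, R = 2000, seed = 9)
  expect_equal(ac$auc_a, 1)
  expect_gt(ac$lower, 0)
  expect_lte(ac$p_value, 0.001)

  # antisymmetry under argument swap (same replicate schedule)
  ac2 <- compare_auc_bootstrap(labels, noise, perfect, R = 2000, seed = 9)
  expect_equal(ac2$delta, -ac$delta)
  expect_equal(c(ac2$lower, ac2$upper), c(-ac$upper, -ac$lower),
               tolerance = 1e-12)
})

test_that("confounder-free two-tier model nests the univariate Cox fit", {
  set.seed(12)
  n <- 100
  score <- rep(c(0, 2), each = n / 2)
  times <- rexp(n, 0.03 * exp(0.8 * (score > 0)))
  events <- rbinom(n, 1, 0.8)
  coh <- make_cohort(times, events)
  a <- make_assignment(coh$clinical$patient_id, score)
  mv <- final_multivariable(coh, a, confounders = character(0))
  uni <- cox_fit(times, events, data.frame(z = as.numeric(score > 0)))
  expect_equal(mv$fit$terms$beta[1], uni$terms$beta[1], tolerance = 1e-10)
  expect_equal(mv$fit$loglik, uni$loglik, tolerance = 1e-10)
})

test_that("multivariable model recovers tier and age effects", {
  set.seed(2)
  n <- 800
  tier_idx <- sample(0:2, n, TRUE, prob = c(0.25, 0.40, 0.35))
  age <- pmin(pmax(rnorm(n, 67, 10), 19), 87)
  beta_tier <- c(0, 0.7, 1.4)[tier_idx + 1]
  t_death <- rexp(n, 0.01 * exp(beta_tier + 0.03 * (age - 67)))
  t_cens <- pmin(rexp(n, 0.005), 120)
  times <- pmin(t_death, t_cens)
  events <- as.integer(t_death <= t_cens)
  coh <- make_cohort(times, events, extra = data.frame(age = age))
  a <- make_assignment(coh$clinical$patient_id,
                       ifelse(tier_idx == 2, 2, tier_idx))
  mv <- final_multivariable(coh, a, confounders = "age")
  terms <- mv$fit$terms
  expect_lt(abs(terms$beta[terms$term == "tierintermediate"] - 0.7), 0.2)
  expect_lt(abs(terms$beta[terms$term == "tieradverse"] - 1.4), 0.2)
  expect_lt(abs(terms$beta[terms$term == "age"] - 0.03), 0.01)
  # ranking is sorted by Wald chi-square and invariant to covariate order
  expect_true(all(diff(mv$ranking$wald_chisq) <= 1e-12))
})

test_that("a zero-event reference tier is flagged with a profile bound", {
  set.seed(30)
  n <- 120
  score <- rep(c(0, 2), c(40, 80))
  times <- c(runif(40, 80, 120), rexp(80, 0.05))
  events <- c(rep(0, 40), rbinom(80, 1, 0.9))
  coh <- make_cohort(times, events)
  a <- make_assignment(coh$clinical$patient_id, score)
  mv <- final_multivariable(coh, a, confounders = character(0))
  expect_true(any(mv$fit$monotone))
  expect_false(is.null(mv$profile_bounds))
  b <- mv$profile_bounds$bound[1]
  expect_true(is.finite(b))
  expect_identical(mv$profile_bounds$side[1], "lower")
  # the finite profile bound sits below the (diverging) point estimate
  expect_lt(b, mv$fit$terms$beta[mv$fit$terms$term == "tieradverse"])
})

test_that("favourable reference tier is mandatory", {
  d <- random_surv_data(40)
  coh <- make_cohort(d$times, d$events)
  a <- make_assignment(coh$clinical$patient_id, rep(c(1, 2), 20))
  expect_error(final_multivariable(coh, a, confounders = character(0)),
               "favourable")
})
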