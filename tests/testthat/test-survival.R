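test_that("log-rank statistic matches a hand-computed O-E/V oracle", {
  time <- c(3, 5, 7, 2, 4, 9)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  group <- c("a", "a", "a", "b", "b", "b")
  lr <- logrank_test(group, time, event)
  expect_equal(lr$statistic, oracle_logrank_2g(group, time, event),
               tolerance = 1e-9)
  expect_equal(lr$df, 1)
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))
})

test_that("identical event tables give a null log-rank and 3 groups are supported", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(TRUE, 8)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(group, time, event)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(8)
  g3 <- sample(c("x", "y", "z"), 60, replace = TRUE)
  t3 <- rexp(60, 0.1)
  lr3 <- logrank_test(g3, t3, rep(TRUE, 60))
  expect_equal(lr3$df, 2)
  expect_error(logrank_test(rep("a", 5), 1:5, rep(TRUE, 5)), "2 groups")
})

test_that("Kaplan-Meier median matches the product-limit oracle", {
  expect_equal(km_median(1:9, rep(TRUE, 9)), 5)
  expect_true(is.na(km_median(1:9, rep(FALSE, 9))))
  set.seed(14)
  for (i in 1:20) {
    n <- 40
    time <- rexp(n, 0.08)
    event <- runif(n) < 0.75
    if (sum(event) == 0) next
    expect_equal(km_median(time, event), oracle_km_median(time, event))
  }
})

test_that("Cox fit recovers a known per-SD hazard ratio and rejects bad input", {
  set.seed(77)
  n <- 500
  x <- rnorm(n)
  d <- simulate_survival(cbind(x), log(2), baseline_hazard = 0.04,
                         censor_window = 72)
  fit <- fit_cox(x, d$time, d$event)
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.4)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  expect_error(fit_cox(rep(1, n), d$time, d$event), "constant")
  expect_error(fit_cox(x[1:20], d$time[1:20], rep(FALSE, 20)), "10")
})

test_that("the Cox score test at beta = 0 reproduces the log-rank statistic", {
  set.seed(18)
  n <- 80
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.5 * g))
  event <- rep(TRUE, n)  # untied, uncensored: score test == log-rank
  fit <- survival::coxph(survival::Surv(time, event) ~ g)
  lr <- logrank_test(g, time, event)
  expect_equal(unname(fit$score), lr$statistic, tolerance = 1e-6)
})

test_that("restricted mean integrates survival curves exactly", {
  # exponential survival, closed form (1 - exp(-lambda*cap)) / lambda
  tt <- seq(0, 60, by = 0.005)
  rms <- restricted_mean(tt, exp(-0.1 * tt), cap = 60)
  expect_equal(rms, (1 - exp(-6)) / 0.1, tolerance = 1e-6 / 10)
  # vanishing hazard: restricted mean tends to the cap
  expect_equal(restricted_mean(tt, exp(-1e-9 * tt), cap = 60), 60,
               tolerance = 1e-6)
  # step function: exact rectangle areas
  expect_equal(restricted_mean(c(1, 2), c(0.5, 0.25), cap = 3,
                               stepfun = TRUE),
               1 * 1 + 1 * 0.5 + 1 * 0.25)
  expect_error(restricted_mean(tt, exp(-tt), cap = -1), "positive")
})

test_that("model-based RMS decreases in a harmful covariate and tracks the closed form", {
  set.seed(55)
  n <- 600
  x <- rnorm(n)
  lambda <- 0.1
  d <- simulate_survival(cbind(x), 0.5, baseline_hazard = lambda,
                         censor_window = 200)
  fit <- fit_cox(x, d$time, d$event, scale_feature = FALSE)
  curve <- rms_curve(fit, grid = c(-1, 0, 1), cap = 60)
  expect_true(all(diff(curve$rms) < 0))
  # at the covariate mean the model RMS approximates the exponential truth
  expect_equal(curve$rms[curve$value == 0], (1 - exp(-6)) / lambda,
               tolerance = 0.05)
  expect_error(rms_curve(fit, 0, cap = 0), "positive")
})

test_that("public-clone screen applies the Bonferroni rule over tested clones", {
  set.seed(40)
  cfg <- cohort_config(n_patients = 50, seed = 13, fast = TRUE,
                       n_public = 12, public_prob = 0.6)
  coh <- generate_cohort(cfg)
  cl <- coh$clinical
  res <- public_clone_screen(coh$tils, cl$pfs_months, cl$pfs_event,
                             stage = stage_stratum(cl$figo_stage),
                             min_share = 20)
  expect_gt(nrow(res), 1)
  m <- nrow(res)
  expect_equal(res$p_bonferroni, pmin(1, res$p * m))
  expect_true(all(res$p_bonferroni <= 1))
  expect_true(all(res$n_repertoires >= 20))

  # nothing passes an impossible threshold
  expect_message(
    empty <- public_clone_screen(coh$tils, cl$pfs_months, cl$pfs_event,
                                 min_share = 1000),
    "nothing to test")
  expect_equal(nrow(empty), 0)
})

test_that("serology interaction test is the deviance between nested Cox fits", {
  set.seed(66)
  n <- 400
  ov <- rnorm(n)
  sero <- rbinom(n, 1, 0.25) == 1
  beta_ov <- ifelse(sero, -0.4, 0.4)
  d <- simulate_survival(cbind(ov * beta_ov), 1, baseline_hazard = 0.05,
                         censor_window = 72)
  it <- serology_interaction_test(ov, sero, d$time, d$event)
  expect_equal(it$statistic,
               2 * (it$fit_full$loglik[2] - it$fit_reduced$loglik[2]))
  expect_equal(it$df, 1)
  expect_lt(it$p, 0.05)  # strong simulated sign reversal is detected

  expect_error(serology_interaction_test(ov, rep(TRUE, n), d$time, d$event),
               "both serostatus levels")
})

test_that("stratified fits recover opposite-sign overlap effects by serostatus", {
  cfg <- cohort_config(
    n_patients = 400, seed = 21, fast = TRUE,
    betas_overlap_by_serostatus = c(seropositive = -0.4, seronegative = 0.4))
  coh <- generate_cohort(cfg)
  cl <- coh$clinical
  sero <- coh$truth$serostatus
  adj <- data.frame(stage = coh$truth$stage_high)
  fit_pos <- fit_cox(coh$truth$overlap[sero], cl$pfs_months[sero],
                     cl$pfs_event[sero], adjust = adj[sero, , drop = FALSE])
  fit_neg <- fit_cox(coh$truth$overlap[!sero], cl$pfs_months[!sero],
                     cl$pfs_event[!sero], adjust = adj[!sero, , drop = FALSE])
  expect_lt(fit_pos$hr, 1)  # overlap protective in seropositives
  expect_gt(fit_neg$hr, 1)  # and harmful in seronegatives
})
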