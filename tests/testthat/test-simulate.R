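test_that("clone frequency laws behave at their limits", {
  u <- sample_frequencies(100, "zipf", exponent = 0)
  expect_equal(u, rep(0.01, 100))
  expect_equal(clonality(u), 0)
  # Zipf clonality grows with the exponent
  cl_s <- vapply(c(0.5, 1, 1.5), function(s) {
    clonality(sample_frequencies(200, "zipf", exponent = s))
  }, numeric(1))
  expect_true(all(diff(cl_s) > 0))
  # Dirichlet concentration limit: alpha -> Inf approaches uniform
  flat <- sample_frequencies(200, "dirichlet", alpha = 1e6, seed = 3)
  expect_lt(clonality(flat), 0.01)
  # and clonality decreases with alpha on average
  mean_cl <- function(a) {
    mean(vapply(1:50, function(s) {
      clonality(sample_frequencies(100, "dirichlet", alpha = a, seed = s))
    }, numeric(1)))
  }
  expect_gt(mean_cl(0.2), mean_cl(5))
  expect_error(sample_frequencies(10, "zipf", exponent = -1), "non-negative")
  expect_error(sample_frequencies(10, "dirichlet", alpha = 0), "positive")
  expect_error(sample_frequencies(0), "positive")
})

test_that("matched pairs share clones as configured", {
  cfg0 <- suppressWarnings(cohort_config(n_patients = 5, fast = TRUE,
                                         shared_fraction = 0,
                                         tumor_enrichment = 1))
  pair0 <- generate_matched_pair(cfg0, seed = 2)
  expect_equal(overlap_summary(pair0$pbmc, pair0$til)$shared_clones, 0)
  expect_equal(length(pair0$truth$shared_cdr3), 0)

  # full sharing with identical small pools and deep sampling: the PBMC
  # repertoire is (almost) entirely made of tumor clones
  cfg1 <- cohort_config(n_patients = 5, fast = TRUE,
                        shared_fraction = 1, tumor_enrichment = 1,
                        n_clones_til = c(200, 200),
                        n_clones_pbmc = c(200, 200),
                        depth_til = c(1e5, 1e5), depth_pbmc = c(1e5, 1e5))
  pair1 <- generate_matched_pair(cfg1, seed = 5)
  expect_gt(overlap_summary(pair1$pbmc, pair1$til)$clone_overlap_pbmc, 0.95)
})

test_that("tumor-selective sharing makes TIL-side overlap exceed PBMC-side overlap", {
  cfg <- cohort_config(n_patients = 5, fast = TRUE)
  ovs <- lapply(1:15, function(s) {
    pair <- generate_matched_pair(cfg, seed = 200 + s)
    overlap_summary(pair$pbmc, pair$til)
  })
  til_side <- vapply(ovs, `[[`, numeric(1), "clone_overlap_til")
  pbmc_side <- vapply(ovs, `[[`, numeric(1), "clone_overlap_pbmc")
  expect_gt(mean(til_side), mean(pbmc_side))
})

test_that("tumor enrichment concentrates the intended mass on shared clones", {
  cfg <- cohort_config(n_patients = 5, fast = TRUE, shared_fraction = 0.3,
                       tumor_enrichment = 5,
                       zipf_exponent_til = 0.8,
                       n_clones_til = c(2000, 2000))
  mass <- vapply(1:100, function(s) {
    tr <- generate_matched_pair(cfg, seed = s)$truth
    sum(tr$til_freq[match(tr$shared_cdr3, tr$til_cdr3)])
  }, numeric(1))
  e <- 5
  sf <- 0.3
  target <- e * sf / (1 - sf + e * sf)  # enrichment-weighted share of mass
  expect_equal(mean(mass), target, tolerance = 0.02)
})

test_that("observed clone frequencies converge to the generating frequencies", {
  cfg <- cohort_config(n_patients = 5, fast = TRUE,
                       n_clones_til = c(200, 200))
  dev <- vapply(c(1e3, 1e4, 1e5, 1e6), function(d) {
    pair <- generate_matched_pair(cfg, seed = 31, depth_til = d)
    obs <- pair$til$clones
    f_obs <- obs$frequency[match(pair$truth$til_cdr3, obs$cdr3_aa)]
    f_obs[is.na(f_obs)] <- 0
    max(abs(f_obs - pair$truth$til_freq))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 0.005)
})

test_that("simulated survival has the proportional-hazards null and limits", {
  set.seed(91)
  # under beta = 0 the log-rank p across random splits is uniform
  pvals <- vapply(1:200, function(i) {
    d <- simulate_survival(matrix(rnorm(50), ncol = 1), 0,
                           baseline_hazard = 0.05, censor_window = 72)
    g <- rep(c(0, 1), length.out = 50)
    logrank_test(g, d$time, d$event)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  # a vanishing censoring window censors everything
  d0 <- simulate_survival(matrix(rnorm(100), ncol = 1), 0.3,
                          baseline_hazard = 0.05, censor_window = 1e-6,
                          seed = 5)
  expect_true(all(!d0$event))
  expect_error(simulate_survival(matrix(0, 2, 1), 1, baseline_hazard = 0,
                                 censor_window = 10), "positive")
  expect_error(simulate_survival(matrix(0, 2, 1), Inf, baseline_hazard = 1,
                                 censor_window = 10), "finite")
})

test_that("cohorts are reproducible and respect clinical invariants", {
  cfg <- cohort_config(n_patients = 12, seed = 19, fast = TRUE)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  cl <- c1$clinical
  expect_equal(nrow(cl), 12)
  expect_true(all(cl$cd8_density <= cl$cd3_density))
  expect_true(all(cl$pfs_months > 0) && all(cl$os_months > 0))
  expect_true(all(as.character(cl$figo_stage) %in%
                    c("I", "II", "IIIA", "IIIB", "IIIC", "IV")))
  expect_true(all(vapply(c1$tils, n_clones, numeric(1)) > 0))
  # repertoires carry the right patient ids for pairing
  expect_equal(unname(vapply(c1$pbmcs, function(r) r$patient_id,
                             character(1))),
               cl$patient_id)
})

test_that("configuration validation catches infeasible settings", {
  expect_error(cohort_config(ihc_rho = 1.5), "correlation")
  expect_error(cohort_config(shared_fraction = 2), "0, 1")
  expect_error(cohort_config(baseline_hazard_pfs = -1), "positive")
  expect_warning(cohort_config(shared_fraction = 0, tumor_enrichment = 5),
                 "no effect")
  expect_error(cohort_config(nonsense = 1), "unknown configuration")
})
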