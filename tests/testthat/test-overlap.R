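test_that("overlap summary matches the worked example", {
  pbmc <- repertoire(c("CAAF", "CCCF", "CDDF", "CEEF"), c(50, 30, 15, 5),
                     compartment = "PBMC", patient_id = "P1")
  til <- repertoire(c("CAAF", "CGGF"), c(80, 20), patient_id = "P1")
  o <- overlap_summary(pbmc, til)
  expect_equal(o$shared_clones, 1)
  expect_equal(o$clone_overlap_pbmc, 0.25)
  expect_equal(o$read_overlap_pbmc, 0.50)
  expect_equal(o$clone_overlap_til, 0.5)
  expect_equal(o$read_overlap_til, 0.8)
  expect_equal(o$pbmc_exclusive_reads, 0.50)
  expect_equal(o$pbmc_exclusive_clones, 0.75)
})

test_that("identical and disjoint repertoires give the extreme overlaps", {
  a <- repertoire(c("CAAF", "CCCF"), c(70, 30), compartment = "PBMC")
  b <- repertoire(c("CAAF", "CCCF"), c(10, 90))
  o <- overlap_summary(a, b)
  expect_equal(o$clone_overlap_pbmc, 1)
  expect_equal(o$read_overlap_pbmc, 1)
  expect_equal(o$pbmc_exclusive_reads, 0)

  d <- repertoire(c("CHHF", "CKKF"), c(10, 90))
  o2 <- overlap_summary(a, d)
  expect_equal(o2$shared_clones, 0)
  expect_equal(o2$clone_overlap_pbmc, 0)
  expect_equal(o2$read_overlap_til, 0)
  expect_equal(o2$pbmc_exclusive_reads, 1)
})

test_that("mismatched patients and empty repertoires are rejected", {
  a <- repertoire("CAAF", 10, patient_id = "P1", compartment = "PBMC")
  b <- repertoire("CAAF", 10, patient_id = "P2")
  expect_error(overlap_summary(a, b), "pairing error")
})

test_that("overlap fields agree with a brute-force set oracle on random pairs", {
  set.seed(21)
  for (i in 1:40) {
    # draw from a small id pool so the pair shares clones by construction
    pbmc <- random_repertoire(sample(5:120, 1), patient = "P1",
                              compartment = "PBMC", id_pool = 300)
    til <- random_repertoire(sample(5:120, 1), patient = "P1",
                             id_pool = 300)
    o <- overlap_summary(pbmc, til)
    e <- oracle_overlap(pbmc, til)
    expect_equal(o$shared_clones, e$shared_clones)
    expect_equal(o$clone_overlap_pbmc, e$clone_overlap_pbmc, tolerance = 1e-9)
    expect_equal(o$clone_overlap_til, e$clone_overlap_til, tolerance = 1e-9)
    expect_equal(o$read_overlap_pbmc, e$read_overlap_pbmc, tolerance = 1e-9)
    expect_equal(o$read_overlap_til, e$read_overlap_til, tolerance = 1e-9)
    expect_equal(o$pbmc_exclusive_reads, 1 - e$read_overlap_pbmc,
                 tolerance = 1e-12)
    expect_lte(o$shared_clones, min(n_clones(pbmc), n_clones(til)))
  }
})

test_that("read-level overlap exceeds clone-level overlap when shared clones dominate", {
  # one abundant shared clone among many rare exclusive ones
  pbmc <- repertoire(c("CAAF", seq_for_id(1:20)), c(500, rep(5, 20)),
                     compartment = "PBMC")
  til <- repertoire("CAAF", 100)
  o <- overlap_summary(pbmc, til)
  expect_gt(o$read_overlap_pbmc, o$clone_overlap_pbmc)
})

test_that("diversity ratio is seeded, reproducible and validates depth", {
  rep1 <- random_repertoire(100, integer_copies = TRUE, patient = "P1",
                            compartment = "PBMC")
  rep2 <- repertoire(rep1$clones$cdr3_aa, rep1$clones$copies,
                     patient_id = "P1")
  # identical clone tables rarefied with the same seed give ratio 1
  expect_equal(diversity_ratio(rep1, rep2, depth = 50, seed = 3), 1)
  r1 <- diversity_ratio(rep1, random_repertoire(40, integer_copies = TRUE,
                                                patient = "P1"),
                        depth = 30, seed = 9)
  # bit-for-bit reproducibility under a fixed seed
  set.seed(1)
  rep3 <- random_repertoire(40, integer_copies = TRUE, patient = "P1")
  set.seed(99)  # unrelated global state must not matter
  expect_identical(diversity_ratio(rep1, rep3, depth = 30, seed = 123),
                   diversity_ratio(rep1, rep3, depth = 30, seed = 123))
  expect_error(diversity_ratio(rep1, rep3, depth = 1e9), "depth")
})

test_that("a single-clone TIL repertoire floors the rarefied ratio at the PBMC count", {
  pbmc <- repertoire(seq_for_id(1:100), rep(10, 100), compartment = "PBMC")
  til <- repertoire("CAAF", 1000)
  r <- diversity_ratio(pbmc, til, depth = 50, seed = 2)
  expect_gte(r, 1)  # TIL rarefied count is exactly 1
})

test_that("mean rarefied clone count matches the hypergeometric expectation", {
  set.seed(33)
  counts <- ceiling(runif(60, 1, 20))
  rep <- repertoire(seq_for_id(1:60), counts, compartment = "PBMC")
  til <- repertoire("CAAF", sum(counts))  # rarefied count 1, exposes the numerator
  d <- 150
  ratios <- vapply(1:100, function(s) {
    diversity_ratio(rep, til, depth = d, seed = s)
  }, numeric(1))
  expected <- oracle_rarefied_clones(counts, d)
  expect_equal(mean(ratios), expected, tolerance = 0.02)
})

test_that("per-clone frequency changes use log2 ratios with infinite sentinels", {
  pbmc <- repertoire(c("CAAF", "CCCF", "CDDF"), c(10, 50, 40),
                     compartment = "PBMC")
  til <- repertoire(c("CAAF", "CCCF", "CEEF"), c(40, 50, 10))
  tab <- per_clone_change(pbmc, til)
  expect_equal(tab$log2_ratio[tab$cdr3_aa == "CAAF"], 2)
  expect_equal(tab$log2_ratio[tab$cdr3_aa == "CCCF"], 0)
  expect_equal(tab$log2_ratio[tab$cdr3_aa == "CEEF"], Inf)   # TIL-exclusive
  expect_equal(tab$freq_pbmc[tab$cdr3_aa == "CEEF"], 0)
  expect_equal(tab$log2_ratio[tab$cdr3_aa == "CDDF"], -Inf)  # PBMC-exclusive
  # shared clones first, by decreasing absolute change
  shared <- tab[tab$shared, ]
  expect_equal(shared$cdr3_aa, c("CAAF", "CCCF"))
  expect_true(all(which(tab$shared) < which(!tab$shared)))
})

test_that("sharing table counts repertoires and averages over carriers only", {
  r1 <- repertoire(c("CAAF", "CCCF"), c(30, 70), patient_id = "P1")
  r2 <- repertoire(c("CAAF", "CDDF"), c(50, 50), patient_id = "P2")
  r3 <- repertoire(c("CAAF", "CEEF"), c(10, 90), patient_id = "P3")
  st <- sharing_table(list(r1, r2, r3))
  expect_equal(st$n_repertoires[st$cdr3_aa == "CAAF"], 3)
  expect_equal(st$mean_frequency[st$cdr3_aa == "CAAF"],
               mean(c(0.3, 0.5, 0.1)))
  expect_equal(st$mean_frequency[st$cdr3_aa == "CCCF"], 0.7)
  st2 <- sharing_table(list(r1, r2, r3), min_share = 2)
  expect_equal(st2$cdr3_aa, "CAAF")
  expect_error(sharing_table(list(r1, r1)), "duplicate patient ids")
})
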