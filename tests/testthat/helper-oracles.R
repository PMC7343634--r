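# Independent brute-force oracles and fixture builders shared by the tests.
# The oracles are deliberately written as plain loops over the definitions,
# not via the package's own code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic unique CDR3-like sequence for an integer id (base-20 digits)
seq_for_id <- function(i, len = 6) {
  vapply(i, function(x) {
    d <- integer(len)
    for (j in seq_len(len)) {
      d[j] <- x %% 20
      x <- x %/% 20
    }
    paste0("C", paste(AA20[d + 1], collapse = ""), "F")
  }, character(1))
}

random_repertoire <- function(n, max_copies = 1000, patient = "P1",
                              compartment = "TIL", integer_copies = FALSE,
                              id_pool = 10^6) {
  copies <- runif(n, 0.5, max_copies)
  if (integer_copies) copies <- ceiling(copies)
  repertoire(seq_for_id(sample.int(id_pool, n)), copies,
             patient_id = patient, compartment = compartment)
}

oracle_entropy <- function(p) {
  h <- 0
  for (x in p) {
    if (x > 0) h <- h - x * log2(x)
  }
  h
}

oracle_clonality <- function(p) {
  if (length(p) == 1) return(1)
  1 - oracle_entropy(p) / log2(length(p))
}

oracle_n25 <- function(p) {
  p <- sort(p, decreasing = TRUE)
  acc <- 0
  for (k in seq_along(p)) {
    acc <- acc + p[k]
    if (acc > 0.25 + 1e-9) return(k)
  }
  length(p)
}

oracle_overlap <- function(pbmc, til) {
  pb <- pbmc$clones
  tl <- til$clones
  shared <- character(0)
  for (s in pb$cdr3_aa) {
    if (s %in% tl$cdr3_aa) shared <- c(shared, s)
  }
  read_pb <- 0
  for (i in seq_len(nrow(pb))) {
    if (pb$cdr3_aa[i] %in% shared) read_pb <- read_pb + pb$frequency[i]
  }
  read_tl <- 0
  for (i in seq_len(nrow(tl))) {
    if (tl$cdr3_aa[i] %in% shared) read_tl <- read_tl + tl$frequency[i]
  }
  list(shared_clones = length(shared),
       clone_overlap_pbmc = length(shared) / nrow(pb),
       clone_overlap_til = length(shared) / nrow(tl),
       read_overlap_pbmc = read_pb,
       read_overlap_til = read_tl)
}

# product-limit survival curve: returns step function values at event times
oracle_km <- function(time, event) {
  o <- order(time)
  time <- time[o]
  event <- event[o]
  uts <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(uts))
  for (k in seq_along(uts)) {
    t <- uts[k]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = uts, surv = surv)
}

oracle_km_median <- function(time, event) {
  km <- oracle_km(time, event)
  i <- which(km$surv <= 0.5)
  if (length(i) == 0) NA_real_ else km$time[i[1]]
}

# two-group log-rank statistic by direct O - E / V summation
oracle_logrank_2g <- function(group, time, event) {
  g <- as.integer(as.factor(group))
  uts <- sort(unique(time[event]))
  O <- 0
  E <- 0
  V <- 0
  for (t in uts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# closed-form expected number of unique clones after rarefying integer
# counts c to depth d without replacement
oracle_rarefied_clones <- function(counts, d) {
  total <- sum(counts)
  sum(1 - exp(lchoose(total - counts, d) - lchoose(total, d)))
}

make_clinical <- function(n, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    cd3 <- exp(rnorm(n, log(100), 1))
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      figo_stage = sample(c("I", "II", "IIIA", "IIIB", "IIIC", "IV"), n,
                          replace = TRUE, prob = c(.1, .1, .05, .05, .5, .2)),
      cd3_density = cd3, cd8_density = cd3 * runif(n, 0.1, 0.9),
      titer_nyeso1 = ifelse(runif(n) < 0.25, 500, 50),
      titer_magea1 = ifelse(runif(n) < 0.1, 300, 10),
      titer_magea3 = ifelse(runif(n) < 0.1, 300, 10),
      titer_p53 = ifelse(runif(n) < 0.1, 300, 10),
      pfs_months = rexp(n, 1 / 15) + 0.1, pfs_event = runif(n) < 0.7,
      os_months = rexp(n, 1 / 40) + 0.1, os_event = runif(n) < 0.5,
      platinum_sensitive = runif(n) < 0.5,
      stringsAsFactors = FALSE)
  })
}
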