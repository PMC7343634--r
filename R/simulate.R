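#' Draw a clone frequency vector from a heavy-tailed law
#'
#' Generates the latent relative frequencies of a repertoire either from a
#' Zipf power law (p_k proportional to k^-s; s = 0 gives a uniform
#' repertoire, larger s a more clonal one) or from a symmetric Dirichlet
#' distribution (small alpha gives a skewed repertoire, alpha -> Inf tends
#' to uniform).
#'
#' @param n_clones_count number of clones (>= 1).
#' @param law `"zipf"` or `"dirichlet"`.
#' @param exponent Zipf exponent s >= 0.
#' @param alpha Dirichlet concentration > 0.
#' @param seed optional integer seed (only the Dirichlet law is random).
#' @return Frequency vector sorted in descending order, summing to 1.
#' @export
sample_frequencies <- function(n_clones_count, law = c("zipf", "dirichlet"),
                               exponent = 1, alpha = 1, seed = NULL) {
  law <- match.arg(law)
  if (!is.numeric(n_clones_count) || n_clones_count < 1) {
    stop("`n_clones_count` must be a positive integer", call. = FALSE)
  }
  if (law == "zipf") {
    if (!is.finite(exponent) || exponent < 0) {
      stop("Zipf exponent must be a finite non-negative number",
           call. = FALSE)
    }
    p <- seq_len(n_clones_count)^(-exponent)
    p / sum(p)
  } else {
    if (!is.finite(alpha) || alpha <= 0) {
      stop("Dirichlet concentration must be strictly positive",
           call. = FALSE)
    }
    with_seed(seed, {
      g <- rgamma(n_clones_count, shape = alpha)
      sort(g / sum(g), decreasing = TRUE)
    })
  }
}

# random CDR3-like amino-acid sequences: initial C, terminal F, 6-12
# variable residues; guaranteed unique within the returned vector
random_cdr3 <- function(n) {
  draw <- function(k) {
    len <- sample(6:12, k, replace = TRUE)
    out <- character(k)
    for (l in unique(len)) {
      idx <- which(len == l)
      m <- matrix(sample(AA_ALPHABET, length(idx) * l, replace = TRUE),
                  nrow = length(idx))
      body <- do.call(paste0, lapply(seq_len(l), function(j) m[, j]))
      out[idx] <- paste0("C", body, "F")
    }
    out
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}

#' Configuration for the synthetic matched-cohort generator
#'
#' Defaults emulate the structure of a 99-patient ovarian cancer cohort
#' with matched TIL and PBMC compartments: heavy-tailed (Zipf) clone
#' frequencies that are more clonal at the tumor site, thousands to tens
#' of thousands of TIL clones against a much larger peripheral pool,
#' log-uniform sequencing depths within the printed coverage range, 30% of
#' TIL clones also seeded in the blood with 5-fold tumor-site enrichment,
#' CD3 infiltration density rank-correlated with TIL read depth (Spearman
#' 0.34), 25% NY-ESO-1 seroprevalence (about 38% positive for at least one
#' of four antigens), and exponential proportional-hazards survival driven
#' by repertoire-derived covariates.  `fast = TRUE` scales read depths
#' down 100-fold and clone pools 10-fold for quick end-to-end runs; the
#' statistical structure is unchanged.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; a fixed seed gives a byte-identical cohort.
#' @param fast use down-scaled depths and clone pools.
#' @param ... overrides for any default listed below.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 99, seed = 1, fast = FALSE, ...) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    clone_law = "zipf",
    zipf_exponent_til = 1.0, zipf_exponent_pbmc = 0.85,
    dirichlet_alpha = 1,
    n_clones_til = c(3000, 16000), n_clones_pbmc = c(60000, 100000),
    depth_til = c(2e4, 5e6), depth_pbmc = c(1e6, 8e6),
    shared_fraction = 0.3, tumor_enrichment = 5, shared_rank_weight = 0.5,
    n_public = 40, public_prob = 0.25,
    ihc_rho = 0.34, cd3_meanlog = log(100), cd3_sdlog = 1.1,
    cd8_beta_shape = c(2, 5),
    sero_prevalence = c(nyeso1 = 0.25, magea1 = 0.06, magea3 = 0.06,
                        p53 = 0.06),
    stage_probs = c(I = 0.08, II = 0.07, IIIA = 0.04, IIIB = 0.04,
                    IIIC = 0.57, IV = 0.20),
    serous_prob = 0.66, platinum_prob = 0.55,
    betas = c(focus_cd3 = 0, clone_overlap_pbmc = 0, stage_high = 0.7),
    betas_overlap_by_serostatus = NULL,
    baseline_hazard_pfs = 0.045, baseline_hazard_os = 0.014,
    censor_window = 72)
  if (fast) {
    cfg$depth_til <- cfg$depth_til / 100
    cfg$depth_pbmc <- cfg$depth_pbmc / 100
    cfg$n_clones_til <- cfg$n_clones_til / 20
    cfg$n_clones_pbmc <- cfg$n_clones_pbmc / 20
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    stop("`shared_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (cfg$tumor_enrichment < 1) {
    stop("`tumor_enrichment` must be >= 1", call. = FALSE)
  }
  if (cfg$shared_fraction == 0 && cfg$tumor_enrichment != 1) {
    warning("`tumor_enrichment` has no effect when `shared_fraction` is 0",
            call. = FALSE)
  }
  if (abs(cfg$ihc_rho) > 1) {
    stop("`ihc_rho` must be a correlation in [-1, 1]", call. = FALSE)
  }
  if (cfg$baseline_hazard_pfs <= 0 || cfg$baseline_hazard_os <= 0) {
    stop("baseline hazards must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(cfg$betas))) {
    stop("log hazard ratios in `betas` must be finite", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

draw_pool_freq <- function(n, config, compartment) {
  if (config$clone_law == "zipf") {
    s <- if (compartment == "TIL") config$zipf_exponent_til else
      config$zipf_exponent_pbmc
    sample_frequencies(n, "zipf", exponent = s)
  } else {
    sample_frequencies(n, "dirichlet", alpha = config$dirichlet_alpha)
  }
}

#' Generate one patient's matched TIL/PBMC repertoire pair
#'
#' Draws latent clone pools for both compartments from the configured
#' frequency law, seeds a `shared_fraction` of the TIL clones into the
#' PBMC pool (placed on blood clones chosen with probability proportional
#' to frequency^`shared_rank_weight`, so shared clones tend to be common
#' in the blood too), multiplies the TIL frequencies of shared clones by
#' `tumor_enrichment` and renormalizes, then samples reads multinomially
#' at the two depths.  The returned truth records the intended shared set
#' and the generating (pre-sampling) frequencies.
#'
#' @param config a [cohort_config()].
#' @param patient_id identifier attached to both repertoires.
#' @param seed optional integer seed; `NULL` uses the current RNG stream
#'   (as when called from [generate_cohort()]).
#' @param depth_til,depth_pbmc optional fixed read depths; drawn
#'   log-uniformly from the configured ranges when `NULL`.
#' @param public_clones optional character vector of cohort-level public
#'   CDR3 sequences to place into the TIL pool (each carried with
#'   probability `config$public_prob`).
#' @return List with elements `til`, `pbmc` (observed `tcr_repertoire`
#'   objects) and `truth` (generating pools, frequencies, shared set,
#'   depths).
#' @export
generate_matched_pair <- function(config, patient_id = "P001", seed = NULL,
                                  depth_til = NULL, depth_pbmc = NULL,
                                  public_clones = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n_til <- round(rloguniform(1, config$n_clones_til))
    n_pbmc <- round(rloguniform(1, config$n_clones_pbmc))
    if (is.null(depth_til)) depth_til <- round(rloguniform(1, config$depth_til))
    if (is.null(depth_pbmc)) {
      depth_pbmc <- round(rloguniform(1, config$depth_pbmc))
    }
    til_freq <- draw_pool_freq(n_til, config, "TIL")
    til_ids <- random_cdr3(n_til)
    if (!is.null(public_clones) && length(public_clones) > 0) {
      carried <- public_clones[runif(length(public_clones)) < config$public_prob]
      if (length(carried) > 0) {
        slots <- sample.int(n_til, min(length(carried), n_til))
        til_ids[slots] <- carried[seq_along(slots)]
      }
    }
    n_shared <- round(config$shared_fraction * n_til)
    shared_idx <- if (n_shared > 0) sample.int(n_til, n_shared) else integer(0)
    if (n_shared > 0 && config$tumor_enrichment != 1) {
      til_freq[shared_idx] <- til_freq[shared_idx] * config$tumor_enrichment
      til_freq <- til_freq / sum(til_freq)
    }
    pbmc_freq <- draw_pool_freq(n_pbmc, config, "PBMC")
    pbmc_ids <- random_cdr3(n_pbmc)
    if (n_shared > 0) {
      # weighted sampling without replacement via exponential keys
      # (equivalent to successive draws with prob proportional to w)
      w <- pbmc_freq^config$shared_rank_weight
      keys <- rexp(n_pbmc) / w
      k <- min(n_shared, n_pbmc)
      slots <- order(keys)[seq_len(k)]
      pbmc_ids[slots] <- til_ids[shared_idx][seq_len(k)]
    }
    til_counts <- as.vector(rmultinom(1, depth_til, til_freq))
    pbmc_counts <- as.vector(rmultinom(1, depth_pbmc, pbmc_freq))
    obs_t <- til_counts > 0
    obs_p <- pbmc_counts > 0
    list(
      til = repertoire(til_ids[obs_t], til_counts[obs_t],
                       patient_id = patient_id, compartment = "TIL",
                       validate = FALSE),
      pbmc = repertoire(pbmc_ids[obs_p], pbmc_counts[obs_p],
                        patient_id = patient_id, compartment = "PBMC",
                        validate = FALSE),
      truth = list(shared_cdr3 = til_ids[shared_idx],
                   til_cdr3 = til_ids, til_freq = til_freq,
                   pbmc_cdr3 = pbmc_ids, pbmc_freq = pbmc_freq,
                   depth_til = depth_til, depth_pbmc = depth_pbmc))
  })
}

#' Simulate proportional-hazards survival endpoints
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(x %*% betas)`; censoring times are independent
#' uniform on (0, `censor_window`].  An observation is an event when the
#' event time does not exceed the censoring time.
#'
#' @param x numeric covariate matrix (or vector), typically z-scored.
#' @param betas log hazard ratios, one per column of `x`.
#' @param baseline_hazard events per month for a covariate profile of 0
#'   (> 0).
#' @param censor_window months of administrative follow-up.
#' @param seed optional integer seed.
#' @return Data frame with columns `time` (months) and `event` (logical).
#' @export
simulate_survival <- function(x, betas, baseline_hazard, censor_window,
                              seed = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(betas))) {
    stop("`betas` must be finite", call. = FALSE)
  }
  if (!is.finite(baseline_hazard) || baseline_hazard <= 0) {
    stop("`baseline_hazard` must be strictly positive", call. = FALSE)
  }
  stopifnot(ncol(x) == length(betas))
  lp <- drop(x %*% betas)
  with_seed(seed, {
    n <- nrow(x)
    t_event <- rexp(n, rate = baseline_hazard * exp(lp))
    t_cens <- runif(n, 0, censor_window)
    data.frame(time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
               event = t_event <= t_cens)
  })
}

#' Generate a synthetic matched cohort
#'
#' Produces, for each patient, matched TIL/PBMC repertoires (see
#' [generate_matched_pair()]) and a clinical record.  CD3 density and TIL
#' read depth are linked through a Gaussian copula whose correlation is
#' calibrated so their Spearman correlation matches `ihc_rho`; CD8 is a
#' Beta-distributed fraction of CD3; per-antigen serostatus is Bernoulli
#' with the configured prevalences, with reciprocal titers drawn above or
#' below the 100 cut-point accordingly.  Survival endpoints (PFS and OS)
#' are simulated under proportional hazards from the z-scored focus ratio
#' and TIL/PBMC clone overlap of the *observed* repertoires, plus the
#' high-stage indicator; the overlap effect may differ by NY-ESO-1
#' serostatus (`betas_overlap_by_serostatus`, named `seropositive` /
#' `seronegative`) to emulate antigen-dependent sign reversal.  Fixed
#' seeds give byte-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A list of class `tcr_cohort` with elements `clinical` (data
#'   frame), `tils`, `pbmcs` (named lists of repertoires), and `truth`
#'   (generating features, linear predictor, per-patient pool truths,
#'   public clone set, and the betas used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    public_clones <- random_cdr3(config$n_public)

    # Gaussian copula linking TIL depth and CD3 density at the target
    # Spearman correlation (Pearson rho = 2 sin(pi rho_s / 6))
    rho_p <- 2 * sin(pi * config$ihc_rho / 6)
    z1 <- rnorm(n)
    z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * rnorm(n)
    depth_til <- round(qloguniform(pnorm(z1), config$depth_til))
    cd3 <- qlnorm(pnorm(z2), config$cd3_meanlog, config$cd3_sdlog)
    cd8 <- cd3 * rbeta(n, config$cd8_beta_shape[1], config$cd8_beta_shape[2])

    stage <- sample(names(config$stage_probs), n, replace = TRUE,
                    prob = config$stage_probs)
    histology <- ifelse(runif(n) < config$serous_prob, "serous", "non-serous")
    platinum <- runif(n) < config$platinum_prob
    titers <- lapply(config$sero_prevalence, function(prev) {
      pos <- runif(n) < prev
      round(ifelse(pos, 10^runif(n, 2.02, 3.5), 10^runif(n, 0, 2)), 1)
    })

    pairs <- lapply(seq_len(n), function(i) {
      generate_matched_pair(config, patient_id = ids[i],
                            depth_til = depth_til[i],
                            public_clones = public_clones)
    })
    tils <- lapply(pairs, `[[`, "til")
    pbmcs <- lapply(pairs, `[[`, "pbmc")
    names(tils) <- names(pbmcs) <- ids

    focus <- vapply(tils, n_clones, numeric(1)) / cd3
    ov <- vapply(seq_len(n), function(i) {
      overlap_summary(pbmcs[[i]], tils[[i]])$clone_overlap_pbmc
    }, numeric(1))
    z_focus <- standardize(focus)
    z_overlap <- standardize(ov)
    sero <- titers$nyeso1 > 100
    stage_high <- as.numeric(stage %in% c("IIIC", "IV"))

    split <- config$betas_overlap_by_serostatus
    if (is.null(split)) {
      x <- cbind(focus = z_focus, overlap = z_overlap, stage = stage_high)
      b <- c(config$betas[["focus_cd3"]],
             config$betas[["clone_overlap_pbmc"]],
             config$betas[["stage_high"]])
    } else {
      x <- cbind(focus = z_focus,
                 overlap_pos = z_overlap * sero,
                 overlap_neg = z_overlap * (1 - sero),
                 stage = stage_high)
      b <- c(config$betas[["focus_cd3"]],
             split[["seropositive"]], split[["seronegative"]],
             config$betas[["stage_high"]])
    }
    pfs <- simulate_survival(x, b, config$baseline_hazard_pfs,
                             config$censor_window)
    os <- simulate_survival(x, b, config$baseline_hazard_os,
                            config$censor_window)

    clinical <- data.frame(
      patient_id = ids,
      figo_stage = factor(stage, levels = FIGO_STAGES),
      histology = histology,
      cd3_density = round(cd3, 1), cd8_density = round(cd8, 1),
      titer_nyeso1 = titers$nyeso1, titer_magea1 = titers$magea1,
      titer_magea3 = titers$magea3, titer_p53 = titers$p53,
      pfs_months = round(pfs$time, 3), pfs_event = pfs$event,
      os_months = round(os$time, 3), os_event = os$event,
      platinum_sensitive = platinum,
      stringsAsFactors = FALSE)

    structure(list(
      clinical = clinical, tils = tils, pbmcs = pbmcs,
      truth = list(z_focus = unname(z_focus), z_overlap = unname(z_overlap),
                   focus = unname(focus), overlap = unname(ov),
                   serostatus = unname(sero), stage_high = stage_high,
                   lp = drop(x %*% b), betas = b,
                   public_clones = public_clones,
                   pairs = lapply(pairs, `[[`, "truth"))),
      class = "tcr_cohort")
  })
}

#' @export
print.tcr_cohort <- function(x, ...) {
  n <- nrow(x$clinical)
  cat(sprintf("Synthetic matched TCR cohort: %d patients\n", n))
  cat(sprintf("  TIL clones (median): %.0f; PBMC clones (median): %.0f\n",
              median(vapply(x$tils, n_clones, numeric(1))),
              median(vapply(x$pbmcs, n_clones, numeric(1)))))
  cat(sprintf("  PFS events: %d; OS events: %d; NY-ESO-1 seropositive: %d\n",
              sum(x$clinical$pfs_event), sum(x$clinical$os_event),
              sum(x$clinical$titer_nyeso1 > 100)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' Emits one clone table per repertoire (`<patient>_TIL.tsv`,
#' `<patient>_PBMC.tsv`), the clinical table (`clinical.tsv`) and a truth
#' table of generating features (`truth_features.tsv`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$tils)) {
    write_repertoire_table(cohort$tils[[id]],
                           file.path(dir, paste0(id, "_TIL.tsv")))
    write_repertoire_table(cohort$pbmcs[[id]],
                           file.path(dir, paste0(id, "_PBMC.tsv")))
  }
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- data.frame(patient_id = cohort$clinical$patient_id,
                      z_focus = cohort$truth$z_focus,
                      z_overlap = cohort$truth$z_overlap,
                      serostatus = cohort$truth$serostatus,
                      lp = cohort$truth$lp)
  write.table(truth, file.path(dir, "truth_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
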