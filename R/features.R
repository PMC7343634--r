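#' Impute CD4 T-cell density from CD3 and CD8 stains
#'
#' CD4 density is imputed as the difference between the CD3 (pan T-cell)
#' and CD8 densities.  When measurement noise puts CD8 above CD3 the
#' difference is clamped at 0 with a warning.
#'
#' @param cd3,cd8 numeric densities (lymphocytes/mm^2); vectorized.
#' @return Imputed CD4 density.
#' @export
impute_cd4 <- function(cd3, cd8) {
  out <- cd3 - cd8
  if (any(out < 0, na.rm = TRUE)) {
    warning(sum(out < 0, na.rm = TRUE),
            " patient(s) with CD8 density above CD3; CD4 clamped at 0",
            call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Focus ratio: unique TIL clones per infiltrating T cell
#'
#' The ratio of the number of unique TIL clonotypes to the IHC-measured
#' T-cell density (lymphocytes/mm^2).  Ratios closer to zero indicate a
#' more focal, monoclonal infiltrate; large ratios imply a polyclonal
#' repertoire.  A zero or missing density makes the ratio undefined (NA).
#'
#' @param n_clones_count unique TIL clone count(s).
#' @param density CD3/CD8/CD4 density (lymphocytes/mm^2); vectorized.
#' @return Numeric focus ratio, `NA` where the density is not positive.
#' @export
focus_ratio <- function(n_clones_count, density) {
  ifelse(is.na(density) | density <= 0, NA_real_, n_clones_count / density)
}

#' Dichotomize FIGO stage into low and high strata
#'
#' Stages I, II, IIIA and IIIB form the low stratum; IIIC and IV the high
#' stratum.  This binary stratum is the stage adjustment used throughout
#' the survival models.
#'
#' @param stage character or factor of FIGO stages
#'   (I/II/IIIA/IIIB/IIIC/IV).
#' @return Factor with levels `low`, `high`.
#' @export
stage_stratum <- function(stage) {
  stage <- toupper(as.character(stage))
  bad <- which(!(stage %in% FIGO_STAGES))
  if (length(bad) > 0) {
    stop("unknown FIGO stage: ", stage[bad[1]], call. = FALSE)
  }
  factor(ifelse(stage %in% c("IIIC", "IV"), "high", "low"),
         levels = c("low", "high"))
}

#' Median split of high-stage patients by CD3 infiltration
#'
#' Splits patients (intended: the high-stage stratum) at the median CD3
#' density.  Ties and the median point itself go to the low-infiltration
#' group, so an odd cohort of distinct densities yields groups differing by
#' one with the extra patient in the low group (e.g. 39 low / 38 high for
#' 77 patients).
#'
#' @param cd3 numeric CD3 densities, one per patient (length >= 2).
#' @return Factor with levels `low`, `high`.
#' @export
infiltration_split <- function(cd3) {
  if (length(cd3) < 2) {
    stop("at least 2 patients are required for a median split",
         call. = FALSE)
  }
  if (length(unique(cd3)) == 1) {
    stop("degenerate split: all CD3 densities are equal", call. = FALSE)
  }
  factor(ifelse(cd3 <= median(cd3), "low", "high"),
         levels = c("low", "high"))
}

#' Three evenly sized infiltration/diversity groups
#'
#' Partitions the cohort into (i) high infiltration, (ii) low infiltration
#' with low TIL diversity (a focused repertoire), and (iii) low
#' infiltration with high diversity.  Thresholds are data driven: the
#' infiltration threshold takes the top third by CD3 density, and the
#' diversity threshold splits the remainder in half by unique-clone count,
#' so the three group sizes differ by at most one (remainders go first to
#' the high-infiltration group, then to the low-diversity group).  Ties
#' are broken by patient id, so the partition is independent of input
#' order.
#'
#' @param patient_id patient identifiers.
#' @param cd3 CD3 densities.
#' @param diversity unique TIL clone counts.
#' @return Factor (aligned with the input) with levels
#'   `high_infiltration`, `low_inf_low_diversity`, `low_inf_high_diversity`.
#' @export
diversity_tertiles <- function(patient_id, cd3, diversity) {
  n <- length(patient_id)
  if (n < 3) {
    stop("at least 3 patients are required for the three-group split",
         call. = FALSE)
  }
  stopifnot(length(cd3) == n, length(diversity) == n)
  k_hi <- ceiling(n / 3)
  ord_inf <- order_c(-cd3, as.character(patient_id))
  hi <- ord_inf[seq_len(k_hi)]
  rest <- ord_inf[-seq_len(k_hi)]
  k_lowdiv <- ceiling(length(rest) / 2)
  ord_div <- rest[order_c(diversity[rest], as.character(patient_id)[rest])]
  lowdiv <- ord_div[seq_len(k_lowdiv)]
  out <- rep("low_inf_high_diversity", n)
  out[hi] <- "high_infiltration"
  out[lowdiv] <- "low_inf_low_diversity"
  factor(out, levels = c("high_infiltration", "low_inf_low_diversity",
                         "low_inf_high_diversity"))
}

#' Seropositivity call from a reciprocal ELISA titer
#'
#' A reciprocal titer strictly greater than 100 is considered a significant
#' spontaneous antibody response; a titer of exactly 100 is negative.
#'
#' @param titer non-negative reciprocal titer(s).
#' @return Logical vector of calls.
#' @export
serology_call <- function(titer) {
  if (any(titer < 0, na.rm = TRUE)) {
    stop("reciprocal titers must be non-negative", call. = FALSE)
  }
  titer > 100
}

#' Scale a covariate to unit standard deviation
#'
#' Optionally natural-log transforms, then centers and scales so that
#' hazard ratios for the covariate are per one standard deviation,
#' making variables on different scales comparable.
#'
#' @param x numeric vector with at least two distinct values.
#' @param log_first take the natural log before scaling (requires strictly
#'   positive values); used for skewed densities such as lym/mm^2.
#' @return Z-score vector (mean 0, sd 1).
#' @export
standardize <- function(x, log_first = FALSE) {
  if (log_first) {
    if (any(x <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    x <- log(x)
  }
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Derive per-patient analysis features
#'
#' Joins the clinical table with per-repertoire summaries and overlap
#' metrics and derives the features used by the prognostic models: focus
#' ratios against CD3/CD8/imputed-CD4 densities, the low/high stage
#' stratum, the infiltration median split within the high-stage stratum,
#' the three-way infiltration/diversity grouping, per-antigen serology
#' calls and the any-antigen indicator (an OR over NY-ESO-1, MAGE-A1,
#' MAGE-A3 and p53).
#'
#' @param clinical clinical data frame (one row per patient; see
#'   [read_clinical_table()]).
#' @param til_summaries data frame of TIL [summarize_repertoire()] rows.
#' @param overlaps optional data frame of [overlap_summary()] rows.
#' @return The clinical data frame augmented with feature columns.
#' @export
patient_features <- function(clinical, til_summaries, overlaps = NULL) {
  stopifnot("patient_id" %in% names(clinical))
  idx <- match(clinical$patient_id, til_summaries$patient_id)
  if (anyNA(idx)) {
    stop("features stage: no TIL summary for patient(s) ",
         paste(utils::head(clinical$patient_id[is.na(idx)], 3),
               collapse = ", "), call. = FALSE)
  }
  out <- clinical
  out$diversity <- til_summaries$diversity[idx]
  out$clonality <- til_summaries$clonality[idx]
  out$cd4_density <- impute_cd4(out$cd3_density, out$cd8_density)
  out$focus_cd3 <- focus_ratio(out$diversity, out$cd3_density)
  out$focus_cd8 <- focus_ratio(out$diversity, out$cd8_density)
  out$focus_cd4 <- focus_ratio(out$diversity, out$cd4_density)
  out$stage_stratum <- stage_stratum(out$figo_stage)
  out$infiltration_stratum <- factor(NA, levels = c("low", "high"))
  high <- out$stage_stratum == "high"
  if (sum(high) >= 2 && length(unique(out$cd3_density[high])) > 1) {
    out$infiltration_stratum[high] <- infiltration_split(out$cd3_density[high])
  }
  out$tertile_group <- diversity_tertiles(out$patient_id, out$cd3_density,
                                          out$diversity)
  antigens <- c(nyeso1 = "titer_nyeso1", magea1 = "titer_magea1",
                magea3 = "titer_magea3", p53 = "titer_p53")
  present <- antigens[antigens %in% names(out)]
  for (a in names(present)) {
    out[[paste0("sero_", a)]] <- serology_call(out[[present[[a]]]])
  }
  sero_cols <- paste0("sero_", names(present))
  if (length(sero_cols) > 0) {
    out$any_seropositive <- Reduce(`|`, out[sero_cols])
  }
  if (!is.null(overlaps)) {
    oidx <- match(out$patient_id, overlaps$patient_id)
    for (col in setdiff(names(overlaps), "patient_id")) {
      out[[col]] <- overlaps[[col]][oidx]
    }
  }
  out
}
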