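#' Construct a TCR repertoire
#'
#' A repertoire is the set of unique CDR3 amino-acid clonotypes observed in
#' one compartment (tumor-infiltrating lymphocytes, TIL, or peripheral blood,
#' PBMC) of one patient.  Clone identity is the CDR3 amino-acid sequence:
#' rows with the same `cdr3_aa` (e.g. nucleotide variants converging on one
#' protein sequence) are aggregated by summing their copy numbers.  Copy
#' numbers are kept as reals because upstream PCR-efficiency normalization
#' can make them fractional.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences (uppercase,
#'   standard 20-residue alphabet).
#' @param copies numeric vector of non-negative copy numbers (normalized read
#'   counts per unique CDR3 amino-acid sequence).
#' @param cdr3_nt optional character vector of nucleotide sequences.
#' @param patient_id patient identifier (scalar) or `NA`.
#' @param compartment `"TIL"` or `"PBMC"`.
#' @param region_reads optional sample-level total TCR-region read count
#'   (carried by TRUST-like tables and used by [cpk()]); `NULL` if unknown.
#' @param validate check sequences against the amino-acid alphabet and
#'   copies for negatives; can be disabled for trusted internal callers
#'   (e.g. the cohort generator) on large repertoires.
#' @return An object of class `tcr_repertoire`: a list with elements
#'   `patient_id`, `compartment`, `clones` (data frame with columns
#'   `cdr3_aa`, `cdr3_nt`, `copies`, `frequency`, ordered by descending
#'   copies then sequence), `total_reads` and `region_reads`.
#' @examples
#' rep <- repertoire(c("CASSF", "CARRF"), c(30, 10))
#' rep$clones$frequency  # 0.75 0.25
#' @export
repertoire <- function(cdr3_aa, copies, cdr3_nt = NULL,
                       patient_id = NA_character_,
                       compartment = c("TIL", "PBMC"),
                       region_reads = NULL, validate = TRUE) {
  compartment <- match.arg(compartment)
  cdr3_aa <- as.character(cdr3_aa)
  copies <- as.numeric(copies)
  if (length(cdr3_aa) != length(copies)) {
    stop("`cdr3_aa` and `copies` must have the same length", call. = FALSE)
  }
  if (length(cdr3_aa) > 0 && validate) {
    if (anyNA(cdr3_aa) || any(!nzchar(cdr3_aa))) {
      stop("CDR3 amino-acid sequences must be non-empty", call. = FALSE)
    }
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3_aa)
    if (any(bad)) {
      stop("invalid CDR3 amino-acid sequence(s): ",
           paste(utils::head(cdr3_aa[bad], 3), collapse = ", "),
           " (must be uppercase, 20-residue alphabet)", call. = FALSE)
    }
    neg <- which(is.na(copies) | copies < 0)
    if (length(neg) > 0) {
      stop("negative or missing copy number at row ", neg[1], call. = FALSE)
    }
  }
  if (is.null(cdr3_nt)) cdr3_nt <- rep(NA_character_, length(cdr3_aa))
  df <- data.frame(cdr3_aa = cdr3_aa, cdr3_nt = as.character(cdr3_nt),
                   copies = copies, stringsAsFactors = FALSE)
  # aggregate nucleotide variants sharing one amino-acid sequence
  if (anyDuplicated(df$cdr3_aa)) {
    agg <- rowsum(df$copies, df$cdr3_aa)
    nt <- tapply(df$cdr3_nt, df$cdr3_aa, function(x) {
      x <- x[!is.na(x)]
      if (length(unique(x)) == 1) x[1] else NA_character_
    })
    df <- data.frame(cdr3_aa = rownames(agg),
                     cdr3_nt = as.character(nt[rownames(agg)]),
                     copies = agg[, 1], stringsAsFactors = FALSE)
  }
  df <- df[df$copies > 0, , drop = FALSE]
  total <- sum(df$copies)
  df$frequency <- if (total > 0) df$copies / total else numeric(nrow(df))
  df <- df[order_c(-df$copies, df$cdr3_aa), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(patient_id = patient_id, compartment = compartment,
                 clones = df, total_reads = total,
                 region_reads = region_reads),
            class = "tcr_repertoire")
}

#' Number of unique clonotypes in a repertoire
#' @param rep a `tcr_repertoire`.
#' @return Integer count of unique CDR3 amino-acid sequences.
#' @export
n_clones <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  nrow(rep$clones)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire: patient %s, %s compartment\n",
              x$patient_id, x$compartment))
  cat(sprintf("  %d unique clones, %.0f total reads", n_clones(x),
              x$total_reads))
  if (!is.null(x$region_reads)) {
    cat(sprintf(" (%.0f TCR-region reads)", x$region_reads))
  }
  cat("\n")
  if (n_clones(x) > 0) {
    top <- utils::head(x$clones, 5)
    cat("  top clones:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-20s %10.1f  (%.4f)\n", top$cdr3_aa[i],
                  top$copies[i], top$frequency[i]))
    }
  }
  invisible(x)
}

# rebuild a repertoire from a clone subset, preserving metadata
rebuild_repertoire <- function(rep, keep) {
  df <- rep$clones[keep, , drop = FALSE]
  repertoire(df$cdr3_aa, df$copies, df$cdr3_nt,
             patient_id = rep$patient_id, compartment = rep$compartment,
             region_reads = rep$region_reads)
}

#' Remove low-copy clones
#'
#' Clones supported by fewer than `min_copies` copies are dropped as
#' low-level sequencing noise; the default threshold of 20 copies keeps a
#' clone with exactly 20 copies (only strictly fewer are excluded).  The
#' comparison uses the (possibly normalized, fractional) copy number.
#' Frequencies are renormalized over the survivors and the repertoire total
#' is recomputed.
#'
#' @param rep a `tcr_repertoire`.
#' @param min_copies non-negative copy threshold (default 20).
#' @return The filtered `tcr_repertoire` (possibly empty).
#' @export
filter_low_copy <- function(rep, min_copies = 20) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (!is.numeric(min_copies) || length(min_copies) != 1 || min_copies < 0) {
    stop("`min_copies` must be a single non-negative number", call. = FALSE)
  }
  rebuild_repertoire(rep, rep$clones$copies >= min_copies)
}

#' Keep only complete CDR3 sequences
#'
#' Retains clones whose amino-acid sequence encodes a complete CDR3: it must
#' begin with the initial cysteine (`C`) and end with the terminal
#' phenylalanine (`F`).  Fragmentary calls (common in assemblies from bulk
#' RNA-seq) fail this rule.  Frequencies are renormalized over survivors.
#'
#' @param rep a `tcr_repertoire`.
#' @return The filtered `tcr_repertoire`.
#' @export
filter_complete_cdr3 <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  keep <- startsWith(rep$clones$cdr3_aa, "C") &
    endsWith(rep$clones$cdr3_aa, "F")
  rebuild_repertoire(rep, keep)
}

#' Rescale copy numbers by primer-set efficiency factors
#'
#' Hook for amplification-bias correction: each clone's copy number is
#' multiplied by the factor of its primer set.  With `factors = NULL`
#' (the default) this is the identity — the vendor's own normalization is
#' assumed to have been applied upstream.  Relative frequencies are
#' unchanged by a single global factor.
#'
#' @param rep a `tcr_repertoire`.
#' @param factors `NULL`, a single positive number applied to all clones, or
#'   a named positive vector of per-primer-set factors.
#' @param primer_sets optional character vector (one entry per clone, in
#'   `rep$clones` order) naming each clone's primer set; required when
#'   `factors` is a named vector.
#' @return The rescaled `tcr_repertoire`.
#' @export
normalize_copies <- function(rep, factors = NULL, primer_sets = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (is.null(factors)) {
    return(rep)
  }
  if (!is.numeric(factors) || any(!is.finite(factors)) || any(factors <= 0)) {
    stop("normalization factors must be strictly positive", call. = FALSE)
  }
  if (length(factors) == 1 && is.null(names(factors))) {
    mult <- rep(factors, n_clones(rep))
  } else {
    if (is.null(names(factors)) || is.null(primer_sets)) {
      stop("named `factors` require a `primer_sets` assignment per clone",
           call. = FALSE)
    }
    if (length(primer_sets) != n_clones(rep)) {
      stop("`primer_sets` must have one entry per clone", call. = FALSE)
    }
    unknown <- setdiff(unique(primer_sets), names(factors))
    if (length(unknown) > 0) {
      stop("no factor given for primer set(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mult <- unname(factors[primer_sets])
  }
  repertoire(rep$clones$cdr3_aa, rep$clones$copies * mult,
             rep$clones$cdr3_nt, patient_id = rep$patient_id,
             compartment = rep$compartment, region_reads = rep$region_reads)
}
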