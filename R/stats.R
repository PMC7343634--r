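#' Relative clone frequencies, sorted descending
#'
#' Returns the frequency vector p(1) >= p(2) >= ... >= p(N) that all
#' repertoire summary statistics are computed from.  Ties are broken by
#' lexicographic CDR3 sequence so the ordering is deterministic.
#'
#' @param rep a non-empty `tcr_repertoire`.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
clone_frequencies <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (n_clones(rep) == 0) {
    stop("empty repertoire: no clone frequencies", call. = FALSE)
  }
  df <- rep$clones[order_c(-rep$clones$frequency, rep$clones$cdr3_aa), ]
  setNames(df$frequency, df$cdr3_aa)
}

check_freq_vector <- function(p) {
  if (!is.numeric(p) || length(p) == 0) {
    stop("frequency vector must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("frequencies must be finite and in (0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Shannon entropy of a clone frequency vector (bits)
#'
#' H(p) = -sum_k p_k log2 p_k, with 0 log 0 = 0.  Ranges from 0 (single
#' clone) to log2 N (perfectly even repertoire).
#'
#' @param p numeric vector of clone frequencies summing to 1.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # 1
#' @export
shannon_entropy <- function(p) {
  check_freq_vector(p)
  -sum(p * log2(p))
}

#' Clonality (one minus Pielou's evenness)
#'
#' C(p) = 1 - H(p) / log2 N.  0 for a perfectly even repertoire, 1 for a
#' single dominant clone.  A one-clone repertoire makes Pielou's index 0/0;
#' by convention it is maximally clonal and returns 1.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in \[0, 1\].
#' @export
clonality <- function(p) {
  check_freq_vector(p)
  n <- length(p)
  if (n == 1) {
    return(1)
  }
  min(1, max(0, 1 - shannon_entropy(p) / log2(n)))
}

#' Frequency of the most common clone (TOP1)
#' @inheritParams shannon_entropy
#' @return The largest relative frequency.
#' @export
top1 <- function(p) {
  check_freq_vector(p)
  max(p)
}

#' Minimum number of clones capturing more than 25% of the repertoire (N25)
#'
#' The smallest k such that the cumulative frequency of the k most common
#' clones strictly exceeds 0.25.  The inequality is strict: a uniform
#' repertoire of 8 clones has N25 = 3, since two clones reach exactly 0.25.
#' A tolerance of 1e-9 guards the strict comparison against floating-point
#' noise in the cumulative sum.
#'
#' @inheritParams shannon_entropy
#' @return Integer N25.
#' @export
n25 <- function(p) {
  check_freq_vector(p)
  cum <- cumsum(sort(p, decreasing = TRUE))
  unname(which(cum > 0.25 + 1e-9)[1])
}

#' Clonotypes per kiloread (CPK)
#'
#' Unique CDR3 calls normalized by the total read count in the TCR region,
#' per thousand reads — a depth-adjusted diversity measure for samples with
#' very different sequencing coverage.
#'
#' @param n_clones_count number of unique CDR3 calls in the sample.
#' @param total_reads total TCR-region read count (> 0).
#' @return Clonotypes per 1,000 reads.
#' @examples
#' cpk(50, 10000)  # 5
#' @export
cpk <- function(n_clones_count, total_reads) {
  if (!is.numeric(total_reads) || length(total_reads) != 1 ||
      !is.finite(total_reads) || total_reads <= 0) {
    stop("`total_reads` must be a single positive number", call. = FALSE)
  }
  n_clones_count / (total_reads / 1000)
}

#' Summary statistics for one repertoire
#'
#' Computes all per-repertoire statistics from a single sorted frequency
#' vector: Shannon entropy (bits), clonality, diversity (number of unique
#' clones), TOP1, N25, CPK and read depth.  CPK uses the sample-level
#' TCR-region read count when the repertoire carries one (TRUST-like
#' tables), and the repertoire's summed reads otherwise.
#'
#' @param rep a non-empty `tcr_repertoire`.
#' @return A one-row data frame with columns `patient_id`, `compartment`,
#'   `entropy_bits`, `clonality`, `diversity`, `top1`, `n25`, `cpk`,
#'   `depth`.
#' @export
summarize_repertoire <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (n_clones(rep) == 0) {
    stop("empty repertoire: nothing to summarize", call. = FALSE)
  }
  p <- clone_frequencies(rep)
  reads_for_cpk <- if (!is.null(rep$region_reads)) rep$region_reads else
    rep$total_reads
  data.frame(patient_id = rep$patient_id, compartment = rep$compartment,
             entropy_bits = shannon_entropy(p), clonality = clonality(p),
             diversity = length(p), top1 = top1(p), n25 = n25(p),
             cpk = cpk(length(p), reads_for_cpk), depth = rep$total_reads,
             stringsAsFactors = FALSE)
}
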