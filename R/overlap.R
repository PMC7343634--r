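#' Clonal overlap between a patient's PBMC and TIL repertoires
#'
#' Overlap can be measured at the clone level (the chance that a randomly
#' selected clone of one compartment is also found in the other) or at the
#' read level (the fraction of a compartment's reads carried by shared
#' clones).  Both directions are computed; the PBMC side is the
#' conventional "overlap" reported by the pipeline, and its complements are
#' the PBMC-exclusive fractions — the part of the peripheral repertoire
#' spent on clones that do not traffic to the tumor.
#'
#' @param pbmc,til non-empty `tcr_repertoire` objects for the same patient.
#' @return A one-row data frame with columns `patient_id`, `shared_clones`,
#'   `clone_overlap_pbmc`, `clone_overlap_til`, `read_overlap_pbmc`,
#'   `read_overlap_til`, `pbmc_exclusive_clones`, `pbmc_exclusive_reads`.
#' @examples
#' p <- repertoire(c("A", "C", "D", "E"), c(50, 30, 15, 5), compartment = "PBMC")
#' t <- repertoire(c("A", "G"), c(80, 20))
#' overlap_summary(p, t)
#' @export
overlap_summary <- function(pbmc, til) {
  stopifnot(inherits(pbmc, "tcr_repertoire"), inherits(til, "tcr_repertoire"))
  if (!is.na(pbmc$patient_id) && !is.na(til$patient_id) &&
      pbmc$patient_id != til$patient_id) {
    stop(sprintf("pairing error: PBMC patient '%s' does not match TIL patient '%s'",
                 pbmc$patient_id, til$patient_id), call. = FALSE)
  }
  if (n_clones(pbmc) == 0 || n_clones(til) == 0) {
    stop("empty repertoire: overlap is undefined", call. = FALSE)
  }
  shared <- intersect(pbmc$clones$cdr3_aa, til$clones$cdr3_aa)
  in_pbmc <- pbmc$clones$cdr3_aa %in% shared
  in_til <- til$clones$cdr3_aa %in% shared
  clone_pbmc <- length(shared) / n_clones(pbmc)
  read_pbmc <- sum(pbmc$clones$frequency[in_pbmc])
  data.frame(
    patient_id = if (!is.na(pbmc$patient_id)) pbmc$patient_id else
      til$patient_id,
    shared_clones = length(shared),
    clone_overlap_pbmc = clone_pbmc,
    clone_overlap_til = length(shared) / n_clones(til),
    read_overlap_pbmc = read_pbmc,
    read_overlap_til = sum(til$clones$frequency[in_til]),
    pbmc_exclusive_clones = 1 - clone_pbmc,
    pbmc_exclusive_reads = 1 - read_pbmc,
    stringsAsFactors = FALSE)
}

# multivariate hypergeometric rarefaction: subsample `depth` reads without
# replacement from integer clone counts, returning the per-clone draws
rarefy_counts <- function(counts, depth) {
  remaining <- sum(counts)
  drawn <- integer(length(counts))
  left <- depth
  for (i in seq_along(counts)) {
    remaining <- remaining - counts[i]
    x <- rhyper(1, counts[i], remaining, left)
    drawn[i] <- x
    left <- left - x
    if (left == 0) break
  }
  drawn
}

#' Depth-adjusted ratio of PBMC to TIL clone diversity
#'
#' Unique-clone counts are not comparable across compartments sequenced at
#' very different depths, so both repertoires are rarefied (subsampled
#' without replacement) to a common read depth before taking the ratio of
#' unique-clone counts.  Copy numbers are rounded to integers for the
#' subsampling.  The draw is seeded and bit-for-bit reproducible.
#'
#' @inheritParams overlap_summary
#' @param depth common rarefaction depth (reads); defaults to the smaller of
#'   the two repertoire totals.  Must be at least 1 and no larger than
#'   either repertoire.
#' @param seed integer seed for the subsampling.
#' @return Ratio (PBMC unique clones) / (TIL unique clones) after
#'   rarefaction.
#' @export
diversity_ratio <- function(pbmc, til, depth = NULL, seed = 1) {
  stopifnot(inherits(pbmc, "tcr_repertoire"), inherits(til, "tcr_repertoire"))
  cp <- round(pbmc$clones$copies)
  ct <- round(til$clones$copies)
  max_depth <- min(sum(cp), sum(ct))
  if (is.null(depth)) depth <- max_depth
  if (depth < 1 || depth > max_depth) {
    stop(sprintf("rarefaction depth %.0f outside [1, %.0f] supported by both repertoires",
                 depth, max_depth), call. = FALSE)
  }
  # each compartment is rarefied under the same seed, so two identical
  # clone tables always give a ratio of exactly 1
  np <- with_seed(seed, sum(rarefy_counts(cp, depth) > 0))
  nt <- with_seed(seed, sum(rarefy_counts(ct, depth) > 0))
  np / nt
}

#' Per-clone frequency change between compartments
#'
#' One row per clone in the union of the two repertoires, with its relative
#' frequency in each compartment and the log2 ratio TIL/PBMC.  Clones
#' absent from a compartment get frequency 0 and a sentinel ratio of
#' `Inf` (TIL-exclusive) or `-Inf` (PBMC-exclusive).  Shared clones come
#' first, ordered by decreasing absolute log2 ratio; exclusives follow.
#'
#' @inheritParams overlap_summary
#' @return Data frame with columns `cdr3_aa`, `freq_pbmc`, `freq_til`,
#'   `log2_ratio`, `shared`.
#' @export
per_clone_change <- function(pbmc, til) {
  stopifnot(inherits(pbmc, "tcr_repertoire"), inherits(til, "tcr_repertoire"))
  all_clones <- union(pbmc$clones$cdr3_aa, til$clones$cdr3_aa)
  fp <- pbmc$clones$frequency[match(all_clones, pbmc$clones$cdr3_aa)]
  ft <- til$clones$frequency[match(all_clones, til$clones$cdr3_aa)]
  fp[is.na(fp)] <- 0
  ft[is.na(ft)] <- 0
  ratio <- ifelse(fp == 0 & ft == 0, NA_real_,
                  ifelse(fp == 0, Inf, ifelse(ft == 0, -Inf,
                                              log2(ft / fp))))
  out <- data.frame(cdr3_aa = all_clones, freq_pbmc = fp, freq_til = ft,
                    log2_ratio = ratio, shared = fp > 0 & ft > 0,
                    stringsAsFactors = FALSE)
  shared <- out[out$shared, , drop = FALSE]
  shared <- shared[order_c(-abs(shared$log2_ratio), shared$cdr3_aa), ,
                   drop = FALSE]
  excl <- out[!out$shared, , drop = FALSE]
  excl <- excl[order_c(excl$cdr3_aa), , drop = FALSE]
  out <- rbind(shared, excl)
  rownames(out) <- NULL
  out
}

#' Public-clone sharing across patients
#'
#' Counts, for every clone seen in any patient's TIL repertoire, the number
#' of repertoires containing it, together with its mean relative frequency
#' over the repertoires that contain it.  Clones shared by many patients
#' ("public" clones) can then be screened for prognostic associations.
#'
#' @param tils list of `tcr_repertoire` objects, one TIL repertoire per
#'   patient (duplicate patient ids are an error).
#' @param min_share keep only clones found in at least this many
#'   repertoires (default 1 = all).
#' @return Data frame with columns `cdr3_aa`, `n_repertoires`,
#'   `mean_frequency`, ordered by decreasing sharing.
#' @export
sharing_table <- function(tils, min_share = 1) {
  stopifnot(is.list(tils), length(tils) > 0)
  ids <- vapply(tils, function(r) as.character(r$patient_id), character(1))
  if (anyDuplicated(ids[!is.na(ids)])) {
    stop("pairing error: duplicate patient ids in TIL repertoire list",
         call. = FALSE)
  }
  cdr3 <- unlist(lapply(tils, function(r) r$clones$cdr3_aa),
                 use.names = FALSE)
  freq <- unlist(lapply(tils, function(r) r$clones$frequency),
                 use.names = FALSE)
  n_rep <- rowsum(rep(1L, length(cdr3)), cdr3)
  mean_f <- rowsum(freq, cdr3)[, 1] / n_rep[, 1]
  out <- data.frame(cdr3_aa = rownames(n_rep), n_repertoires = n_rep[, 1],
                    mean_frequency = mean_f, stringsAsFactors = FALSE)
  out <- out[out$n_repertoires >= min_share, , drop = FALSE]
  out <- out[order_c(-out$n_repertoires, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
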