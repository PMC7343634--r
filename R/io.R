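#' Read a clone table into a repertoire
#'
#' Reads a tab-separated clone table in one of two dialects.  The
#' `immunoseq_like` dialect carries columns `cdr3_aa`, optional `cdr3_nt`
#' and `copies` (normalized reads per unique CDR3 amino-acid sequence).
#' The `trust_like` dialect carries `cdr3_aa`, a supporting `read_count`
#' and, optionally, a constant `total_tcr_reads` column giving the
#' sample-level TCR-region read count used by [cpk()]; when that column is
#' absent, CPK falls back to the table's summed reads and a warning is
#' issued.  Gzip-compressed files are read transparently.  Nonstandard
#' headers can be mapped with `header_map`, e.g.
#' `c(cdr3_aa = "aminoAcid", copies = "count (templates/reads)")`.
#'
#' @param path path to a TSV file (optionally `.gz`).
#' @param dialect `"immunoseq_like"` or `"trust_like"`.
#' @param patient_id,compartment metadata attached to the repertoire.
#' @param header_map optional named character vector mapping standard column
#'   names (`cdr3_aa`, `cdr3_nt`, `copies`, `total_tcr_reads`) to the file's
#'   actual headers.
#' @return A [repertoire()] object.
#' @export
read_repertoire_table <- function(path,
                                  dialect = c("immunoseq_like", "trust_like"),
                                  patient_id = NA_character_,
                                  compartment = c("TIL", "PBMC"),
                                  header_map = NULL) {
  dialect <- match.arg(dialect)
  compartment <- match.arg(compartment)
  if (!file.exists(path)) {
    stop("clone table not found: ", path, call. = FALSE)
  }
  cols <- c(cdr3_aa = "cdr3_aa", cdr3_nt = "cdr3_nt",
            copies = if (dialect == "trust_like") "read_count" else "copies",
            total_tcr_reads = "total_tcr_reads")
  if (!is.null(header_map)) {
    cols[names(header_map)] <- header_map
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (req in c("cdr3_aa", "copies")) {
    if (!(cols[[req]] %in% names(tab))) {
      stop(sprintf("format error in %s: missing required column '%s'",
                   path, cols[[req]]), call. = FALSE)
    }
  }
  copies <- tab[[cols[["copies"]]]]
  neg <- which(is.na(copies) | copies < 0)
  if (length(neg) > 0) {
    stop(sprintf("data error in %s: negative or missing count at row %d",
                 path, neg[1]), call. = FALSE)
  }
  nt <- if (cols[["cdr3_nt"]] %in% names(tab)) tab[[cols[["cdr3_nt"]]]] else NULL
  region_reads <- NULL
  if (dialect == "trust_like") {
    if (cols[["total_tcr_reads"]] %in% names(tab)) {
      rr <- unique(tab[[cols[["total_tcr_reads"]]]])
      if (length(rr) != 1) {
        stop(sprintf("data error in %s: '%s' must be constant per sample",
                     path, cols[["total_tcr_reads"]]), call. = FALSE)
      }
      region_reads <- as.numeric(rr)
    } else {
      warning("trust_like table without a total TCR-region read column; ",
              "CPK will use the summed clone reads", call. = FALSE)
    }
  }
  repertoire(tab[[cols[["cdr3_aa"]]]], copies, cdr3_nt = nt,
             patient_id = patient_id, compartment = compartment,
             region_reads = region_reads)
}

#' Write a repertoire to a tab-separated clone table
#'
#' Writes the canonical on-disk dialect (`cdr3_aa`, `cdr3_nt`, `copies`,
#' plus `total_tcr_reads` when the repertoire carries a TCR-region read
#' count).  Reading the file back reproduces the clone set and copies.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output path (gzip-compressed if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_repertoire_table <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  df <- rep$clones[, c("cdr3_aa", "cdr3_nt", "copies")]
  if (!is.null(rep$region_reads)) {
    df$total_tcr_reads <- rep$region_reads
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

FIGO_STAGES <- c("I", "II", "IIIA", "IIIB", "IIIC", "IV")

#' Read a clinical cohort table
#'
#' One row per patient.  Required columns: `patient_id`, `figo_stage`
#' (I/II/IIIA/IIIB/IIIC/IV, parsed case-insensitively), `cd3_density` and
#' `cd8_density` (lymphocytes/mm^2), `pfs_months`, `pfs_event`, `os_months`,
#' `os_event`.  Optional: `histology`, reciprocal ELISA titers
#' `titer_nyeso1`, `titer_magea1`, `titer_magea3`, `titer_p53`, and
#' `platinum_sensitive`.  A CD8 density exceeding CD3 raises a warning but
#' the record is retained (measurement noise; downstream CD4 imputation
#' clamps at zero).
#'
#' @param path path to a TSV file (optionally `.gz`).
#' @return A data frame of patient records with `figo_stage` as a factor.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) {
    stop("clinical table not found: ", path, call. = FALSE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "figo_stage", "cd3_density", "cd8_density",
                "pfs_months", "pfs_event", "os_months", "os_event")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stage <- toupper(trimws(as.character(tab$figo_stage)))
  bad <- which(!(stage %in% FIGO_STAGES))
  if (length(bad) > 0) {
    stop(sprintf("data error in %s: unknown FIGO stage '%s' at row %d",
                 path, tab$figo_stage[bad[1]], bad[1]), call. = FALSE)
  }
  tab$figo_stage <- factor(stage, levels = FIGO_STAGES)
  for (col in c("pfs_months", "os_months")) {
    nonpos <- which(!is.finite(tab[[col]]) | tab[[col]] <= 0)
    if (length(nonpos) > 0) {
      stop(sprintf("data error in %s: non-positive %s at row %d",
                   path, col, nonpos[1]), call. = FALSE)
    }
  }
  over <- which(tab$cd8_density > tab$cd3_density)
  if (length(over) > 0) {
    warning(sprintf("CD8 density exceeds CD3 density for %d patient(s) ",
                    length(over)),
            "(e.g. row ", over[1], "); records retained", call. = FALSE)
  }
  tab$pfs_event <- as.logical(tab$pfs_event)
  tab$os_event <- as.logical(tab$os_event)
  tab
}

#' Write a clinical cohort table
#' @param clinical a clinical data frame (see [read_clinical_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(clinical, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
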