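#' Configuration for an end-to-end pipeline run
#'
#' Inputs are either a directory of clone tables plus a clinical table
#' (`input_dir`, as written by [write_cohort()]) or a simulation
#' configuration (`sim`).  Filters default to the deep-sequencing path:
#' copies below 20 are dropped and the complete-CDR3 rule is off (it is
#' meant for assembly-derived tables; set `complete_cdr3 = TRUE` for the
#' TRUST-like path).
#'
#' @param input_dir directory containing `<patient>_TIL.tsv`,
#'   `<patient>_PBMC.tsv` and `clinical.tsv`, or `NULL` when simulating.
#' @param sim a [cohort_config()], or `NULL` when reading from disk.
#' @param out_dir directory for the report bundle.
#' @param dialect clone-table dialect for reading.
#' @param min_copies copy-number filter threshold (0 disables).
#' @param complete_cdr3 apply the complete-CDR3 filter.
#' @param rarefy_depth common depth for the diversity ratio; `NULL` uses
#'   each patient's smaller compartment total.
#' @param seed top-level seed for every stochastic stage.
#' @param endpoint `"pfs"` or `"os"`.
#' @param cap restricted-mean horizon in months.
#' @param min_share sharing threshold for the public-clone screen.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL, out_dir = tempfile("tcrfocus_"),
                            dialect = "immunoseq_like", min_copies = 20,
                            complete_cdr3 = (dialect == "trust_like"),
                            rarefy_depth = NULL, seed = 1,
                            endpoint = c("pfs", "os"), cap = 60,
                            min_share = 25) {
  endpoint <- match.arg(endpoint)
  if (is.null(input_dir) && is.null(sim)) {
    stop("either `input_dir` or `sim` must be given", call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "cohort_config"))
  if (min_copies < 0) stop("`min_copies` must be non-negative", call. = FALSE)
  if (cap <= 0) stop("`cap` must be positive", call. = FALSE)
  structure(list(input_dir = input_dir, sim = sim, out_dir = out_dir,
                 dialect = dialect, min_copies = min_copies,
                 complete_cdr3 = isTRUE(complete_cdr3),
                 rarefy_depth = rarefy_depth, seed = seed,
                 endpoint = endpoint, cap = cap, min_share = min_share),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Run the full analysis pipeline
#'
#' Stages: load (simulate or read) -> filter -> summarize -> overlap ->
#' features -> survival.  Each stage writes an immutable tab-separated
#' table under `out_dir` (`repertoire_summaries.tsv`, `overlap.tsv`,
#' `sharing.tsv`, `features.tsv`, `models.tsv`) plus a `provenance.tsv`
#' recording the configuration, seed and package version.  A rerun with
#' the same configuration and seed reproduces the tables byte for byte.
#' Any stage failure aborts with the stage name and the offending record.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory tables
#'   (`summaries`, `overlap`, `sharing`, `features`, `models`) and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  loaded <- stage("load", {
    if (!is.null(config$sim)) {
      cohort <- generate_cohort(config$sim)
      list(tils = cohort$tils, pbmcs = cohort$pbmcs,
           clinical = cohort$clinical)
    } else {
      til_files <- sort(list.files(config$input_dir, "_TIL\\.tsv(\\.gz)?$",
                                   full.names = TRUE), method = "radix")
      if (length(til_files) == 0) {
        stop("no *_TIL.tsv clone tables in ", config$input_dir)
      }
      ids <- sub("_TIL\\.tsv(\\.gz)?$", "", basename(til_files))
      tils <- lapply(seq_along(ids), function(i) {
        read_repertoire_table(til_files[i], dialect = config$dialect,
                              patient_id = ids[i], compartment = "TIL")
      })
      pbmcs <- lapply(ids, function(id) {
        path <- file.path(config$input_dir, paste0(id, "_PBMC.tsv"))
        if (!file.exists(path)) {
          stop("missing PBMC clone table for patient ", id)
        }
        read_repertoire_table(path, dialect = config$dialect,
                              patient_id = id, compartment = "PBMC")
      })
      names(tils) <- names(pbmcs) <- ids
      list(tils = tils, pbmcs = pbmcs, clinical = NULL)
    }
  })

  filtered <- stage("filter", {
    ff <- function(r) {
      if (config$min_copies > 0) r <- filter_low_copy(r, config$min_copies)
      if (config$complete_cdr3) r <- filter_complete_cdr3(r)
      if (n_clones(r) == 0) {
        stop("patient ", r$patient_id, " ", r$compartment,
             ": no clones survive the filters")
      }
      r
    }
    list(tils = lapply(loaded$tils, ff), pbmcs = lapply(loaded$pbmcs, ff))
  })

  summaries <- stage("summarize", {
    do.call(rbind, c(lapply(filtered$tils, summarize_repertoire),
                     lapply(filtered$pbmcs, summarize_repertoire)))
  })
  rownames(summaries) <- NULL
  write_tsv(summaries, file.path(config$out_dir, "repertoire_summaries.tsv"))

  ids <- names(filtered$tils)
  overlap <- stage("overlap", {
    rows <- lapply(ids, function(id) {
      o <- overlap_summary(filtered$pbmcs[[id]], filtered$tils[[id]])
      o$diversity_ratio <- diversity_ratio(filtered$pbmcs[[id]],
                                           filtered$tils[[id]],
                                           depth = config$rarefy_depth,
                                           seed = config$seed)
      o
    })
    do.call(rbind, rows)
  })
  write_tsv(overlap, file.path(config$out_dir, "overlap.tsv"))
  sharing <- stage("overlap", sharing_table(filtered$tils))
  write_tsv(sharing, file.path(config$out_dir, "sharing.tsv"))

  features <- stage("features", {
    clinical <- loaded$clinical
    if (is.null(clinical)) {
      path <- file.path(config$input_dir, "clinical.tsv")
      if (!file.exists(path)) {
        stop("clinical table not found at ", path)
      }
      clinical <- read_clinical_table(path)
    }
    til_sum <- summaries[summaries$compartment == "TIL", , drop = FALSE]
    patient_features(clinical, til_sum, overlaps = overlap)
  })
  write_tsv(features, file.path(config$out_dir, "features.tsv"))

  models <- stage("survival", {
    time <- if (config$endpoint == "pfs") features$pfs_months else
      features$os_months
    event <- if (config$endpoint == "pfs") features$pfs_event else
      features$os_event
    adjust <- data.frame(stage = features$stage_stratum)
    fit_row <- function(name, x) {
      fit <- tryCatch(fit_cox(x, time, event, adjust = adjust),
                      error = function(e) NULL)
      if (is.null(fit)) {
        return(NULL)
      }
      data.frame(model = name, hr = fit$hr, ci_low = fit$ci_low,
                 ci_high = fit$ci_high, p = fit$p, n = fit$n,
                 events = fit$events, stringsAsFactors = FALSE)
    }
    rows <- list(fit_row("focus_cd3", features$focus_cd3),
                 fit_row("clone_overlap_pbmc", features$clone_overlap_pbmc),
                 fit_row("read_overlap_pbmc", features$read_overlap_pbmc),
                 fit_row("diversity_ratio", features$diversity_ratio))
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    lr <- logrank_test(features$tertile_group, time, event)
    out <- rbind(out, data.frame(model = "tertile_logrank", hr = NA,
                                 ci_low = NA, ci_high = NA, p = lr$p,
                                 n = nrow(features), events = sum(event),
                                 stringsAsFactors = FALSE))
    sero <- features$sero_nyeso1
    if (!is.null(sero) && length(unique(sero)) == 2 &&
        all(tapply(event, sero, sum) > 0)) {
      # an interaction fit that fails or does not converge is omitted
      it <- tryCatch(
        serology_interaction_test(
          features$clone_overlap_pbmc, sero, time, event,
          adjust = data.frame(stage = features$stage_stratum,
                              log_cd3 = log(features$cd3_density))),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(it)) {
        out <- rbind(out, data.frame(model = "serology_x_overlap",
                                     hr = NA, ci_low = NA, ci_high = NA,
                                     p = it$p, n = nrow(features),
                                     events = sum(event),
                                     stringsAsFactors = FALSE))
      }
    }
    screen <- public_clone_screen(filtered$tils, time, event,
                                  stage = features$stage_stratum,
                                  min_share = config$min_share)
    if (nrow(screen) > 0) {
      out <- rbind(out, data.frame(model = paste0("clone:", screen$cdr3_aa),
                                   hr = screen$hr, ci_low = screen$ci_low,
                                   ci_high = screen$ci_high,
                                   p = screen$p_bonferroni,
                                   n = nrow(features), events = sum(event),
                                   stringsAsFactors = FALSE))
    }
    out
  })
  write_tsv(models, file.path(config$out_dir, "models.tsv"))

  prov <- data.frame(
    key = c("package_version", "seed", "endpoint", "min_copies",
            "complete_cdr3", "min_share", "cap", "input",
            "n_patients"),
    value = c(as.character(packageVersion("tcrfocus")),
              config$seed, config$endpoint, config$min_copies,
              config$complete_cdr3, config$min_share, config$cap,
              if (is.null(config$input_dir)) "simulated" else
                config$input_dir,
              length(ids)),
    stringsAsFactors = FALSE)
  write_tsv(prov, file.path(config$out_dir, "provenance.tsv"))

  invisible(list(summaries = summaries, overlap = overlap,
                 sharing = sharing, features = features, models = models,
                 out_dir = config$out_dir))
}
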