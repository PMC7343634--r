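#' Stage-adjusted proportional-hazards fit per unit standard deviation
#'
#' Fits a Cox proportional-hazards model for one feature, scaled internally
#' to unit standard deviation so hazard ratios are comparable across
#' features on different scales.  Adjustment covariates (typically the
#' binary low/high stage stratum, optionally log infiltration density) are
#' entered additively.  Ties are handled by Efron's approximation.
#'
#' @param feature numeric covariate of interest (non-constant).
#' @param time follow-up times in months (> 0).
#' @param event logical event indicators (`FALSE` = censored).
#' @param adjust optional data frame (or named list) of adjustment
#'   covariates aligned with `feature`.
#' @param scale_feature scale `feature` to unit standard deviation before
#'   fitting (default `TRUE`).
#' @return An object of class `tcr_cox`: list with `hr`, `ci_low`,
#'   `ci_high`, `p` (Wald), `n`, `events`, `adjusted_for`, `loglik`, the
#'   underlying `coxph` fit (`fit`), and the feature centering/scaling
#'   used (`feature_mean`, `feature_sd`).
#' @export
fit_cox <- function(feature, time, event, adjust = NULL,
                    scale_feature = TRUE) {
  n <- length(feature)
  stopifnot(length(time) == n, length(event) == n)
  event <- as.logical(event)
  if (sum(event) < 10) {
    stop("at least 10 observed events are required for a stable fit",
         call. = FALSE)
  }
  s <- sd(feature)
  if (!is.finite(s) || s == 0) {
    stop("constant feature: hazard ratio is not identifiable", call. = FALSE)
  }
  m <- mean(feature)
  z <- if (scale_feature) (feature - m) / s else feature
  dat <- data.frame(.time = time, .event = event, .z = z)
  adjusted_for <- character(0)
  if (!is.null(adjust)) {
    adjust <- as.data.frame(adjust)
    stopifnot(nrow(adjust) == n)
    adjusted_for <- names(adjust)
    dat <- cbind(dat, adjust)
  }
  fml <- stats::as.formula(paste(
    "Surv(.time, .event) ~ .z",
    if (length(adjusted_for) > 0)
      paste("+", paste(adjusted_for, collapse = " + ")) else ""))
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        stop("proportional-hazards fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)[[".z"]]
  if (!is.finite(beta) || abs(beta) > 15) {
    stop("proportional-hazards fit is degenerate (|log HR| too large)",
         call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(
    hr = unname(exp(beta)),
    ci_low = unname(sm$conf.int[".z", "lower .95"]),
    ci_high = unname(sm$conf.int[".z", "upper .95"]),
    p = unname(sm$coefficients[".z", "Pr(>|z|)"]),
    n = n, events = sum(event), adjusted_for = adjusted_for,
    loglik = fit$loglik[2], fit = fit, data = dat,
    feature_mean = if (scale_feature) m else 0,
    feature_sd = if (scale_feature) s else 1),
    class = "tcr_cox")
}

#' @export
print.tcr_cox <- function(x, ...) {
  cat(sprintf(
    "Cox proportional hazards (per 1 SD): HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
    x$hr, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  n = %d, events = %d", x$n, x$events))
  if (length(x$adjusted_for) > 0) {
    cat("; adjusted for ", paste(x$adjusted_for, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.tcr_cox <- function(object, ...) coef(object$fit)

#' Log-rank test across groups
#'
#' Standard log-rank chi-square statistic on k - 1 degrees of freedom;
#' supports two or more groups (the three-way infiltration/diversity
#' comparison uses three).
#'
#' @param group group labels (>= 2 distinct groups, each with at least one
#'   event).
#' @param time,event survival endpoint.
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(as.character(group))
  event <- as.logical(event)
  if (nlevels(group) < 2) {
    stop("log-rank test requires at least 2 groups", call. = FALSE)
  }
  ev <- tapply(event, group, sum)
  if (any(ev == 0)) {
    stop("log-rank test requires at least one event per group",
         call. = FALSE)
  }
  sdf <- survdiff(Surv(time, event) ~ group)
  df <- length(sdf$n) - 1
  list(statistic = unname(sdf$chisq), df = df,
       p = pchisq(sdf$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier median survival
#'
#' Product-limit median: the first time the survival curve drops to 0.5 or
#' below.  Undefined (NA) when the curve never reaches 0.5.
#'
#' @param time,event survival endpoint.
#' @return Median survival in months, or `NA` if not reached.
#' @export
km_median <- function(time, event) {
  sf <- survfit(Surv(time, as.logical(event)) ~ 1)
  unname(quantile(sf, probs = 0.5)$quantile)
}

#' Restricted mean of a survival curve
#'
#' Integrates a survival curve from 0 to `cap` months by the trapezoidal
#' rule.  For a Kaplan-Meier-type step function set `stepfun = TRUE`: step
#' points are doubled so the trapezoids reproduce the exact rectangle areas
#' of the right-continuous step curve.  The curve is taken as 1 at time 0
#' and is extended flat from its last point to `cap`.
#'
#' @param times increasing time points.
#' @param surv survival probabilities at `times`.
#' @param cap restriction horizon in months (> 0); 60 by convention for
#'   ovarian cancer.
#' @param stepfun treat `(times, surv)` as a right-continuous step function.
#' @return The restricted mean survival time.
#' @export
restricted_mean <- function(times, surv, cap = 60, stepfun = FALSE) {
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    stop("`cap` must be a single positive number of months", call. = FALSE)
  }
  stopifnot(length(times) == length(surv))
  o <- order(times)
  times <- times[o]
  surv <- surv[o]
  keep <- times <= cap
  times <- times[keep]
  surv <- surv[keep]
  if (length(times) == 0 || times[1] > 0) {
    times <- c(0, times)
    surv <- c(1, surv)
  }
  if (stepfun && length(times) > 1) {
    # duplicate each interior point at the pre-step survival level
    i <- seq_len(length(times) - 1)
    times <- c(times[1], as.vector(rbind(times[i + 1], times[i + 1])))
    surv <- c(surv[1], as.vector(rbind(surv[i], surv[i + 1])))
  }
  if (max(times) < cap) {
    times <- c(times, cap)
    surv <- c(surv, surv[length(surv)])
  }
  dt <- diff(times)
  sum(dt * (utils::head(surv, -1) + utils::tail(surv, -1)) / 2)
}

#' Restricted mean survival as a function of a covariate
#'
#' For a fitted `tcr_cox` model, computes the expected restricted mean
#' survival (integral of the model survival curve up to `cap` months) at
#' each value of the feature on its original scale, holding adjustment
#' covariates at their sample mean (numeric) or most frequent level
#' (factor).  The model curve steps at the observed event times.
#'
#' @param fit a [fit_cox()] result.
#' @param grid feature values (original scale) at which to evaluate.
#' @param cap restriction horizon in months (default 60).
#' @return Data frame with columns `value` and `rms` (months).
#' @export
rms_curve <- function(fit, grid, cap = 60) {
  stopifnot(inherits(fit, "tcr_cox"))
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    stop("`cap` must be a single positive number of months", call. = FALSE)
  }
  z <- (grid - fit$feature_mean) / fit$feature_sd
  nd <- data.frame(.z = z)
  for (a in fit$adjusted_for) {
    col <- fit$data[[a]]
    nd[[a]] <- if (is.numeric(col)) {
      mean(col)
    } else {
      lv <- names(sort(table(col), decreasing = TRUE))[1]
      factor(lv, levels = levels(as.factor(col)))
    }
  }
  sf <- survfit(fit$fit, newdata = nd)
  sv <- sf$surv
  if (is.null(dim(sv))) sv <- matrix(sv, ncol = 1)
  rms <- vapply(seq_len(ncol(sv)), function(j) {
    restricted_mean(sf$time, sv[, j], cap = cap, stepfun = TRUE)
  }, numeric(1))
  data.frame(value = grid, rms = rms)
}

#' Bonferroni-corrected prognostic screen of public clones
#'
#' For every clone found in at least `min_share` patients' TIL
#' repertoires, fits a stage-adjusted Cox model on the clone's per-patient
#' relative frequency scaled to unit standard deviation, and applies a
#' Bonferroni correction over the number of clones actually tested
#' (adjusted p = min(1, raw p x m)).
#'
#' @param tils list of TIL `tcr_repertoire` objects, one per patient,
#'   aligned with `time`/`event`/`stage`.
#' @param time,event survival endpoint.
#' @param stage stage stratum factor (see [stage_stratum()]), or `NULL`
#'   for an unadjusted screen.
#' @param min_share sharing threshold (default 25 repertoires).
#' @return Data frame with one row per tested clone: `cdr3_aa`,
#'   `n_repertoires`, `hr`, `ci_low`, `ci_high`, `p`, `p_bonferroni`.
#'   Empty (with a message) when no clone passes the threshold.
#' @export
public_clone_screen <- function(tils, time, event, stage = NULL,
                                min_share = 25) {
  share <- sharing_table(tils, min_share = min_share)
  empty <- data.frame(cdr3_aa = character(0), n_repertoires = integer(0),
                      hr = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), stringsAsFactors = FALSE)
  if (nrow(share) == 0) {
    message("public-clone screen: no clone shared by at least ", min_share,
            " repertoires; nothing to test")
    return(empty)
  }
  adjust <- if (!is.null(stage)) data.frame(stage = stage) else NULL
  m <- nrow(share)
  rows <- lapply(seq_len(m), function(i) {
    clone <- share$cdr3_aa[i]
    freq <- vapply(tils, function(r) {
      j <- match(clone, r$clones$cdr3_aa)
      if (is.na(j)) 0 else r$clones$frequency[j]
    }, numeric(1))
    fit <- tryCatch(fit_cox(freq, time, event, adjust = adjust),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(NULL)
    }
    data.frame(cdr3_aa = clone, n_repertoires = share$n_repertoires[i],
               hr = fit$hr, ci_low = fit$ci_low, ci_high = fit$ci_high,
               p = fit$p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    message("public-clone screen: no clone yielded an estimable model")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  rownames(out) <- NULL
  out
}

#' Deviance test for a serology-by-feature interaction
#'
#' Likelihood-ratio (deviance) test, on one degree of freedom, of whether
#' the prognostic effect of a repertoire feature (e.g. TIL/PBMC overlap or
#' the PBMC-exclusive fraction) differs between seropositive and
#' seronegative patients.  Compares nested Cox models with and without the
#' feature-by-serostatus interaction term, both containing the feature,
#' serostatus and any adjustment covariates (typically stage stratum and
#' log CD3 density).
#'
#' @param feature numeric repertoire feature (scaled internally to unit
#'   standard deviation).
#' @param serostatus logical seropositivity per patient; both levels must
#'   be present with at least one event each.
#' @param time,event survival endpoint.
#' @param adjust optional data frame of adjustment covariates.
#' @return List with `statistic` (2 x log-likelihood difference), `df`,
#'   `p`, and the two `coxph` fits (`fit_full`, `fit_reduced`).
#' @export
serology_interaction_test <- function(feature, serostatus, time, event,
                                      adjust = NULL) {
  n <- length(feature)
  serostatus <- as.logical(serostatus)
  event <- as.logical(event)
  stopifnot(length(serostatus) == n, length(time) == n, length(event) == n)
  if (length(unique(serostatus)) < 2) {
    stop("both serostatus levels must be present", call. = FALSE)
  }
  if (any(tapply(event, serostatus, sum) == 0)) {
    stop("each serostatus level must contain at least one event",
         call. = FALSE)
  }
  z <- standardize(feature)
  dat <- data.frame(.time = time, .event = event, .z = z,
                    .sero = serostatus)
  terms <- c(".z", ".sero")
  if (!is.null(adjust)) {
    adjust <- as.data.frame(adjust)
    stopifnot(nrow(adjust) == n)
    dat <- cbind(dat, adjust)
    terms <- c(terms, names(adjust))
  }
  base <- paste("Surv(.time, .event) ~", paste(terms, collapse = " + "))
  fit_reduced <- coxph(stats::as.formula(base), data = dat, ties = "efron")
  fit_full <- coxph(stats::as.formula(paste(base, "+ .z:.sero")),
                    data = dat, ties = "efron")
  stat <- 2 * (fit_full$loglik[2] - fit_reduced$loglik[2])
  list(statistic = unname(stat), df = 1L,
       p = pchisq(stat, 1, lower.tail = FALSE),
       fit_full = fit_full, fit_reduced = fit_reduced)
}
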