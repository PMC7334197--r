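#' Proportion of possible variants observed
#'
#' Matches observed variants to the possible-variant table by
#' (`contig`, `pos`, `ref`, `alt`) and returns the fraction of possible
#' sites of the requested class that are observed. Observed variants absent
#' from the possible table (for example indels) are ignored for this
#' statistic.
#'
#' @param possible Possible-variant table from [enumerate_possible()].
#' @param observed Observed variant table (e.g. from [read_variants()]).
#' @param consequence Optional consequence filter (character vector).
#' @param verdict Optional verdict filter (character vector).
#' @return List with `n_observed`, `n_possible` and `fraction`.
#' @export
proportion_observed <- function(possible, observed, consequence = NULL,
                                verdict = NULL) {
  dt <- possible
  sel <- rep(TRUE, nrow(dt))
  if (!is.null(consequence)) sel <- sel & dt$consequence %in% consequence
  if (!is.null(verdict)) sel <- sel & dt$verdict %in% verdict
  dt <- as.data.frame(dt)[sel, , drop = FALSE]
  n_possible <- nrow(dt)
  if (n_possible == 0L)
    return(list(n_observed = 0L, n_possible = 0L, fraction = NaN))
  obs_key <- paste(observed$contig, observed$pos, observed$ref, observed$alt)
  n_observed <- sum(paste(dt$contig, dt$pos, dt$ref, dt$alt) %in% obs_key)
  list(n_observed = n_observed, n_possible = n_possible,
       fraction = n_observed / n_possible)
}

#' Fit the synonymous calibration model
#'
#' Fits, separately for each methylation stratum, a weighted least-squares
#' line mapping relative mutation rate to the proportion of possible sites
#' observed in the cohort. Training uses synonymous sites only, restricted
#' to high-coverage positions (`median_coverage >= high_cov`), with weights
#' equal to the number of possible sites per (context, alternate) group.
#' Predictions are later clamped to `[0, 1]`. A stratum with fewer than two
#' distinct rates falls back to an intercept-only fit with a warning.
#'
#' @param possible Possible-variant table with `mu` and `median_coverage`.
#' @param observed Observed variant table.
#' @param high_cov High-coverage threshold (default 40).
#' @return A `CalibrationModel`: per-stratum intercept/slope plus a training
#'   summary.
#' @export
fit_calibration <- function(possible, observed, high_cov = 40) {
  train <- possible[possible$consequence == "synonymous" &
                      !is.na(possible$mu), ]
  if ("median_coverage" %in% names(train))
    train <- train[!is.na(train$median_coverage) &
                     train$median_coverage >= high_cov, ]
  if (nrow(train) == 0L) stop("empty calibration training set")
  obs_key <- paste(observed$contig, observed$pos, observed$ref, observed$alt)
  train <- data.table::as.data.table(train)
  train[, seen := paste(contig, pos, ref, alt) %in% obs_key]
  grp <- train[, .(n = .N, p = mean(seen)),
               by = .(methylation, context, alt_collapsed, mu)]
  strata <- sort(unique(grp$methylation))
  coefs <- data.table::rbindlist(lapply(strata, function(s) {
    g <- grp[methylation == s]
    if (length(unique(g$mu)) < 2L) {
      warning("calibration stratum ", s,
              ": fewer than 2 distinct rates, intercept-only fallback")
      data.table::data.table(methylation = s,
                             intercept = sum(g$p * g$n) / sum(g$n),
                             slope = 0)
    } else {
      fit <- stats::lm(p ~ mu, data = g, weights = g$n)
      cf <- stats::coef(fit)
      if (anyNA(cf)) {
        warning("calibration stratum ", s,
                ": singular fit, intercept-only fallback")
        data.table::data.table(methylation = s,
                               intercept = sum(g$p * g$n) / sum(g$n),
                               slope = 0)
      } else {
        data.table::data.table(methylation = s, intercept = cf[[1]],
                               slope = cf[[2]])
      }
    }
  }))
  structure(list(coefficients = coefs,
                 training = grp[, .(methylation, context, alt_collapsed,
                                    mu, n, p)],
                 high_cov = high_cov),
            class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat("CalibrationModel (proportion observed ~ mu), strata:\n")
  print(x$coefficients)
  invisible(x)
}

#' Predict proportion of possible sites observed
#'
#' @param model A `CalibrationModel`.
#' @param mu Relative mutation rates.
#' @param methylation Methylation levels (recycled if scalar).
#' @return Predicted proportions, clamped to `[0, 1]`.
#' @export
predict_calibration <- function(model, mu, methylation = 0L) {
  stopifnot(inherits(model, "CalibrationModel"))
  if (length(methylation) == 1L) methylation <- rep(methylation, length(mu))
  cf <- model$coefficients
  idx <- match(methylation, cf$methylation)
  idx[is.na(idx)] <- match(0L, cf$methylation)  # absent stratum -> level 0
  clamp01(cf$intercept[idx] + cf$slope[idx] * mu)
}

#' Coverage-correction model
#'
#' Correction factor applied to expected counts at under-covered sites:
#' `1` at `median_coverage >= high_cov`, `clamp(a + b * log10(coverage), 0,
#' 1)` for `1 <= coverage < high_cov`, and an exclusion sentinel (`NA`) below
#' coverage 1 (such sites are dropped from both observed and expected
#' tallies).
#'
#' @param a,b Coefficients of the log10-linear correction.
#' @param high_cov High-coverage threshold (default 40).
#' @return A `CoverageModel`.
#' @export
coverage_model <- function(a, b, high_cov = 40) {
  structure(list(a = a, b = b, high_cov = high_cov), class = "CoverageModel")
}

#' @export
print.CoverageModel <- function(x, ...) {
  cat(sprintf(
    "CoverageModel: factor = clamp(%.4f + %.4f*log10(cov)) below cov %g\n",
    x$a, x$b, x$high_cov))
  invisible(x)
}

#' Fit the coverage-correction model
#'
#' Groups low-coverage synonymous sites by median coverage, computes the
#' ratio of the observed proportion to the calibration-predicted proportion,
#' and fits a weighted least-squares line of that ratio on log10 coverage.
#'
#' @param possible Possible-variant table with `mu` and `median_coverage`.
#' @param observed Observed variant table.
#' @param calibration Fitted `CalibrationModel`.
#' @param high_cov High-coverage threshold (default 40).
#' @return A `CoverageModel`.
#' @export
fit_coverage_model <- function(possible, observed, calibration,
                               high_cov = 40) {
  low <- possible[possible$consequence == "synonymous" &
                    !is.na(possible$mu) &
                    !is.na(possible$median_coverage) &
                    possible$median_coverage >= 1 &
                    possible$median_coverage < high_cov, ]
  if (nrow(low) == 0L) stop("no low-coverage synonymous sites to fit on")
  obs_key <- paste(observed$contig, observed$pos, observed$ref, observed$alt)
  low <- data.table::as.data.table(low)
  low[, seen := paste(contig, pos, ref, alt) %in% obs_key]
  low[, pred := predict_calibration(calibration, mu, methylation)]
  grp <- low[, .(n = .N, ratio = mean(seen) / mean(pred)),
             by = .(cov = round(median_coverage))]
  if (nrow(grp) < 2L) {
    warning("fewer than 2 coverage bins; flat coverage model")
    return(coverage_model(a = sum(grp$ratio * grp$n) / sum(grp$n), b = 0,
                          high_cov = high_cov))
  }
  fit <- stats::lm(ratio ~ log10(cov), data = grp, weights = grp$n)
  cf <- stats::coef(fit)
  coverage_model(a = cf[[1]], b = cf[[2]], high_cov = high_cov)
}

#' Coverage correction factor
#'
#' @param median_coverage Non-negative coverage values.
#' @param model A `CoverageModel`.
#' @return Factors in `[0, 1]`; `NA` (exclusion sentinel) below coverage 1.
#' @export
coverage_correction_factor <- function(median_coverage, model) {
  stopifnot(inherits(model, "CoverageModel"))
  if (any(median_coverage < 0, na.rm = TRUE))
    stop("coverage must be non-negative")
  out <- rep(NA_real_, length(median_coverage))
  hi <- !is.na(median_coverage) & median_coverage >= model$high_cov
  mid <- !is.na(median_coverage) & median_coverage >= 1 &
    median_coverage < model$high_cov
  out[hi] <- 1
  out[mid] <- clamp01(model$a + model$b * log10(median_coverage[mid]))
  out
}

#' Expected variant count for a class
#'
#' Sums, over the possible sites of the class, the calibration-predicted
#' proportion observed times the site's coverage-correction factor. Sites
#' below coverage 1 (exclusion sentinel) are dropped; sites with no coverage
#' information count with factor 1.
#'
#' @param possible Possible-variant table with `mu` (and optionally
#'   `median_coverage`, `methylation`).
#' @param calibration Fitted `CalibrationModel`.
#' @param coverage_model Optional `CoverageModel`.
#' @param consequence,verdict Optional class filters.
#' @return Expected count (non-negative scalar); 0 with a warning when the
#'   class has no possible sites.
#' @export
expected_counts <- function(possible, calibration, coverage_model = NULL,
                            consequence = NULL, verdict = NULL) {
  sel <- !is.na(possible$mu)
  if (!is.null(consequence)) sel <- sel & possible$consequence %in% consequence
  if (!is.null(verdict)) sel <- sel & possible$verdict %in% verdict
  dt <- as.data.frame(possible)[sel, , drop = FALSE]
  if (nrow(dt) == 0L) {
    warning("no possible sites in class; expected count is 0")
    return(0)
  }
  meth <- if ("methylation" %in% names(dt)) dt$methylation else 0L
  pred <- predict_calibration(calibration, dt$mu, meth)
  if (!is.null(coverage_model) && "median_coverage" %in% names(dt)) {
    fac <- coverage_correction_factor(dt$median_coverage, coverage_model)
    fac[is.na(dt$median_coverage)] <- 1
    keep <- !is.na(fac)
    pred <- pred[keep] * fac[keep]
  }
  sum(pred)
}
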