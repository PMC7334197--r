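#' Proportion of singletons
#'
#' Fraction of variants with allele count exactly 1 in the cohort.
#'
#' @param ac Allele counts (non-empty).
#' @return Proportion in `[0, 1]`.
#' @export
singleton_proportion <- function(ac) {
  if (length(ac) == 0L) stop("empty variant list")
  mean(ac == 1L)
}

#' Fit the MAPS mutability calibration on synonymous variants
#'
#' Groups synonymous variants by (methylation stratum, context, alternate)
#' and fits, per methylation stratum, a weighted least-squares line of the
#' per-group singleton proportion on the relative mutation rate, with
#' weights equal to the group variant counts. A stratum with fewer than two
#' distinct rates (or a singular design) falls back to an intercept-only
#' fit with a warning. Predictions are clamped to `[0, 1]`.
#'
#' @param synonymous Table of synonymous variants with columns `AC`,
#'   `context`, `alt_collapsed`, `methylation`, `mu`.
#' @return A `MapsCalibration` with per-stratum coefficients and a training
#'   summary.
#' @export
fit_maps_calibration <- function(synonymous) {
  dt <- data.table::as.data.table(synonymous)
  dt <- dt[!is.na(mu)]
  if (nrow(dt) == 0L) stop("no synonymous variants to calibrate on")
  grp <- dt[, .(n = .N, ps = mean(AC == 1L)),
            by = .(methylation, context, alt_collapsed, mu)]
  strata <- sort(unique(grp$methylation))
  coefs <- data.table::rbindlist(lapply(strata, function(s) {
    g <- grp[methylation == s]
    fallback <- function() {
      data.table::data.table(methylation = s,
                             intercept = sum(g$ps * g$n) / sum(g$n),
                             slope = 0)
    }
    if (length(unique(g$mu)) < 2L) {
      warning("MAPS stratum ", s,
              ": single mutability value, intercept-only fallback")
      return(fallback())
    }
    fit <- stats::lm(ps ~ mu, data = g, weights = g$n)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      warning("MAPS stratum ", s, ": singular fit, intercept-only fallback")
      return(fallback())
    }
    data.table::data.table(methylation = s, intercept = cf[[1]],
                           slope = cf[[2]])
  }))
  structure(list(coefficients = coefs,
                 training = list(n_variants = nrow(dt),
                                 mu_range = range(grp$mu))),
            class = "MapsCalibration")
}

#' @export
print.MapsCalibration <- function(x, ...) {
  cat(sprintf("MapsCalibration on %d synonymous variants, mu in [%g, %g]\n",
              x$training$n_variants, x$training$mu_range[1],
              x$training$mu_range[2]))
  print(x$coefficients)
  invisible(x)
}

predict_maps <- function(calibration, mu, methylation = 0L) {
  stopifnot(inherits(calibration, "MapsCalibration"))
  if (length(methylation) == 1L) methylation <- rep(methylation, length(mu))
  cf <- calibration$coefficients
  idx <- match(methylation, cf$methylation)
  idx[is.na(idx)] <- match(0L, cf$methylation)
  clamp01(cf$intercept[idx] + cf$slope[idx] * mu)
}

#' Mutability-adjusted proportion of singletons (MAPS)
#'
#' For a variant class, MAPS is the observed singleton proportion minus the
#' mean singleton proportion predicted from mutability, where the prediction
#' is calibrated on synonymous variants. Positive values indicate an
#' enrichment of very rare variants relative to the neutral expectation,
#' i.e. a more deleterious frequency spectrum. The standard error is the
#' binomial SE of the observed proportion.
#'
#' @param variants Table of a class's variants with columns `AC`, `mu`,
#'   `methylation`.
#' @param calibration A `MapsCalibration` from [fit_maps_calibration()].
#' @param class_label Optional label stored in the result.
#' @return A `MapsResult`: list with `class`, `n_variants`, `ps_observed`,
#'   `ps_predicted`, `maps`, `se`.
#' @export
compute_maps <- function(variants, calibration, class_label = NA_character_) {
  dt <- data.table::as.data.table(variants)
  dt <- dt[!is.na(mu)]
  if (nrow(dt) == 0L) stop("empty variant class")
  ps_obs <- mean(dt$AC == 1L)
  ps_pred <- mean(predict_maps(calibration, dt$mu, dt$methylation))
  n <- nrow(dt)
  structure(list(class = class_label,
                 n_variants = n,
                 ps_observed = ps_obs,
                 ps_predicted = ps_pred,
                 maps = ps_obs - ps_pred,
                 se = sqrt(ps_obs * (1 - ps_obs) / n)),
            class = "MapsResult")
}

#' @export
print.MapsResult <- function(x, ...) {
  cat(sprintf(
    "MapsResult [%s]: n=%d ps_obs=%.4f ps_pred=%.4f MAPS=%+.4f (se %.4f)\n",
    x$class, x$n_variants, x$ps_observed, x$ps_predicted, x$maps, x$se))
  invisible(x)
}

#' MAPS across variant classes
#'
#' Convenience wrapper computing [compute_maps()] for each level of a
#' grouping column (for example `verdict` or `consequence`).
#'
#' @param variants Annotated variant table.
#' @param calibration A `MapsCalibration`.
#' @param by Name of the grouping column.
#' @return `data.table` with one row per class.
#' @export
maps_by_class <- function(variants, calibration, by = "verdict") {
  dt <- data.table::as.data.table(variants)
  classes <- unique(dt[[by]])
  grp_col <- dt[[by]]
  data.table::rbindlist(lapply(classes, function(cl) {
    r <- compute_maps(dt[which(grp_col == cl), ], calibration,
                      class_label = cl)
    data.table::data.table(class = cl, n_variants = r$n_variants,
                           ps_observed = r$ps_observed,
                           ps_predicted = r$ps_predicted,
                           maps = r$maps, se = r$se)
  }))
}
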