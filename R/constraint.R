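#' Count observed high-confidence variants of a class
#'
#' Counts distinct variants of a class that carry the `HC` verdict, pass
#' site filters (`PASS` or `.`), and have allele frequency below `max_af`.
#' For non-pLoF classes (synonymous, missense) the verdict requirement is
#' dropped.
#'
#' @param observed Annotated observed-variant table carrying `consequence`,
#'   `verdict`, `AF`, `filter` columns (one row per distinct variant).
#' @param consequence Consequence classes to count.
#' @param require_hc Require verdict `HC` (default `TRUE`; use for pLoF).
#' @param max_af Allele-frequency cutoff (default 0.001).
#' @return Integer count.
#' @export
observed_counts <- function(observed,
                            consequence = PLOF_CONSEQUENCES,
                            require_hc = TRUE, max_af = 0.001) {
  if (nrow(observed) == 0L) return(0L)
  sel <- observed$consequence %in% consequence &
    observed$AF < max_af &
    observed$filter %in% c("PASS", ".")
  if (require_hc) sel <- sel & observed$verdict == "HC"
  sum(sel, na.rm = TRUE)
}

#' Poisson-likelihood confidence interval for the observed/expected ratio
#'
#' Over a ratio grid `r = 0, grid_step, ..., grid_max - grid_step`, the
#' Poisson probability of the observed count at mean `r * n_expected` is
#' computed, cumulated, and normalised by its final value. The lower bound
#' is the largest grid ratio with normalised cumulative below `alpha` (0 if
#' none), the upper bound the smallest grid ratio with normalised cumulative
#' at or above `1 - alpha`. At the default `alpha = 0.05` the bounds form
#' the 90% confidence interval whose upper bound is the LOEUF score.
#'
#' @param n_observed Non-negative integer count.
#' @param n_expected Positive expected count.
#' @param alpha Tail mass on each side (default 0.05).
#' @param grid_max,grid_step Grid specification (defaults 2.0 and 0.001).
#' @return Named numeric vector `c(ci_lower, ci_upper)`.
#' @export
oe_confidence_interval <- function(n_observed, n_expected, alpha = 0.05,
                                   grid_max = 2.0, grid_step = 0.001) {
  if (n_expected <= 0) stop("n_expected must be positive")
  if (n_observed < 0) stop("n_observed must be non-negative")
  r <- seq(0, grid_max - grid_step, by = grid_step)
  lik <- stats::dpois(n_observed, r * n_expected)
  cum <- cumsum(lik)
  cum <- cum / cum[length(cum)]
  below <- which(cum < alpha)
  ci_lower <- if (length(below)) r[max(below)] else 0
  at_or_above <- which(cum >= 1 - alpha)
  if (length(at_or_above)) {
    ci_upper <- r[min(at_or_above)]
  } else {
    ci_upper <- grid_max
  }
  if (n_observed / n_expected > grid_max) {
    warning("observed/expected ratio exceeds grid maximum; ",
            "upper bound clamped to ", grid_max)
    ci_upper <- grid_max
  }
  c(ci_lower = ci_lower, ci_upper = ci_upper)
}

#' LOEUF: loss-of-function observed/expected upper bound fraction
#'
#' The 90% upper bound of the Poisson-likelihood confidence interval of the
#' observed/expected ratio ([oe_confidence_interval()] at `alpha = 0.05`).
#' Full precision is retained; use [loeuf_display()] for the two-decimal
#' table representation.
#'
#' @inheritParams oe_confidence_interval
#' @return LOEUF value (scalar).
#' @export
loeuf <- function(n_observed, n_expected, alpha = 0.05, grid_max = 2.0,
                  grid_step = 0.001) {
  unname(oe_confidence_interval(n_observed, n_expected, alpha = alpha,
                                grid_max = grid_max,
                                grid_step = grid_step)[["ci_upper"]])
}

#' Two-decimal display form of LOEUF
#'
#' Table display truncates toward zero (a computed 1.348 prints as 1.34);
#' machine output keeps full precision.
#'
#' @param x LOEUF values.
#' @return Truncated values.
#' @export
loeuf_display <- function(x) trunc2(x)

#' Assign constraint deciles
#'
#' Ranks records by LOEUF ascending (ties broken by expected count
#' descending, then gene id) and splits them into 10 near-equal bins whose
#' sizes differ by at most one, larger bins first. Decile 1 is the most
#' constrained.
#'
#' @param records Data frame with columns `gene_id`, `oe_upper`,
#'   `n_expected`.
#' @return The records with a `decile` column added.
#' @export
assign_deciles <- function(records) {
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to assign deciles")
  ord <- order(records$oe_upper, -records$n_expected, records$gene_id)
  base <- n %/% 10L
  extra <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  decile <- integer(n)
  decile[ord] <- rep(seq_len(10L), times = sizes)
  records$decile <- decile
  records
}

#' Aggregate pLoF frequency of a gene
#'
#' Estimated proportion of haplotypes carrying at least one high-confidence
#' pLoF allele, assuming independent sites:
#' `1 - prod(1 - allele_frequency)`.
#'
#' @param af Allele frequencies of the gene's HC pLoF variants.
#' @return Frequency in `[0, 1]`; 0 for no variants.
#' @export
aggregate_plof_frequency <- function(af) {
  if (length(af) == 0L) return(0)
  1 - prod(1 - af)
}

#' Homozygote tally of a gene
#'
#' @param nhomalt Homozygote counts of the gene's HC pLoF variants.
#' @return List with `n_variants_homozygous` (variants homozygous in at
#'   least one individual) and `total_homozygotes`.
#' @export
homozygote_tally <- function(nhomalt) {
  if (length(nhomalt) == 0L)
    return(list(n_variants_homozygous = 0L, total_homozygotes = 0L))
  list(n_variants_homozygous = sum(nhomalt > 0L),
       total_homozygotes = sum(nhomalt))
}

#' Expected variant discovery under downsampling
#'
#' For each subsample size `n` (haplotypes), the expected number of distinct
#' variants observed is the sum over variants of the hypergeometric
#' probability of drawing at least one alternate allele:
#' `1 - choose(AN - AC, n) / choose(AN, n)`, evaluated with log factorials.
#' The curve is monotone non-decreasing and concave in `n`, and equals the
#' total variant count at `n = AN`.
#'
#' @param ac Allele counts (one per variant).
#' @param an Total allele number of the cohort (scalar).
#' @param sizes Subsample sizes in haplotypes (each `<= an`).
#' @return `data.table` with columns `n` and `expected_variants`.
#' @export
discovery_curve <- function(ac, an, sizes) {
  stopifnot(length(an) == 1L, all(ac >= 1L), all(ac <= an))
  if (any(sizes > an)) stop("subsample size exceeds AN")
  out <- vapply(sizes, function(n) {
    lp <- lchoose(an - ac, n) - lchoose(an, n)
    sum(1 - exp(lp))
  }, numeric(1))
  data.table::data.table(n = as.integer(sizes), expected_variants = out)
}

#' Per-gene constraint table
#'
#' Combines possible-variant enumeration, the calibrated expectation model
#' and observed cohort variants into one constraint record per gene:
#' observed and expected counts, observed/expected ratio with its confidence
#' interval (upper bound = LOEUF) for the pLoF class, analogous
#' observed/expected columns for synonymous and missense variants, the
#' well-powered flag (`n_expected >= powered_threshold`), aggregate pLoF
#' carrier frequency and homozygote tallies. Deciles are assigned over genes
#' with positive expectation.
#'
#' @param possible Possible-variant table (all transcripts) with `mu`,
#'   `median_coverage`.
#' @param observed Observed variant table joined to the possible annotation
#'   (columns of [read_variants()] plus `gene_id`, `consequence`,
#'   `verdict`).
#' @param calibration Fitted `CalibrationModel`.
#' @param cov_model Optional `CoverageModel`.
#' @param max_af Allele-frequency cutoff for observed counts (default
#'   0.001).
#' @param alpha Confidence level parameter (default 0.05 = 90% interval).
#' @param powered_threshold Expected-count threshold for the well-powered
#'   flag (default 10).
#' @return `data.table`, one row per gene.
#' @export
constraint_table <- function(possible, observed, calibration,
                             cov_model = NULL, max_af = 0.001,
                             alpha = 0.05, powered_threshold = 10) {
  possible <- data.table::as.data.table(possible)
  observed <- data.table::as.data.table(observed)
  genes <- unique(possible$gene_id)
  psplit <- split(possible, by = "gene_id")
  osplit <- split(observed, by = "gene_id")
  empty_obs <- observed[0L]
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    pg <- psplit[[g]]
    og <- osplit[[g]] %||% empty_obs
    exp_lof <- expected_counts(pg, calibration, cov_model,
                               consequence = PLOF_CONSEQUENCES,
                               verdict = "HC")
    exp_syn <- expected_counts(pg, calibration, cov_model,
                               consequence = "synonymous")
    exp_mis <- expected_counts(pg, calibration, cov_model,
                               consequence = "missense")
    obs_lof <- observed_counts(og, PLOF_CONSEQUENCES, require_hc = TRUE,
                               max_af = max_af)
    obs_syn <- observed_counts(og, "synonymous", require_hc = FALSE,
                               max_af = max_af)
    obs_mis <- observed_counts(og, "missense", require_hc = FALSE,
                               max_af = max_af)
    hc <- og[og$verdict == "HC" & og$consequence %in% PLOF_CONSEQUENCES &
               og$filter %in% c("PASS", "."), ]
    hz <- homozygote_tally(hc$nhomalt)
    if (exp_lof > 0) {
      ci <- suppressWarnings(
        oe_confidence_interval(obs_lof, exp_lof, alpha = alpha))
    } else {
      ci <- c(ci_lower = NA_real_, ci_upper = NA_real_)
    }
    rows[[i]] <- data.table::data.table(
      gene_id = g,
      transcript_id = pg$transcript_id[1L],
      n_observed = obs_lof, n_expected = exp_lof,
      oe = if (exp_lof > 0) obs_lof / exp_lof else NA_real_,
      oe_lower = unname(ci["ci_lower"]),
      oe_upper = unname(ci["ci_upper"]),
      well_powered = exp_lof >= powered_threshold,
      obs_syn = obs_syn, exp_syn = exp_syn,
      oe_syn = if (exp_syn > 0) obs_syn / exp_syn else NA_real_,
      obs_mis = obs_mis, exp_mis = exp_mis,
      oe_mis = if (exp_mis > 0) obs_mis / exp_mis else NA_real_,
      agg_plof_freq = aggregate_plof_frequency(hc$AF),
      n_variants_homozygous = hz$n_variants_homozygous,
      n_homalt = hz$total_homozygotes
    )
  }
  out <- data.table::rbindlist(rows)
  out[, decile := NA_integer_]
  ok <- which(out$n_expected > 0 & !is.na(out$oe_upper))
  if (length(ok) >= 10L) {
    binned <- assign_deciles(out[ok])
    out$decile[ok] <- binned$decile
  }
  out[]
}
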