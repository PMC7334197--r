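#' Annotate observed variants against the possible-variant table
#'
#' SNVs are matched to the enumerated possible variants by
#' (`contig`, `pos`, `ref`, `alt`), inheriting gene, consequence, verdict,
#' context, rate and coverage columns; unmatched variants (intergenic SNVs,
#' indels) are dropped here and handled by [annotate_variant()] when indel
#' annotation is needed.
#'
#' @param observed Observed variant table from [read_variants()].
#' @param possible Possible-variant table from [enumerate_possible_all()].
#' @return Annotated `data.table` (one row per matched variant).
#' @export
annotate_observed <- function(observed, possible) {
  obs <- data.table::as.data.table(observed)
  poss <- data.table::as.data.table(possible)
  poss[obs, on = c("contig", "pos", "ref", "alt"), nomatch = NULL,
       .(contig, pos, ref, alt, gene_id, transcript_id, cds_position,
         consequence, verdict, filters, context, alt_collapsed, methylation,
         mu,
         median_coverage = if ("median_coverage" %in% names(poss))
           median_coverage else NA_real_,
         AC = i.AC, AN = i.AN, nhomalt = i.nhomalt, filter = i.filter,
         AF = i.AF)]
}

#' Run the constraint pipeline on a cohort
#'
#' End-to-end driver: enumerates possible variants, annotates the observed
#' cohort, fits the synonymous calibration and the coverage-correction
#' model, and produces the per-gene constraint table. The calibration is
#' trained on the same allele-frequency-filtered view of the cohort that
#' the observed counts use, so expectation and observation refer to the
#' same class of rare variation.
#'
#' @param transcripts List of `TranscriptModel` objects.
#' @param ref A `RefSeq` reference.
#' @param observed Observed variant table from [read_variants()].
#' @param coverage A `CoverageTrack` (or `NULL`).
#' @param rates Mutation-rate table.
#' @param methylation Optional methylation track.
#' @param max_af Allele-frequency cutoff for rare-variant counts (default
#'   0.001).
#' @param high_cov High-coverage threshold (default 40).
#' @param params Rule parameters from [loftee_params()].
#' @param possible Optional precomputed possible-variant table (skips
#'   enumeration).
#' @return List with `possible`, `observed` (annotated), `calibration`,
#'   `cov_model` and `constraint` (per-gene table).
#' @export
run_constraint_pipeline <- function(transcripts, ref, observed,
                                    coverage = NULL,
                                    rates = default_rate_table(),
                                    methylation = NULL,
                                    max_af = 0.001, high_cov = 40,
                                    params = loftee_params(),
                                    possible = NULL) {
  if (is.null(possible)) {
    possible <- enumerate_possible_all(transcripts, ref,
                                       coverage = coverage, rates = rates,
                                       methylation = methylation,
                                       params = params)
  }
  obs_annot <- annotate_observed(observed, possible)
  rare <- obs_annot[obs_annot$AF < max_af &
                      obs_annot$filter %in% c("PASS", "."), ]
  calibration <- fit_calibration(possible, rare, high_cov = high_cov)
  cov_model <- tryCatch(
    fit_coverage_model(possible, rare, calibration, high_cov = high_cov),
    error = function(e) {
      warning("coverage model not fitted (", conditionMessage(e),
              "); applying no correction")
      coverage_model(a = 1, b = 0, high_cov = high_cov)
    })
  constraint <- constraint_table(possible, obs_annot, calibration,
                                 cov_model = cov_model, max_af = max_af)
  list(possible = possible, observed = obs_annot,
       calibration = calibration, cov_model = cov_model,
       constraint = constraint)
}
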