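#' Enumerate all possible SNVs of a transcript
#'
#' Emits, for every CDS base and every essential splice-site base of the
#' transcript, all three alternate alleles, annotated exactly as observed
#' variants are: consequence, pLoF verdict and filters, strand-collapsed
#' mutational context with methylation level, relative mutation rate, and
#' median coverage. Sites whose context window contains `N` (or is truncated
#' by a contig edge) are unscorable: they are skipped and counted in the
#' `n_unscorable` attribute of the result.
#'
#' @param tx A `TranscriptModel`.
#' @param ref A `RefSeq` reference.
#' @param coverage Optional `CoverageTrack`; adds a `median_coverage` column.
#' @param rates Optional mutation-rate table; adds a `mu` column.
#' @param methylation Optional methylation track (see [attach_context()]).
#' @param params Rule parameters from [loftee_params()].
#' @return `data.table` of possible variants, 3 rows per scorable base.
#' @export
enumerate_possible <- function(tx, ref, coverage = NULL, rates = NULL,
                               methylation = NULL, params = loftee_params()) {
  if (tx$cds_length == 0L) stop("transcript has an empty CDS")
  plus <- tx$strand == "+"

  ## ---- CDS sites ----------------------------------------------------------
  gpos <- cds_positions(tx)
  cds_seq <- coding_sequence(tx, ref)
  L <- tx$cds_length
  cds_base <- substring(cds_seq, seq_len(L), seq_len(L))
  idx0 <- seq_len(L) - 1L
  codon_idx <- idx0 %/% 3L
  pic <- idx0 %% 3L
  complete <- (codon_idx + 1L) * 3L <= L
  codon <- substring(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)

  # expand 3 alternates per base (CDS-space alleles)
  alt_map <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  scor <- cds_base %in% DNA_BASES
  rows <- rep(seq_len(L)[scor], each = 3L)
  alt_cds <- unlist(alt_map[cds_base[scor]], use.names = FALSE)
  ref_cds_e <- cds_base[rows]
  codon_e <- codon[rows]
  pic_e <- pic[rows]
  alt_codon <- codon_e
  substr_rep <- function(s, at, b) {
    paste0(substr(s, 1L, at), b, substr(s, at + 2L, 3L))
  }
  alt_codon <- substr_rep(codon_e, pic_e, alt_cds)
  cons <- rep("other", length(rows))
  ok <- complete[rows]
  cons[ok] <- classify_codon_change(codon_e[ok], alt_codon[ok],
                                    codon_idx[rows][ok])

  # splice-region upgrade for the last exonic base before each donor site
  ss <- splice_site_table(tx, params$splice_region_intron)
  exon_last_cds <- genomic_to_cds(tx, ss$pos0[ss$role == "exon_last"])
  exon_last_cds <- exon_last_cds[!is.na(exon_last_cds)]
  upgrade <- idx0[rows] %in% exon_last_cds & cons == "synonymous"
  cons[upgrade] <- "splice_region"

  cds_dt <- data.table::data.table(
    contig = tx$contig,
    pos = as.integer(gpos[rows] + 1L),
    ref = if (plus) ref_cds_e else comp_base(ref_cds_e),
    alt = if (plus) alt_cds else comp_base(alt_cds),
    cds_position = idx0[rows],
    consequence = cons
  )

  ## ---- essential splice sites --------------------------------------------
  ess <- ss[ss$role == "essential", ]
  if (nrow(ess) > 0L) {
    ref_b <- ref_base_at(ref, tx$contig, ess$pos0)
    scor_s <- !is.na(ref_b) & ref_b %in% DNA_BASES
    e_rows <- rep(which(scor_s), each = 3L)
    alt_s <- unlist(alt_map[ref_b[scor_s]], use.names = FALSE)
    spl_dt <- data.table::data.table(
      contig = tx$contig,
      pos = as.integer(ess$pos0[e_rows] + 1L),
      ref = ref_b[e_rows],
      alt = alt_s,
      cds_position = NA_integer_,
      consequence = paste0("splice_", ess$side[e_rows]),
      intron = ess$intron[e_rows],
      side = ess$side[e_rows]
    )
  } else {
    spl_dt <- NULL
  }

  ## ---- verdicts -----------------------------------------------------------
  cds_dt[, verdict := "not_pLoF"]
  cds_dt[, filters := ""]
  trunc_rows <- cds_dt$consequence == "stop_gained"
  if (any(trunc_rows)) {
    f <- character(sum(trunc_rows))
    esc <- nmd_escapes(tx, cds_dt$cds_position[trunc_rows],
                       params$nmd_window)
    f[esc] <- "END_TRUNC"
    if (tx$cds_incomplete)
      f <- ifelse(nzchar(f), paste("END_TRUNC", "INCOMPLETE_CDS", sep = ","),
                  "INCOMPLETE_CDS")
    cds_dt$filters[trunc_rows] <- f
    cds_dt$verdict[trunc_rows] <- ifelse(nzchar(f), "LC", "HC")
  }
  cds_dt$verdict[cds_dt$consequence == "splice_region"] <- "OS"

  if (!is.null(spl_dt)) {
    key <- unique(spl_dt[, .(intron, side)])
    key[, fil := vapply(seq_len(.N), function(i)
      paste(sort(unique(c(
        if (tx$cds_incomplete) "INCOMPLETE_CDS" else character(0),
        splice_site_filters(tx, ref, intron[i], side[i], params)))),
        collapse = ","), character(1))]
    spl_dt <- key[spl_dt, on = c("intron", "side")]
    spl_dt[, verdict := ifelse(nzchar(fil), "LC", "HC")]
    data.table::setnames(spl_dt, "fil", "filters")
    spl_dt[, c("intron", "side") := NULL]
    out <- data.table::rbindlist(list(cds_dt, spl_dt), use.names = TRUE)
  } else {
    out <- cds_dt
  }
  out[, `:=`(gene_id = tx$gene_id, transcript_id = tx$transcript_id)]

  ## ---- context, methylation, rates, coverage ------------------------------
  out <- attach_context(out, ref, methylation)
  # unscorable = alternates dropped for N-context windows plus the three
  # alternates of every reference base that is not A/C/G/T
  n_bad_ref <- sum(!scor)
  if (!is.null(spl_dt)) n_bad_ref <- n_bad_ref + sum(!scor_s)
  n_unscorable <- sum(is.na(out$context)) + 3L * n_bad_ref
  out <- out[!is.na(context)]
  if (!is.null(rates)) out <- lookup_mu(out, rates)
  if (!is.null(coverage))
    out[, median_coverage := coverage_at(coverage, tx$contig, pos - 1L)]
  data.table::setkey(out, contig, pos, ref, alt)
  data.table::setattr(out, "n_unscorable", n_unscorable)
  out[]
}

#' Enumerate possible SNVs for many transcripts
#'
#' @inheritParams enumerate_possible
#' @param transcripts List of `TranscriptModel` objects.
#' @return Combined `data.table` (see [enumerate_possible()]); the
#'   `n_unscorable` attribute is summed across transcripts.
#' @export
enumerate_possible_all <- function(transcripts, ref, coverage = NULL,
                                   rates = NULL, methylation = NULL,
                                   params = loftee_params()) {
  parts <- lapply(transcripts, enumerate_possible, ref = ref,
                  coverage = coverage, rates = rates,
                  methylation = methylation, params = params)
  out <- data.table::rbindlist(parts, use.names = TRUE)
  data.table::setattr(out, "n_unscorable",
                      sum(vapply(parts, attr, numeric(1), "n_unscorable")))
  data.table::setkey(out, contig, pos, ref, alt)
  out[]
}
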