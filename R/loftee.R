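#' Rule parameters for pLoF classification
#'
#' Tunable constants of the first-principles pLoF filters.
#'
#' @param nmd_window Number of coding bases upstream of the 3'-most
#'   exon-exon junction within which a premature stop is predicted to escape
#'   nonsense-mediated decay (default 50, the canonical NMD rule).
#' @param min_intron Minimum intron length in bases; essential-splice
#'   disruptions of shorter introns are low confidence (default 15).
#' @param rescue_window Half-width (bases, sense orientation) of the scan for
#'   a frame-preserving cryptic GT/AG site rescuing a disrupted splice site
#'   (default 15).
#' @param splice_region_intron Intronic positions (inclusive range from the
#'   exon boundary) annotated as splice region (default 3-8).
#' @param max_indel Maximum indel length annotated; larger events are
#'   rejected as structural (default 50).
#' @param flank Flank in bases around the transcript span within which
#'   variants are annotated (default 200).
#' @return List of parameters.
#' @export
loftee_params <- function(nmd_window = 50L, min_intron = 15L,
                          rescue_window = 15L,
                          splice_region_intron = c(3L, 8L),
                          max_indel = 50L, flank = 200L) {
  list(nmd_window = as.integer(nmd_window),
       min_intron = as.integer(min_intron),
       rescue_window = as.integer(rescue_window),
       splice_region_intron = as.integer(splice_region_intron),
       max_indel = as.integer(max_indel),
       flank = as.integer(flank))
}

PLOF_CONSEQUENCES <- c("stop_gained", "frameshift", "splice_donor",
                       "splice_acceptor")

## shared truncation rule: does a premature stop / frameshift at CDS offset
## cds_pos escape NMD on this transcript?
nmd_escapes <- function(tx, cds_pos, nmd_window) {
  junction <- last_coding_junction(tx)
  if (is.na(junction)) return(rep(TRUE, length(cds_pos)))  # single coding exon
  cds_pos >= junction - nmd_window
}

## per-intron splice filters, computed once per (intron, side)
splice_site_filters <- function(tx, ref, intron, side, params) {
  introns <- tx_introns(tx)
  ilen <- introns$end[intron] - introns$start[intron]
  filters <- character(0)
  if (ilen < params$min_intron) filters <- c(filters, "SMALL_INTRON")
  dinucs <- intron_boundary_dinucs(tx, ref, intron)
  if (!(identical(dinucs$first2, "GT") && identical(dinucs$last2, "AG")))
    filters <- c(filters, "NON_CANONICAL_INTRON")
  if (has_splice_rescue(tx, ref, intron, side, params$rescue_window))
    filters <- c(filters, "SPLICE_RESCUE")
  filters
}

#' Classify a pLoF call as high or low confidence
#'
#' Applies the first-principles filters to a [annotate_variant()] call:
#' * `END_TRUNC`: stop-gained/frameshift in the last coding exon or within
#'   the NMD-escape window upstream of the 3'-most exon-exon junction
#'   (in single-coding-exon transcripts every premature stop escapes NMD).
#' * `SMALL_INTRON`: essential-splice disruption of an intron shorter than
#'   `min_intron` bases.
#' * `SPLICE_RESCUE`: a frame-preserving cryptic GT/AG within the rescue
#'   window of a disrupted essential splice site.
#' * `NON_CANONICAL_INTRON`: the disrupted intron is not GT..AG.
#' * `INCOMPLETE_CDS`: the transcript CDS length is not a multiple of 3.
#'
#' A filtered call is low confidence (`LC`, with its named filters), an
#' unfiltered one high confidence (`HC`). Predicted splice-affecting variants
#' outside the two essential intronic bases (consequence `splice_region`)
#' receive the other-splice verdict `OS`; everything else is `not_pLoF`.
#'
#' @param call A `ConsequenceCall` from [annotate_variant()] on the same
#'   transcript.
#' @param tx The `TranscriptModel` the call was made on.
#' @param ref A `RefSeq` reference.
#' @param params Rule parameters from [loftee_params()].
#' @return A `LofteeVerdict`: list with `verdict` (`HC`/`LC`/`OS`/
#'   `not_pLoF`), `filters` (character vector), and the `call`.
#' @export
classify_plof <- function(call, tx, ref, params = loftee_params()) {
  if (!identical(call$transcript_id, tx$transcript_id))
    stop("call was produced on transcript ", call$transcript_id,
         ", not ", tx$transcript_id)
  cons <- call$consequence
  filters <- character(0)
  verdict <- "not_pLoF"
  if (cons %in% c("stop_gained", "frameshift")) {
    if (tx$cds_incomplete) filters <- c(filters, "INCOMPLETE_CDS")
    if (!is.na(call$cds_position) &&
        nmd_escapes(tx, call$cds_position, params$nmd_window))
      filters <- c(filters, "END_TRUNC")
    verdict <- if (length(filters)) "LC" else "HC"
  } else if (cons %in% c("splice_donor", "splice_acceptor")) {
    if (tx$cds_incomplete) filters <- c(filters, "INCOMPLETE_CDS")
    g0 <- as.integer(call$variant$pos) - 1L
    ss <- splice_site_table(tx, params$splice_region_intron)
    hit <- ss[ss$role == "essential" & ss$pos0 == g0, ]
    if (nrow(hit) == 0L) {
      # indel spanning the essential site: locate by overlap
      introns <- tx_introns(tx)
      width <- max(nchar(call$variant$ref) - 1L, 1L)
      affected <- seq.int(g0, g0 + width)
      hit <- ss[ss$role == "essential" & ss$pos0 %in% affected, ][1L, ]
    }
    filters <- c(filters,
                 splice_site_filters(tx, ref, hit$intron, hit$side, params))
    verdict <- if (length(filters)) "LC" else "HC"
  } else if (cons == "splice_region") {
    verdict <- "OS"
  }
  structure(list(call = call, verdict = verdict,
                 filters = sort(unique(filters))),
            class = "LofteeVerdict")
}

#' @export
print.LofteeVerdict <- function(x, ...) {
  cat(sprintf("LofteeVerdict: %s %s%s\n", x$call$consequence, x$verdict,
              if (length(x$filters))
                paste0(" {", paste(x$filters, collapse = ","), "}") else ""))
  invisible(x)
}
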