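#' Consequence severity ordering
#'
#' Fixed most-severe-first ordering used to reduce each (variant, transcript)
#' pair to a single consequence term.
#'
#' @return Character vector of consequence terms, most severe first.
#' @export
consequence_order <- function() {
  c("stop_gained", "frameshift", "splice_donor", "splice_acceptor",
    "stop_lost", "start_lost", "missense", "inframe_indel",
    "splice_region", "synonymous", "intron", "utr", "other")
}

most_severe <- function(candidates) {
  ord <- consequence_order()
  hit <- ord[ord %in% candidates]
  if (length(hit) == 0L) "other" else hit[1L]
}

## ---- splice-site geometry -------------------------------------------------

## table of essential splice and splice-region positions for every intron,
## in genomic 0-based coordinates, with sides labelled in the transcript
## (sense) orientation
splice_site_table <- function(tx, splice_region_intron = c(3L, 8L)) {
  introns <- tx_introns(tx)
  n <- nrow(introns)
  if (n == 0L)
    return(data.table::data.table(intron = integer(0), pos0 = integer(0),
                                  role = character(0), side = character(0)))
  lo <- splice_region_intron[1L]; hi <- splice_region_intron[2L]
  res <- vector("list", n)
  for (i in seq_len(n)) {
    is <- introns$start[i]; ie <- introns$end[i]
    if (tx$strand == "+") {
      donor <- c(is, is + 1L)
      acceptor <- c(ie - 2L, ie - 1L)
      donor_region <- seq.int(is + lo - 1L, min(is + hi - 1L, ie - 1L))
      acceptor_region <- seq.int(max(ie - hi, is), ie - lo)
      exon_last <- is - 1L
    } else {
      donor <- c(ie - 2L, ie - 1L)
      acceptor <- c(is, is + 1L)
      donor_region <- seq.int(max(ie - hi, is), ie - lo)
      acceptor_region <- seq.int(is + lo - 1L, min(is + hi - 1L, ie - 1L))
      exon_last <- ie
    }
    res[[i]] <- data.table::data.table(
      intron = i,
      pos0 = c(donor, acceptor, donor_region, acceptor_region, exon_last),
      role = c(rep("essential", 4L),
               rep("region_intronic", length(donor_region) +
                     length(acceptor_region)),
               "exon_last"),
      side = c("donor", "donor", "acceptor", "acceptor",
               rep("donor", length(donor_region)),
               rep("acceptor", length(acceptor_region)),
               "donor"))
  }
  data.table::rbindlist(res)
}

## sense-orientation intron boundary dinucleotides
intron_boundary_dinucs <- function(tx, ref, intron) {
  introns <- tx_introns(tx)
  is <- introns$start[intron]; ie <- introns$end[intron]
  if (tx$strand == "+") {
    list(first2 = ref_fetch(ref, tx$contig, is, is + 2L),
         last2 = ref_fetch(ref, tx$contig, ie - 2L, ie))
  } else {
    list(first2 = ref_fetch(ref, tx$contig, ie - 2L, ie, strand = "-"),
         last2 = ref_fetch(ref, tx$contig, is, is + 2L, strand = "-"))
  }
}

## TRUE when a frame-preserving cryptic GT (donor) / AG (acceptor) lies
## within +/- window sense bases of the canonical dinucleotide
has_splice_rescue <- function(tx, ref, intron, site, window = 15L) {
  introns <- tx_introns(tx)
  is <- introns$start[intron]; ie <- introns$end[intron]
  plus <- tx$strand == "+"
  target <- if (site == "donor") "GT" else "AG"
  anchor <- if (site == "donor") {
    if (plus) is else ie - 2L
  } else {
    if (plus) ie - 2L else is
  }
  deltas <- setdiff(seq.int(-window, window, by = 3L), 0L)
  len <- ref_lengths(ref)[[tx$contig]]
  for (d in deltas) {
    g <- if (plus) anchor + d else anchor - d
    if (g < 0L || g + 2L > len) next
    dinuc <- ref_fetch(ref, tx$contig, g, g + 2L,
                       strand = if (plus) "+" else "-")
    if (identical(dinuc, target)) return(TRUE)
  }
  FALSE
}

## ---- codon-level classification -------------------------------------------

classify_codon_change <- function(ref_codon, alt_codon, codon_idx) {
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  out <- rep("missense", length(ref_codon))
  out[is.na(ref_aa) | is.na(alt_aa)] <- "other"
  out[!is.na(ref_aa) & !is.na(alt_aa) & ref_aa == alt_aa] <- "synonymous"
  out[!is.na(alt_aa) & alt_aa == "*" & !is.na(ref_aa) & ref_aa != "*"] <-
    "stop_gained"
  out[!is.na(ref_aa) & ref_aa == "*" & !is.na(alt_aa) & alt_aa != "*"] <-
    "stop_lost"
  start_hit <- codon_idx == 0L & ref_codon == "ATG" & alt_codon != "ATG" &
    !is.na(ref_aa)
  out[start_hit] <- "start_lost"
  out
}

## ---- single-variant annotation --------------------------------------------

#' Annotate the consequence of one variant on one transcript
#'
#' Computes the single most-severe consequence of a (minimally represented)
#' variant against a transcript using the standard genetic code. Essential
#' splice sites are the two intronic bases adjacent to each internal exon
#' boundary; the splice region covers the last exonic base before a donor
#' site and intronic positions 3-8 on either side. Indels whose length
#' change is not a multiple of 3 inside the CDS are frameshifts, otherwise
#' in-frame indels; events longer than `max_indel` are rejected as
#' structural.
#'
#' @param variant A list or single-row data frame with `pos` (1-based),
#'   `ref`, `alt`.
#' @param tx A `TranscriptModel`.
#' @param ref A `RefSeq` reference.
#' @param params Rule parameters from [loftee_params()].
#' @return A `ConsequenceCall`: list with `transcript_id`, `consequence`,
#'   `cds_position` (0-based or `NA`), `out_of_range`, and the `variant`.
#' @export
annotate_variant <- function(variant, tx, ref, params = loftee_params()) {
  pos <- as.integer(variant$pos); ref_a <- variant$ref; alt_a <- variant$alt
  if (ref_a == alt_a) stop("ref and alt alleles are identical")
  if (abs(nchar(alt_a) - nchar(ref_a)) > params$max_indel)
    stop("event larger than ", params$max_indel,
         " bp rejected as structural")
  g0 <- pos - 1L
  span <- range(c(tx$exons$start, tx$exons$end))
  call <- list(variant = variant, transcript_id = tx$transcript_id,
               consequence = "other", cds_position = NA_integer_,
               out_of_range = FALSE)
  class(call) <- "ConsequenceCall"
  if (g0 < span[1] - params$flank || g0 >= span[2] + params$flank) {
    call$out_of_range <- TRUE
    return(call)
  }
  ss <- splice_site_table(tx, params$splice_region_intron)
  snv <- is_snv(ref_a, alt_a)
  if (snv) {
    cand <- character(0)
    ess <- ss[ss$role == "essential" & ss$pos0 == g0, ]
    if (nrow(ess) > 0L)
      cand <- c(cand, paste0("splice_", ess$side[1L]))
    cds_pos <- genomic_to_cds(tx, g0)
    if (!is.na(cds_pos)) {
      codon_idx <- cds_pos %/% 3L
      if ((codon_idx + 1L) * 3L <= tx$cds_length) {
        cds_seq <- coding_sequence(tx, ref)
        ref_codon <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
        pic <- cds_pos %% 3L
        alt_base <- if (tx$strand == "+") alt_a else comp_base(alt_a)
        alt_codon <- ref_codon
        substr(alt_codon, pic + 1L, pic + 1L) <- alt_base
        cand <- c(cand, classify_codon_change(ref_codon, alt_codon, codon_idx))
      }
      if (nrow(ss[ss$role == "exon_last" & ss$pos0 == g0, ]) > 0L)
        cand <- c(cand, "splice_region")
      call$cds_position <- cds_pos
    } else if (nrow(ss[ss$role == "region_intronic" & ss$pos0 == g0, ]) > 0L) {
      cand <- c(cand, "splice_region")
    } else if (in_intervals(g0, tx_introns(tx))) {
      cand <- c(cand, "intron")
    } else if (in_intervals(g0, tx$exons)) {
      cand <- c(cand, "utr")
    }
    call$consequence <- most_severe(cand)
    return(call)
  }
  # indel path (minimal representation assumed)
  len_diff <- nchar(alt_a) - nchar(ref_a)
  affected <- if (nchar(ref_a) > 1L) seq.int(g0 + 1L, g0 + nchar(ref_a) - 1L)
              else c(g0, g0 + 1L)
  cand <- character(0)
  ess <- ss[ss$role == "essential" & ss$pos0 %in% affected, ]
  if (nrow(ess) > 0L) cand <- c(cand, paste0("splice_", ess$side))
  cds_hits <- genomic_to_cds(tx, affected)
  if (any(!is.na(cds_hits))) {
    cand <- c(cand, if (len_diff %% 3L != 0L) "frameshift" else
      "inframe_indel")
    call$cds_position <- min(cds_hits, na.rm = TRUE)
  } else if (any(vapply(affected, in_intervals, logical(1),
                        iv = tx_introns(tx)))) {
    cand <- c(cand, "intron")
  } else if (any(vapply(affected, in_intervals, logical(1), iv = tx$exons))) {
    cand <- c(cand, "utr")
  }
  call$consequence <- most_severe(cand)
  call
}

in_intervals <- function(p, iv) {
  if (nrow(iv) == 0L) return(FALSE)
  any(p >= iv$start & p < iv$end)
}

#' @export
print.ConsequenceCall <- function(x, ...) {
  cat(sprintf("ConsequenceCall: %s on %s (cds_position %s)%s\n",
              x$consequence, x$transcript_id,
              ifelse(is.na(x$cds_position), "NA", x$cds_position),
              if (isTRUE(x$out_of_range)) " [out of range]" else ""))
  invisible(x)
}
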