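#' Construct a transcript model
#'
#' A `TranscriptModel` carries the exon and CDS structure of one transcript
#' and is the coordinate frame for all consequence annotation. Intervals are
#' 0-based half-open genomic coordinates on a single contig; they are stored
#' in ascending genomic order internally and presented 5'->3' in transcript
#' orientation by the accessors.
#'
#' @param transcript_id,gene_id,gene_symbol Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column data frames (`start`, `end`) of 0-based
#'   half-open intervals. Exons must be non-overlapping; every CDS interval
#'   must lie within an exon.
#' @param canonical Logical flag marking the gene's representative transcript.
#' @return A `TranscriptModel` object.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exons, cds, gene_symbol = gene_id,
                             canonical = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(exons) <- NULL
  rownames(cds) <- NULL
  if (nrow(exons) == 0L) stop("transcript must have at least one exon")
  if (any(exons$start >= exons$end) || any(cds$start >= cds$end))
    stop("intervals must satisfy start < end")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons overlap in transcript ", transcript_id)
  for (i in seq_len(nrow(cds))) {
    inside <- cds$start[i] >= exons$start & cds$end[i] <= exons$end
    if (!any(inside))
      stop("CDS interval outside exons in transcript ", transcript_id)
  }
  cds_length <- sum(cds$end - cds$start)
  if (cds_length <= 0L) stop("transcript has zero CDS length")
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    gene_symbol = gene_symbol,
    contig = contig,
    strand = strand,
    exons = exons,
    cds = cds,
    cds_length = cds_length,
    cds_incomplete = (cds_length %% 3L) != 0L,
    canonical = isTRUE(canonical)
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf(
    "TranscriptModel %s (%s, %s strand): %d exon(s), CDS %d bp%s%s\n",
    x$transcript_id, x$gene_id, x$strand, nrow(x$exons), x$cds_length,
    if (x$cds_incomplete) " [incomplete CDS]" else "",
    if (x$canonical) " [canonical]" else ""))
  invisible(x)
}

#' Exons in transcript orientation
#'
#' Returns the exon (or CDS) intervals ordered 5'->3' along the transcript:
#' ascending genomic order on the plus strand, descending on the minus
#' strand.
#'
#' @param tx A `TranscriptModel`.
#' @param what `"exons"` or `"cds"`.
#' @return Data frame of `start`, `end` intervals.
#' @export
tx_intervals <- function(tx, what = c("exons", "cds")) {
  what <- match.arg(what)
  iv <- tx[[what]]
  if (tx$strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

## introns in ascending genomic order: gaps between consecutive exons
tx_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n], end = ex$start[-1L])
}

## genomic 0-based positions of the CDS, ordered 5'->3' along the transcript;
## element i is the genomic position of CDS offset i-1
cds_positions <- function(tx) {
  iv <- tx_intervals(tx, "cds")
  pos <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    p <- seq.int(iv$start[i], iv$end[i] - 1L)
    if (tx$strand == "-") rev(p) else p
  }), use.names = FALSE)
  as.integer(pos)
}

## map genomic 0-based positions to 0-based CDS offsets (NA when not in CDS)
genomic_to_cds <- function(tx, gpos0) {
  cp <- cds_positions(tx)
  match(gpos0, cp) - 1L
}

## CDS offset of the 3'-most exon-exon junction that interrupts the CDS, or
## NA when the CDS lies in a single exon
last_coding_junction <- function(tx) {
  iv <- tx_intervals(tx, "cds")
  if (nrow(iv) < 2L) return(NA_integer_)
  widths <- iv$end - iv$start
  as.integer(sum(widths) - widths[length(widths)])
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the CDS exon slices 5'->3' in transcript orientation
#' (reverse-complementing on the minus strand). The CDS-completeness flag is
#' propagated as the `"incomplete"` attribute.
#'
#' @param tx A `TranscriptModel`.
#' @param ref A `RefSeq` reference.
#' @return Character CDS string with attribute `incomplete`.
#' @export
coding_sequence <- function(tx, ref) {
  iv <- tx_intervals(tx, "cds")
  parts <- vapply(seq_len(nrow(iv)), function(i)
    ref_fetch(ref, tx$contig, iv$start[i], iv$end[i], strand = tx$strand),
    character(1))
  s <- paste(parts, collapse = "")
  attr(s, "incomplete") <- tx$cds_incomplete
  s
}

#' Read transcript models from GTF
#'
#' Parses `exon` and `CDS` features carrying `transcript_id` and `gene_id`
#' attributes into [transcript_model()] objects. GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention at
#' this boundary. The canonical transcript is taken from a configurable
#' attribute tag (any transcript whose `tag` attribute equals
#' `canonical_tag`); when no transcript of a gene carries the tag, the
#' longest-CDS transcript is designated canonical, ties broken by
#' lexicographic transcript id.
#'
#' Transcripts whose CDS falls outside their exons are rejected with a
#' message; a file yielding zero usable transcripts is an error.
#'
#' @param path Path to a GTF file.
#' @param canonical_tag Value of the `tag` attribute marking canonical
#'   transcripts (default `"canonical"`).
#' @return Named list of `TranscriptModel` objects (by transcript id).
#' @export
read_transcripts <- function(path, canonical_tag = "canonical") {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  md$type <- as.character(md$type)
  md <- md[md$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(md) == 0L) stop("no exon/CDS features in GTF: ", path)
  if (is.null(md$transcript_id) || is.null(md$gene_id))
    stop("GTF features must carry transcript_id and gene_id attributes")
  has_tag <- "tag" %in% names(md)
  models <- list()
  for (txid in unique(md$transcript_id)) {
    rows <- md[md$transcript_id == txid, , drop = FALSE]
    ex <- rows[rows$type == "exon", , drop = FALSE]
    cd <- rows[rows$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cd) == 0L) {
      message("skipping transcript ", txid, ": missing exon or CDS features")
      next
    }
    sym <- if (!is.null(rows$gene_name)) rows$gene_name[1] else
      rows$gene_id[1]
    canon <- has_tag && any(!is.na(rows$tag) & rows$tag == canonical_tag)
    m <- tryCatch(
      transcript_model(
        transcript_id = txid,
        gene_id = rows$gene_id[1],
        gene_symbol = sym,
        contig = as.character(rows$seqnames[1]),
        strand = as.character(rows$strand[1]),
        # GTF 1-based inclusive -> 0-based half-open
        exons = data.frame(start = ex$start - 1L, end = ex$end),
        cds = data.frame(start = cd$start - 1L, end = cd$end),
        canonical = canon
      ),
      error = function(e) {
        message("rejecting transcript ", txid, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(m)) models[[txid]] <- m
  }
  if (length(models) == 0L) stop("no usable transcripts in GTF: ", path)
  if (!any(vapply(models, function(m) m$canonical, logical(1)))) {
    models <- flag_canonical_fallback(models)
  }
  models
}

## longest-CDS transcript per gene becomes canonical; ties -> lexicographic id
flag_canonical_fallback <- function(models) {
  genes <- vapply(models, function(m) m$gene_id, character(1))
  for (g in unique(genes)) {
    ids <- names(models)[genes == g]
    lens <- vapply(models[ids], function(m) m$cds_length, integer(1))
    pick <- ids[order(-lens, ids)][1]
    models[[pick]]$canonical <- TRUE
  }
  models
}

#' Write transcript models to GTF
#'
#' Inverse of [read_transcripts()]: emits `exon` and `CDS` features with
#' `gene_id`, `transcript_id`, `gene_name` attributes and a
#' `tag "canonical"` attribute on canonical transcripts. CDS phase is
#' computed from cumulative coding length.
#'
#' @param models List of `TranscriptModel` objects.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(models, path, source = "lofkit") {
  lines <- character(0)
  for (m in models) {
    attr_base <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                         m$gene_id, m$transcript_id, m$gene_symbol)
    if (m$canonical)
      attr_base <- paste(attr_base, 'tag "canonical";')
    ex <- m$exons
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(m$contig, source, "exon",
                              ex$start[i] + 1L, ex$end[i], ".", m$strand, ".",
                              attr_base, sep = "\t"))
    }
    cd <- tx_intervals(m, "cds")
    cum <- cumsum(c(0L, cd$end - cd$start))
    phase <- (3L - (cum[-length(cum)] %% 3L)) %% 3L
    ord <- seq_len(nrow(cd))
    for (k in ord) {
      lines <- c(lines, paste(m$contig, source, "CDS",
                              cd$start[k] + 1L, cd$end[k], ".", m$strand,
                              phase[k], attr_base, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
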