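#' Read cohort variant records from VCF
#'
#' Reads a VCF (v4.2) with `AC` and `AN` INFO fields (and optionally
#' `nhomalt`, defaulting to 0) into a flat table of bi-allelic records.
#' Multi-allelic sites are split into one record per alternate allele and
#' reduced to minimal representation by shared suffix/prefix trimming before
#' any downstream annotation. Records with `AC > AN` are rejected with a
#' message; site filters are propagated verbatim.
#'
#' @param path Path to a VCF file.
#' @return `data.table` with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `AC`, `AN`, `nhomalt`, `filter`, `AF`.
#' @export
read_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "cohort")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  if (is.null(info$AC) || is.null(info$AN))
    stop("VCF INFO must contain AC and AN: ", path)
  ac <- as.integer(unlist(info$AC))
  an <- as.integer(unlist(info$AN))
  nh <- if (!is.null(info$nhomalt)) as.integer(unlist(info$nhomalt))
        else rep(0L, length(ac))
  nh[is.na(nh)] <- 0L
  filt <- as.character(rr$FILTER)
  dt <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    AC = ac, AN = an, nhomalt = nh, filter = filt
  )
  bad <- !is.na(dt$AC) & !is.na(dt$AN) & dt$AC > dt$AN
  if (any(bad)) {
    message("rejecting ", sum(bad), " record(s) with AC > AN")
    dt <- dt[!bad]
  }
  dt <- dt[ref != alt]
  trimmed <- normalize_alleles(dt$pos, dt$ref, dt$alt)
  dt[, `:=`(pos = trimmed$pos, ref = trimmed$ref, alt = trimmed$alt)]
  dt[, AF := AC / AN]
  data.table::setkey(dt, contig, pos, ref, alt)
  dt[]
}

#' Minimal allele representation
#'
#' Trims shared suffix bases, then shared prefix bases (advancing `pos`),
#' keeping at least one base on each allele, so that e.g. `CTT>CT` at
#' position 100 becomes the canonical single-base deletion `CT>C`.
#'
#' @param pos 1-based positions.
#' @param ref,alt Allele strings.
#' @return List of trimmed `pos`, `ref`, `alt` vectors.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    # suffix trim
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # prefix trim
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a per-base median coverage track
#'
#' The track is a BED-like TSV with columns `contig`, `start` (0-based),
#' `end` (exclusive) and `median_coverage`; runs of equal coverage are stored
#' as intervals. Positions outside the track are "uncovered" and reported as
#' `NA` by [coverage_at()].
#'
#' @param path Path to the TSV (with header).
#' @return A `CoverageTrack` object.
#' @export
read_coverage <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  data.table::setnames(dt, c("contig", "start", "end", "median_coverage"))
  coverage_track(dt)
}

#' Build a coverage track from an interval table
#'
#' @param dt Data frame/`data.table` with columns `contig`, `start`, `end`
#'   (0-based half-open) and `median_coverage` (non-negative).
#' @return A `CoverageTrack` object.
#' @export
coverage_track <- function(dt) {
  dt <- data.table::as.data.table(dt)[, .(contig, start, end,
                                          median_coverage)]
  if (any(dt$median_coverage < 0)) stop("median_coverage must be >= 0")
  if (any(dt$start >= dt$end)) stop("coverage intervals must have start < end")
  data.table::setkey(dt, contig, start)
  structure(list(intervals = dt), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", nrow(x$intervals), "interval(s) on",
      length(unique(x$intervals$contig)), "contig(s)\n")
  invisible(x)
}

#' Median coverage at genomic positions
#'
#' @param track A `CoverageTrack`.
#' @param contig Contig name (scalar or vector parallel to `pos0`).
#' @param pos0 0-based positions.
#' @return Numeric vector of median coverage; `NA` for positions outside the
#'   track (the "uncovered" sentinel).
#' @export
coverage_at <- function(track, contig, pos0) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (length(contig) == 1L) contig <- rep(contig, length(pos0))
  out <- rep(NA_real_, length(pos0))
  iv <- track$intervals
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    sub <- iv[contig == ctg]
    if (nrow(sub) == 0L) next
    idx <- findInterval(pos0[sel], sub$start)
    hit <- idx >= 1L & idx <= nrow(sub)
    hit[hit] <- pos0[sel][hit] < sub$end[idx[hit]]
    res <- rep(NA_real_, sum(sel))
    res[hit] <- sub$median_coverage[idx[hit]]
    out[sel] <- res
  }
  out
}

#' Write a coverage track to TSV
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  data.table::fwrite(track$intervals, path, sep = "\t")
  invisible(path)
}
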