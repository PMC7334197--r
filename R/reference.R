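#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into an in-memory reference accessor. Contig names are
#' taken from the first whitespace-delimited token of each header and must be
#' unique. Sequence is normalised to upper case; any character outside
#' `A/C/G/T/N` is preserved and later treated as unscorable by the mutation
#' model.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `RefSeq` supporting [ref_fetch()] queries.
#' @seealso [ref_fetch()], [coding_sequence()]
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig names in FASTA: ", path)
  ref_from_strings(toupper(as.character(seqs)))
}

#' Build a reference accessor from named character sequences
#'
#' In-memory constructor used by the synthetic-data generator and in tests;
#' equivalent to writing a FASTA and calling [read_reference()].
#'
#' @param seqs Named character vector of contig sequences.
#' @return A `RefSeq` object.
#' @export
ref_from_strings <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  structure(
    list(seq = toupper(seqs), lengths = nchar(seqs)),
    class = "RefSeq"
  )
}

#' @export
print.RefSeq <- function(x, ...) {
  cat("RefSeq with", length(x$seq), "contig(s):\n")
  for (nm in names(x$seq))
    cat(sprintf("  %s (%d bp)\n", nm, x$lengths[[nm]]))
  invisible(x)
}

#' Contig lengths of a reference
#' @param ref A `RefSeq` object.
#' @return Named integer vector of contig lengths.
#' @export
ref_lengths <- function(ref) {
  stopifnot(inherits(ref, "RefSeq"))
  ref$lengths
}

#' Fetch reference sequence by interval
#'
#' Coordinates are 0-based half-open, the package-wide internal convention.
#' With `strand = "-"` the reverse complement of the plus-strand slice is
#' returned.
#'
#' @param ref A `RefSeq` object.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval, `0 <= start < end <= contig
#'   length`.
#' @param strand `"+"` or `"-"`.
#' @return Upper-case sequence string.
#' @export
ref_fetch <- function(ref, contig, start, end, strand = "+") {
  stopifnot(inherits(ref, "RefSeq"))
  if (!contig %in% names(ref$seq)) stop("unknown contig: ", contig)
  if (start < 0 || end > ref$lengths[[contig]] || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, contig, ref$lengths[[contig]]))
  s <- substr(ref$seq[[contig]], start + 1L, end)
  if (identical(strand, "-")) revcomp(s) else s
}

## vectorised single-base lookup at 0-based positions; returns NA outside the
## contig instead of erroring (used by bulk enumeration)
ref_base_at <- function(ref, contig, pos0) {
  stopifnot(inherits(ref, "RefSeq"), length(contig) == 1L)
  if (!contig %in% names(ref$seq)) stop("unknown contig: ", contig)
  len <- ref$lengths[[contig]]
  out <- rep(NA_character_, length(pos0))
  ok <- pos0 >= 0L & pos0 < len
  if (any(ok)) {
    out[ok] <- substring(ref$seq[[contig]], pos0[ok] + 1L, pos0[ok] + 1L)
  }
  out
}

## vectorised k-mer lookup at 0-based start positions (fixed width)
ref_kmer_at <- function(ref, contig, start0, width) {
  stopifnot(inherits(ref, "RefSeq"), length(contig) == 1L)
  len <- ref$lengths[[contig]]
  out <- rep(NA_character_, length(start0))
  ok <- start0 >= 0L & (start0 + width) <= len
  if (any(ok)) {
    out[ok] <- substring(ref$seq[[contig]], start0[ok] + 1L,
                         start0[ok] + width)
  }
  out
}

#' Write a reference to FASTA
#'
#' @param ref A `RefSeq` object.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, width = 70L) {
  stopifnot(inherits(ref, "RefSeq"))
  dna <- Biostrings::DNAStringSet(ref$seq)
  Biostrings::writeXStringSet(dna, filepath = path, width = width)
  invisible(path)
}
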