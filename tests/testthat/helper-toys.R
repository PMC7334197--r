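# In-code fixture builders: small plus-strand genes assembled from explicit
# exon/intron sequences, plus a strand-mirror constructor used by the
# verdict-symmetry checks.

# Build a single-contig toy gene. exon_seqs are sense-orientation exon
# sequences; intron_seqs sit between them (sense orientation as well, so
# canonical introns should start GT and end AG). Returns the reference, the
# transcript model and the padding offset.
toy_gene <- function(exon_seqs, intron_seqs = NULL, pad = 30L,
                     contig = "chrT", transcript_id = "TXT",
                     gene_id = "GENET") {
  n <- length(exon_seqs)
  if (is.null(intron_seqs)) intron_seqs <- character(0)
  stopifnot(length(intron_seqs) == max(n - 1L, 0L))
  pad_seq <- paste(rep("C", pad), collapse = "")
  parts <- character(0)
  starts <- integer(n); ends <- integer(n)
  off <- pad
  for (i in seq_len(n)) {
    starts[i] <- off
    ends[i] <- off + nchar(exon_seqs[i])
    parts <- c(parts, exon_seqs[i])
    off <- ends[i]
    if (i < n) {
      parts <- c(parts, intron_seqs[i])
      off <- off + nchar(intron_seqs[i])
    }
  }
  genome <- paste0(pad_seq, paste(parts, collapse = ""), pad_seq)
  ref <- ref_from_strings(stats::setNames(genome, contig))
  tx <- transcript_model(transcript_id, gene_id, contig, "+",
                         exons = data.frame(start = starts, end = ends),
                         cds = data.frame(start = starts, end = ends),
                         canonical = TRUE)
  list(ref = ref, tx = tx)
}

# Mirror a toy gene onto the minus strand: reverse-complement the genome and
# reflect all intervals. Sense-orientation sequence content is unchanged, so
# every annotation and verdict must be identical.
mirror_toy <- function(toy) {
  g <- toy$ref$seq[[1]]
  L <- nchar(g)
  contig <- names(toy$ref$seq)[1]
  ref <- ref_from_strings(stats::setNames(revcomp_chr(g), contig))
  refl <- function(iv) {
    data.frame(start = L - iv$end, end = L - iv$start)
  }
  tx <- transcript_model(toy$tx$transcript_id, toy$tx$gene_id, contig, "-",
                         exons = refl(toy$tx$exons),
                         cds = refl(toy$tx$cds),
                         canonical = toy$tx$canonical)
  list(ref = ref, tx = tx)
}

# test-local reverse complement (independent of the package helper)
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# mirror a plus-strand 1-based SNV onto the mirrored genome
mirror_snv <- function(toy, pos, ref_allele, alt_allele) {
  L <- nchar(toy$ref$seq[[1]])
  list(pos = L - pos + 1L,
       ref = chartr("ACGT", "TGCA", ref_allele),
       alt = chartr("ACGT", "TGCA", alt_allele))
}

# convenience: annotate + classify in one go
verdict_of <- function(toy, pos, ref_allele, alt_allele,
                       params = loftee_params()) {
  v <- list(pos = pos, ref = ref_allele, alt = alt_allele)
  call <- annotate_variant(v, toy$tx, toy$ref, params)
  classify_plof(call, toy$tx, toy$ref, params)
}

# codon-safe neutral filler (no stop codons, no GT/AG dinucleotides):
# repeats of "CAC"
filler <- function(n_codons) paste(rep("CAC", n_codons), collapse = "")
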