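# The truth-table toy: CDS 210 bp in exons of 90/61/59 bp, junction at CDS
# offset 151, NMD-escape boundary at offset 101 (junction - 50). Helpers
# from test-consequence.R are redefined here to keep the file standalone.
tritoy <- function(...) {
  exon1 <- paste0("ATG", "AAA", "TGG", filler(27))
  exon2 <- paste0(filler(3), "TGGCAA", strrep("C", 46))
  exon3 <- paste0(strrep("C", 2), "TGG", strrep("C", 54))
  toy_gene(c(exon1, exon2, exon3),
           c(paste0("GT", strrep("C", 26), "AG"), ...))
}

tri_gpos <- function(toy, cds_offset) {
  lofkit:::cds_positions(toy$tx)[cds_offset + 1L] + 1L
}

expect_verdict <- function(v, verdict, filters = character(0), label = "") {
  expect_identical(v$verdict, verdict, label = paste(label, "verdict"))
  expect_identical(v$filters, sort(filters), label = paste(label, "filters"))
}

both_strands <- function(toy, pos, ref_a, alt_a, fn) {
  fn(verdict_of(toy, pos, ref_a, alt_a), "plus")
  mir <- mirror_toy(toy)
  mv <- mirror_snv(toy, pos, ref_a, alt_a)
  fn(verdict_of(mir, mv$pos, mv$ref, mv$alt), "minus")
}

test_that("premature stops escape NMD in and near the last exon", {
  toy <- tritoy(paste0("GT", strrep("C", 26), "AG"))
  # early stop, > 50 coding bases from the final junction: HC
  both_strands(toy, tri_gpos(toy, 8), "G", "A", function(v, lab)
    expect_verdict(v, "HC", label = paste("early stop", lab)))
  # boundary - 1 (offset 100, via TGG -> TAG): still HC
  both_strands(toy, tri_gpos(toy, 100), "G", "A", function(v, lab)
    expect_verdict(v, "HC", label = paste("boundary-1", lab)))
  # boundary (offset 101, via TGG -> TGA): escapes NMD
  both_strands(toy, tri_gpos(toy, 101), "G", "A", function(v, lab)
    expect_verdict(v, "LC", "END_TRUNC", paste("boundary", lab)))
  # boundary + 1 (offset 102, via CAA -> TAA): escapes NMD
  both_strands(toy, tri_gpos(toy, 102), "C", "T", function(v, lab)
    expect_verdict(v, "LC", "END_TRUNC", paste("boundary+1", lab)))
  # stop in the last exon (offset 154, TGG -> TAG)
  both_strands(toy, tri_gpos(toy, 154), "G", "A", function(v, lab)
    expect_verdict(v, "LC", "END_TRUNC", paste("last exon", lab)))
})

test_that("every premature stop in a single-exon transcript is END_TRUNC", {
  toy <- toy_gene(paste0("ATG", "TGG", filler(30), "TGG", filler(30)))
  for (off in c(5, 98)) {   # TGG third bases at CDS offsets 5 and 98
    v <- verdict_of(toy, tri_gpos(toy, off), "G", "A")
    expect_identical(v$call$consequence, "stop_gained")
    expect_verdict(v, "LC", "END_TRUNC", paste("offset", off))
  }
})

test_that("frameshift indels follow the same NMD-escape rule", {
  toy <- tritoy(paste0("GT", strrep("C", 26), "AG"))
  del_at <- function(cds_off) {
    p <- tri_gpos(toy, cds_off) - 1L
    r2 <- ref_fetch(toy$ref, "chrT", p - 1L, p + 1L)
    verdict_of(toy, p, r2, substr(r2, 1, 1))
  }
  v <- del_at(30)
  expect_identical(v$call$consequence, "frameshift")
  expect_verdict(v, "HC", label = "early frameshift")
  v <- del_at(160)
  expect_verdict(v, "LC", "END_TRUNC", "last-exon frameshift")
})

test_that("small-intron filter triggers strictly below 15 bp", {
  for (ilen in c(14L, 15L, 16L)) {
    toy <- toy_gene(c(paste0("ATG", filler(19)), filler(20)),
                    paste0("GT", strrep("C", ilen - 4L), "AG"))
    is1 <- toy$tx$exons$end[1]
    expected <- if (ilen < 15L) list(v = "LC", f = "SMALL_INTRON")
                else list(v = "HC", f = character(0))
    both_strands(toy, is1 + 1L, "G", "A", function(v, lab) {
      expect_identical(v$call$consequence, "splice_donor")
      expect_verdict(v, expected$v, expected$f,
                     paste("intron", ilen, lab))
    })
  }
})

test_that("frame-preserving cryptic sites rescue splice disruptions", {
  # cryptic GT 6 bases into the intron (in frame): rescued
  toy <- tritoy(paste0("GT", "CCCC", "GT", strrep("C", 20), "AG"))
  is2 <- toy$tx$exons$end[2]
  both_strands(toy, is2 + 1L, "G", "A", function(v, lab)
    expect_verdict(v, "LC", "SPLICE_RESCUE", paste("in-frame", lab)))
  # cryptic GT 7 bases in (frame-breaking): no rescue
  toy <- tritoy(paste0("GT", "CCCCC", "GT", strrep("C", 19), "AG"))
  is2 <- toy$tx$exons$end[2]
  both_strands(toy, is2 + 1L, "G", "A", function(v, lab)
    expect_verdict(v, "HC", label = paste("frame-breaking", lab)))
})

test_that("non-canonical introns make essential-splice calls low confidence", {
  toy <- tritoy(paste0("GC", strrep("C", 26), "AG"))
  is2 <- toy$tx$exons$end[2]
  both_strands(toy, is2 + 1L, "G", "A", function(v, lab)
    expect_verdict(v, "LC", "NON_CANONICAL_INTRON", lab))
})

test_that("incomplete CDS adds its filter to every pLoF call", {
  toy <- toy_gene(c("ATGTGGCACC", filler(10)),
                  paste0("GT", strrep("C", 26), "AG"))
  expect_true(toy$tx$cds_incomplete)
  v <- verdict_of(toy, tri_gpos(toy, 5), "G", "A")  # TGG -> TGA, early
  expect_identical(v$call$consequence, "stop_gained")
  expect_identical(v$verdict, "LC")
  expect_true("INCOMPLETE_CDS" %in% v$filters)
  is1 <- toy$tx$exons$end[1]
  v <- verdict_of(toy, is1 + 1L, "G", "A")
  expect_true("INCOMPLETE_CDS" %in% v$filters)
})

test_that("splice-region substitutions get the other-splice verdict", {
  toy <- tritoy(paste0("GT", strrep("C", 26), "AG"))
  is1 <- toy$tx$exons$end[1]
  for (off in 3:8) {
    both_strands(toy, is1 + off, "C", "A", function(v, lab)
      expect_verdict(v, "OS", label = paste0("+", off, " ", lab)))
  }
  v <- verdict_of(toy, is1 + 9L, "C", "A")
  expect_identical(v$verdict, "not_pLoF")
  # synonymous change at the last exonic base before a donor: OS
  v <- verdict_of(toy, tri_gpos(toy, 89), "C", "T")
  expect_identical(v$call$consequence, "splice_region")
  expect_identical(v$verdict, "OS")
  # missense at the same base outranks the splice-region term
  v <- verdict_of(toy, tri_gpos(toy, 89), "C", "A")
  expect_identical(v$call$consequence, "missense")
  expect_identical(v$verdict, "not_pLoF")
})

test_that("every pLoF-class call receives exactly one HC/LC verdict", {
  cfg <- sim_config(seed = 5L, n_genes = 4L, cds_length = c(450L, 900L))
  sim <- generate_reference_and_transcripts(cfg)
  poss <- enumerate_possible_all(sim$transcripts, sim$ref)
  plof <- poss[poss$consequence %in%
                 c("stop_gained", "frameshift", "splice_donor",
                   "splice_acceptor"), ]
  expect_gt(nrow(plof), 0L)
  expect_true(all(plof$verdict %in% c("HC", "LC")))
  expect_true(all((plof$verdict == "LC") == nzchar(plof$filters)))
  os <- poss[poss$consequence == "splice_region", ]
  expect_true(all(os$verdict == "OS"))
})

test_that("bulk enumeration verdicts match the single-variant classifier", {
  cfg <- sim_config(seed = 9L, n_genes = 2L, cds_length = c(450L, 600L))
  sim <- generate_reference_and_transcripts(cfg)
  for (tx in sim$transcripts) {
    poss <- enumerate_possible(tx, sim$ref)
    idx <- which(poss$consequence %in%
                   c("stop_gained", "splice_donor", "splice_acceptor",
                     "splice_region", "synonymous", "missense"))
    idx <- idx[seq(1L, length(idx), by = 23L)]  # systematic subsample
    for (i in idx) {
      call <- annotate_variant(list(pos = poss$pos[i], ref = poss$ref[i],
                                    alt = poss$alt[i]), tx, sim$ref)
      v <- classify_plof(call, tx, sim$ref)
      expect_identical(call$consequence, poss$consequence[i],
                       label = paste("row", i, tx$transcript_id))
      expect_identical(v$verdict, poss$verdict[i],
                       label = paste("row", i, tx$transcript_id))
      expect_identical(paste(v$filters, collapse = ","), poss$filters[i],
                       label = paste("row", i, tx$transcript_id))
    }
  }
})
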