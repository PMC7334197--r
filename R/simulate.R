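#' Simulation configuration
#'
#' Defines the conditions of a synthetic cohort: gene structure ranges, a
#' cohort size, a genome-scale segregation intensity, per-gene-group pLoF
#' depletion, CpG/coverage structure and the site-frequency spectrum.
#'
#' The mutation-selection model is deliberately minimal and matches what the
#' constraint machinery consumes: sites are independent (no linkage), each
#' possible SNV segregates with probability
#' `d_eff * (1 - exp(-theta0 * mu))` where `d_eff` is the gene's depletion
#' for high-confidence pLoF sites and 1 otherwise (depletion thins the
#' segregation probability, so observed/expected recovers `d` even at
#' near-saturated CpG sites), and segregating sites draw an allele count
#' from a truncated
#' `1/k` spectrum. Depletion therefore scales the mass of the pLoF spectrum
#' (fewer segregating sites) while the spectrum shape is shared across
#' classes; `sfs_kmax_scale` optionally shortens the spectrum of a verdict
#' class (values < 1 make that class rarer), which is how cohorts with
#' graded frequency spectra are produced.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param n_genes Number of genes.
#' @param exons_per_gene Inclusive range of exon counts.
#' @param cds_length Inclusive range of CDS lengths (bases; values are
#'   rounded to multiples of 3).
#' @param intron_length Inclusive range of intron lengths.
#' @param n_haplotypes Cohort allele number AN.
#' @param theta0 Per-site segregation intensity multiplier; the probability
#'   that a neutral site with rate `mu` segregates is
#'   `1 - exp(-theta0 * mu)`.
#' @param depletion_by_group Named depletions `d` in `(0, 1]` applied to
#'   HC pLoF sites of genes in each group.
#' @param group_fractions Named fractions of genes per group (sum to 1).
#' @param sfs_kmax_scale Named per-verdict-class (`HC`, `LCOS`, `OTHER`)
#'   scale of the SFS truncation point `round(scale * AN)`; 1 = the shared
#'   neutral spectrum.
#' @param cpg_plant_rate Expected planted CpG dinucleotides per base
#'   (elevated CpG density; default 0.02).
#' @param fraction_low_coverage Fraction of coverage runs drawn in the
#'   under-covered range `[2, high_cov)`.
#' @param fraction_uncovered Fraction of coverage runs with coverage 0
#'   (excluded sites).
#' @param high_cov High-coverage threshold shared with the expectation
#'   model.
#' @param coverage_dropout Whether variant calling probability degrades as
#'   `clamp(log10(cov)/log10(high_cov), 0, 1)` at under-covered sites.
#' @param intergenic Spacer length between genes.
#' @param contig Contig name of the simulated genome.
#' @return A validated `SimulationConfig` list.
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 300L,
                       exons_per_gene = c(3L, 6L),
                       cds_length = c(450L, 7500L),
                       intron_length = c(60L, 300L),
                       n_haplotypes = 20000L,
                       theta0 = 4e7,
                       depletion_by_group = c(strong = 0.1, moderate = 0.5,
                                              neutral = 1.0),
                       group_fractions = c(strong = 0.15, moderate = 0.35,
                                           neutral = 0.5),
                       sfs_kmax_scale = c(HC = 1, LCOS = 1, OTHER = 1),
                       cpg_plant_rate = 0.02,
                       fraction_low_coverage = 0.10,
                       fraction_uncovered = 0.02,
                       high_cov = 40,
                       coverage_dropout = TRUE,
                       intergenic = 200L,
                       contig = "chr1") {
  if (cds_length[1] > cds_length[2] || exons_per_gene[1] > exons_per_gene[2]
      || intron_length[1] > intron_length[2])
    stop("infeasible range: lower bound exceeds upper bound")
  if (cds_length[1] < 9L * exons_per_gene[2])
    stop("minimum CDS length too short for the maximum exon count")
  if (any(depletion_by_group < 0) || any(depletion_by_group > 1))
    stop("depletions must be in [0, 1]")
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("group fractions must sum to 1")
  if (!identical(sort(names(depletion_by_group)),
                 sort(names(group_fractions))))
    stop("depletion_by_group and group_fractions must share names")
  if (any(sfs_kmax_scale <= 0) || any(sfs_kmax_scale > 1))
    stop("sfs_kmax_scale values must be in (0, 1]")
  if (!all(c("HC", "LCOS", "OTHER") %in% names(sfs_kmax_scale)))
    stop("sfs_kmax_scale must name the classes HC, LCOS and OTHER")
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    cds_length = as.integer(cds_length),
    intron_length = as.integer(intron_length),
    n_haplotypes = as.integer(n_haplotypes),
    theta0 = theta0,
    depletion_by_group = depletion_by_group,
    group_fractions = group_fractions,
    sfs_kmax_scale = sfs_kmax_scale,
    cpg_plant_rate = cpg_plant_rate,
    fraction_low_coverage = fraction_low_coverage,
    fraction_uncovered = fraction_uncovered,
    high_cov = high_cov,
    coverage_dropout = isTRUE(coverage_dropout),
    intergenic = as.integer(intergenic),
    contig = contig
  ), class = "SimulationConfig")
}

## split a CDS length into n exon pieces of at least min_piece bases
split_cds <- function(total, n, min_piece = 9L) {
  if (n == 1L) return(total)
  w <- diff(sort(c(0, stats::runif(n - 1L), 1)))
  sizes <- pmax(min_piece, round(w * total))
  # repair the sum on the largest piece
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] +
    (total - sum(sizes))
  if (any(sizes < min_piece)) return(split_cds(total, n, min_piece))
  sizes
}

rand_bases <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference, transcript set and tracks
#'
#' Builds a random genome of `n_genes` protein-coding genes (one canonical
#' transcript each, random strand, CDS length a multiple of 3, canonical
#' GT..AG introns), with planted CpG dinucleotides, a CpG methylation track
#' and a run-length coverage track. Deterministic given the configuration.
#'
#' @param config A `SimulationConfig`.
#' @return List with `ref` (`RefSeq`), `transcripts` (list of
#'   `TranscriptModel`), `methylation` (table `contig`, `pos0`, `level`),
#'   `coverage` (`CoverageTrack`), and `genes` (per-gene truth: group and
#'   depletion).
#' @export
generate_reference_and_transcripts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    # deterministic group sizes matching the configured fractions
    counts <- round(config$group_fractions * n)
    counts[1] <- counts[1] + (n - sum(counts))
    groups <- sample(rep(names(counts), times = counts))
    pieces <- character(0)
    offset <- 0L
    transcripts <- list()
    gene_rows <- list()
    for (i in seq_len(n)) {
      gid <- sprintf("GENE%04d", i)
      tid <- sprintf("TX%04d", i)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                     1L)
      cds_len <- 3L * sample(seq(ceiling(config$cds_length[1] / 3),
                                 floor(config$cds_length[2] / 3)), 1L)
      exon_sizes <- split_cds(cds_len, n_ex)
      intron_sizes <- if (n_ex > 1L)
        sample(seq(config$intron_length[1], config$intron_length[2]),
               n_ex - 1L, replace = TRUE) else integer(0)
      spacer <- rand_bases(config$intergenic)
      gene_len <- cds_len + sum(intron_sizes)
      seq_chars <- sample(DNA_BASES, gene_len, replace = TRUE)
      # elevated CpG density
      n_plant <- stats::rpois(1L, config$cpg_plant_rate * gene_len)
      if (n_plant > 0L && gene_len > 2L) {
        at <- sample(gene_len - 1L, min(n_plant, gene_len - 1L))
        seq_chars[at] <- "C"; seq_chars[at + 1L] <- "G"
      }
      # exon/intron layout within the gene (gene-local 0-based)
      starts <- integer(n_ex); ends <- integer(n_ex)
      cur <- 0L
      for (e in seq_len(n_ex)) {
        starts[e] <- cur
        ends[e] <- cur + exon_sizes[e]
        cur <- ends[e] + if (e < n_ex) intron_sizes[e] else 0L
      }
      # canonical splice dinucleotides in the sense orientation
      for (e in seq_len(n_ex - 1L)) {
        is <- ends[e]; ie <- starts[e + 1L]
        if (strand == "+") {
          seq_chars[is + 1L] <- "G"; seq_chars[is + 2L] <- "T"
          seq_chars[ie - 1L] <- "A"; seq_chars[ie] <- "G"
        } else {
          seq_chars[is + 1L] <- "C"; seq_chars[is + 2L] <- "T"
          seq_chars[ie - 1L] <- "A"; seq_chars[ie] <- "C"
        }
      }
      gene_start <- offset + config$intergenic
      pieces <- c(pieces, spacer, paste(seq_chars, collapse = ""))
      offset <- gene_start + gene_len
      transcripts[[tid]] <- transcript_model(
        transcript_id = tid, gene_id = gid, contig = config$contig,
        strand = strand,
        exons = data.frame(start = gene_start + starts,
                           end = gene_start + ends),
        cds = data.frame(start = gene_start + starts,
                         end = gene_start + ends),
        canonical = TRUE)
      gene_rows[[i]] <- data.table::data.table(
        gene_id = gid, transcript_id = tid, group = groups[i],
        depletion = unname(config$depletion_by_group[groups[i]]))
    }
    pieces <- c(pieces, rand_bases(config$intergenic))
    genome <- paste(pieces, collapse = "")
    ref <- ref_from_strings(stats::setNames(genome, config$contig))

    # methylation: every plus-strand CpG in the genome gets a level
    cg <- gregexpr("CG", genome, fixed = TRUE)[[1]]
    cg <- cg[cg > 0]
    meth <- data.table::data.table(
      contig = config$contig,
      pos0 = as.integer(cg) - 1L,
      level = sample(0:2, length(cg), replace = TRUE,
                     prob = c(0.2, 0.2, 0.6)))

    # coverage in runs of 50 bp
    run <- 50L
    n_runs <- ceiling(nchar(genome) / run)
    u <- stats::runif(n_runs)
    covv <- integer(n_runs)
    covv[u < config$fraction_uncovered] <- 0L
    low <- u >= config$fraction_uncovered &
      u < config$fraction_uncovered + config$fraction_low_coverage
    covv[low] <- sample(seq(2L, config$high_cov - 1L), sum(low),
                        replace = TRUE)
    hi <- covv == 0L & !(u < config$fraction_uncovered)
    covv[hi] <- sample(seq(config$high_cov, config$high_cov + 20L),
                       sum(hi), replace = TRUE)
    cov_dt <- data.table::data.table(
      contig = config$contig,
      start = (seq_len(n_runs) - 1L) * run,
      end = pmin(seq_len(n_runs) * run, nchar(genome)),
      median_coverage = as.numeric(covv))

    list(ref = ref, transcripts = transcripts, methylation = meth,
         coverage = coverage_track(cov_dt),
         genes = data.table::rbindlist(gene_rows))
  })
}

## calling probability as a function of coverage in the generative model
true_coverage_factor <- function(cov, high_cov) {
  out <- clamp01(log10(pmax(cov, 1e-9)) / log10(high_cov))
  out[is.na(cov) | cov < 1] <- 0
  out
}

#' Simulate a cohort of variant calls
#'
#' Runs the mutation-selection model over every possible SNV of the
#' simulated transcripts (see [sim_config()] for the model) and returns the
#' cohort variant table plus the per-site truth scaffold.
#'
#' @param config A `SimulationConfig`.
#' @param sim Output of [generate_reference_and_transcripts()].
#' @param rates Mutation-rate table (default [default_rate_table()]).
#' @param params Rule parameters from [loftee_params()].
#' @return List with `variants` (cohort table: `contig`, `pos`, `ref`,
#'   `alt`, `AC`, `AN`, `nhomalt`, `filter`, `AF`), `possible` (annotated
#'   possible-variant table) and `truth` (per-site class, depletion and
#'   segregation probability).
#' @export
simulate_cohort <- function(config, sim, rates = default_rate_table(),
                            params = loftee_params()) {
  stopifnot(inherits(config, "SimulationConfig"))
  possible <- enumerate_possible_all(sim$transcripts, sim$ref,
                                     coverage = sim$coverage, rates = rates,
                                     methylation = sim$methylation,
                                     params = params)
  truth <- data.table::copy(possible)
  truth[sim$genes, on = "gene_id",
        `:=`(group = i.group, depletion = i.depletion)]
  truth[, sfs_class := data.table::fifelse(
    verdict == "HC" & consequence %in% PLOF_CONSEQUENCES, "HC",
    data.table::fifelse(verdict %in% c("LC", "OS"), "LCOS", "OTHER"))]
  truth[, d_eff := data.table::fifelse(sfs_class == "HC", depletion, 1)]
  # depletion thins the segregation probability directly, so the
  # observed/expected ratio of a gene group recovers d at every mutability,
  # including near-saturated CpG transitions
  p_seg <- truth$d_eff * (1 - exp(-config$theta0 * truth$mu))
  if (config$coverage_dropout) {
    p_seg <- p_seg * true_coverage_factor(truth$median_coverage,
                                          config$high_cov)
  } else {
    p_seg[is.na(truth$median_coverage) | truth$median_coverage < 1] <- 0
  }
  neutral_sat <- 1 - exp(-config$theta0 *
                           max(truth$mu[truth$consequence == "synonymous"],
                               na.rm = TRUE))
  if (neutral_sat > 0.99)
    warning("saturation regime: most mutable neutral sites segregate with ",
            "probability ", round(neutral_sat, 4))
  truth[, p_segregate := p_seg]
  an <- config$n_haplotypes
  withr::with_seed(config$seed + 1L, {
    seg <- stats::runif(nrow(truth)) < truth$p_segregate
    variants <- truth[seg, .(contig, pos, ref, alt, gene_id, sfs_class)]
    variants[, AC := 0L]
    for (cl in unique(variants$sfs_class)) {
      kmax <- max(1L, as.integer(round(
        an * config$sfs_kmax_scale[[cl]])))
      idx <- which(variants$sfs_class == cl)
      variants$AC[idx] <- sample.int(kmax, length(idx), replace = TRUE,
                                     prob = 1 / seq_len(kmax))
    }
    variants[, AN := an]
    variants[, AF := AC / AN]
    n_ind <- an %/% 2L
    variants[, nhomalt := pmin(stats::rbinom(.N, n_ind, AF^2),
                               AC %/% 2L)]
  })
  variants[, filter := "PASS"]
  variants[, c("gene_id", "sfs_class") := NULL]
  data.table::setkey(variants, contig, pos, ref, alt)
  list(variants = variants[], possible = possible, truth = truth[])
}

#' Write a cohort variant table to VCF
#'
#' Emits a sorted VCF v4.2 with `AC`, `AN`, `nhomalt` INFO fields and contig
#' header lines, readable by [read_variants()].
#'
#' @param variants Cohort variant table (see [simulate_cohort()]).
#' @param path Output path.
#' @param ref Optional `RefSeq` used to write contig lengths.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, path, ref = NULL) {
  v <- data.table::as.data.table(variants)
  data.table::setorder(v, contig, pos, ref, alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    paste0("##INFO=<ID=nhomalt,Number=A,Type=Integer,",
           "Description=\"Homozygous-alternate individuals\">"))
  if (!is.null(ref)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(ref_lengths(ref)), ref_lengths(ref)))
  } else {
    header <- c(header, sprintf("##contig=<ID=%s>", unique(v$contig)))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tAC=%d;AN=%d;nhomalt=%d",
                  v$contig, v$pos, v$ref, v$alt, v$filter, v$AC, v$AN,
                  v$nhomalt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write all simulation outputs to a directory
#'
#' Writes `ref.fa`, `genes.gtf`, `meth.tsv`, `rates.tsv`, `cov.tsv`,
#' `cohort.vcf` and `truth.tsv`.
#'
#' @param sim Output of [generate_reference_and_transcripts()].
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param rates Rate table used for the cohort.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, cohort, dir,
                             rates = default_rate_table()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference(sim$ref, file.path(dir, "ref.fa"))
  write_transcripts_gtf(sim$transcripts, file.path(dir, "genes.gtf"))
  data.table::fwrite(sim$methylation, file.path(dir, "meth.tsv"), sep = "\t")
  write_rate_table(rates, file.path(dir, "rates.tsv"))
  write_coverage(sim$coverage, file.path(dir, "cov.tsv"))
  write_cohort_vcf(cohort$variants, file.path(dir, "cohort.vcf"),
                   ref = sim$ref)
  truth <- cohort$truth[, .(contig, pos, ref, alt, gene_id, group,
                            depletion, sfs_class, mu, methylation,
                            p_segregate)]
  data.table::fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
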