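#' Attach strand-collapsed trinucleotide context and methylation
#'
#' For each site the 3-mer reference window centred on the position is
#' extracted and strand-collapsed so the central base is `A` or `C` (when the
#' central base is `G` or `T` the window and the alternate allele are
#' reverse-complemented). Methylation levels are read from an optional track
#' at CpG dinucleotides only (a site whose collapsed context is `NCG`);
#' non-CpG sites are forced to level 0, as is any CpG absent from the track.
#' Windows containing `N` or truncated by a contig edge are unscorable and
#' returned with `NA` context.
#'
#' @param sites Data frame/`data.table` with columns `contig`, `pos`
#'   (1-based) and `alt` (genomic alternate base).
#' @param ref A `RefSeq` reference.
#' @param methylation Optional methylation track: data frame with columns
#'   `contig`, `pos0` (0-based position of the plus-strand C of the CpG) and
#'   `level` in `{0, 1, 2}`.
#' @return `data.table` copy of `sites` with added columns `context`
#'   (collapsed 3-mer), `alt_collapsed`, `methylation`.
#' @export
attach_context <- function(sites, ref, methylation = NULL) {
  dt <- data.table::as.data.table(sites)
  n <- nrow(dt)
  context <- rep(NA_character_, n)
  alt_c <- rep(NA_character_, n)
  meth <- rep(0L, n)
  for (ctg in unique(dt$contig)) {
    sel <- which(dt$contig == ctg)
    p0 <- dt$pos[sel] - 1L
    win <- ref_kmer_at(ref, ctg, p0 - 1L, 3L)
    bad <- is.na(win) | grepl("[^ACGT]", win)
    win[bad] <- NA_character_
    central <- substring(win, 2L, 2L)
    flip <- !is.na(central) & central %in% c("G", "T")
    ctx <- win
    av <- dt$alt[sel]
    if (any(flip)) {
      ctx[flip] <- revcomp(win[flip])
      av[flip] <- comp_base(av[flip])
    }
    av[is.na(win)] <- NA_character_
    # CpG position of the plus-strand C: the site itself when central C is
    # followed by G; the preceding base when central G is preceded by C
    is_cpg <- !is.na(ctx) & substring(ctx, 2L, 3L) == "CG"
    cpg_pos0 <- rep(NA_integer_, length(sel))
    cpg_pos0[is_cpg & !flip] <- p0[is_cpg & !flip]
    cpg_pos0[is_cpg & flip] <- p0[is_cpg & flip] - 1L
    if (!is.null(methylation) && any(is_cpg)) {
      mt <- data.table::as.data.table(methylation)
      key <- paste(ctg, cpg_pos0[is_cpg])
      lv <- mt$level[match(key, paste(mt$contig, mt$pos0))]
      lv[is.na(lv)] <- 0L
      meth[sel][is_cpg] <- as.integer(lv)
    }
    context[sel] <- ctx
    alt_c[sel] <- av
  }
  dt$context <- context
  dt$alt_collapsed <- alt_c
  dt$methylation <- meth
  dt
}

#' Discretise a continuous methylation fraction to levels 0/1/2
#'
#' @param fraction Methylation fraction in `[0, 1]`.
#' @param cuts Cut points: below `cuts[1]` is level 0, between the cuts
#'   level 1, above `cuts[2]` level 2 (defaults 0.2 and 0.6).
#' @return Integer levels.
#' @export
methylation_level <- function(fraction, cuts = c(0.2, 0.6)) {
  findInterval(fraction, cuts)
}

#' Read a mutation-rate table
#'
#' TSV with columns `context` (collapsed 3-mer, central base `A` or `C`),
#' `alt` (collapsed alternate), `methylation_level` (0/1/2) and `mu`
#' (relative per-site per-generation mutation rate, positive).
#'
#' @param path Path to the TSV (with header).
#' @return `data.table` keyed by (`context`, `alt`, `methylation_level`).
#' @export
read_rate_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = c("context", "alt")))
  validate_rate_table(dt)
}

validate_rate_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  need <- c("context", "alt", "methylation_level", "mu")
  if (!all(need %in% names(dt)))
    stop("rate table must have columns ", paste(need, collapse = ", "))
  if (any(dt$mu <= 0)) stop("mutation rates must be positive")
  if (any(!substring(dt$context, 2L, 2L) %in% c("A", "C")))
    stop("rate-table contexts must be strand-collapsed (central A or C)")
  data.table::setkey(dt, context, alt, methylation_level)
  dt[]
}

#' Write a mutation-rate table
#' @param rates Rate table (`data.table`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  data.table::fwrite(rates, path, sep = "\t")
  invisible(path)
}

#' Default relative mutation-rate table
#'
#' A deterministic table covering all 32 collapsed trinucleotide contexts
#' times 3 alternate alleles times 3 methylation levels. Rates follow the
#' canonical structure of germline mutability: transitions exceed
#' transversions, flanking G/C content modulates the rate, and CpG
#' transitions are boosted with methylation level (hypermutability of
#' methylated CpG sites). Units are per site per generation.
#'
#' @param base_transversion,base_transition Baseline rates.
#' @param cpg_multipliers Multipliers applied to the transition rate at CpG
#'   sites for methylation levels 0, 1, 2.
#' @return Rate table `data.table` (see [read_rate_table()]).
#' @export
default_rate_table <- function(base_transversion = 1.2e-9,
                               base_transition = 4e-9,
                               cpg_multipliers = c(2, 6, 20)) {
  flanks <- expand.grid(l = DNA_BASES, r = DNA_BASES,
                        stringsAsFactors = FALSE)
  rows <- list()
  transition_of <- c(A = "G", C = "T")
  for (central in c("A", "C")) {
    for (i in seq_len(nrow(flanks))) {
      ctx <- paste0(flanks$l[i], central, flanks$r[i])
      gc_flank <- sum(c(flanks$l[i], flanks$r[i]) %in% c("G", "C"))
      mod <- 0.75 + 0.25 * gc_flank            # 0.75, 1.00, 1.25
      is_cpg <- central == "C" && flanks$r[i] == "G"
      for (alt in setdiff(DNA_BASES, central)) {
        ti <- alt == transition_of[[central]]
        base <- if (ti) base_transition else base_transversion
        for (ml in 0:2) {
          mu <- base * mod
          if (is_cpg && ti) mu <- mu * cpg_multipliers[ml + 1L]
          rows[[length(rows) + 1L]] <-
            data.table::data.table(context = ctx, alt = alt,
                                   methylation_level = ml, mu = mu)
        }
      }
    }
  }
  validate_rate_table(data.table::rbindlist(rows))
}

## join mu onto a table carrying context/alt_collapsed/methylation columns
lookup_mu <- function(dt, rates) {
  idx <- rates[data.table::data.table(context = dt$context,
                                      alt = dt$alt_collapsed,
                                      methylation_level = dt$methylation),
               on = c("context", "alt", "methylation_level")]
  dt$mu <- idx$mu
  dt
}
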