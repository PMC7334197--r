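# Simulated cohorts shared across test files, built lazily and cached for
# the duration of the test run.

.cohort_cache <- new.env(parent = emptyenv())

# Default study conditions: 300 genes, AN = 20,000, three depletion groups
# (0.1 / 0.5 / 1.0) acting on HC pLoF segregation, shared SFS shape.
default_cohort <- function() {
  if (!is.null(.cohort_cache$default)) return(.cohort_cache$default)
  cfg <- sim_config()
  sim <- generate_reference_and_transcripts(cfg)
  cohort <- simulate_cohort(cfg, sim)
  vcf <- tempfile(fileext = ".vcf")
  write_cohort_vcf(cohort$variants, vcf, ref = sim$ref)
  observed <- read_variants(vcf)
  res <- run_constraint_pipeline(sim$transcripts, sim$ref, observed,
                                 coverage = sim$coverage,
                                 rates = default_rate_table(),
                                 methylation = sim$methylation,
                                 possible = cohort$possible)
  out <- list(cfg = cfg, sim = sim, cohort = cohort, observed = observed,
              res = res)
  .cohort_cache$default <- out
  out
}

# Depleted cohort with graded frequency spectra across verdict classes:
# HC pLoF sites are strongly shifted toward singletons, LC/OS sites
# intermediately, everything else neutral. Used by the MAPS-ordering and
# LOFTEE frequency-spectrum checks.
depleted_cohort <- function() {
  if (!is.null(.cohort_cache$depleted)) return(.cohort_cache$depleted)
  cfg <- sim_config(seed = 202L, n_genes = 200L,
                    exons_per_gene = c(3L, 5L),
                    cds_length = c(1200L, 2400L),
                    depletion_by_group = c(constrained = 0.5),
                    group_fractions = c(constrained = 1),
                    sfs_kmax_scale = c(HC = 0.005, LCOS = 0.03, OTHER = 1))
  sim <- generate_reference_and_transcripts(cfg)
  cohort <- simulate_cohort(cfg, sim)
  annotated <- annotate_observed(cohort$variants, cohort$possible)
  out <- list(cfg = cfg, sim = sim, cohort = cohort, annotated = annotated)
  .cohort_cache$depleted <- out
  out
}
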