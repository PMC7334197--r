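test_that("enumeration emits 3 alternates per CDS and essential splice base", {
  # 9-base single-exon CDS: 27 possible variants, no splice sites
  toy <- toy_gene("ATGAAATAA")
  poss <- enumerate_possible(toy$tx, toy$ref)
  expect_equal(nrow(poss), 27L)
  expect_false(any(poss$consequence %in% c("splice_donor",
                                           "splice_acceptor")))
  # 2-exon transcript: 4 essential splice bases x 3 alternates on top
  toy2 <- toy_gene(c("ATGAAA", "CCCTAA"), paste0("GT", strrep("C", 26), "AG"))
  poss2 <- enumerate_possible(toy2$tx, toy2$ref)
  expect_equal(nrow(poss2), 12L * 3L + 12L)
  expect_equal(sum(poss2$consequence == "splice_donor"), 6L)
  expect_equal(sum(poss2$consequence == "splice_acceptor"), 6L)
})

test_that("sites with N in the context window are unscorable", {
  toy <- toy_gene("ATGANATAA")
  poss <- enumerate_possible(toy$tx, toy$ref)
  # the N base and both neighbours lose their 3 alternates each
  expect_equal(attr(poss, "n_unscorable"), 9L)
  expect_equal(nrow(poss), 27L - 9L)
})

test_that("context collapse puts A or C at the centre and maps CpG", {
  ref <- ref_from_strings(c(c = "TACGTT"))
  # central C of ACG (a CpG): kept as-is
  ctx <- attach_context(data.frame(contig = "c", pos = 3, alt = "T"), ref)
  expect_identical(ctx$context, "ACG")
  expect_identical(ctx$alt_collapsed, "T")
  # central G of CGT: reverse-complemented to ACG, alt A -> T
  ctx <- attach_context(data.frame(contig = "c", pos = 4, alt = "A"), ref)
  expect_identical(ctx$context, "ACG")
  expect_identical(ctx$alt_collapsed, "T")
  # methylation read from the track at both CpG representations
  meth <- data.frame(contig = "c", pos0 = 2, level = 2)
  ctx <- attach_context(data.frame(contig = "c", pos = c(3, 4),
                                   alt = c("T", "A")), ref, meth)
  expect_equal(ctx$methylation, c(2L, 2L))
  # non-CpG site: methylation forced to 0 even with a track present
  ctx <- attach_context(data.frame(contig = "c", pos = 2, alt = "G"), ref,
                        data.frame(contig = "c", pos0 = 1, level = 2))
  expect_equal(ctx$methylation, 0L)
})

test_that("context multiset is invariant under genome reverse-complement", {
  cfg <- sim_config(seed = 3L, n_genes = 2L, cds_length = c(450L, 600L))
  sim <- generate_reference_and_transcripts(cfg)
  poss <- enumerate_possible_all(sim$transcripts, sim$ref)
  mir_ref <- ref_from_strings(stats::setNames(
    revcomp_chr(sim$ref$seq[[1]]), names(sim$ref$seq)))
  L <- nchar(sim$ref$seq[[1]])
  mir_sites <- data.frame(contig = names(sim$ref$seq),
                          pos = L - poss$pos + 1L,
                          alt = chartr("ACGT", "TGCA", poss$alt))
  mir_ctx <- attach_context(mir_sites, mir_ref)
  expect_identical(sort(paste(mir_ctx$context, mir_ctx$alt_collapsed)),
                   sort(paste(poss$context, poss$alt_collapsed)))
})

test_that("rate table round trip and coverage of required combinations", {
  rates <- default_rate_table()
  expect_equal(nrow(rates), 32L * 3L * 3L)
  expect_true(all(rates$mu > 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rates, f)
  back <- read_rate_table(f)
  expect_equal(back$mu, rates$mu)
  # methylated CpG transitions are the fastest rates
  cpg <- rates[substr(rates$context, 2, 3) == "CG" & rates$alt == "T" &
                 rates$methylation_level == 2, ]
  expect_true(min(cpg$mu) > max(rates$mu[rates$methylation_level == 0 &
                                           rates$alt != "T"]))
})

test_that("proportion observed is a simple matched fraction", {
  poss <- data.table::data.table(
    contig = "c", pos = 1:10, ref = "A", alt = "G",
    consequence = "synonymous", verdict = "not_pLoF")
  obs <- data.table::data.table(contig = "c", pos = c(1L, 4L, 9L),
                                ref = "A", alt = "G")
  expect_equal(proportion_observed(poss, obs)$fraction, 0.3)
  expect_equal(proportion_observed(poss, obs[0])$fraction, 0)
  expect_equal(proportion_observed(poss, poss)$fraction, 1)
  # observed records absent from the possible table are ignored
  obs_indel <- data.table::data.table(contig = "c", pos = 50L, ref = "AT",
                                      alt = "A")
  expect_equal(proportion_observed(poss, obs_indel)$n_observed, 0L)
})

# build a synthetic training table: n_sites per context group with given mu,
# observing each site independently with probability p(mu)
calib_fixture <- function(mus, p_fun, n_sites = 400L, seed = 1L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(mus), function(i) {
      data.table::data.table(
        contig = "c", pos = seq_len(n_sites) + i * 10000L,
        ref = "A", alt = "G", consequence = "synonymous",
        verdict = "not_pLoF", context = sprintf("CTX%02d", i),
        alt_collapsed = "G", methylation = 0L, mu = mus[i],
        median_coverage = 50)
    })
    poss <- data.table::rbindlist(rows)
    seen <- stats::runif(nrow(poss)) < p_fun(poss$mu)
    list(possible = poss, observed = poss[seen, .(contig, pos, ref, alt)])
  })
}

test_that("calibration recovers a constant and a linear response", {
  # constant proportion 0.5: slope 0, intercept 0.5 (deterministic half)
  poss <- calib_fixture(c(1e-9, 4e-9, 8e-9), function(mu) 0.5)$possible
  obs <- poss[seq(1, .N, by = 2), .(contig, pos, ref, alt)]
  model <- fit_calibration(poss, obs)
  # flat response: the slope contributes nothing over the mutability range
  expect_lt(abs(model$coefficients$slope) * 8e-9, 1e-8)
  expect_equal(model$coefficients$intercept, 0.5, tolerance = 1e-6)
  # proportion min(1, 1e8 * mu): slope recovered within 5% on the linear
  # region (generate-and-refit with a fixed seed)
  fx <- calib_fixture(seq(1e-9, 8e-9, by = 1e-9),
                      function(mu) pmin(1, 1e8 * mu), n_sites = 2000L)
  model <- fit_calibration(fx$possible, fx$observed)
  expect_lt(abs(model$coefficients$slope - 1e8) / 1e8, 0.05)
  # predictions clamp to [0, 1]
  expect_equal(predict_calibration(model, 1e-6), 1)
  expect_gte(predict_calibration(model, 0), 0)
})

test_that("calibration falls back to intercept-only on a single rate", {
  fx <- calib_fixture(4e-9, function(mu) 0.3, n_sites = 1000L)
  expect_warning(model <- fit_calibration(fx$possible, fx$observed),
                 "intercept-only")
  expect_equal(model$coefficients$slope, 0)
  expect_error(fit_calibration(fx$possible[0], fx$observed), "empty")
})

test_that("coverage correction factor follows the piecewise rule", {
  m <- coverage_model(a = 0.1, b = 0.5, high_cov = 40)
  expect_equal(coverage_correction_factor(45, m), 1)
  expect_equal(coverage_correction_factor(40, m), 1)
  expect_true(is.na(coverage_correction_factor(0.5, m)))
  expect_equal(coverage_correction_factor(10, m), 0.1 + 0.5)
  expect_equal(coverage_correction_factor(c(2, 39), m),
               pmin(1, pmax(0, 0.1 + 0.5 * log10(c(2, 39)))))
  expect_error(coverage_correction_factor(-1, m), "non-negative")
})

test_that("fitted coverage model evaluates to a + b at coverage 10", {
  # synthetic low-coverage data with true factor log10(cov)/log10(40)
  withr::with_seed(7, {
    covs <- rep(c(2, 5, 10, 20, 30), each = 3000L)
    poss <- data.table::data.table(
      contig = "c", pos = seq_along(covs), ref = "A", alt = "G",
      consequence = "synonymous", verdict = "not_pLoF",
      context = "ACA", alt_collapsed = "G", methylation = 0L,
      mu = 4e-9, median_coverage = covs)
    hi <- data.table::copy(poss)[, `:=`(pos = pos + 1000000L,
                                        median_coverage = 50)]
    p_base <- 0.4
    fac <- log10(covs) / log10(40)
    seen_lo <- stats::runif(nrow(poss)) < p_base * fac
    seen_hi <- stats::runif(nrow(hi)) < p_base
    all_poss <- data.table::rbindlist(list(poss, hi))
    obs <- data.table::rbindlist(list(poss[seen_lo], hi[seen_hi]))[
      , .(contig, pos, ref, alt)]
    suppressWarnings(calib <- fit_calibration(all_poss, obs))
    cm <- fit_coverage_model(all_poss, obs, calib)
    expect_equal(coverage_correction_factor(10, cm), cm$a + cm$b)
    # recovers the generative log-linear factor
    expect_equal(cm$b, 1 / log10(40), tolerance = 0.1)
    expect_equal(cm$a, 0, tolerance = 0.06)
  })
})

test_that("expected counts are coverage-weighted sums of predictions", {
  calib <- structure(list(
    coefficients = data.table::data.table(methylation = 0L, intercept = 0.2,
                                          slope = 0),
    training = NULL, high_cov = 40), class = "CalibrationModel")
  poss <- data.table::data.table(
    contig = "c", pos = 1:10, ref = "A", alt = "G",
    consequence = "synonymous", verdict = "not_pLoF", context = "ACA",
    alt_collapsed = "G", methylation = 0L, mu = 4e-9,
    median_coverage = 50)
  expect_equal(expected_counts(poss, calib), 2.0)
  # half the sites at factor 0.5
  cm <- coverage_model(a = 0.5, b = 0, high_cov = 40)
  poss$median_coverage[1:5] <- 10
  expect_equal(expected_counts(poss, calib, cm), 1.5)
  # sites below coverage 1 are excluded
  poss$median_coverage[1:5] <- 0.5
  expect_equal(expected_counts(poss, calib, cm), 1.0)
  expect_warning(out <- expected_counts(poss[0], calib), "no possible sites")
  expect_equal(out, 0)
})

test_that("expected counts are monotone in mutability and coverage", {
  fx <- calib_fixture(seq(1e-9, 8e-9, by = 1e-9),
                      function(mu) pmin(1, 5e7 * mu), n_sites = 1000L)
  calib <- fit_calibration(fx$possible, fx$observed)
  cm <- coverage_model(a = 0, b = 1 / log10(40))
  site <- function(mu, cov) data.table::data.table(
    contig = "c", pos = 1L, ref = "A", alt = "G",
    consequence = "synonymous", verdict = "not_pLoF", context = "ACA",
    alt_collapsed = "G", methylation = 0L, mu = mu, median_coverage = cov)
  exp_mu <- vapply(c(1e-9, 3e-9, 6e-9, 8e-9),
                   function(m) expected_counts(site(m, 50), calib, cm),
                   numeric(1))
  expect_true(all(diff(exp_mu) >= 0))
  exp_cov <- vapply(c(2, 10, 25, 40, 60),
                    function(cv) expected_counts(site(4e-9, cv), calib, cm),
                    numeric(1))
  expect_true(all(diff(exp_cov) >= 0))
})
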