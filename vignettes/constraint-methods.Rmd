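---
title: "Quantifying loss-of-function constraint: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying loss-of-function constraint: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genes that are essential in the heterozygous state are depleted of
predicted loss-of-function (pLoF) variants — stop-gained, frameshift and
essential-splice alleles — in population cohorts. Measuring that depletion
requires three ingredients that this package implements end to end:

1. a *specific* pLoF call set, because raw pLoF annotations are heavily
   enriched for artefacts (terminal truncations that escape
   nonsense-mediated decay, rescued splice sites, annotation errors);
2. a *neutral expectation* for how many rare variants a gene should harbour
   in a cohort of a given size, driven by local sequence context, CpG
   methylation and sequencing depth; and
3. a *statistic* that compares observation to expectation while
   acknowledging that small genes carry almost no information.

The headline statistic is the 90% upper bound of a Poisson-likelihood
confidence interval on the observed/expected ratio of rare high-confidence
pLoF variants — the LOEUF score. Low LOEUF means confident depletion;
high LOEUF mixes truly tolerant genes with genes too small to judge.

# pLoF annotation and first-principles filtering

`annotate_variant()` reduces each (variant, transcript) pair to a single
most-severe consequence with a fixed ordering (stop_gained > frameshift >
splice_donor/acceptor > stop_lost > start_lost > missense > inframe_indel >
splice_region > synonymous > intron/UTR/other). Essential splice sites are
the two intronic bases flanking each internal exon; the splice region is
the last exonic base before a donor plus intronic positions 3–8.

`classify_plof()` then sorts pLoF-class calls into high confidence (HC),
low confidence (LC, with named filters) or other-splice (OS):

* **END_TRUNC** — a premature stop or frameshift in the last coding exon
  or within `nmd_window` coding bases upstream of the 3'-most exon–exon
  junction is predicted to escape nonsense-mediated decay. The default
  window is 50 bases, the canonical "50-nucleotide rule"; in a
  single-coding-exon transcript every premature stop escapes.
* **SMALL_INTRON** — essential-splice disruption of an intron shorter than
  `min_intron` (default 15 bases): such micro-introns are usually
  annotation artefacts.
* **SPLICE_RESCUE** — a frame-preserving cryptic GT (donor) or AG
  (acceptor) within `rescue_window` (default ±15) sense-orientation bases
  of the disrupted site. This is a deliberate simplification of full
  donor-strength modelling: the scan asks only for a canonical
  dinucleotide at an offset divisible by 3, which captures the common
  rescue geometry without a trained splice model.
* **NON_CANONICAL_INTRON** — the disrupted intron is not GT..AG, so the
  "essential" bases may not be essential.
* **INCOMPLETE_CDS** — the transcript's CDS length is not a multiple of 3;
  all pLoF calls on such transcripts are low confidence.

A verdict is LC exactly when at least one filter fires. OS marks predicted
splice-affecting substitutions outside the two essential bases. Verdicts
are strand-symmetric by construction and the test suite asserts this on
mirrored genomes. Only SNVs and indels up to 50 bp are annotated; larger
events belong to structural-variant callers.

# The mutational expectation model

Every possible SNV in a transcript's CDS and essential splice sites is
enumerated (3 alternates per scorable base) and annotated identically to
observed variants. Each site carries a strand-collapsed trinucleotide
context (central base A or C), an alternate allele, and a methylation
level in {0, 1, 2} at CpG sites (discretised from a continuous fraction at
cut points 0.2 and 0.6 when a continuous track is supplied). A
mutation-rate table maps (context, alternate, methylation) to a relative
rate μ per site per generation; methylated CpG transitions are the fastest
class by an order of magnitude.

The calibration (`fit_calibration()`) regresses, per methylation stratum,
the proportion of possible synonymous sites observed in the cohort on μ,
weighted by the number of possible sites per (context, alternate) group,
using only sites at high coverage (`high_cov`, default 40). Predictions
are clamped to [0, 1], which absorbs CpG-transition saturation. We predict
a bounded proportion rather than a raw count because at current cohort
sizes the most mutable contexts approach saturation while rare contexts
remain linear; a per-stratum line on the bounded scale captures both
regimes adequately and degrades gracefully (an intercept-only fallback)
when a stratum lacks rate spread.

Coverage enters twice. Sites below median coverage 1 are excluded from
both observed and expected tallies. Sites between 1 and `high_cov` receive
a correction factor `clamp(a + b·log10(coverage), 0, 1)` fitted on
low-coverage synonymous sites as the ratio of observed to
calibration-predicted proportions (`fit_coverage_model()`). The log-linear
form mirrors how callability decays with depth in exome data; the
coefficients are cohort-specific and therefore always fitted or supplied,
never hard-coded.

Expected counts for any class are then the sum over that class's possible
sites of predicted proportion × coverage factor. The same
allele-frequency filter (default AF < 0.1%) is applied to the observed
variants used for calibration and to the observed counts being compared,
so expectation and observation describe the same class of rare variation.
The 0.1% default reflects that constraint is a statement about rare,
deleterious variation; common pLoF alleles are dominated by annotation
errors and balanced/neutral sites.

# Constraint statistics

For each gene, `constraint_table()` reports observed and expected counts
for HC pLoF, synonymous and missense classes, the observed/expected ratio,
and its confidence interval. The interval is defined by a fixed grid
algorithm: over ratios r = 0, 0.001, …, 1.999, the Poisson likelihood of
the observed count at mean r·expected is cumulated and normalised by its
total; the lower bound is the largest grid ratio with normalised
cumulative below α and the upper bound the smallest at or above 1 − α
(α = 0.05, a 90% interval). The upper bound is LOEUF. The grid constants
are part of the definition (they are what make the worked examples
reproducible: 0 observed/2 expected gives 1.348, 0 observed/100 expected
gives 0.029); an independent fine-grid oracle and the closed form for zero
observed guard the implementation in the test suite. Display output
truncates LOEUF toward zero at two decimals (1.348 prints as 1.34); all
machine output keeps full precision.

Genes with positive expectation are ranked by LOEUF (ties broken by larger
expectation, then gene id) and binned into ten near-equal deciles, larger
bins first; decile 1 is the most constrained. Genes with ≥ 10 expected
pLoF variants are flagged well powered — below that, LOEUF cannot
distinguish constraint from smallness, which is precisely the ambiguity
the upper bound encodes. Genes with zero expectation are excluded from
deciles entirely rather than assigned the grid maximum: they carry no
information and would contaminate the tolerant tail.

Per-gene summaries also include the aggregate pLoF carrier frequency
`1 − Π(1 − AF)` over HC variants (independent-sites assumption) and
homozygote tallies from the `nhomalt` INFO field.

`discovery_curve()` gives the expected number of distinct variants at a
downsampled haplotype count n as a sum of hypergeometric probabilities
`1 − C(AN−AC, n)/C(AN, n)`, evaluated with log-factorials; it is exact
(matched against full subset enumeration at small AN in the tests),
monotone and concave.

# MAPS

The mutability-adjusted proportion of singletons compares a class's
singleton fraction with the fraction predicted from its mutability, where
the prediction is a per-methylation-stratum weighted regression of
per-context singleton proportions on μ fitted on synonymous variants.
By the weighted-least-squares residual identity, MAPS of the synonymous
training set is zero to machine precision — a property the acceptance
tests assert at 1e-10. The standard error is binomial on the observed
proportion; it deliberately ignores calibration uncertainty, which is
shared across classes and does not affect between-class comparisons at
the resolution used here (this is the package's choice; the source
analyses do not specify their interval construction).

# The synthetic cohort generator

`sim_config()` + `generate_reference_and_transcripts()` +
`simulate_cohort()` produce a complete input set — FASTA, GTF, methylation
and coverage tracks, rate table, VCF with AC/AN/nhomalt and a truth
table — under an explicit mutation–selection model:

* Sites are independent (no linkage) and each possible SNV segregates
  with probability `d_eff · (1 − exp(−θ0·μ))`, where `d_eff` is the
  gene's planted depletion for HC pLoF sites and 1 otherwise. Depletion
  multiplies the segregation probability (not the intensity inside the
  exponential) so that the observed/expected ratio recovers d at every
  mutability, including near-saturated methylated CpG transitions — the
  minimal mechanism that makes parameter recovery well defined.
* Segregating sites draw allele counts from a truncated `P(AC=k) ∝ 1/k`
  spectrum. In the default configuration the spectrum shape is identical
  across classes (depletion scales its mass, fewer segregating pLoF
  sites), which makes the MAPS null hold exactly by design. The
  `sfs_kmax_scale` knob shortens the spectrum of a verdict class
  (truncation at `scale·AN`) to produce cohorts with graded frequency
  spectra — rarer HC pLoF than LC/OS than synonymous — for the MAPS
  ordering and frequency-dependent filtering checks.
* Coverage is drawn in 50-bp runs with configurable under-covered and
  uncovered fractions, and calling probability degrades as
  `log10(cov)/log10(40)` below the high-coverage threshold, giving the
  coverage model something real to fit.
* Homozygote counts are binomial under Hardy–Weinberg from the allele
  frequency, capped at AC/2.

Defaults are 300 genes with CDS lengths 450–7500 bp (3–6 exons, GT..AG
introns, elevated CpG density), AN = 20,000 haplotypes and θ0 = 4×10⁷,
chosen so that the median gene expects on the order of ten rare pLoF
variants and roughly half the genes clear the well-powered threshold —
the regime the constraint statistics are designed for — while a full
simulation plus pipeline runs in a few minutes on one CPU. Gene groups
with planted depletion 0.1/0.5/1.0 occupy 15/35/50% of genes, so the
strongly constrained group is a minority, as in real exomes.

What the generator does **not** emulate: linkage and haplotype structure,
demography-driven frequency spectra, recurrent mutation, indel mutation
(indels appear only as planted test cases), per-population structure, and
sequencing artefact modes. Passing recovery tests therefore demonstrates
that the statistical machinery is correct under its own assumptions — not
that those assumptions capture human cohort data.

# Numerical choices and edge cases

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at the GTF/VCF boundaries (1-based), and round-trip tests
  pin the bijection.
* Multi-allelic VCF records are split and minimally represented
  (suffix-then-prefix trimming) before annotation.
* Canonical transcripts come from a GTF `tag` attribute; absent that, the
  longest CDS per gene wins, ties broken lexicographically — a fallback
  the source material does not define, fixed here for determinism.
* N-containing context windows make a site unscorable (skipped and
  counted) rather than an error.
* Records with AC > AN are rejected with a message; `nhomalt` defaults
  to 0.
* The confidence-interval grid clamps ratios above 2.0 with a warning;
  genes beyond that are unconstrained by any reading.
* The generator is byte-deterministic given its configuration (all
  randomness flows through one seed).

# Limitations

The LOFTEE-style filter set is a faithful core, not a complete
re-implementation: no machine-learned donor strength, no ancestral-allele
filtering, no phasing-aware multi-nucleotide codon correction. The
calibration's bounded-linear form is a pragmatic stand-in for richer
saturation models and is exposed through configurable constants. pLI-style
mixture modelling and per-population constraint are out of scope. Real
cohort idiosyncrasies (call-rate structure, batch effects) must be
expressed upstream as site filters in the input VCF.
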