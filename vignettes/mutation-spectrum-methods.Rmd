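---
title: "Methods: compartment comparisons of the rare-variant mutation spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment comparisons of the rare-variant mutation spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutspectra)
```

## The problem

Rare polymorphisms in a large cohort are recent enough that selection and
biased gene conversion have had little time to act on them, so their
spectrum — the distribution of variants over mutation types — closely tracks
the de novo mutation spectrum, at a density millions of times higher than
pedigree sequencing can deliver.  `mutspectra` implements the comparative
machinery this enables: contrasting the spectrum between genomic
*compartments* (late vs early replicating regions, recombination hotspot
tiers, the X chromosome vs autosomes, the pseudoautosomal region, ...) to
read off the biochemical and sex-specific processes that shape germline
mutation.

## The statistic

Every single-base substitution is placed in its trinucleotide context and
collapsed with its reverse complement, giving 32 canonical contexts
(central C or T) and 96 mutation types in six classes (C>A, C>G, C>T,
T>A, T>C, T>G).  Within a compartment, for type $i$:

* **Opportunities** $O_i$: the number of sites whose (N-free, complete)
  trinucleotide matches type $i$'s context — the sites where a single base
  change could have produced that type.  Opportunities depend only on the
  sequence, never on the variants, and absorb base-composition differences
  between compartments.
* **Diversity** $d_i = S_i / O_i$, with $S_i$ the number of segregating
  sites of type $i$ (each derived allele of a multiallelic site counted as
  its own biallelic site with the shared major allele).
* **Relative diversity** $r_i = d_i / D$, where $D = S_\mathrm{tot} /
  O_\mathrm{tot}$ is the compartment's total diversity.  Dividing by $D$
  removes population-genetic forces (drift, linked selection, differences
  in effective population size, e.g. between X and autosomes) that scale
  diversity uniformly across types.  The tables satisfy
  $\sum_i r_i\, O_i / O_\mathrm{tot} = 1$ exactly; we verify this to
  1e-12 on every emitted table.  $O_\mathrm{tot}$ sums over the 96 types,
  so each site is counted three times; all downstream ratios are invariant
  to this convention (verified numerically in the tests).

To compare a *test* compartment against a *reference*, the null holds that
the test count for type $i$ is
$$ S_i^T \sim \mathrm{Binomial}\!\left(O_i^T,\; p_i\right), \qquad
   p_i = d_i^R \cdot \frac{D^T}{D^R}, $$
i.e. the expected count is the reference spectrum rescaled to the test
compartment's base composition and overall diversity.  The enrichment
ratio $e_i = (d_i^T/D^T)/(d_i^R/D^R)$ then equals $S_i^T / E_i$ with
$E_i = O_i^T p_i$ (an algebraic identity, asserted to floating tolerance
on every result).  Significance uses the exact two-tailed binomial
p-value (minimum-likelihood convention; the doubled-one-tail convention
is a configuration option) against a Bonferroni threshold
$\alpha / m$ where $m$ counts the types actually testable in the run —
96 normally, 84 after CpG exclusion, 6 at class level.  Confidence
intervals are exact Clopper–Pearson intervals on $S_i^T/O_i^T$, divided
by $p_i$.

Because opportunity counts reach millions, the two-sided p-value is
computed with an $O(\log n)$ bisection on the unimodal PMF rather than
the $O(n)$ enumeration used by `binom.test()`; the two agree exactly
wherever the latter is feasible (tested over all $n \le 50$, all
outcomes, eleven null probabilities).

### The reference is treated as fixed — and when that matters

The null above conditions on the observed reference spectrum, ignoring
its own sampling error.  This is deliberate and mirrors how the
comparison is used in practice, where the reference ("all other autosomal
windows combined", "autosomes outside hotspots") carries vastly more
information than the test compartment.  The consequence is quantifiable:
if the test and reference carry comparable information, the variance of
$e_i$ is roughly twice what the binomial null assumes, the z-scale is
inflated by $\sqrt{1 + I_T/I_R}$, and the family-wise error rate is far
above nominal.  Our test suite measures both regimes at ~50,000 variants
per compartment: with a 50× reference the measured FWER over 200 null
replicates is ~0.05; with an equal-size reference it is ~0.75.  The
equal-size property test is kept in the suite, failing, as an honest
record of this behavior: **conclusions from this test are only calibrated
when the reference dominates the test compartment.**  Accounting for
reference sampling error (e.g. a beta-binomial null) is out of scope.

### Derived comparisons

* **Scored bins** (`scored_bin_enrichment()`): a scored compartment
  (hotspot intensities) is partitioned — by explicit thresholds with the
  closed inequalities as printed (late $\le -0.5$, early $\ge 0.5$), by
  break points, or by length-weighted quantiles — and each bin is tested
  against one fixed external reference.  Exclusion regions (e.g. regions
  rich in clustered de novo mutations) are subtracted from both sides
  first.  Empty bins are flagged, not fatal.
* **Covariate matching** (`matched_comparison()`): both compartments are
  tiled into windows (default 100 kb), the covariate is averaged per
  window (base-pair-weighted over bedGraph segments), reference windows
  outside the test's covariate range are discarded (common-support
  restriction — without it the outer bins' within-bin means are badly
  mismatched), the test windows define quantile bins, and reference
  windows are subsampled with a stated seed to the test's bin
  proportions.  The diagnostic output reports per-bin window counts and
  the matched means; a test-occupied bin with no reference windows is an
  error naming the bin.  This matching construction is the package's own
  design; quantile-bin frequency matching was chosen over e.g.
  nearest-neighbour matching because it keeps the matched reference a
  plain compartment (a set of whole windows) on which the ordinary
  pipeline runs unchanged.
* **Regional trends** (`window_enrichment()`, `fit_trend()`,
  `chromosome_enrichment()`): each window's class-level spectrum is
  compared against all *other* windows pooled (leave-one-out, so summing
  window counts reproduces the scope-wide spectrum exactly), and the
  enrichment ratio is regressed on the window's mean covariate by
  ordinary least squares on the raw ratio scale (log scale available as
  an option).  $R^2$ is reported as the fraction of variance explained;
  a constant covariate yields an undefined (NA) $R^2$, never 0.  Windows
  with zero diversity are flagged and excluded from the fit.  Partial
  terminal windows are retained and flagged.

## Polarization and filtering rules

The major allele is treated as ancestral by default; the variant's
context keeps the reference flanking bases and only the central base is
replaced when the major allele differs from the reference.  Sites at
exactly 50% derived frequency are skipped (no defensible direction;
skipping avoids a directional bias), as are indels, non-ACGT alleles,
flankless contig-end positions, N-containing contexts, and REF
mismatches — every skip is logged with a reason, because the filters are
part of the analysis.  An ancestral-reconstruction mode
(`polarization_mode("ancestral-genome", ...)`) replaces the major-allele
rule for sensitivity analyses; sites where the reconstruction matches
neither allele are skipped.  No frequency filter is applied by default
(rare variants dominate; retaining the few common ones does not change
the comparisons); a 1% maximum-frequency cutoff and count bounds are
available via `frequency_filter()` for robustness checks, as is CpG
exclusion (`exclude_types(x, "cpg")`, 12 types) and exclusion of any
user-chosen hypermutable set from the normalization.

## What the simulator emulates

`simulate_variants()` provides planted ground truth for every stage.  Its
defaults are the study conditions the pipeline is meant for:

* **Cohort size**: 6,930 diploid individuals = 13,860 chromosomes, the
  denominator written into every simulated record.
* **Site-frequency spectrum**: derived allele counts follow a truncated
  power law $P(j) \propto j^{-\alpha}$, $j = 1..n-1$, with
  $\alpha = 1.7965$ solved (once, by `sfs_alpha_for_singletons()`) so the
  expected singleton fraction is 53% at that cohort size.  This
  reproduces the singleton share and the dominance of variants at three
  copies or fewer (~76%), the features the analyses depend on; a single
  exponent cannot simultaneously match the observed doubleton share
  (it gives ~15% where ~11% is observed), and no demographic realism is
  attempted.
* **Multiallelic sites**: ~6% of sites carry two derived alleles,
  constructed by co-locating pairs of independently drawn variants with
  the same context and distinct alternatives.
* **Rates**: per-type counts are drawn as
  $S_i \sim \mathrm{Poisson}(O_i \cdot \mathrm{rate}_i \cdot
  \mathrm{multiplier}_i)$ — equivalent to per-site Bernoulli at these
  rates but much faster, with closed-form expectations recorded in the
  truth manifest.  The default rate vector is a stylized human-like
  spectrum (class weights with C>T dominant and the twelve CpG
  transitions boosted ~10×, scaled to a mean of 0.014 per opportunity,
  the genome-wide density of ~120M SNPs over ~2.9 Gb); a flat vector
  (`uniform_rate_vector()`) is used wherever equal power per class
  matters more than realism.  Compartment multipliers plant effects per
  class or per type; per-window multipliers of the form
  $1 + \beta x_w$ plant covariate-driven structure.
* **Placement**: positions are drawn uniformly without collision from the
  compartment's opportunity sites for the type's context, so every
  simulated variant reclassifies to its planted type (checked), except
  for the vanishing fraction of draws above 50% frequency whose
  polarization legitimately flips.

What it does **not** emulate: linkage disequilibrium, demography beyond
the SFS shape, sequencing error, mutation-rate heterogeneity beyond the
planted structure, or realistic chromosome lengths — simulations run at
desk scale (contigs of 0.2–4 Mb; the tests state their sizes in each
fixture).  Passing tests therefore demonstrate that the *pipeline
machinery* is correct and calibrated under known structure, not that any
particular biological claim holds in real data.

## Numerical and design choices

* Intervals live in `GenomicRanges` (1-based, closed) and are merged at
  construction; BED/bedGraph I/O converts coordinates via `rtracklayer`.
  Scored compartments must be disjoint.  A variant belongs to a
  compartment by its focal position only; flanks may extend outside.
* Flank-truncated positions are excluded from opportunities *and* their
  variants skipped, keeping numerator and denominator consistent.
* $S_i \le O_i$ is expected but deliberately not fatal: an alt-major site
  polarizes to a context that may not exist in the reference sequence
  (opportunities are sequence-only), so rare excesses are legitimate and
  warn rather than stop.
* Two-sided p-value ties are resolved with the conventional
  $1 + 10^{-7}$ relative tolerance, matching `binom.test()`.
* Null probabilities $p_i > 1$ (possible when diversities are extreme)
  are clamped and recorded in the result's `clamped` attribute.
* Every random stage takes an explicit seed (`withr::with_seed`), reruns
  are byte-identical, and `run_pipeline()` echoes the full configuration
  plus input checksums into a JSON manifest.

## Known limitations

* The binomial test's anticonservativeness with non-dominant references,
  discussed above — the central caveat for small-vs-small comparisons.
* Quantile-bin matching equalizes bin occupancy, not within-bin covariate
  distributions; with ten bins and common support the residual mean
  mismatch is small (the diagnostics report it), but a strong nonlinear
  rate–covariate relationship could leak through.
* Multiallelic sites at high derived frequency are polarized per
  observation, not per site; with a singleton-heavy SFS this distinction
  is immaterial.
* Enrichment ratios are compared on the raw scale; for very small counts
  the ratio distribution is skewed and the log-scale option may be
  preferable.
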