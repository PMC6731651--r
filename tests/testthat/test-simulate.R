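test_that("simulated genomes are deterministic with the requested composition", {
  expect_identical(as.character(simulate_genome(500, seed = 401)),
                   as.character(simulate_genome(500, seed = 401)))
  expect_false(identical(as.character(simulate_genome(500, seed = 401)),
                         as.character(simulate_genome(500, seed = 402))))
  gc1 <- simulate_genome(300, gc = 1, seed = 403)
  expect_false(grepl("[AT]", as.character(gc1[[1L]])))
  # realized GC within a binomial CI of the request
  g <- simulate_genome(1e6, gc = 0.41, seed = 404)
  counts <- Biostrings::alphabetFrequency(g[[1L]])[c("C", "G")]
  ci <- binom_ci(sum(counts), 1e6, 0.999)
  expect_gt(0.41, ci[1, "lower"])
  expect_lt(0.41, ci[1, "upper"])
})

test_that("simulation defaults encode the cohort conditions", {
  truth <- simulation_truth()
  expect_equal(truth$n_individuals, 6930L)
  expect_equal(truth$n_chromosomes, 13860L)
  expect_equal(truth$multiallelic_fraction, 0.06)
  # exponent solves the 53% singleton target at the cohort size
  expect_equal(expected_singleton_fraction(truth$sfs_alpha, 13860L), 0.53,
               tolerance = 1e-6)
  expect_error(simulation_truth(multipliers = list(a = c(bogus = 2))),
               "unknown multiplier keys")
  expect_error(simulation_truth(multipliers = list(a = c("C>A" = -1))),
               "positive")
})

test_that("variant simulation is deterministic and writes byte-identical VCFs", {
  dir <- withr::local_tempdir()
  g <- simulate_genome(5e4, seed = 405)
  comp <- whole_compartment(g)
  truth <- simulation_truth(uniform_rate_vector(0.005), seed = 406)
  p1 <- file.path(dir, "a.vcf"); p2 <- file.path(dir, "b.vcf")
  write_vcf(simulate_variants(g, comp, truth)$variants, p1, g)
  write_vcf(simulate_variants(g, comp, truth)$variants, p2, g)
  expect_identical(readLines(p1), readLines(p2))
  # zero rates give a valid VCF with zero records
  none <- simulate_variants(g, comp, simulation_truth(
    uniform_rate_vector(0), seed = 1))
  expect_equal(nrow(none$variants), 0L)
  p0 <- file.path(dir, "none.vcf")
  write_vcf(none$variants, p0, g)
  expect_equal(nrow(read_variants(p0)), 0L)
  # impossible rates fail with advice rather than colliding
  expect_error(simulate_variants(g, comp, simulation_truth(
    uniform_rate_vector(0.9), seed = 1)), "lower the rate")
})

test_that("every simulated variant reclassifies to its planted type", {
  fx <- quick_cohort(seed = 407, rate = 0.006, length = 1.5e5)
  cl <- classify_variants(fx$sim$variants, fx$genome)
  # the generator writes the genome (major) allele as REF; only the rare
  # high-frequency draws flip polarization
  minor <- 2L * cl$ac < cl$an
  expect_true(all(!is.na(cl$type[minor])))
  expect_identical(cl$type[minor], cl$true_type[minor])
})

test_that("realized multiallelic fraction and SFS match the planted law", {
  fx <- quick_cohort(seed = 408, rate = 0.008, length = 4e5)
  v <- fx$sim$variants
  n_sites <- nrow(unique(v[, c("chrom", "pos")]))
  frac <- (nrow(v) - n_sites) / n_sites
  expect_gt(frac, 0.05); expect_lt(frac, 0.07)
  # multiallelic records share REF and carry distinct alts
  dup <- v[duplicated(v[, c("chrom", "pos")]) |
             duplicated(v[, c("chrom", "pos")], fromLast = TRUE), ]
  by_site <- split(dup, paste(dup$chrom, dup$pos))
  expect_true(all(vapply(by_site, function(s)
    length(unique(s$ref)) == 1L && !anyDuplicated(s$alt), logical(1))))
  # realized singleton fraction within a binomial CI of the closed form
  fr <- sfs_fractions(variant_sfs(v))
  expected <- expected_singleton_fraction(fx$truth$sfs_alpha, 13860L)
  ci <- binom_ci(round(fr["singleton"] * nrow(v)), nrow(v), 0.999)
  expect_gt(expected, ci[1, "lower"])
  expect_lt(expected, ci[1, "upper"])
})

test_that("pipeline spectra are consistent with planted rates across seeds", {
  # chi-square per seed over the 96 types; at level 0.01 over 20 seeds,
  # more than two rejections would indicate a generator/pipeline mismatch
  g <- simulate_genome(2e5, seed = 410)
  comp <- whole_compartment(g)
  opp <- count_contexts(g, comp)
  sites <- list(all = context_site_table(g, comp))
  lambda <- opp$types * uniform_rate_vector(0.008)
  rejections <- 0L
  for (seed in 421:440) {
    truth <- simulation_truth(uniform_rate_vector(0.008), seed = seed)
    sim <- simulate_variants(g, comp, truth, sites = sites)
    spec <- tabulate_spectrum(sim$variants, comp, g, opp = opp)
    chi2 <- sum((spec$S - lambda)^2 / lambda)
    if (pchisq(chi2, df = 96L, lower.tail = FALSE) < 0.01) {
      rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, 2L)
})

test_that("the truth manifest recomputes expected counts in closed form", {
  g <- simulate_genome(1e5, seed = 411)
  left <- compartment_set("left", data.frame(chrom = "chr1", start = 1L,
                                             end = 5e4L))
  right <- compartment_set("right", data.frame(chrom = "chr1",
                                               start = 5e4L + 1L,
                                               end = 1e5L))
  truth <- simulation_truth(uniform_rate_vector(0.004),
                            multipliers = list(left = c("C>G" = 1.4)),
                            seed = 412)
  sim <- simulate_variants(g, list(left = left, right = right), truth)
  ex <- sim$expected
  expect_equal(nrow(ex), 192L)
  # lambda column is exactly opportunities x rate x multiplier
  expect_equal(ex$lambda, ex$opportunities * ex$rate * ex$multiplier)
  # opportunities agree with the sequence-only counter per compartment
  oL <- count_contexts(g, left)
  expect_equal(ex$opportunities[ex$compartment == "left"],
               unname(oL$types))
  # multipliers recorded where planted, 1 elsewhere
  expect_true(all(ex$multiplier[ex$compartment == "left" &
                                  ex$class == "C>G"] == 1.4))
  expect_true(all(ex$multiplier[ex$compartment == "right"] == 1))
})

test_that("simulated compartments are recoverable and covariate means match the generator", {
  g <- simulate_genome(4e5, seed = 413)
  sc <- simulate_compartments(g, window_width = 2e4)
  # halves partition the contig
  expect_equal(compartment_width(sc$halves$left) +
                 compartment_width(sc$halves$right), 4e5)
  expect_equal(length(compartment_subtract(sc$halves$left,
                                           sc$halves$left)), 0L)
  # binning the scored hotspots recovers the tiers exactly
  tiers <- bin_by_score(sc$hotspots, edges = (1:3) + 0.5, mode = "breaks")
  sc_scores <- S4Vectors::mcols(as_granges(sc$hotspots))$score
  expect_equal(lengths(tiers), setNames(as.integer(table(sc_scores)),
                                        names(tiers)))
  # covariate windows carry the generating function's value at the midpoint
  gr <- as_granges(sc$covariate)
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
  expect_equal(S4Vectors::mcols(gr)$score, sin(2 * pi * mid / 4e5),
               tolerance = 1e-12)
  # per-window means of the emitted bedGraph match a per-base oracle
  dir <- withr::local_tempdir()
  write_compartment(sc$covariate, file.path(dir, "cov.bedgraph"))
  track <- read_bedgraph(file.path(dir, "cov.bedgraph"))
  w <- tile_windows(g, 4e4)
  means <- window_covariate_means(w, track)
  # windows are unions of whole covariate windows, so the mean is the
  # average of the covered scores
  expect_equal(means[1L],
               mean(S4Vectors::mcols(gr)$score[1:2]), tolerance = 1e-6)
})
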