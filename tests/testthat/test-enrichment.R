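test_that("two-tailed exact binomial p-values match binom.test on small cases", {
  withr::with_seed(201, {
    for (i in 1:300) {
      n <- sample(1:60, 1)
      x <- sample(0:n, 1)
      p <- runif(1, 0.01, 0.99)
      expect_equal(binom_p_two_sided(x, n, p),
                   binom.test(x, n, p)$p.value, tolerance = 1e-12)
    }
  })
  # the worked example: S = 5 of O = 20 at p = 0.1 equals the PMF sum
  pmf <- dbinom(0:20, 20, 0.1)
  oracle <- sum(pmf[pmf <= dbinom(5, 20, 0.1)])
  expect_equal(binom_p_two_sided(5, 20, 0.1), oracle, tolerance = 1e-12)
  # doubled-one-tail convention
  expect_equal(binom_p_two_sided(5, 20, 0.1, convention = "double"),
               min(1, 2 * min(pbinom(5, 20, 0.1),
                              pbinom(4, 20, 0.1, lower.tail = FALSE))))
  # degenerate null probabilities
  expect_equal(binom_p_two_sided(0, 10, 0), 1)
  expect_equal(binom_p_two_sided(3, 10, 0), 0)
  expect_equal(binom_p_two_sided(10, 10, 1), 1)
})

test_that("large-trial p-values agree with the Poisson regime", {
  # at n = 5e6 the bisection path must stay exact; compare against the
  # Poisson limit which is accurate to ~1e-6 at these rates
  n <- 5e6
  p <- 1e-4
  for (x in c(400L, 460L, 500L, 540L, 620L)) {
    pois <- local({
      lam <- n * p
      d <- dpois(x, lam)
      sum(dpois(0:2000, lam)[dpois(0:2000, lam) <= d * (1 + 1e-7)])
    })
    expect_equal(binom_p_two_sided(x, n, p), pois, tolerance = 1e-3)
  }
})

test_that("Clopper-Pearson interval matches binom.test and hits exact bounds", {
  expect_equal(binom_ci(0, 25)[, "lower"], c(lower = 0))
  expect_equal(binom_ci(25, 25)[, "upper"], c(upper = 1))
  withr::with_seed(202, {
    for (i in 1:50) {
      n <- sample(5:200, 1)
      x <- sample(0:n, 1)
      ci <- binom_ci(x, n, 0.95)
      bt <- binom.test(x, n)$conf.int
      expect_equal(unname(ci[1, ]), c(bt[1], bt[2]), tolerance = 1e-9)
    }
  })
  # independent beta-quantile evaluation for the worked case
  expect_equal(unname(binom_ci(5, 20, 0.95)[1, ]),
               c(qbeta(0.025, 5, 16), qbeta(0.975, 6, 15)),
               tolerance = 1e-12)
})

test_that("a compartment tested against itself is null by construction", {
  fx <- quick_cohort(seed = 211, rate = 0.01, length = 1e5)
  spec <- tabulate_spectrum(fx$sim$variants, fx$comp, fx$genome)
  res <- enrichment_test(spec, spec)
  expect_true(all(abs(res$enrichment[res$testable] - 1) < 1e-12))
  expect_false(any(res$significant))
  expect_equal(attr(res, "diversity_ratio"), 1)
})

test_that("enrichment ratio equals S over expected and inverts under swap", {
  fx <- quick_cohort(seed = 212, rate = 0.008, length = 2e5)
  g <- fx$genome
  left <- compartment_set("left", data.frame(chrom = "chr1", start = 1L,
                                             end = 1e5L))
  right <- compartment_set("right", data.frame(chrom = "chr1",
                                               start = 1e5L + 1L,
                                               end = 2e5L))
  cl <- classify_variants(fx$sim$variants, g)
  st <- tabulate_spectrum(cl, left, g)
  sr <- tabulate_spectrum(cl, right, g)
  res <- enrichment_test(st, sr)
  i <- res$testable
  expect_equal(res$enrichment[i], (res$S / res$expected)[i],
               tolerance = 1e-12)
  # swapping test and reference maps every ratio to its reciprocal
  swapped <- enrichment_test(sr, st)
  expect_equal(swapped$enrichment[i], 1 / res$enrichment[i],
               tolerance = 1e-9)
  # algebraic definition from relative diversities
  expect_equal(res$enrichment[i],
               ((st$S / st$O) / attr(st, "D"))[i] /
                 ((sr$S / sr$O) / attr(sr, "D"))[i],
               tolerance = 1e-12)
})

test_that("untestable types are reported, flagged, and excluded from m", {
  S_ref <- rep(50, 96); S_ref[3] <- 0        # no reference counts
  O <- rep(1e4, 96)
  S_test <- rep(52, 96)
  O_test <- O; O_test[7] <- 0; S_test[7] <- 0  # no test opportunities
  test <- spectrum_from_counts(S_test, O_test, "t")
  ref <- spectrum_from_counts(S_ref, O, "r")
  res <- enrichment_test(test, ref)
  expect_false(res$testable[3])
  expect_false(res$testable[7])
  expect_equal(attr(res, "m"), 94L)
  expect_true(all(is.na(res$p_value[c(3, 7)])))
  expect_equal(nrow(res), 96L)
  # degenerate reference is an error
  empty_ref <- spectrum_from_counts(rep(0, 96), O, "r0")
  expect_error(enrichment_test(test, empty_ref), "degenerate reference")
  # mismatched type sets are an error
  expect_error(enrichment_test(collapse_to_classes(test), ref),
               "different type sets")
})

test_that("family-wise error is controlled when the reference dominates the test", {
  # the binomial null treats the reference spectrum as fixed, so its
  # calibration requires the reference to carry much more information than
  # the test compartment (here 50x); 200 null replicates at ~5e4 test
  # variants
  O_t <- uniform_rate_vector(1)* 5e6
  O_r <- O_t * 50
  rate <- uniform_rate_vector(1e-4)  # ~520 expected per type
  n_rep <- 200L
  hits <- withr::with_seed(221, {
    vapply(seq_len(n_rep), function(i) {
      St <- simulate_spectrum_counts(O_t, rate)
      Sr <- simulate_spectrum_counts(O_r, rate)
      res <- enrichment_test(spectrum_from_counts(St, O_t, "t"),
                             spectrum_from_counts(Sr, O_r, "r"))
      any(res$significant)
    }, logical(1))
  })
  fwer <- mean(hits)
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(fwer, 0.05 + 3 * mc_se)
})

test_that("a planted class multiplier is recovered with the right magnitude", {
  g <- simulate_genome(8e5, seed = 231)
  left <- compartment_set("left", data.frame(chrom = "chr1", start = 1L,
                                             end = 4e5L))
  right <- compartment_set("right", data.frame(chrom = "chr1",
                                               start = 4e5L + 1L,
                                               end = 8e5L))
  truth <- simulation_truth(uniform_rate_vector(0.012),
                            multipliers = list(left = c("C>A" = 1.5)),
                            seed = 231)
  sim <- simulate_variants(g, list(left = left, right = right), truth)
  cl <- classify_variants(sim$variants, g)
  st <- collapse_to_classes(tabulate_spectrum(cl, left, g))
  sr <- collapse_to_classes(tabulate_spectrum(cl, right, g))
  res <- enrichment_test(st, sr)
  e_ca <- res$enrichment[res$type == "C>A"]
  # normalization deflates the raw 1.5x ratio because the planted class
  # also raises the test compartment's total diversity
  f_expect <- 1.5 / ((80 + 16 * 1.5) / 96)
  expect_gt(e_ca, f_expect * 0.93)
  expect_lt(e_ca, f_expect * 1.07)
  expect_true(res$significant[res$type == "C>A"])
})

test_that("scored-bin enrichment is flat under the null and flags empty bins", {
  g <- simulate_genome(6e5, seed = 241)
  sc <- simulate_compartments(g, window_width = 2e4)
  comps <- c(setNames(
    lapply(1:4, function(i) {
      b <- bin_by_score(sc$hotspots, edges = (1:3) + 0.5, mode = "breaks")[[i]]
      compartment_set(paste0("tier", i), as_granges(b))
    }), paste0("tier", 1:4)),
    list(reference = sc$hotspot_reference))
  truth <- simulation_truth(uniform_rate_vector(0.01), seed = 241)
  sim <- simulate_variants(g, comps, truth)
  res <- scored_bin_enrichment(sim$variants, g, scored = sc$hotspots,
                               reference = sc$hotspot_reference,
                               edges = (1:3) + 0.5, mode = "breaks")
  sm <- bin_class_summary(res, "C>G")
  expect_true(all(abs(sm$enrichment - 1) < 0.45))
  # across 4 bins x 6 classes a stray rejection or two is consistent with
  # the test's nominal level (the reference here is only ~10x the bins);
  # a planted effect would fire one class across most bins instead
  n_sig <- sum(vapply(res, function(b)
    sum(b$result$significant), integer(1)))
  expect_lte(n_sig, 2L)
  # a bin whose score range contains no intervals is flagged, not fatal
  res2 <- scored_bin_enrichment(sim$variants, g, scored = sc$hotspots,
                                reference = sc$hotspot_reference,
                                edges = c(1.5, 2.5, 3.5, 99), mode = "breaks")
  expect_true(res2[[5L]]$empty)
  expect_false(res2[[1L]]$empty)
})

test_that("matched comparison is a near no-op when covariate distributions agree", {
  g <- simulate_genome(4e5, n_contigs = 2L, seed = 251)
  cov <- covariate_windows(g, 4e4, fun = function(mid, len) 2 * mid / len - 1)
  test <- compartment_set("c1", genome_extent(g)[1L])
  pool <- compartment_set("c2", genome_extent(g)[2L])
  truth <- simulation_truth(uniform_rate_vector(0.008), seed = 251)
  sim <- simulate_variants(g, list(c1 = test, c2 = pool), truth)
  mc <- matched_comparison(sim$variants, g, test, pool, cov,
                           window_width = 4e4, n_bins = 5, seed = 9,
                           collapse = TRUE)
  expect_false(any(mc$result$significant))
  expect_lt(abs(mc$diagnostics$matched_mean_covariate -
                  mc$diagnostics$test_mean_covariate), 0.1)
  # unmatchable bins raise an error naming the bin
  cov_bad <- local({
    gr <- as_granges(cov)
    x <- ifelse(as.character(GenomeInfoDb::seqnames(gr)) == "chr1",
                S4Vectors::mcols(gr)$score + 10, S4Vectors::mcols(gr)$score)
    compartment_set("covariate", GenomicRanges::granges(gr), score = x)
  })
  expect_error(matched_comparison(sim$variants, g, test, pool, cov_bad,
                                  window_width = 4e4, n_bins = 5),
               "covariate")
})
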