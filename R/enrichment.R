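#' Exact two-tailed binomial p-value
#'
#' Minimum-likelihood convention (the standard exact two-sided test, as in
#' [stats::binom.test()]): the p-value is the total probability of all
#' outcomes whose point probability does not exceed that of the observed
#' count (up to a 1 + 1e-7 relative tolerance guarding against ties broken
#' by floating-point rounding).  Because opportunity counts run to millions
#' of trials, the opposite-tail boundary is located by bisection on the
#' unimodal PMF rather than by enumeration, making the computation
#' O(log n); results agree exactly with `binom.test()` where the latter is
#' feasible.  The doubled-one-tail convention is available as an option.
#'
#' @param x Observed successes (vectorized).
#' @param n Number of trials.
#' @param p Null success probability.
#' @param convention `"minlik"` (default) or `"double"` (twice the smaller
#'   one-sided tail, capped at 1).
#' @return Numeric vector of p-values.
#' @export
binom_p_two_sided <- function(x, n, p, convention = c("minlik", "double")) {
  convention <- match.arg(convention)
  stopifnot(all(x >= 0), all(x <= n), all(p >= 0), all(p <= 1))
  k <- max(length(x), length(n), length(p))
  x <- rep_len(x, k); n <- rep_len(n, k); p <- rep_len(p, k)
  vapply(seq_len(k), function(i) {
    binom_p_scalar(x[i], n[i], p[i], convention)
  }, numeric(1))
}

binom_p_scalar <- function(x, n, p, convention) {
  if (p == 0) return(if (x == 0) 1 else 0)
  if (p == 1) return(if (x == n) 1 else 0)
  if (convention == "double") {
    return(min(1, 2 * min(pbinom(x, n, p),
                          pbinom(x - 1, n, p, lower.tail = FALSE))))
  }
  rel_err <- 1 + 1e-07
  d <- dbinom(x, n, p)
  mode <- floor(n * p + p)
  if (x == mode || dbinom(mode, n, p) <= d * rel_err) return(1)
  if (x < mode) {
    # smallest k >= mode whose PMF has dropped to <= d (PMF decreasing
    # to the right of the mode)
    if (dbinom(n, n, p) > d * rel_err) return(pbinom(x, n, p))
    lo <- mode; hi <- n
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (dbinom(mid, n, p) <= d * rel_err) hi <- mid else lo <- mid
    }
    min(1, pbinom(x, n, p) + pbinom(hi - 1, n, p, lower.tail = FALSE))
  } else {
    if (dbinom(0, n, p) > d * rel_err) {
      return(pbinom(x - 1, n, p, lower.tail = FALSE))
    }
    lo <- 0; hi <- mode
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (dbinom(mid, n, p) <= d * rel_err) lo <- mid else hi <- mid
    }
    min(1, pbinom(lo, n, p) + pbinom(x - 1, n, p, lower.tail = FALSE))
  }
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval on a proportion from the beta quantile form; matches
#' `binom.test()$conf.int`.  The lower bound is exactly 0 when `x = 0` and
#' the upper bound exactly 1 when `x = n`.
#'
#' @param x Successes (vectorized).
#' @param n Trials.
#' @param level Confidence level (default 0.95).
#' @return A two-column matrix (`lower`, `upper`).
#' @export
binom_ci <- function(x, n, level = 0.95) {
  stopifnot(all(x >= 0), all(x <= n), level > 0, level < 1)
  k <- max(length(x), length(n))
  x <- rep_len(x, k); n <- rep_len(n, k)
  a <- 1 - level
  lower <- ifelse(x == 0, 0, qbeta(a / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - a / 2, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

#' Per-type enrichment test between two compartments
#'
#' For each mutation type the observed count in the test compartment is
#' compared to a binomial null whose per-opportunity success probability is
#' the reference relative diversity rescaled to the test compartment's
#' overall diversity: `p_i = d_i_ref * D_test / D_ref`.  The expected count
#' is then the reference spectrum re-expressed on the test compartment's
#' base composition and diversity, and the enrichment ratio
#' `e_i = (d_i_test / D_test) / (d_i_ref / D_ref)` equals `S_i / E_i`.
#' Significance uses the exact two-tailed p-value at the
#' Bonferroni-corrected level `alpha / m`, where `m` counts the testable
#' types in this run (96 for a full catalog, 84 after CpG exclusion, 6 at
#' class level).  Types with no reference counts (or no test opportunities)
#' are reported but flagged untestable.  The reference spectrum is treated
#' as fixed: its own sampling error is deliberately ignored, so the test is
#' calibrated when the reference carries much more information than the
#' test compartment (see the methods vignette for the consequences when it
#' does not).
#'
#' @param test,ref `spectrum_table`s over the same type set (both type- or
#'   both class-level).
#' @param alpha Family-wise significance level (default 0.05).
#' @param level Confidence level for the Clopper-Pearson interval on the
#'   enrichment ratio.
#' @param convention Two-tailed convention, see [binom_p_two_sided()].
#' @return An `enrichment_result` data.frame: `type`, `class`, `S`, `O`,
#'   `p_null`, `expected`, `enrichment`, `ci_lower`, `ci_upper`, `p_value`,
#'   `significant`, `testable`; attributes `alpha`, `m`, `level`,
#'   `diversity_ratio` (D_test/D_ref), `clamped` (types whose null
#'   probability was clamped into [0, 1]), and the compartment names.
#' @export
enrichment_test <- function(test, ref, alpha = 0.05, level = 0.95,
                            convention = c("minlik", "double")) {
  convention <- match.arg(convention)
  stopifnot(inherits(test, "spectrum_table"), inherits(ref, "spectrum_table"))
  if (!identical(test$type, ref$type)) {
    stop("test and reference tables cover different type sets")
  }
  D_T <- attr(test, "D"); D_R <- attr(ref, "D")
  if (is.na(D_R) || D_R <= 0) {
    stop("degenerate reference compartment (no diversity)")
  }
  f <- D_T / D_R
  p_raw <- ifelse(ref$O > 0, (ref$S / ref$O) * f, NA_real_)
  clamped <- !is.na(p_raw) & (p_raw > 1 | p_raw < 0)
  p_null <- pmin(1, pmax(0, p_raw))
  expected <- test$O * p_null
  enrichment <- ifelse(expected > 0, test$S / expected, NA_real_)
  testable <- test$O > 0 & ref$O > 0 & ref$S > 0
  m <- sum(testable)
  p_value <- rep(NA_real_, nrow(test))
  ci_lower <- ci_upper <- rep(NA_real_, nrow(test))
  if (m > 0) {
    idx <- which(testable)
    p_value[idx] <- binom_p_two_sided(test$S[idx], test$O[idx],
                                      p_null[idx], convention)
    ci <- binom_ci(test$S[idx], test$O[idx], level)
    ci_lower[idx] <- ci[, "lower"] / p_null[idx]
    ci_upper[idx] <- ci[, "upper"] / p_null[idx]
  }
  significant <- testable & !is.na(p_value) & p_value < alpha / max(m, 1L)
  out <- data.frame(type = test$type, class = test$class,
                    S = test$S, O = test$O, p_null = p_null,
                    expected = expected, enrichment = enrichment,
                    ci_lower = ci_lower, ci_upper = ci_upper,
                    p_value = p_value, significant = significant,
                    testable = testable, stringsAsFactors = FALSE)
  structure(out, class = c("enrichment_result", "data.frame"),
            alpha = alpha, m = m, level = level,
            diversity_ratio = f, convention = convention,
            clamped = test$type[clamped],
            test_compartment = attr(test, "compartment"),
            ref_compartment = attr(ref, "compartment"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: '%s' vs reference '%s'; %d/%d testable, %d significant at alpha = %g / m = %d\n",
    attr(x, "test_compartment"), attr(x, "ref_compartment"),
    attr(x, "m"), nrow(x), sum(x$significant), attr(x, "alpha"),
    attr(x, "m")))
  NextMethod()
}

#' Write an enrichment result as TSV
#' @param x An `enrichment_result`.
#' @param path Output file.
#' @param params Extra parameters for the comment block.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(x, path, params = list()) {
  write_tsv(as.data.frame(x), path, params = c(
    list(test = attr(x, "test_compartment"),
         reference = attr(x, "ref_compartment"),
         alpha = attr(x, "alpha"), m = attr(x, "m"),
         level = attr(x, "level"), convention = attr(x, "convention"),
         diversity_ratio = attr(x, "diversity_ratio")), params))
}

#' Enrichment across score bins of a scored compartment
#'
#' Partitions a scored compartment (e.g. hotspot intensities) into bins,
#' builds a class-level spectrum for each bin, and tests every bin against
#' one fixed external reference compartment.  Exclusion regions are
#' subtracted from both sides before any counting.
#'
#' @param variants Variant table (classified or not) or VCF path.
#' @param genome `DNAStringSet` or FASTA path.
#' @param scored A scored `CompartmentSet`.
#' @param reference The fixed reference `CompartmentSet`.
#' @param exclusions Optional `CompartmentSet` removed from bins and
#'   reference alike.
#' @param edges,n_bins,mode Binning parameters, see [bin_by_score()].
#' @param collapse If `TRUE` (default) run the comparison at the 6-class
#'   level, otherwise over all 96 types.
#' @param drop Types to exclude from the spectra (e.g. `"cpg"`).
#' @param alpha,level,convention Passed to [enrichment_test()].
#' @param polarization,filter Passed to [tabulate_spectrum()].
#' @return A `scored_bin_enrichment` list, one element per bin:
#'   `list(bin, n_intervals, empty, result)` where `result` is an
#'   `enrichment_result` (or `NULL` when the bin has no opportunities;
#'   empty bins are flagged, not fatal).
#' @export
scored_bin_enrichment <- function(variants, genome, scored, reference,
                                  exclusions = NULL, edges = NULL,
                                  n_bins = NULL,
                                  mode = c("threshold", "breaks", "quantile"),
                                  collapse = TRUE, drop = NULL,
                                  alpha = 0.05, level = 0.95,
                                  convention = "minlik",
                                  polarization = "major-allele",
                                  filter = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  bins <- bin_by_score(scored, edges = edges, n_bins = n_bins,
                       mode = match.arg(mode))
  if (!is.null(exclusions)) {
    bins <- lapply(bins, function(b) {
      if (length(b)) compartment_subtract(b, exclusions, name = b$name) else b
    })
    reference <- compartment_subtract(reference, exclusions,
                                      name = reference$name)
  }
  cl <- if (is.data.frame(variants) && "type" %in% names(variants)) {
    as.data.table(variants)
  } else {
    classify_variants(variants, genome, polarization)
  }
  prep <- function(comp) {
    t <- tabulate_spectrum(cl, comp, genome, polarization, filter)
    if (!is.null(drop)) t <- exclude_types(t, drop)
    if (collapse) t <- collapse_to_classes(t)
    t
  }
  ref_spec <- prep(reference)
  out <- lapply(bins, function(b) {
    if (length(b) == 0L) {
      return(list(bin = b$name, n_intervals = 0L, empty = TRUE,
                  result = NULL))
    }
    spec <- prep(b)
    if (attr(spec, "O_tot") == 0) {
      return(list(bin = b$name, n_intervals = length(b), empty = TRUE,
                  result = NULL))
    }
    list(bin = b$name, n_intervals = length(b), empty = FALSE,
         result = enrichment_test(spec, ref_spec, alpha = alpha,
                                  level = level, convention = convention))
  })
  structure(out, class = "scored_bin_enrichment")
}

#' Per-bin summary of one mutation class across score bins
#' @param x A `scored_bin_enrichment`.
#' @param class Mutation class (default `"C>G"`, the class tracked across
#'   hotspot intensities).
#' @return `data.frame` with one row per non-empty bin: enrichment ratio,
#'   CI, p-value, significance.
#' @export
bin_class_summary <- function(x, class = "C>G") {
  rows <- lapply(x, function(b) {
    if (b$empty) {
      return(data.frame(bin = b$bin, empty = TRUE, S = NA_real_,
                        enrichment = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    r <- b$result
    i <- match(class, r$type)
    if (is.na(i)) stop("class not present in results: ", class)
    data.frame(bin = b$bin, empty = FALSE, S = r$S[i],
               enrichment = r$enrichment[i], ci_lower = r$ci_lower[i],
               ci_upper = r$ci_upper[i], p_value = r$p_value[i],
               significant = r$significant[i])
  })
  do.call(rbind, rows)
}

#' Compartment comparison matched on a covariate
#'
#' Compares a test compartment to a reference pool after matching their
#' covariate distributions (e.g. X vs autosomes matched for mean
#' replication timing).  Both compartments are tiled into windows, the
#' covariate is averaged per window, the test windows define `n_bins`
#' quantile bins, and reference windows are subsampled (with a stated seed)
#' so that the reference occupies the bins in the same proportions as the
#' test.  The enrichment test then runs against the pooled matched
#' reference.
#'
#' @param variants Variant table (classified or not) or VCF path.
#' @param genome `DNAStringSet` or FASTA path.
#' @param test,ref_pool `CompartmentSet`s.
#' @param covariate A scored `GRanges`/`CompartmentSet` track (bedGraph
#'   style).
#' @param window_width Window width in bp for matching (default 100 kb).
#' @param n_bins Number of covariate quantile bins (default 5).
#' @param seed Seed for the reference subsampling.
#' @param collapse Run at class level (`TRUE`) or over all 96 types.
#' @param drop Types to exclude (e.g. `"cpg"`).
#' @param alpha,level,convention Passed to [enrichment_test()].
#' @param polarization,filter Passed to [tabulate_spectrum()].
#' @return A `matched_comparison` list: `result` (enrichment vs matched
#'   reference), `matched_ref` (the subsampled reference compartment), and
#'   `diagnostics` (per-bin window counts and mean covariate of test,
#'   pool, and matched reference).  An error names any test-occupied bin
#'   with no reference windows.
#' @export
matched_comparison <- function(variants, genome, test, ref_pool, covariate,
                               window_width = 1e5, n_bins = 5, seed = 1,
                               collapse = FALSE, drop = NULL,
                               alpha = 0.05, level = 0.95,
                               convention = "minlik",
                               polarization = "major-allele",
                               filter = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  wins <- function(comp) {
    w <- unlist(GenomicRanges::slidingWindows(reduce(as_granges(comp)),
                                              width = window_width,
                                              step = window_width))
    mcols(w)$covariate <- window_covariate_means(w, covariate)
    if (anyNA(mcols(w)$covariate)) {
      stop("covariate track does not cover all windows")
    }
    w
  }
  wt <- wins(test)
  wr <- wins(ref_pool)
  xt <- mcols(wt)$covariate
  # common-support restriction: reference windows outside the test
  # compartment's covariate range can never be matched and would drag the
  # outer bins' means away from the test's
  keep_r <- mcols(wr)$covariate >= min(xt) & mcols(wr)$covariate <= max(xt)
  if (!any(keep_r)) stop("no reference windows inside the test covariate range")
  wr <- wr[keep_r]
  xr <- mcols(wr)$covariate
  edges <- quantile(xt, probs = seq_len(n_bins - 1L) / n_bins, names = FALSE)
  bin_of <- function(x) findInterval(x, edges, left.open = FALSE) + 1L
  bt <- bin_of(xt)
  br <- bin_of(xr)
  t_b <- tabulate(bt, nbins = n_bins)
  r_b <- tabulate(br, nbins = n_bins)
  short <- which(t_b > 0 & r_b == 0)
  if (length(short)) {
    stop("no reference windows available in covariate bin(s) ",
         paste(short, collapse = ", "))
  }
  ratio <- min((r_b / t_b)[t_b > 0])
  n_take <- ifelse(t_b > 0, pmax(1L, floor(ratio * t_b)), 0L)
  n_take <- pmin(n_take, r_b)
  pick <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_bins), function(b) {
      cand <- which(br == b)
      if (n_take[b] == 0L) integer(0)
      else sort(sample(cand, n_take[b]))
    }))
  })
  matched_ref <- compartment_set(paste0(ref_pool$name, "-matched"),
                                 granges(wr[pick]))
  cl <- if (is.data.frame(variants) && "type" %in% names(variants)) {
    as.data.table(variants)
  } else {
    classify_variants(variants, genome, polarization)
  }
  prep <- function(comp) {
    t <- tabulate_spectrum(cl, comp, genome, polarization, filter)
    if (!is.null(drop)) t <- exclude_types(t, drop)
    if (collapse) t <- collapse_to_classes(t)
    t
  }
  res <- enrichment_test(prep(test), prep(matched_ref), alpha = alpha,
                         level = level, convention = convention)
  mw <- width(wr[pick])
  diagnostics <- list(
    bins = data.frame(bin = seq_len(n_bins), test_windows = t_b,
                      pool_windows = r_b, matched_windows = n_take),
    test_mean_covariate = sum(xt * width(wt)) / sum(width(wt)),
    pool_mean_covariate = sum(xr * width(wr)) / sum(width(wr)),
    matched_mean_covariate = sum(xr[pick] * mw) / sum(mw),
    seed = seed, n_bins = n_bins, window_width = window_width
  )
  structure(list(result = res, matched_ref = matched_ref,
                 diagnostics = diagnostics),
            class = "matched_comparison")
}
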