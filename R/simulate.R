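#' Solve the SFS power-law exponent for a target singleton fraction
#'
#' The simulator draws derived allele counts from a truncated power law
#' `P(j) proportional to j^-alpha`, `j = 1 .. n-1`.  This solves for the
#' exponent whose expected singleton fraction `1 / sum(j^-alpha)` matches a
#' target, e.g. the 53% singleton fraction observed in 13,860 sampled
#' chromosomes.
#'
#' @param fraction Target singleton fraction (default 0.53).
#' @param n_chromosomes Number of sampled chromosomes (default 13,860,
#'   i.e. 6,930 diploid individuals).
#' @return The exponent `alpha`.
#' @export
sfs_alpha_for_singletons <- function(fraction = 0.53,
                                     n_chromosomes = 13860L) {
  stopifnot(fraction > 0, fraction < 1, n_chromosomes >= 4L)
  j <- seq_len(n_chromosomes - 1L)
  uniroot(function(a) 1 / sum(j^(-a)) - fraction,
          interval = c(0.5, 6), tol = 1e-10)$root
}

#' Expected singleton fraction of the truncated power-law SFS
#' @param alpha Exponent.
#' @param n_chromosomes Sampled chromosomes.
#' @return Expected fraction of variants with derived allele count 1.
#' @export
expected_singleton_fraction <- function(alpha, n_chromosomes) {
  j <- seq_len(n_chromosomes - 1L)
  1 / sum(j^(-alpha))
}

#' Stylized human-like per-type mutation rate vector
#'
#' Per-opportunity, per-type segregating-site rates with human-like class
#' weights and hypermutable CpG transitions (C>T at NCG contexts boosted
#' relative to other C>T types), scaled so the mean rate across the 96
#' types equals `mean_rate`.  With the default mean of 0.014 a simulated
#' compartment accrues about 0.042 segregating sites per base, the density
#' of the ~120M SNPs per ~2.9 Gb that motivates the desk-scale defaults.
#'
#' @param mean_rate Mean per-opportunity rate over the 96 types.
#' @param cpg_boost Multiplier of CpG C>T types relative to other C>T types.
#' @return Named numeric vector of 96 rates in catalog order.
#' @export
default_rate_vector <- function(mean_rate = 0.014, cpg_boost = 10) {
  catalog <- build_catalog()
  class_w <- c("C>A" = 0.10, "C>G" = 0.09, "C>T" = 0.40,
               "T>A" = 0.07, "T>C" = 0.28, "T>G" = 0.06)
  w <- class_w[catalog$class] / 16
  cpg_ct <- catalog$class == "C>T" & substr(catalog$context, 2, 3) == "CG"
  w[cpg_ct] <- w[cpg_ct] * cpg_boost
  w <- w / mean(w) * mean_rate
  setNames(as.numeric(w), catalog$type)
}

#' Flat per-type rate vector
#' @param rate Common per-opportunity rate for all 96 types.
#' @return Named numeric vector of 96 rates.
#' @export
uniform_rate_vector <- function(rate) {
  setNames(rep(rate, 96L), build_catalog()$type)
}

#' Ground truth for a simulated cohort
#'
#' Collects every planted parameter: the base 96-type per-opportunity rate
#' vector, per-compartment multipliers, the SFS exponent and cohort size,
#' and the multiallelic fraction.  Defaults are the study conditions
#' emulated throughout: a cohort of 6,930 diploid individuals (13,860
#' chromosomes), a singleton-heavy SFS (53% singletons), and ~6% of sites
#' multiallelic.
#'
#' @param base_rate Named 96-vector of per-opportunity rates
#'   ([default_rate_vector()] by default).
#' @param multipliers Named list, one element per compartment name; each a
#'   named numeric vector keyed by class (`"C>A"`) and/or type
#'   (`"ACA>AAA"`).  Unlisted compartments/types get multiplier 1.
#' @param sfs_alpha SFS exponent; default solved so the expected singleton
#'   fraction is 53% at the cohort size.
#' @param n_individuals Diploid individuals (default 6,930).
#' @param multiallelic_fraction Target fraction of sites carrying two
#'   derived alleles (default 0.06).
#' @param seed Seed used by [simulate_variants()] unless overridden.
#' @return A `simulation_truth` object.
#' @export
simulation_truth <- function(base_rate = default_rate_vector(),
                             multipliers = NULL,
                             sfs_alpha = NULL,
                             n_individuals = 6930L,
                             multiallelic_fraction = 0.06,
                             seed = 1L) {
  catalog <- build_catalog()
  if (!is.null(names(base_rate))) base_rate <- base_rate[catalog$type]
  stopifnot(length(base_rate) == 96L, all(base_rate >= 0),
            n_individuals >= 2L,
            multiallelic_fraction >= 0, multiallelic_fraction < 1)
  n_chromosomes <- 2L * as.integer(n_individuals)
  if (is.null(sfs_alpha)) {
    sfs_alpha <- sfs_alpha_for_singletons(0.53, n_chromosomes)
  }
  if (!is.null(multipliers)) {
    stopifnot(is.list(multipliers), !is.null(names(multipliers)))
    ok <- unlist(lapply(multipliers, names))
    bad <- setdiff(ok, c(mutation_classes(), catalog$type))
    if (length(bad)) stop("unknown multiplier keys: ",
                          paste(bad, collapse = ", "))
    if (any(unlist(multipliers) <= 0)) stop("multipliers must be positive")
  }
  structure(list(base_rate = setNames(as.numeric(base_rate), catalog$type),
                 multipliers = multipliers,
                 sfs_alpha = sfs_alpha,
                 n_individuals = as.integer(n_individuals),
                 n_chromosomes = n_chromosomes,
                 multiallelic_fraction = multiallelic_fraction,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Resolve a truth's multiplier vector for one compartment
#' @param truth A `simulation_truth`.
#' @param compartment Compartment name.
#' @return Named numeric vector of 96 multipliers.
#' @export
resolve_multipliers <- function(truth, compartment) {
  catalog <- build_catalog()
  m <- setNames(rep(1, 96L), catalog$type)
  spec <- truth$multipliers[[compartment]]
  if (!is.null(spec)) {
    for (key in names(spec)) {
      if (key %in% mutation_classes()) {
        m[catalog$class == key] <- m[catalog$class == key] * spec[[key]]
      } else {
        m[key] <- m[key] * spec[[key]]
      }
    }
  }
  m
}

#' Simulate an i.i.d. random genome
#'
#' @param length Contig length in bp (recycled over contigs).
#' @param gc GC fraction (bases drawn i.i.d.).
#' @param n_contigs Number of contigs.
#' @param seed Seed; identical seeds give identical sequence.
#' @param contig_names Names (default `chr1`, `chr2`, ...).
#' @return A named `DNAStringSet`.
#' @export
simulate_genome <- function(length, gc = 0.41, n_contigs = 1L, seed = 1L,
                            contig_names = NULL) {
  stopifnot(all(length > 0), gc >= 0, gc <= 1, n_contigs >= 1L)
  lens <- rep_len(as.integer(length), n_contigs)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  g <- DNAStringSet(seqs)
  names(g) <- contig_names %||% paste0("chr", seq_len(n_contigs))
  g
}

#' Table of opportunity sites by canonical context
#'
#' Enumerates every position in the compartment whose trinucleotide is
#' complete and N-free, with its canonical context and the orientation in
#' which the canonical form was found (`fwd = TRUE` when the genome strand
#' already carries the central pyrimidine).  This is the placement index
#' the simulator draws variant positions from; its per-context tallies
#' equal [count_contexts()] on the same compartment.
#'
#' @param genome A `DNAStringSet`.
#' @param comp A `CompartmentSet` (or `GRanges`).
#' @return `data.table` with `chrom`, `pos`, `ctx` (canonical context),
#'   `fwd`.
#' @export
context_site_table <- function(genome, comp) {
  gr <- reduce(as_granges(comp))
  pieces <- list()
  for (ct in unique(as.character(seqnames(gr)))) {
    if (!ct %in% names(genome)) stop("contig absent from genome: ", ct)
    seq <- genome[[ct]]
    rng <- IRanges::ranges(gr[seqnames(gr) == ct])
    for (ctx in canonical_contexts()) {
      fwd_pos <- start(matchPattern(ctx, seq)) + 1L
      rev_pos <- start(matchPattern(revcomp_kmer(ctx), seq)) + 1L
      for (orient in c(TRUE, FALSE)) {
        pos <- if (orient) fwd_pos else rev_pos
        if (!base::length(pos)) next
        keep <- IRanges::overlapsAny(IRanges(pos, pos), rng)
        pos <- pos[keep]
        if (!base::length(pos)) next
        pieces[[base::length(pieces) + 1L]] <-
          data.table(chrom = ct, pos = pos, ctx = ctx, fwd = orient)
      }
    }
  }
  if (!base::length(pieces)) {
    return(data.table(chrom = character(0), pos = integer(0),
                      ctx = character(0), fwd = logical(0)))
  }
  st <- rbindlist(pieces)
  setorder(st, chrom, pos)
  st[]
}

#' Split one whole-genome site table across compartments
#'
#' Scans the genome once with [context_site_table()] and partitions the
#' rows by compartment membership, which is much cheaper than scanning per
#' compartment when many (e.g. per-window) compartments share a genome.
#'
#' @param genome A `DNAStringSet`.
#' @param compartments Named list of `CompartmentSet`s.
#' @param st Optional precomputed whole-genome [context_site_table()].
#' @return Named list of site `data.table`s aligned with `compartments`.
#' @export
sites_by_compartment <- function(genome, compartments, st = NULL) {
  if (is.null(st)) st <- context_site_table(genome, genome_extent(genome))
  if (is.null(names(compartments))) {
    names(compartments) <- vapply(compartments, `[[`, "", "name")
  }
  # one overlap join for all compartments, then split the row indices
  comp_gr <- lapply(compartments, as_granges)
  all_gr <- do.call(c, unname(lapply(comp_gr, granges)))
  comp_id <- rep(seq_along(compartments), lengths(comp_gr))
  q <- GRanges(st$chrom, IRanges(st$pos, st$pos))
  h <- harmonize_seqlevels(q, all_gr)
  hit <- findOverlaps(h$a, h$b, ignore.strand = TRUE, select = "first")
  found <- !is.na(hit)
  grp <- comp_id[hit[found]]
  rows_by_comp <- split(which(found), grp)
  out <- lapply(seq_along(compartments), function(i) {
    rows <- rows_by_comp[[as.character(i)]]
    if (is.null(rows)) st[0L] else st[rows]
  })
  setNames(out, names(compartments))
}

#' Draw derived allele counts from the truncated power-law SFS
#' @param n_draws Number of variants.
#' @param n_chromosomes Sampled chromosomes (support is `1 .. n-1`).
#' @param alpha Exponent.
#' @return Integer vector of derived allele counts.
#' @export
sample_allele_counts <- function(n_draws, n_chromosomes, alpha) {
  j <- seq_len(n_chromosomes - 1L)
  p <- j^(-alpha)
  sample(j, n_draws, replace = TRUE, prob = p / sum(p))
}

# greedy pairing of rows with distinct alt alleles inside one
# (context, orientation) group; returns a 2-column index matrix
pair_distinct_alts <- function(alts) {
  groups <- split(seq_along(alts), alts)
  pairs <- vector("list", base::length(alts) %/% 2L)
  np <- 0L
  repeat {
    sizes <- lengths(groups)
    live <- which(sizes > 0L)
    if (base::length(live) < 2L) break
    ord <- live[order(sizes[live], decreasing = TRUE)]
    i <- groups[[ord[1L]]][1L]
    j <- groups[[ord[2L]]][1L]
    groups[[ord[1L]]] <- groups[[ord[1L]]][-1L]
    groups[[ord[2L]]] <- groups[[ord[2L]]][-1L]
    np <- np + 1L
    pairs[[np]] <- c(i, j)
  }
  if (np == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, pairs[seq_len(np)])
}

#' Simulate a rare-variant callset with planted spectrum structure
#'
#' For each compartment and mutation type the segregating-site count is
#' drawn as `Poisson(O_ctx * base_rate * multiplier)` (equivalent to
#' per-site Bernoulli at the low rates used, but with closed-form expected
#' counts), positions are placed uniformly on the compartment's opportunity
#' sites for that context without collisions, each variant receives a
#' derived allele count from the truncated power-law SFS, and a target
#' fraction of co-located pairs with distinct alternative alleles is merged
#' into multiallelic sites.  The reference allele written to the VCF is the
#' genome base (the ancestral/major allele for the overwhelming majority of
#' variants, whose derived frequency is below one half).
#'
#' @param genome A `DNAStringSet`.
#' @param compartments A `CompartmentSet` or named list of disjoint
#'   `CompartmentSet`s.
#' @param truth A [simulation_truth()].
#' @param sites Optional named list of precomputed [context_site_table()]s
#'   (one per compartment) to avoid re-scanning the genome.
#' @param seed Overrides `truth$seed`.
#' @return A `simulated_cohort` list: `variants` (`data.table` with
#'   `chrom`, `pos`, `ref`, `alt`, `ac`, `an`, `true_type`,
#'   `compartment`), `truth`, and `expected` (`data.table` per compartment
#'   and type with opportunities, multiplier, and expected count `lambda`;
#'   sufficient to recompute every `E[S_i]` in closed form).
#' @export
simulate_variants <- function(genome, compartments, truth, sites = NULL,
                              seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (inherits(compartments, "CompartmentSet")) {
    compartments <- setNames(list(compartments), compartments$name)
  }
  if (is.null(names(compartments))) {
    names(compartments) <- vapply(compartments, `[[`, "", "name")
  }
  all_gr <- lapply(compartments, as_granges)
  tot_w <- sum(vapply(all_gr, function(g) sum(width(g)), numeric(1)))
  uni_w <- sum(width(reduce(do.call(c, unname(lapply(all_gr, granges))))))
  if (uni_w != tot_w) stop("compartments must be disjoint")
  seed <- seed %||% truth$seed
  catalog <- build_catalog()

  drawn <- withr::with_seed(seed, {
    out <- list()
    expected <- list()
    for (cname in names(compartments)) {
      st <- sites[[cname]] %||%
        context_site_table(genome, compartments[[cname]])
      o_ctx <- setNames(numeric(32L), canonical_contexts())
      if (nrow(st)) {
        tab <- st[, .N, by = "ctx"]
        o_ctx[tab$ctx] <- tab$N
      }
      mult <- resolve_multipliers(truth, cname)
      lambda <- o_ctx[catalog$context] * truth$base_rate * mult
      expected[[cname]] <- data.table(
        compartment = cname, type = catalog$type,
        class = catalog$class, opportunities = as.numeric(o_ctx[catalog$context]),
        rate = as.numeric(truth$base_rate), multiplier = as.numeric(mult),
        lambda = as.numeric(lambda))
      S <- rpois(96L, lambda)
      if (!any(S > 0)) next
      idx_by_ctx <- split(seq_len(nrow(st)), st$ctx)
      for (ctx in canonical_contexts()) {
        ti <- which(catalog$context == ctx)
        k <- sum(S[ti])
        if (k == 0L) next
        avail <- idx_by_ctx[[ctx]]
        if (is.null(avail) || base::length(avail) < k) {
          stop("planted rate too high: ", k, " variants requested for ",
               base::length(avail %||% integer(0)), " ", ctx,
               " sites in '", cname, "'; lower the rate")
        }
        rows <- st[avail[sample.int(base::length(avail), k)]]
        rows[, alt_canon := rep(catalog$alt[ti], S[ti])]
        rows[, true_type := rep(catalog$type[ti], S[ti])]
        out[[base::length(out) + 1L]] <- rows[, list(
          chrom, pos, ctx, fwd, alt_canon, true_type,
          compartment = cname)]
      }
    }
    v <- if (base::length(out)) rbindlist(out) else
      data.table(chrom = character(0), pos = integer(0),
                 ctx = character(0), fwd = logical(0),
                 alt_canon = character(0), true_type = character(0),
                 compartment = character(0))
    # multiallelic construction: merge co-located pairs with distinct alts
    if (truth$multiallelic_fraction > 0 && nrow(v) > 1L) {
      M <- round(truth$multiallelic_fraction * nrow(v) /
                   (1 + truth$multiallelic_fraction))
      if (M > 0L) {
        v[, row_id := .I]
        grp <- v[, list(ids = list(row_id)), by = list(compartment, ctx, fwd)]
        merged <- 0L
        for (gi in seq_len(nrow(grp))) {
          if (merged >= M) break
          ids <- grp$ids[[gi]]
          if (base::length(ids) < 2L) next
          prs <- pair_distinct_alts(v$alt_canon[ids])
          if (!nrow(prs)) next
          take <- min(nrow(prs), M - merged)
          for (pi in seq_len(take)) {
            v$pos[ids[prs[pi, 2L]]] <- v$pos[ids[prs[pi, 1L]]]
          }
          merged <- merged + take
        }
        v[, row_id := NULL]
      }
    }
    if (nrow(v)) {
      v[, ref := ifelse(fwd, substr(ctx, 2L, 2L),
                        complement_bases(substr(ctx, 2L, 2L)))]
      v[, alt := ifelse(fwd, alt_canon, complement_bases(alt_canon))]
      v[, ac := sample_allele_counts(nrow(v), truth$n_chromosomes,
                                     truth$sfs_alpha)]
      v[, an := truth$n_chromosomes]
    } else {
      v[, `:=`(ref = character(0), alt = character(0),
               ac = integer(0), an = integer(0))]
    }
    list(v = v, expected = expected)
  })
  v <- drawn$v
  v[, c("ctx", "fwd", "alt_canon") := NULL]
  setcolorder(v, c("chrom", "pos", "ref", "alt", "ac", "an",
                   "true_type", "compartment"))
  setorder(v, chrom, pos, alt)
  structure(list(variants = v[], truth = truth,
                 expected = rbindlist(drawn$expected), seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  n_sites <- nrow(unique(x$variants[, c("chrom", "pos")]))
  cat(sprintf("simulated_cohort: %s variant observations at %s sites (%s multiallelic), %d chromosomes, seed %d\n",
              format(nrow(x$variants), big.mark = ","),
              format(n_sites, big.mark = ","),
              format(nrow(x$variants) - n_sites, big.mark = ","),
              x$truth$n_chromosomes, x$seed))
  invisible(x)
}

#' Draw per-type segregating-site counts (the count layer only)
#'
#' The Poisson layer of [simulate_variants()] without placement, allele
#' frequencies, or VCF output: per-type counts
#' `S_i ~ Poisson(O_i * rate_i * multiplier_i)`.  Useful for studying the
#' sampling behavior of downstream statistics at scale.
#'
#' @param opp An `OpportunityTable` (or named 96-vector of opportunities).
#' @param rate Named 96-vector of per-opportunity rates.
#' @param multiplier Named multiplier vector (class and/or type keys) or a
#'   96-vector; default all 1.
#' @param seed Optional seed.
#' @return Named integer vector of 96 counts.
#' @export
simulate_spectrum_counts <- function(opp, rate, multiplier = NULL,
                                     seed = NULL) {
  catalog <- build_catalog()
  O <- if (inherits(opp, "OpportunityTable")) opp$types else opp[catalog$type]
  rate <- rate[catalog$type]
  m <- setNames(rep(1, 96L), catalog$type)
  if (!is.null(multiplier)) {
    if (base::length(multiplier) == 96L) {
      m <- multiplier[catalog$type]
    } else {
      for (key in names(multiplier)) {
        if (key %in% mutation_classes()) {
          m[catalog$class == key] <- m[catalog$class == key] * multiplier[[key]]
        } else {
          m[key] <- m[key] * multiplier[[key]]
        }
      }
    }
  }
  lambda <- as.numeric(O) * as.numeric(rate) * as.numeric(m)
  draw <- function() setNames(rpois(96L, lambda), catalog$type)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Smooth covariate track over genome windows
#'
#' Tiles the genome into windows and scores each window with a smooth
#' deterministic function of its midpoint, emulating a broad-scale
#' covariate such as replication timing on the [-1, 1] scale (positive =
#' earlier than average).
#'
#' @param genome A `DNAStringSet`.
#' @param width Window width in bp.
#' @param fun `function(mid, contig_length)` returning the score; default a
#'   single sinusoid along each contig.
#' @return A scored `CompartmentSet` of windows.
#' @export
covariate_windows <- function(genome, width,
                              fun = function(mid, len)
                                sin(2 * pi * mid / len)) {
  w <- tile_windows(genome, width, name = "covariate")
  gr <- as_granges(w)
  lens <- setNames(Biostrings::width(genome), names(genome))
  mid <- (start(gr) + end(gr)) / 2
  score <- fun(mid, lens[as.character(seqnames(gr))])
  compartment_set("covariate", granges(gr), score = as.numeric(score))
}

#' Simulate compartment definitions and a covariate track
#'
#' Emits the interval structures the pipeline's comparisons run on, for a
#' given simulated genome: two disjoint halves of the first contig, late
#' and early compartments cut from a smooth covariate track at the
#' replication-timing thresholds (late <= -0.5, early >= 0.5), a tiered
#' scored compartment emulating hotspots of increasing intensity with its
#' non-hotspot reference, and the covariate track itself.  With `dir` set,
#' compartments are written as BED (scored sets as 5-column BED) and the
#' covariate as bedGraph.
#'
#' @param genome A `DNAStringSet`.
#' @param window_width Covariate window width (default 50 kb).
#' @param covariate_fun Score function, see [covariate_windows()].
#' @param n_tiers Number of hotspot intensity tiers (default 4).
#' @param tier_width Width of each hotspot interval (default 20 kb).
#' @param tiers_per_level Hotspot intervals per tier (default 8).
#' @param dir Optional output directory for BED/bedGraph files.
#' @return Named list: `halves` (list of two `CompartmentSet`s), `late`,
#'   `early`, `hotspots` (scored), `hotspot_reference`, `covariate`
#'   (scored windows).
#' @export
simulate_compartments <- function(genome, window_width = 5e4,
                                  covariate_fun = NULL,
                                  n_tiers = 4L, tier_width = 2e4,
                                  tiers_per_level = 8L, dir = NULL) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  c1 <- names(genome)[1L]
  half <- lens[[c1]] %/% 2L
  halves <- list(
    left = compartment_set("left", GRanges(c1, IRanges(1L, half))),
    right = compartment_set("right", GRanges(c1, IRanges(half + 1L,
                                                         lens[[c1]])))
  )
  cov <- if (is.null(covariate_fun)) {
    covariate_windows(genome, window_width)
  } else {
    covariate_windows(genome, window_width, covariate_fun)
  }
  rt <- bin_by_score(cov, edges = c(-0.5, 0.5), mode = "threshold",
                     names = c("late", "early"))
  late <- compartment_set("late", granges(as_granges(rt$late)))
  early <- compartment_set("early", granges(as_granges(rt$early)))
  # hotspot tiers laid out round-robin along the first contig
  n_spots <- n_tiers * tiers_per_level
  pitch <- lens[[c1]] %/% (n_spots + 1L)
  if (pitch < 2000L) stop("contig too short for requested hotspots")
  tier_width <- min(tier_width, pitch %/% 2L)
  starts <- pitch * seq_len(n_spots) - tier_width %/% 2L
  scores <- rep(seq_len(n_tiers), length.out = n_spots)
  hot <- compartment_set("hotspots",
                         GRanges(c1, IRanges(starts,
                                             width = tier_width)),
                         score = scores)
  hot_ref <- compartment_complement(hot, genome, name = "non-hotspot")
  out <- list(halves = halves, late = late, early = early,
              hotspots = hot, hotspot_reference = hot_ref,
              covariate = cov)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_compartment(halves$left, file.path(dir, "left.bed"))
    write_compartment(halves$right, file.path(dir, "right.bed"))
    write_compartment(late, file.path(dir, "late.bed"))
    write_compartment(early, file.path(dir, "early.bed"))
    write_compartment(hot, file.path(dir, "hotspots.bed"))
    write_compartment(hot_ref, file.path(dir, "non_hotspot.bed"))
    write_compartment(cov, file.path(dir, "covariate.bedgraph"))
  }
  out
}
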