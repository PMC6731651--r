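#' Per-window class enrichment relative to the rest of a scope
#'
#' For each window, the class-level spectrum is compared to the pooled
#' spectrum of all *other* windows in the scope (leave-one-out, so that
#' summing the window counts reproduces the scope-wide spectrum exactly).
#' The enrichment ratio is the window's relative class diversity over the
#' rest's relative class diversity, the statistic plotted against mean
#' replication timing in 1-Mb window analyses.  Windows with no diversity
#' are flagged unusable rather than dropped.
#'
#' @param variants Variant table (classified or not) or VCF path.
#' @param genome `DNAStringSet` or FASTA path.
#' @param windows A `CompartmentSet` of disjoint windows (e.g. from
#'   [tile_windows()]), or a `GRanges`.
#' @param covariate Optional scored track ([read_bedgraph()] style) or a
#'   numeric vector of per-window values; reported as the window mean.
#' @param polarization,filter Passed to classification/filtering.
#' @param window_opps Optional precomputed list of per-window 6-class
#'   opportunity matrices (from a previous run's `"O_matrix"` attribute) to
#'   avoid recounting contexts.
#' @return A `window_enrichment` data.frame, one row per window x class:
#'   `window`, `chrom`, `start`, `end`, `covariate`, `class`, `S`, `O`,
#'   `enrichment`, `usable`; attributes `S_matrix`/`O_matrix` (window x
#'   class counts).
#' @export
window_enrichment <- function(variants, genome, windows, covariate = NULL,
                              polarization = "major-allele", filter = NULL,
                              window_opps = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  wgr <- as_granges(windows)
  if (!GenomicRanges::isDisjoint(wgr)) stop("windows must be disjoint")
  nw <- length(wgr)
  cls <- mutation_classes()
  catalog <- build_catalog()

  cl <- if (is.data.frame(variants) && "type" %in% names(variants)) {
    as.data.table(variants)
  } else {
    classify_variants(variants, genome, polarization)
  }
  keep <- is.na(cl$skip) & apply_frequency_filter(cl, filter)
  cl <- cl[keep]
  q <- GRanges(cl$chrom, IRanges(cl$pos, cl$pos))
  h <- harmonize_seqlevels(q, wgr)
  hits <- findOverlaps(h$a, h$b, ignore.strand = TRUE, select = "first")
  inside <- !is.na(hits)
  win_id <- hits[inside]
  vclass <- factor(catalog$class[match(cl$type[inside], catalog$type)],
                   levels = cls)
  S <- matrix(0, nrow = nw, ncol = length(cls), dimnames = list(NULL, cls))
  tab <- table(factor(win_id, levels = seq_len(nw)), vclass)
  S[] <- as.numeric(tab)

  if (is.null(window_opps)) {
    O <- matrix(0, nrow = nw, ncol = length(cls), dimnames = list(NULL, cls))
    for (i in seq_len(nw)) {
      opp <- count_contexts(genome, compartment_set("w", wgr[i]))
      O[i, ] <- rowsum(as.numeric(opp$types), catalog$class)[cls, 1L]
    }
  } else {
    O <- window_opps
    stopifnot(nrow(O) == nw, identical(colnames(O), cls))
  }

  S_tot <- colSums(S); O_tot <- colSums(O)
  Sw <- rowSums(S); Ow <- rowSums(O)
  S_all <- sum(Sw); O_all <- sum(Ow)

  xw <- if (is.null(covariate)) {
    rep(NA_real_, nw)
  } else if (is.numeric(covariate)) {
    stopifnot(length(covariate) == nw)
    covariate
  } else {
    window_covariate_means(wgr, covariate)
  }

  rows <- lapply(seq_len(nw), function(i) {
    D_w <- if (Ow[i] > 0) Sw[i] / Ow[i] else NA_real_
    S_rest <- S_tot - S[i, ]; O_rest <- O_tot - O[i, ]
    D_rest <- (S_all - Sw[i]) / (O_all - Ow[i])
    usable <- !is.na(D_w) && D_w > 0 && D_rest > 0
    d_w <- ifelse(O[i, ] > 0, S[i, ] / O[i, ], NA_real_)
    d_rest <- ifelse(O_rest > 0, S_rest / O_rest, NA_real_)
    e <- if (usable) (d_w / D_w) / (d_rest / D_rest) else rep(NA_real_, 6L)
    data.frame(window = i, chrom = as.character(seqnames(wgr))[i],
               start = start(wgr)[i], end = end(wgr)[i],
               covariate = xw[i], class = cls, S = S[i, ], O = O[i, ],
               enrichment = as.numeric(e),
               usable = usable & is.finite(e) & O[i, ] > 0,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("window_enrichment", "data.frame"),
            S_matrix = S, O_matrix = O)
}

#' Fit the trend of class enrichment on a covariate
#'
#' Ordinary least squares of the per-window enrichment ratio on the window
#' mean covariate (raw ratio scale by default; set `log = TRUE` to regress
#' on the log ratio).  R-squared is the fraction of variance in enrichment
#' explained by the covariate.
#'
#' @param enrichments A `window_enrichment` data.frame.
#' @param class Mutation class to fit.
#' @param log Regress `log(enrichment)` instead of the raw ratio.
#' @return A one-row `trend_fit` data.frame: `class`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope), `n`.  With a constant covariate the
#'   fit is undefined: `r_squared` is `NA`, not 0.
#' @export
fit_trend <- function(enrichments, class, log = FALSE) {
  stopifnot(class %in% mutation_classes())
  d <- enrichments[enrichments$class == class & enrichments$usable &
                     !is.na(enrichments$covariate), , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need at least 3 usable windows to fit a trend (have ",
         nrow(d), ")")
  }
  y <- if (log) base::log(d$enrichment) else d$enrichment
  if (stats::sd(d$covariate) == 0) {
    warning("constant covariate; trend undefined")
    return(structure(
      data.frame(class = class, slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_, p_value = NA_real_, n = nrow(d)),
      class = c("trend_fit", "data.frame")))
  }
  fit <- lm(y ~ d$covariate)
  n <- nrow(d)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  # computed directly so an exactly collinear input gives R^2 = 1 and
  # p = 0 instead of a summary.lm() warning
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  sxx <- sum((d$covariate - mean(d$covariate))^2)
  se <- sqrt((rss / (n - 2L)) / sxx)
  tstat <- if (se > 0) unname(coef(fit)[2L]) / se else Inf
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  structure(
    data.frame(class = class, slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = r2, p_value = pv, n = n),
    class = c("trend_fit", "data.frame"))
}

#' Trend fits for all six classes
#' @param enrichments A `window_enrichment` data.frame.
#' @param log Passed to [fit_trend()].
#' @return A six-row `trend_fit` data.frame.
#' @export
fit_all_trends <- function(enrichments, log = FALSE) {
  out <- do.call(rbind, lapply(mutation_classes(), function(cl)
    fit_trend(enrichments, cl, log = log)))
  rownames(out) <- NULL
  out
}

#' Chromosome-level enrichment and trend
#'
#' The window statistic applied with whole contigs as the units: each
#' contig's class spectrum is compared to all other contigs combined
#' (leave-one-out), and the per-contig enrichment is regressed on the
#' contig's mean covariate.
#'
#' @param variants Variant table (classified or not) or VCF path.
#' @param genome `DNAStringSet` or FASTA path.
#' @param contigs Contig names to include (default: all in `genome`).
#' @param covariate Optional scored track or per-contig numeric vector.
#' @param polarization,filter As elsewhere.
#' @return List with `enrichment` (a `window_enrichment` with one window
#'   per contig) and `trends` (six-row `trend_fit`, or `NULL` when fewer
#'   than 3 contigs or no covariate).
#' @export
chromosome_enrichment <- function(variants, genome, contigs = NULL,
                                  covariate = NULL,
                                  polarization = "major-allele",
                                  filter = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.null(contigs)) contigs <- names(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  wgr <- GRanges(contigs, IRanges(1L, lens[contigs]))
  enr <- window_enrichment(variants, genome, compartment_set("contigs", wgr),
                           covariate = covariate,
                           polarization = polarization, filter = filter)
  enr$window <- NULL
  trends <- if (length(contigs) >= 3L && !all(is.na(enr$covariate))) {
    fit_all_trends(enr)
  } else {
    NULL
  }
  list(enrichment = enr, trends = trends)
}
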