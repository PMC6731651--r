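#' Genomic compartments
#'
#' A compartment is a named set of genomic intervals, internally a
#' `GRanges`.  Unscored compartments are merged (overlapping or abutting
#' intervals collapsed) and sorted at construction; scored compartments
#' (e.g. hotspot tiers, covariate windows) keep one score per interval and
#' must be non-overlapping.
#'
#' @param name Compartment label.
#' @param ranges A `GRanges`, or a `data.frame` with columns `chrom`,
#'   `start`, `end` (1-based, closed) and optionally `score`.
#' @param score Optional numeric score per interval (overrides any `score`
#'   column / metadata).
#' @return A `CompartmentSet` (S3) with fields `name` and `ranges`.
#' @export
compartment_set <- function(name, ranges, score = NULL) {
  if (is.data.frame(ranges)) {
    if (any(ranges$end < ranges$start)) {
      stop("intervals must satisfy start <= end")
    }
    if (is.null(score) && "score" %in% names(ranges)) score <- ranges$score
    ranges <- GRanges(ranges$chrom, IRanges(ranges$start, ranges$end))
  }
  stopifnot(is(ranges, "GRanges"))
  ranges <- GenomicRanges::sort(granges(ranges, use.mcols = TRUE))
  if (is.null(score) && !is.null(mcols(ranges)$score)) {
    score <- mcols(ranges)$score
  }
  if (any(width(ranges) < 1L)) stop("intervals must satisfy start <= end")
  if (is.null(score)) {
    ranges <- reduce(ranges)
  } else {
    stopifnot(length(score) == length(ranges))
    if (length(ranges) > 1L &&
        !GenomicRanges::isDisjoint(ranges)) {
      stop("scored compartments must have non-overlapping intervals")
    }
    mcols(ranges)$score <- as.numeric(score)
  }
  structure(list(name = name, ranges = ranges), class = "CompartmentSet")
}

#' @export
print.CompartmentSet <- function(x, ...) {
  cat(sprintf("CompartmentSet '%s': %d interval(s), %s bp%s\n",
              x$name, length(x$ranges),
              format(sum(width(x$ranges)), big.mark = ","),
              if (!is.null(mcols(x$ranges)$score)) ", scored" else ""))
  invisible(x)
}

#' @export
length.CompartmentSet <- function(x) length(x$ranges)

#' Extract the `GRanges` of a compartment
#' @param comp A `CompartmentSet` (or `GRanges`, returned as-is).
#' @return A `GRanges`.
#' @export
as_granges <- function(comp) {
  if (is(comp, "GRanges")) return(comp)
  stopifnot(inherits(comp, "CompartmentSet"))
  comp$ranges
}

#' Total width of a compartment in bases
#' @param comp A `CompartmentSet`.
#' @return Integer number of bases covered.
#' @export
compartment_width <- function(comp) sum(width(as_granges(comp)))

# put two GRanges on a common seqlevel universe so set ops don't warn
harmonize_seqlevels <- function(a, b) {
  lev <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lev
  seqlevels(b) <- lev
  list(a = a, b = b)
}

#' Interval algebra on compartments
#'
#' Standard set semantics on the underlying intervals; results are merged
#' and sorted.  `compartment_complement()` takes the complement within a
#' genome extent (a `DNAStringSet`, `Seqinfo`, or another compartment
#' covering the full extent).
#'
#' @param a,b `CompartmentSet`s.
#' @param name Label for the result (a default is derived from the inputs).
#' @return A `CompartmentSet`.
#' @export
compartment_intersect <- function(a, b, name = NULL) {
  h <- harmonize_seqlevels(as_granges(a), as_granges(b))
  compartment_set(name %||% paste0(a$name, "&", b$name),
                  GenomicRanges::intersect(reduce(h$a), reduce(h$b),
                                           ignore.strand = TRUE))
}

#' @rdname compartment_intersect
#' @export
compartment_subtract <- function(a, b, name = NULL) {
  h <- harmonize_seqlevels(as_granges(a), as_granges(b))
  compartment_set(name %||% paste0(a$name, "-", b$name),
                  GenomicRanges::setdiff(reduce(h$a), reduce(h$b),
                                         ignore.strand = TRUE))
}

#' @rdname compartment_intersect
#' @param extent Genome extent for the complement: `DNAStringSet`,
#'   `Seqinfo`, or `CompartmentSet`/`GRanges`.
#' @export
compartment_complement <- function(a, extent, name = NULL) {
  full <- genome_extent(extent)
  h <- harmonize_seqlevels(full, as_granges(a))
  compartment_set(name %||% paste0("not-", a$name),
                  GenomicRanges::setdiff(h$a, reduce(h$b),
                                         ignore.strand = TRUE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Full genome extent as a `GRanges`
#' @param x A `DNAStringSet`, `Seqinfo`, `CompartmentSet` or `GRanges`.
#' @return `GRanges` covering each contig end to end (for sequence inputs),
#'   or the reduced ranges of `x`.
#' @export
genome_extent <- function(x) {
  if (is(x, "DNAStringSet")) {
    return(GRanges(names(x), IRanges(1L, Biostrings::width(x)),
                   seqlengths = setNames(Biostrings::width(x), names(x))))
  }
  if (is(x, "Seqinfo")) {
    return(GRanges(seqlevels(x), IRanges(1L, seqlengths(x)), seqinfo = x))
  }
  reduce(as_granges(x))
}

#' Test membership of positions in a compartment
#' @param comp A `CompartmentSet`.
#' @param chrom,pos Vectors of contig names and 1-based positions.
#' @return Logical vector.
#' @export
compartment_member <- function(comp, chrom, pos) {
  gr <- as_granges(comp)
  q <- GRanges(chrom, IRanges(pos, pos))
  h <- harmonize_seqlevels(q, gr)
  IRanges::overlapsAny(h$a, h$b, ignore.strand = TRUE)
}

# length-weighted quantiles of interval scores
weighted_score_quantile <- function(score, w, probs) {
  ord <- order(score)
  score <- score[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) score[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Partition a scored compartment into bins by score
#'
#' Three modes:
#' \describe{
#'   \item{`threshold`}{`edges = c(low, high)`: a "low" bin with
#'     score <= low and a "high" bin with score >= high, the middle
#'     discarded (closed inequalities, as in late <= -0.5 vs early >= 0.5
#'     replication timing).  A single edge splits into `<=` and `>`.}
#'   \item{`breaks`}{`edges` are strictly increasing cut points; intervals
#'     fall into `length(edges) + 1` half-open bins
#'     (-Inf, e1), [e1, e2), ..., [ek, Inf).}
#'   \item{`quantile`}{`n_bins` bins with edges computed from the
#'     interval-length-weighted score distribution.}
#' }
#'
#' @param comp A scored `CompartmentSet`.
#' @param edges Numeric thresholds / cut points (threshold and breaks modes).
#' @param n_bins Number of quantile bins (quantile mode).
#' @param mode One of `"threshold"`, `"breaks"`, `"quantile"`.
#' @param names Optional bin names.
#' @return Named list of `CompartmentSet`s (possibly with empty interval
#'   sets), each keeping its interval scores.
#' @export
bin_by_score <- function(comp, edges = NULL, n_bins = NULL,
                         mode = c("threshold", "breaks", "quantile"),
                         names = NULL) {
  mode <- match.arg(mode)
  gr <- as_granges(comp)
  score <- mcols(gr)$score
  if (is.null(score) || anyNA(score)) {
    stop("every interval needs a score for binning")
  }
  if (mode %in% c("threshold", "breaks")) {
    if (is.null(edges) || is.unsorted(edges, strictly = TRUE)) {
      stop("edges must be strictly increasing")
    }
  }
  if (mode == "threshold") {
    if (length(edges) == 1L) {
      idx <- list(which(score <= edges), which(score > edges))
      nm <- names %||% paste0(c("le_", "gt_"), edges)
    } else if (length(edges) == 2L) {
      idx <- list(which(score <= edges[1L]), which(score >= edges[2L]))
      nm <- names %||% c(paste0("le_", edges[1L]), paste0("ge_", edges[2L]))
    } else {
      stop("threshold mode takes one or two edges")
    }
  } else {
    if (mode == "quantile") {
      stopifnot(!is.null(n_bins), n_bins >= 1L)
      if (n_bins == 1L) {
        edges <- numeric(0)
      } else {
        probs <- seq_len(n_bins - 1L) / n_bins
        edges <- weighted_score_quantile(score, width(gr), probs)
      }
    }
    k <- length(edges) + 1L
    bin <- findInterval(score, edges, left.open = FALSE) + 1L
    idx <- lapply(seq_len(k), function(b) which(bin == b))
    nm <- names %||% paste0("bin", seq_len(k))
  }
  stopifnot(length(nm) == length(idx))
  out <- lapply(seq_along(idx), function(i) {
    sub <- gr[idx[[i]]]
    structure(list(name = nm[i], ranges = sub), class = "CompartmentSet")
  })
  setNames(out, nm)
}

#' Tile a genome extent into fixed-width windows
#'
#' Windows are non-overlapping and cover each contig completely; a final
#' partial window is retained and flagged in the `partial` metadata column.
#'
#' @param extent A `DNAStringSet`, `Seqinfo`, `CompartmentSet` or `GRanges`.
#'   For compartments, each interval is tiled independently.
#' @param width Window width in bp (> 0).
#' @param name Compartment label for the window set.
#' @return A scored-capable `CompartmentSet` whose ranges carry a `partial`
#'   flag.
#' @export
tile_windows <- function(extent, width, name = "windows") {
  stopifnot(width > 0)
  gr <- genome_extent(extent)
  tiles <- unlist(GenomicRanges::slidingWindows(gr, width = width,
                                                step = width))
  mcols(tiles)$partial <- GenomicRanges::width(tiles) < width
  structure(list(name = name, ranges = tiles), class = "CompartmentSet")
}

#' Per-window length-weighted mean of a scored track
#'
#' The covariate value of a window is the base-pair-weighted mean of the
#' track segments overlapping it (e.g. mean replication timing of a 1-Mb
#' window from a bedGraph).  Windows with no overlapping segment get `NA`.
#'
#' @param windows A `CompartmentSet` or `GRanges` of windows.
#' @param track A scored `GRanges` (e.g. from [read_bedgraph()]) or scored
#'   `CompartmentSet`.
#' @return Numeric vector, one value per window.
#' @export
window_covariate_means <- function(windows, track) {
  w <- as_granges(windows)
  t <- as_granges(track)
  score <- mcols(t)$score
  if (is.null(score)) stop("track has no score")
  h <- harmonize_seqlevels(w, t)
  hits <- findOverlaps(h$a, h$b, ignore.strand = TRUE)
  ov <- pintersect(h$a[queryHits(hits)], h$b[subjectHits(hits)])
  wbp <- width(ov)
  q <- queryHits(hits)
  num <- rep(0, length(w))
  den <- rep(0, length(w))
  agg_n <- rowsum(wbp * score[subjectHits(hits)], q)
  agg_d <- rowsum(wbp, q)
  at <- as.integer(rownames(agg_n))
  num[at] <- agg_n[, 1L]
  den[at] <- agg_d[, 1L]
  ifelse(den > 0, num / den, NA_real_)
}
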