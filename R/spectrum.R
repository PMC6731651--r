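#' Frequency filter for cohort variants
#'
#' The default analysis keeps all frequencies (rare variants dominate the
#' data and high-frequency variants are too few to matter); a maximum
#' derived-allele-frequency cutoff (e.g. 1%) and count bounds are exposed
#' for sensitivity analyses.
#'
#' @param max_freq Maximum derived allele frequency, exclusive upper bound
#'   applied as `derived_ac / an < max_freq` (or `NULL` for no bound).
#' @param min_count,max_count Inclusive bounds on the derived allele count.
#' @return A `frequency_filter` object.
#' @export
frequency_filter <- function(max_freq = NULL, min_count = NULL,
                             max_count = NULL) {
  if (!is.null(max_freq)) stopifnot(max_freq > 0, max_freq <= 1)
  if (!is.null(min_count)) stopifnot(min_count >= 1)
  if (!is.null(max_count) && !is.null(min_count)) {
    stopifnot(max_count >= min_count)
  }
  structure(list(max_freq = max_freq, min_count = min_count,
                 max_count = max_count), class = "frequency_filter")
}

apply_frequency_filter <- function(v, filt) {
  if (is.null(filt)) return(rep(TRUE, nrow(v)))
  stopifnot(inherits(filt, "frequency_filter"))
  count <- if ("derived_ac" %in% names(v) && !anyNA(v$derived_ac)) {
    v$derived_ac
  } else if ("derived_ac" %in% names(v)) {
    ifelse(is.na(v$derived_ac), v$ac, v$derived_ac)
  } else {
    v$ac
  }
  keep <- rep(TRUE, nrow(v))
  if (!is.null(filt$max_freq)) keep <- keep & (count / v$an < filt$max_freq)
  if (!is.null(filt$min_count)) keep <- keep & count >= filt$min_count
  if (!is.null(filt$max_count)) keep <- keep & count <= filt$max_count
  keep
}

# core constructor: counts named by catalog type + opportunities
new_spectrum_table <- function(S, opp, compartment, level = "type") {
  catalog <- build_catalog()
  if (level == "type") {
    stopifnot(length(S) == 96L)
    df <- data.frame(type = catalog$type, class = catalog$class,
                     context = catalog$context, alt = catalog$alt,
                     S = as.numeric(S), O = as.numeric(opp),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(type = names(S), class = names(S),
                     context = NA_character_, alt = NA_character_,
                     S = as.numeric(S), O = as.numeric(opp),
                     stringsAsFactors = FALSE)
  }
  excess <- df$S > df$O
  if (any(excess)) {
    # a handful of alt-major sites can carry an ancestral context absent
    # from the reference sequence; anything systematic means the
    # opportunity table does not match the compartment/genome
    warning("segregating sites exceed opportunities for ",
            sum(excess), " type(s): ",
            paste(head(df$type[excess], 5L), collapse = ", "),
            if (sum(excess) > 5L) ", ...")
  }
  S_tot <- sum(df$S)
  O_tot <- sum(df$O)
  D <- if (O_tot > 0) S_tot / O_tot else NA_real_
  df$d <- ifelse(df$O > 0, df$S / df$O, NA_real_)
  df$r <- if (!is.na(D) && D > 0) df$d / D else NA_real_
  structure(df, class = c("spectrum_table", "data.frame"),
            compartment = compartment, level = level,
            S_tot = S_tot, O_tot = O_tot, D = D)
}

#' Totals of a spectrum table
#' @param t A `spectrum_table`.
#' @return Named list with `S_tot`, `O_tot` and total diversity `D`
#'   (`S_tot / O_tot`, opportunities summed over all 96 types so each site
#'   is counted three times; downstream enrichment ratios are invariant to
#'   this constant).
#' @export
spectrum_totals <- function(t) {
  list(S_tot = attr(t, "S_tot"), O_tot = attr(t, "O_tot"), D = attr(t, "D"))
}

#' @export
print.spectrum_table <- function(x, ...) {
  tt <- spectrum_totals(x)
  cat(sprintf("spectrum_table '%s' (%s level): %s segregating sites, %s opportunities, D = %.4g\n",
              attr(x, "compartment"), attr(x, "level"),
              format(tt$S_tot, big.mark = ","),
              format(tt$O_tot, big.mark = ","), tt$D))
  NextMethod()
}

#' Build a spectrum table directly from per-type counts
#'
#' Used when counts come from a source other than variant classification,
#' e.g. closed-form simulation of the count layer.
#'
#' @param S Numeric vector of 96 per-type segregating-site counts, in
#'   catalog order (or named by type).
#' @param opp An `OpportunityTable` or a 96-vector of opportunities.
#' @param compartment Compartment label.
#' @return A `spectrum_table`.
#' @export
spectrum_from_counts <- function(S, opp, compartment = "compartment") {
  catalog <- build_catalog()
  if (!is.null(names(S))) S <- S[catalog$type]
  O <- if (inherits(opp, "OpportunityTable")) opp$types else opp
  if (!is.null(names(O))) O <- O[catalog$type]
  new_spectrum_table(S, O, compartment)
}

#' Tabulate the mutation spectrum of a compartment
#'
#' Classifies the variant stream (unless already classified), restricts it
#' to observations whose focal position lies inside the compartment, applies
#' the frequency filter, and counts segregating sites per type.  Each
#' derived allele of a multiallelic site counts separately.  Variants that
#' fail classification are excluded from the counts but their positions
#' remain in the opportunity totals: opportunities are a property of the
#' sequence alone.
#'
#' @param variants Variant table (see [classify_variants()]), a classified
#'   table (with `type`/`skip` columns), or a VCF path.
#' @param comp A `CompartmentSet`.
#' @param genome A `DNAStringSet` (or FASTA path).
#' @param polarization Polarization rule, see [polarization_mode()].
#' @param filter Optional [frequency_filter()].
#' @param opp Optional precomputed [count_contexts()] table for `comp`;
#'   must match the same compartment and genome.
#' @return A `spectrum_table` with attributes `skips` (skip-reason summary)
#'   and the totals described in [spectrum_totals()].
#' @export
tabulate_spectrum <- function(variants, comp, genome,
                              polarization = "major-allele",
                              filter = NULL, opp = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  cl <- if (is.data.frame(variants) && "type" %in% names(variants)) {
    as.data.table(variants)
  } else {
    classify_variants(variants, genome, polarization)
  }
  if (is.null(opp)) opp <- count_contexts(genome, comp)
  stopifnot(inherits(opp, "OpportunityTable"))
  inside <- compartment_member(comp, cl$chrom, cl$pos)
  keep <- inside & is.na(cl$skip) & apply_frequency_filter(cl, filter)
  catalog <- build_catalog()
  S <- setNames(numeric(96L), catalog$type)
  if (any(keep)) {
    counts <- table(factor(cl$type[keep], levels = catalog$type))
    S[] <- as.numeric(counts)
  }
  out <- new_spectrum_table(S, opp$types,
                            if (inherits(comp, "CompartmentSet"))
                              comp$name else "compartment")
  attr(out, "skips") <- skip_summary(cl[inside])
  out
}

#' Site frequency spectrum of a variant stream
#'
#' Histogram of derived allele counts (1 ... n-1) over all retained
#' variants; multiallelic sites contribute one entry per derived allele.
#'
#' @param variants Variant table or VCF path; if classified, the polarized
#'   `derived_ac` is used, otherwise the raw `ac`.
#' @param filter Optional [frequency_filter()].
#' @return A `data.table` with `allele_count` and `n_variants` (only
#'   observed counts appear; an empty stream yields zero rows), with
#'   attribute `n_chromosomes`.
#' @export
variant_sfs <- function(variants, filter = NULL) {
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_variants(variants)
  }
  v <- as.data.table(variants)
  if (!all(c("ac", "an") %in% names(v))) {
    stop("variant stream lacks allele-count fields (ac/an)")
  }
  count <- if ("derived_ac" %in% names(v)) {
    ifelse(is.na(v$derived_ac), v$ac, v$derived_ac)
  } else {
    v$ac
  }
  keep <- apply_frequency_filter(v, filter)
  if ("skip" %in% names(v)) keep <- keep & is.na(v$skip)
  count <- count[keep]
  if (!length(count)) {
    out <- data.table(allele_count = integer(0), n_variants = integer(0))
  } else {
    tab <- table(count)
    out <- data.table(allele_count = as.integer(names(tab)),
                      n_variants = as.integer(tab))
  }
  setattr(out, "n_chromosomes",
          if (nrow(v)) max(v$an) else NA_integer_)
  out[]
}

#' Singleton and doubleton fractions of an SFS
#' @param sfs Output of [variant_sfs()].
#' @return Named numeric vector with `singleton` and `doubleton` fractions.
#' @export
sfs_fractions <- function(sfs) {
  tot <- sum(sfs$n_variants)
  f <- function(k) {
    i <- match(k, sfs$allele_count)
    if (is.na(i)) 0 else sfs$n_variants[i] / tot
  }
  c(singleton = f(1L), doubleton = f(2L))
}

#' Collapse a 96-type spectrum to the 6 mutation classes
#'
#' Counts and opportunities are summed within each class; totals (and hence
#' total diversity D) are unchanged.
#'
#' @param t A type-level `spectrum_table`.
#' @return A class-level `spectrum_table` (6 rows).
#' @export
collapse_to_classes <- function(t) {
  stopifnot(inherits(t, "spectrum_table"), attr(t, "level") == "type")
  cls <- mutation_classes()
  S <- setNames(as.numeric(rowsum(t$S, t$class)[cls, 1L]), cls)
  O <- setNames(as.numeric(rowsum(t$O, t$class)[cls, 1L]), cls)
  out <- new_spectrum_table(S, O, attr(t, "compartment"), level = "class")
  attr(out, "skips") <- attr(t, "skips")
  out
}

#' Drop mutation types from a spectrum
#'
#' Dropped types are removed from the counts, the opportunities, and the
#' totals defining the overall diversity; remaining relative diversities are
#' recomputed.  Used to exclude the 12 hypermutable CpG types, or any highly
#' mutable set whose weight would distort the normalization of other types.
#'
#' @param t A type-level `spectrum_table`.
#' @param drop Character vector of type labels, or `"cpg"` for the CpG set.
#' @return A `spectrum_table` with `96 - length(drop)` rows.
#' @export
exclude_types <- function(t, drop) {
  stopifnot(inherits(t, "spectrum_table"), attr(t, "level") == "type")
  if (identical(drop, "cpg")) drop <- cpg_types()
  if (!length(drop)) return(t)
  unknown <- setdiff(drop, build_catalog()$type)
  if (length(unknown)) {
    stop("not catalog types: ", paste(unknown, collapse = ", "))
  }
  keep <- !(t$type %in% drop)
  df <- as.data.frame(t)[keep, , drop = FALSE]
  S_tot <- sum(df$S)
  O_tot <- sum(df$O)
  D <- if (O_tot > 0) S_tot / O_tot else NA_real_
  df$d <- ifelse(df$O > 0, df$S / df$O, NA_real_)
  df$r <- if (!is.na(D) && D > 0) df$d / D else NA_real_
  rownames(df) <- NULL
  structure(df, class = c("spectrum_table", "data.frame"),
            compartment = attr(t, "compartment"), level = "type",
            S_tot = S_tot, O_tot = O_tot, D = D,
            skips = attr(t, "skips"))
}

#' Write a spectrum table as TSV
#' @param t A `spectrum_table`.
#' @param path Output file.
#' @param params Extra parameters for the comment block.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(t, path, params = list()) {
  tt <- spectrum_totals(t)
  write_tsv(as.data.frame(t), path,
            params = c(list(compartment = attr(t, "compartment"),
                            level = attr(t, "level"),
                            S_tot = tt$S_tot, O_tot = tt$O_tot, D = tt$D),
                       params))
}
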