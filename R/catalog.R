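#' @title The 96-type mutation catalog
#' @name catalog
#' @description
#' Single-base substitutions are considered in their trinucleotide context
#' (one flanking base on each side) and collapsed with their reverse
#' complement, so that every type is represented with a central pyrimidine
#' (C or T).  This yields 32 canonical contexts and, with 3 alternative
#' alleles each, 96 mutation types grouped into the 6 classes
#' C>A, C>G, C>T, T>A, T>C, T>G.
NULL

#' The six mutation classes, in catalog order
#' @return Character vector of length 6.
#' @export
mutation_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

DNA_BASES <- c("A", "C", "G", "T")

# vectorized complement / reverse complement for plain character k-mers
complement_bases <- function(x) chartr("ACGT", "TGCA", x)

revcomp_kmer <- function(x) {
  n <- nchar(x)
  if (all(n == 3L)) {
    paste0(
      complement_bases(substr(x, 3L, 3L)),
      complement_bases(substr(x, 2L, 2L)),
      complement_bases(substr(x, 1L, 1L))
    )
  } else {
    vapply(strsplit(complement_bases(x), ""), function(ch)
      paste(rev(ch), collapse = ""), character(1))
  }
}

# catalog and lookup tables are built once per session
.catalog_cache <- new.env(parent = emptyenv())

#' Build the ordered catalog of 96 mutation types
#'
#' Types are ordered class-major (C>A, C>G, C>T, T>A, T>C, T>G) and,
#' within each class, by the lexicographic order of the 16 contexts.
#' The order is fixed and identical across runs; all spectrum tables use it.
#'
#' @return A `data.frame` with one row per type and columns `type`
#'   (e.g. `"ACA>AAA"`), `class`, `context` (canonical trinucleotide, central
#'   pyrimidine), `ref` (central base) and `alt`.
#' @examples
#' nrow(build_catalog())  # 96
#' @export
build_catalog <- function() {
  if (!is.null(.catalog_cache$catalog)) return(.catalog_cache$catalog)
  rows <- lapply(mutation_classes(), function(cl) {
    ref <- substr(cl, 1L, 1L)
    alt <- substr(cl, 3L, 3L)
    ctx <- as.vector(t(outer(DNA_BASES, DNA_BASES,
                             function(l, r) paste0(l, ref, r))))
    ctx <- sort(ctx)
    data.frame(
      type    = paste0(ctx, ">", paste0(substr(ctx, 1, 1), alt, substr(ctx, 3, 3))),
      class   = cl,
      context = ctx,
      ref     = ref,
      alt     = alt,
      stringsAsFactors = FALSE
    )
  })
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  .catalog_cache$catalog <- catalog
  catalog
}

#' The 32 canonical trinucleotide contexts, in catalog order
#' @return Character vector of length 32 (16 central-C then 16 central-T
#'   contexts, each lexicographically ordered).
#' @export
canonical_contexts <- function() unique(build_catalog()$context)

# named integer vector mapping all 192 raw "ctx>alt" keys to catalog rows
type_lookup <- function() {
  if (!is.null(.catalog_cache$lookup)) return(.catalog_cache$lookup)
  cat96 <- build_catalog()
  key_canon <- paste0(cat96$context, ">", cat96$alt)
  key_rc    <- paste0(revcomp_kmer(cat96$context), ">",
                      complement_bases(cat96$alt))
  lookup <- setNames(rep(seq_len(96L), 2L), c(key_canon, key_rc))
  .catalog_cache$lookup <- lookup
  lookup
}

# map each of the 64 raw contexts to its canonical (central-pyrimidine) form
context_lookup <- function() {
  if (!is.null(.catalog_cache$ctx_lookup)) return(.catalog_cache$ctx_lookup)
  raw <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES,
    function(lc, r) paste0(substr(lc, 1, 1), substr(lc, 2, 2), r)
  ))
  raw <- sort(unique(raw))
  canon <- ifelse(substr(raw, 2, 2) %in% c("C", "T"), raw, revcomp_kmer(raw))
  .catalog_cache$ctx_lookup <- setNames(canon, raw)
  .catalog_cache$ctx_lookup
}

#' Canonicalize a (context, alt) observation onto the 96-type catalog
#'
#' A substitution observed with a central purine is replaced by its reverse
#' complement, e.g. `CGT` with alt `A` becomes `ACG>ATG`.  Observations
#' already carrying a central pyrimidine are returned unchanged.
#'
#' @param context Character vector of trinucleotides (the central base is the
#'   ancestral allele, flanks come from the reference sequence).
#' @param alt Character vector of derived alleles, recycled against `context`.
#' @return Character vector of catalog type labels (`"ACG>ATG"` style).
#' @examples
#' canonicalize_type("CGT", "A")  # "ACG>ATG"
#' @export
canonicalize_type <- function(context, alt) {
  if (length(alt) == 1L) alt <- rep(alt, length(context))
  stopifnot(length(alt) == length(context))
  ok <- grepl("^[ACGT]{3}$", context) & alt %in% DNA_BASES
  if (!all(ok)) {
    stop("ambiguous base in context or alt: ",
         paste(unique(paste0(context[!ok], ">", alt[!ok])), collapse = ", "))
  }
  if (any(substr(context, 2, 2) == alt)) {
    stop("alt must differ from the central base of the context")
  }
  idx <- type_lookup()[paste0(context, ">", alt)]
  build_catalog()$type[idx]
}

#' Identify CpG mutation types
#'
#' A type is a CpG type when its canonical context has a central C
#' immediately followed by G (contexts ACG, CCG, GCG, TCG), regardless of the
#' alternative allele.  Exactly 12 of the 96 types qualify; they are the ones
#' removed by CpG exclusion in X-autosome and hotspot comparisons.
#'
#' @param type Character vector of catalog type labels (or a catalog
#'   `data.frame`, in which case its `type` column is used).
#' @return Logical vector.
#' @examples
#' is_cpg_type("ACG>ATG")  # TRUE
#' @export
is_cpg_type <- function(type) {
  if (is.data.frame(type)) type <- type$type
  catalog <- build_catalog()
  idx <- match(type, catalog$type)
  if (anyNA(idx)) stop("unknown mutation type: ",
                       paste(type[is.na(idx)], collapse = ", "))
  substr(catalog$context[idx], 2, 3) == "CG"
}

#' The 12 CpG mutation types
#' @return Character vector of type labels.
#' @export
cpg_types <- function() {
  catalog <- build_catalog()
  catalog$type[is_cpg_type(catalog$type)]
}

#' Polarization rule for assigning ancestral and derived alleles
#'
#' Under the `"major-allele"` rule (the default throughout), the major allele
#' at a site is treated as ancestral; sites where the two alleles are at
#' exactly 50% frequency are skipped rather than assigned a direction.  Under
#' `"ancestral-genome"`, the ancestral allele is read from a supplied
#' reconstruction; sites where it matches neither observed allele are
#' skipped.
#'
#' @param mode `"major-allele"` or `"ancestral-genome"`.
#' @param ancestral A `DNAStringSet` (or FASTA path) with the ancestral
#'   sequence; required iff `mode = "ancestral-genome"`.
#' @return A `polarization_mode` object.
#' @export
polarization_mode <- function(mode = c("major-allele", "ancestral-genome"),
                              ancestral = NULL) {
  mode <- match.arg(mode)
  if (mode == "ancestral-genome") {
    if (is.null(ancestral)) {
      stop("ancestral sequence is required for ancestral-genome polarization")
    }
    if (is.character(ancestral)) ancestral <- read_genome(ancestral)
    stopifnot(is(ancestral, "DNAStringSet"))
  } else if (!is.null(ancestral)) {
    stop("ancestral sequence is only used with mode = 'ancestral-genome'")
  }
  structure(list(mode = mode, ancestral = ancestral),
            class = "polarization_mode")
}

as_polarization <- function(pol) {
  if (inherits(pol, "polarization_mode")) return(pol)
  polarization_mode(pol)
}

# extract trinucleotide contexts centred on pos (1-based); "" where no flank
extract_contexts <- function(genome, chrom, pos) {
  out <- character(length(pos))
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  for (ct in unique(chrom)) {
    sel <- which(chrom == ct)
    p <- pos[sel]
    valid <- p > 1L & p < lens[[ct]]
    v <- sel[valid]
    if (length(v)) {
      out[v] <- as.character(Biostrings::extractAt(
        genome[[ct]], IRanges(start = pos[v] - 1L, width = 3L)))
    }
  }
  out
}

#' Classify cohort variants onto the 96-type catalog
#'
#' Each observation (one row per derived allele; multiallelic sites
#' contribute one row per alternative) is polarized, placed in its
#' trinucleotide context taken from the reference sequence, and mapped to a
#' canonical type.  The context always keeps the reference flanking bases;
#' only the central base is replaced by the ancestral allele when that
#' differs from the reference (e.g. when the major allele is the alternative
#' allele).  Observations that cannot be classified are kept with a recorded
#' `skip` reason rather than dropped silently:
#' \describe{
#'   \item{`not_snp`}{ref or alt is not a single A/C/G/T base}
#'   \item{`no_flank`}{position at a contig end, trinucleotide incomplete}
#'   \item{`n_context`}{flanking context contains a non-ACGT symbol}
#'   \item{`ref_mismatch`}{VCF REF disagrees with the reference sequence}
#'   \item{`ambiguous_polarization`}{derived allele at exactly 50% frequency}
#'   \item{`ancestral_mismatch`}{ancestral base matches neither allele}
#' }
#'
#' @param variants A `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `ac` (derived allele count as recorded in the
#'   VCF, i.e. the ALT count), `an` (total sampled chromosomes); or a VCF
#'   path, read via [read_variants()].
#' @param genome A `DNAStringSet` reference (or FASTA path).
#' @param polarization A [polarization_mode()] or its mode string.
#' @return A `data.table`: the input columns plus `type` (catalog label or
#'   `NA`), `derived_ac` (count of the derived allele after polarization) and
#'   `skip` (`NA` or a reason above).
#' @export
classify_variants <- function(variants, genome,
                              polarization = "major-allele") {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_variants(variants)
  }
  pol <- as_polarization(polarization)
  v <- as.data.table(variants)
  req <- c("chrom", "pos", "ref", "alt", "ac", "an")
  if (!all(req %in% names(v))) {
    stop("variants need columns: ", paste(req, collapse = ", "))
  }
  missing_contig <- setdiff(unique(v$chrom), names(genome))
  if (length(missing_contig)) {
    stop("contig(s) absent from reference: ",
         paste(missing_contig, collapse = ", "))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(v$pos < 1L | v$pos > lens[v$chrom])) {
    stop("variant position outside contig bounds")
  }

  n <- nrow(v)
  skip <- rep(NA_character_, n)
  is_snp <- v$ref %in% DNA_BASES & v$alt %in% DNA_BASES
  skip[!is_snp] <- "not_snp"

  ctx <- extract_contexts(genome, v$chrom, v$pos)
  no_flank <- ctx == ""
  skip[is.na(skip) & no_flank] <- "no_flank"
  good_ctx <- grepl("^[ACGT]{3}$", ctx)
  skip[is.na(skip) & !good_ctx] <- "n_context"
  centre <- substr(ctx, 2, 2)
  skip[is.na(skip) & centre != v$ref] <- "ref_mismatch"

  anc <- der <- rep(NA_character_, n)
  der_ac <- rep(NA_integer_, n)
  live <- is.na(skip)
  if (pol$mode == "major-allele") {
    tie <- live & (2L * v$ac == v$an)
    skip[tie] <- "ambiguous_polarization"
    live <- is.na(skip)
    alt_major <- 2L * v$ac > v$an
    anc[live] <- ifelse(alt_major[live], v$alt[live], v$ref[live])
    der[live] <- ifelse(alt_major[live], v$ref[live], v$alt[live])
    der_ac[live] <- ifelse(alt_major[live],
                           v$an[live] - v$ac[live], v$ac[live])
  } else {
    anc_genome <- pol$ancestral
    miss <- setdiff(unique(v$chrom), names(anc_genome))
    if (length(miss)) {
      stop("contig(s) absent from ancestral sequence: ",
           paste(miss, collapse = ", "))
    }
    anc_ctx <- extract_contexts(anc_genome, v$chrom, v$pos)
    anc_base <- ifelse(anc_ctx == "", NA_character_, substr(anc_ctx, 2, 2))
    usable <- live & !is.na(anc_base) &
      (anc_base == v$ref | anc_base == v$alt)
    skip[live & !usable] <- "ancestral_mismatch"
    live <- is.na(skip)
    anc[live] <- anc_base[live]
    der[live] <- ifelse(anc_base[live] == v$ref[live],
                        v$alt[live], v$ref[live])
    der_ac[live] <- ifelse(anc_base[live] == v$ref[live],
                           v$ac[live], v$an[live] - v$ac[live])
  }

  type <- rep(NA_character_, n)
  if (any(live)) {
    ctx_anc <- ctx
    repl <- live & anc != v$ref
    substr(ctx_anc[repl], 2, 2) <- anc[repl]
    type[live] <- canonicalize_type(ctx_anc[live], der[live])
  }
  v[, `:=`(type = type, derived_ac = der_ac, skip = skip)]
  v[]
}

#' Summarize classification skip reasons
#'
#' @param classified Output of [classify_variants()].
#' @return `data.table` of `skip` reason and count.
#' @export
skip_summary <- function(classified) {
  skip <- NULL
  as.data.table(classified)[!is.na(skip), .N, by = skip][order(skip)]
}

#' Write a skip log (contig, position, reason) as TSV
#' @param classified Output of [classify_variants()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_skip_log <- function(classified, path) {
  skip <- chrom <- pos <- NULL
  log <- as.data.table(classified)[!is.na(skip),
                                   list(contig = chrom, position = pos,
                                        reason = skip)]
  fwrite(log, path, sep = "\t")
  invisible(path)
}
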