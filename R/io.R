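#' Read a reference genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions down to the contig identifier.
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#' @param genome A named `DNAStringSet`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path) {
  writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read cohort variants from a VCF
#'
#' Reads a VCF 4.x file with cohort allele-count fields (`AC`, Number=A, and
#' `AN`) and expands every record to one row per alternative allele, the
#' unit at which multiallelic sites are counted (each derived allele treated
#' as a separate biallelic site).
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A `data.table` with columns `chrom`, `pos`, `ref`, `alt`, `ac`,
#'   `an`.
#' @export
read_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  inf <- VariantAnnotation::info(vcf)
  if (!all(c("AC", "AN") %in% colnames(inf))) {
    stop("VCF lacks AC/AN allele-count fields")
  }
  nalt <- S4Vectors::elementNROWS(alt)
  ac <- inf$AC
  if (is.list(ac) || is(ac, "List")) {
    ac_flat <- unlist(ac, use.names = FALSE)
  } else {
    ac_flat <- ac
  }
  if (length(ac_flat) != sum(nalt)) {
    stop("AC field length does not match the number of alternative alleles")
  }
  idx <- rep(seq_along(rr), nalt)
  data.table(
    chrom = as.character(seqnames(rr))[idx],
    pos   = start(rr)[idx],
    ref   = as.character(VariantAnnotation::ref(vcf))[idx],
    alt   = as.character(unlist(alt, use.names = FALSE)),
    ac    = as.integer(ac_flat),
    an    = as.integer(inf$AN)[idx]
  )
}

#' Write cohort variants as a sorted VCF with AC/AN fields
#'
#' Rows sharing a contig and position are emitted as one multiallelic
#' record with comma-separated ALT and AC.  Output is deterministic given
#' the input table.
#'
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt`, `ac`,
#'   `an` (one row per derived allele).
#' @param path Output `.vcf` path.
#' @param contig_lengths Optional named vector (or `DNAStringSet`) used for
#'   `##contig` header lines.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  chrom <- pos <- ref <- alt <- ac <- an <- NULL
  v <- as.data.table(variants)[, list(chrom, pos, ref, alt, ac, an)]
  setorder(v, chrom, pos, alt)
  if (is(contig_lengths, "DNAStringSet")) {
    contig_lengths <- setNames(Biostrings::width(contig_lengths),
                               names(contig_lengths))
  }
  rec <- if (nrow(v) == 0L) {
    v[, list(ref = character(0), alt = character(0), ac = character(0),
             an = integer(0)), by = list(chrom, pos)]
  } else {
    v[, {
      if (length(unique(ref)) != 1L || length(unique(an)) != 1L) {
        stop("co-located alleles must share REF and AN")
      }
      list(ref = ref[1L], alt = paste(alt, collapse = ","),
           ac = paste(ac, collapse = ","), an = an[1L])
    }, by = list(chrom, pos)]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutspectra",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>",
              names(contig_lengths), as.integer(contig_lengths))
    },
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total number of alleles\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAC=%s;AN=%d",
                  rec$chrom, rec$pos, rec$ref, rec$alt, rec$ac, rec$an)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a compartment from a BED file
#'
#' 3-column BED gives plain intervals; 5-column BED (with the score field)
#' gives a scored compartment, the dialect used for hotspot intensities.
#'
#' @param path BED file.
#' @param name Compartment label (defaults to the file stem).
#' @return A `CompartmentSet`.
#' @export
read_bed_compartment <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  compartment_set(name %||% sub("\\.bed(\\.gz)?$", "", basename(path)), gr)
}

#' Read a continuous scored track from a bedGraph file
#' @param path bedGraph file (4 columns).
#' @return A `GRanges` with a `score` metadata column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a compartment (or scored track) to BED / bedGraph
#' @param comp A `CompartmentSet`.
#' @param path Output path; format chosen by extension (`.bed` or
#'   `.bedgraph`).
#' @return The path, invisibly.
#' @export
write_compartment <- function(comp, path) {
  gr <- as_granges(comp)
  fmt <- if (grepl("\\.bedgraph$", tolower(path))) "bedGraph" else "BED"
  rtracklayer::export(gr, path, format = fmt)
  invisible(path)
}

#' Write a table as TSV with a parameter comment block
#'
#' All tabular outputs use this format: `#`-prefixed lines recording the
#' parameters of the run, then a header line and tab-separated values.
#'
#' @param x A `data.frame`.
#' @param path Output file.
#' @param params Named list echoed into the comment block.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = ","), character(1))),
               con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    body <- do.call(paste, c(lapply(x, function(col) {
      if (is.numeric(col) && !is.integer(col)) {
        formatC(col, digits = 15, format = "g")
      } else {
        as.character(col)
      }
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return A `data.table` (comment block skipped).
#' @export
read_tsv <- function(path) {
  fread(path, sep = "\t", skip = max(0L, length(grep(
    "^#", readLines(path, n = 100L)))))
}
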