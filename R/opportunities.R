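#' Count mutational opportunities per canonical context
#'
#' A mutational opportunity for a type is a site at which a single base
#' change could have produced that type: every position inside the
#' compartment whose full trinucleotide (position +/- 1) is N-free
#' contributes one opportunity to its canonical context, and hence to each
#' of the context's three types.  Positions lacking a complete flank (contig
#' ends) contribute nothing.  Counts depend only on sequence composition,
#' never on observed variants; this is what makes the normalized spectrum
#' comparable between compartments of different base composition.
#'
#' @param genome A `DNAStringSet` (or FASTA path).
#' @param comp A `CompartmentSet` (or `GRanges`); intervals are merged
#'   before counting so each position is counted once.
#' @return An `OpportunityTable`: list with `compartment` (name), `contexts`
#'   (named count vector over the 32 canonical contexts) and `types` (named
#'   vector over the 96 types; each context count serves its 3 alts).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' count_contexts(g, compartment_set("all", data.frame(
#'   chrom = "chr1", start = 1, end = 4)))$contexts[["ACG"]]  # 2
#' @export
count_contexts <- function(genome, comp) {
  if (is.character(genome)) genome <- read_genome(genome)
  gr <- reduce(as_granges(comp))
  bad <- setdiff(unique(as.character(seqnames(gr))), names(genome))
  if (length(bad)) {
    stop("contig(s) absent from reference: ", paste(bad, collapse = ", "))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  raw <- integer(64L)
  names(raw) <- names(context_lookup())
  if (length(gr)) {
    if (any(end(gr) > lens[as.character(seqnames(gr))])) {
      stop("compartment extends past contig end")
    }
    for (i in seq_along(gr)) {
      ct <- as.character(seqnames(gr)[i])
      s <- max(1L, start(gr)[i] - 1L)
      e <- min(lens[[ct]], end(gr)[i] + 1L)
      if (e - s + 1L < 3L) next
      f <- oligonucleotideFrequency(subseq(genome[[ct]], s, e), width = 3L)
      raw <- raw + f[names(raw)]
    }
  }
  canon <- context_lookup()
  contexts <- setNames(numeric(32L), canonical_contexts())
  agg <- rowsum(as.numeric(raw), canon[names(raw)])
  contexts[rownames(agg)] <- agg[, 1L]
  catalog <- build_catalog()
  types <- setNames(contexts[catalog$context], catalog$type)
  structure(list(compartment = if (inherits(comp, "CompartmentSet"))
                   comp$name else "compartment",
                 contexts = contexts, types = types),
            class = "OpportunityTable")
}

#' @export
print.OpportunityTable <- function(x, ...) {
  cat(sprintf("OpportunityTable for '%s': %s context sites (%s type opportunities)\n",
              x$compartment,
              format(sum(x$contexts), big.mark = ","),
              format(sum(x$types), big.mark = ",")))
  invisible(x)
}

#' Add two opportunity tables (disjoint compartments)
#' @param a,b `OpportunityTable`s.
#' @param name Name for the combined table.
#' @return An `OpportunityTable`.
#' @export
opportunity_add <- function(a, b, name = paste0(a$compartment, "+", b$compartment)) {
  structure(list(compartment = name,
                 contexts = a$contexts + b$contexts,
                 types = a$types + b$types),
            class = "OpportunityTable")
}
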