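# shared fixtures: everything is generated in code, no stored data

tiny_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

whole_compartment <- function(genome, name = "all") {
  compartment_set(name, genome_extent(genome))
}

random_genome_chars <- function(n, seed, with_n = FALSE) {
  withr::with_seed(seed, {
    letters <- c("A", "C", "G", "T", if (with_n) "N")
    prob <- if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
    paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
  })
}

# independent oracle: per-position scan counting canonical contexts
naive_context_counts <- function(seq_str, starts, ends) {
  counts <- setNames(numeric(32L), canonical_contexts())
  L <- nchar(seq_str)
  seen <- logical(L)
  for (k in seq_along(starts)) {
    for (p in seq(max(2L, starts[k]), min(L - 1L, ends[k]))) {
      if (seen[p]) next
      seen[p] <- TRUE
      tri <- substr(seq_str, p - 1L, p + 1L)
      if (grepl("[^ACGT]", tri)) next
      centre <- substr(tri, 2L, 2L)
      canon <- if (centre %in% c("C", "T")) tri else {
        paste0(
          chartr("ACGT", "TGCA", substr(tri, 3, 3)),
          chartr("ACGT", "TGCA", substr(tri, 2, 2)),
          chartr("ACGT", "TGCA", substr(tri, 1, 1))
        )
      }
      counts[canon] <- counts[canon] + 1
    }
  }
  counts
}

# reverse-complement an entire dataset: genome, compartment, and variants
revcomp_dataset <- function(genome, variants, comp = NULL) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  rc_genome <- Biostrings::reverseComplement(genome)
  names(rc_genome) <- names(genome)
  v <- data.table::as.data.table(variants)
  v$pos <- lens[v$chrom] - v$pos + 1L
  v$ref <- chartr("ACGT", "TGCA", v$ref)
  v$alt <- chartr("ACGT", "TGCA", v$alt)
  out <- list(genome = rc_genome, variants = v)
  if (!is.null(comp)) {
    gr <- as_granges(comp)
    ct <- as.character(GenomeInfoDb::seqnames(gr))
    new_start <- lens[ct] - GenomicRanges::end(gr) + 1L
    new_end <- lens[ct] - GenomicRanges::start(gr) + 1L
    out$comp <- compartment_set(comp$name, data.frame(
      chrom = ct, start = new_start, end = new_end))
  }
  out
}

# small cohort simulated on a fresh random genome; used by several files
quick_cohort <- function(seed, rate = 0.005, length = 2e5,
                         multipliers = NULL, n_individuals = 6930L) {
  g <- simulate_genome(length, seed = seed)
  comp <- whole_compartment(g)
  truth <- simulation_truth(uniform_rate_vector(rate),
                            multipliers = multipliers,
                            n_individuals = n_individuals, seed = seed)
  sim <- simulate_variants(g, comp, truth)
  list(genome = g, comp = comp, truth = truth, sim = sim)
}
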