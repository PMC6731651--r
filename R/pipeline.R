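#' Configuration for a preset pipeline run
#'
#' Bundles every tunable of an end-to-end run: the preset comparison to
#' perform, simulation scale, planted effects, filters, significance
#' settings, and the seed.  The full configuration is echoed into the run
#' manifest so each output is regenerable from the manifest alone.
#'
#' @param preset One of `"null-selftest"` (one rate vector, compare two
#'   halves of a contig), `"late-vs-early"` (planted C>A multiplier in the
#'   late-replicating compartment), `"hotspot-bins"` (monotone C>G
#'   multipliers across hotspot intensity tiers), `"matched-timing"`
#'   (covariate-driven rates with a covariate-shifted test contig,
#'   compared with and without matching).
#' @param outdir Output directory.
#' @param seed Seed for every random stage.
#' @param genome_length Contig length (bp).
#' @param mean_rate Mean per-opportunity per-type rate.
#' @param n_individuals Cohort size (diploid); the default 6,930 matches
#'   the female cohort whose 13,860 chromosomes set the SFS denominator.
#' @param window_width Covariate window width (bp).
#' @param effect Planted effect size (preset-specific: C>A multiplier for
#'   `late-vs-early`, per-tier C>G step for `hotspot-bins`, covariate slope
#'   for `matched-timing`).
#' @param alpha Family-wise significance level.
#' @param max_freq Optional derived-allele-frequency cutoff.
#' @param drop_cpg Exclude the 12 CpG types from comparisons.
#' @param convention Two-tailed p-value convention.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("null-selftest", "late-vs-early",
                                       "hotspot-bins", "matched-timing"),
                            outdir, seed = 1L, genome_length = 1e6,
                            mean_rate = 0.01, n_individuals = 6930L,
                            window_width = 5e4, effect = 1.2,
                            alpha = 0.05, max_freq = NULL,
                            drop_cpg = FALSE, convention = "minlik") {
  preset <- match.arg(preset)
  cfg <- list(preset = preset, outdir = outdir, seed = as.integer(seed),
              genome_length = genome_length, mean_rate = mean_rate,
              n_individuals = as.integer(n_individuals),
              window_width = window_width, effect = effect, alpha = alpha,
              max_freq = max_freq, drop_cpg = drop_cpg,
              convention = convention)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  if (!is.numeric(cfg$genome_length) || cfg$genome_length < 2e5) {
    problems <- c(problems, "genome_length must be >= 200 kb")
  }
  if (cfg$mean_rate <= 0 || cfg$mean_rate > 0.1) {
    problems <- c(problems, "mean_rate must be in (0, 0.1]")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "alpha must be in (0, 1)")
  }
  if (!is.null(cfg$max_freq) && (cfg$max_freq <= 0 || cfg$max_freq > 1)) {
    problems <- c(problems, "max_freq must be in (0, 1]")
  }
  if (cfg$effect <= 0) problems <- c(problems, "effect must be positive")
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(cfg)
}

#' Run an end-to-end preset pipeline
#'
#' Simulates genome, compartments and cohort according to the preset,
#' writes the inputs (FASTA, VCF, BED/bedGraph), runs the spectrum and
#' enrichment stages, and writes all result tables plus a JSON manifest
#' (configuration echo, package version, input checksums).  Reruns with
#' the same configuration produce byte-identical bundles.
#'
#' @param config A [pipeline_config()]; alternatively pass the preset name
#'   and fields as `...` for convenience.
#' @param ... Fields forwarded to [pipeline_config()] when `config` is a
#'   preset name.
#' @return Invisibly, a result bundle: `config`, `cohort`, `spectra`,
#'   `result` (the preset's main `enrichment_result` or comparison
#'   object), `sfs`, `files`.
#' @export
run_pipeline <- function(config, ...) {
  if (is.character(config)) config <- pipeline_config(config, ...)
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  filt <- if (!is.null(cfg$max_freq)) frequency_filter(max_freq = cfg$max_freq)
  drop <- if (cfg$drop_cpg) "cpg"
  paths <- list()
  tsv_params <- list(preset = cfg$preset, seed = cfg$seed,
                     alpha = cfg$alpha, convention = cfg$convention)

  n_contigs <- if (cfg$preset == "matched-timing") 2L else 1L
  genome <- simulate_genome(cfg$genome_length, gc = 0.41,
                            n_contigs = n_contigs, seed = cfg$seed)
  paths$genome <- file.path(cfg$outdir, "genome.fa")
  write_genome(genome, paths$genome)

  setup <- switch(
    cfg$preset,
    "null-selftest" = {
      sc <- simulate_compartments(genome, window_width = cfg$window_width,
                                  dir = cfg$outdir)
      list(compartments = sc$halves, test = "left", ref = "right",
           truth = simulation_truth(
             base_rate = uniform_rate_vector(cfg$mean_rate),
             n_individuals = cfg$n_individuals, seed = cfg$seed))
    },
    "late-vs-early" = {
      sc <- simulate_compartments(genome, window_width = cfg$window_width,
                                  dir = cfg$outdir)
      list(compartments = list(late = sc$late, early = sc$early),
           test = "late", ref = "early",
           truth = simulation_truth(
             base_rate = default_rate_vector(cfg$mean_rate),
             multipliers = list(late = c("C>A" = cfg$effect)),
             n_individuals = cfg$n_individuals, seed = cfg$seed),
           scored = sc$covariate)
    },
    "hotspot-bins" = {
      sc <- simulate_compartments(genome, window_width = cfg$window_width,
                                  dir = cfg$outdir)
      tiers <- bin_by_score(sc$hotspots, edges = seq_len(3) + 0.5,
                            mode = "breaks",
                            names = paste0("tier", 1:4))
      mult <- setNames(lapply(0:3, function(i)
        c("C>G" = 1 + (cfg$effect - 1) * i)), paste0("tier", 1:4))
      comps <- c(tiers, list(reference = sc$hotspot_reference))
      list(compartments = comps, test = NULL, ref = "reference",
           truth = simulation_truth(
             base_rate = default_rate_vector(cfg$mean_rate),
             multipliers = mult,
             n_individuals = cfg$n_individuals, seed = cfg$seed),
           scored = sc$hotspots)
    },
    "matched-timing" = {
      # class rates depend only on the covariate; the test contig's
      # covariate is shifted upward relative to the reference contig
      # linear-ramp covariates: reference contig spans [-1, 1], test contig
      # only [0, 0.7], so the test is covariate-shifted but its support is
      # nested inside the reference pool's with uniform window density
      cov <- covariate_windows(genome, cfg$window_width,
                               fun = function(mid, len) 2 * mid / len - 1)
      gr <- as_granges(cov)
      shift <- as.character(seqnames(gr)) == names(genome)[1L]
      x <- ifelse(shift, 0.35 + 0.35 * mcols(gr)$score, mcols(gr)$score)
      cov <- compartment_set("covariate", granges(gr), score = x)
      wins <- lapply(seq_along(gr), function(i)
        compartment_set(paste0("w", i), granges(gr[i])))
      names(wins) <- paste0("w", seq_along(gr))
      beta <- cfg$effect
      mult <- setNames(lapply(seq_along(gr), function(i)
        c("C>A" = 1 + beta * (x[i] + 1.0))), names(wins))
      list(compartments = wins, test = NULL, ref = NULL,
           truth = simulation_truth(
             base_rate = default_rate_vector(cfg$mean_rate),
             multipliers = mult,
             n_individuals = cfg$n_individuals, seed = cfg$seed),
           scored = cov,
           test_comp = compartment_set("chr1-test",
                                       genome_extent(genome)[1L]),
           ref_comp = compartment_set("chr2-ref",
                                      genome_extent(genome)[2L]))
    })

  sites <- sites_by_compartment(genome, setup$compartments)
  cohort <- simulate_variants(genome, setup$compartments, setup$truth,
                              sites = sites, seed = cfg$seed)
  paths$vcf <- file.path(cfg$outdir, "cohort.vcf")
  write_vcf(cohort$variants, paths$vcf, contig_lengths = genome)
  fwrite(cohort$expected, file.path(cfg$outdir, "truth_manifest.tsv"),
         sep = "\t")

  classified <- classify_variants(read_variants(paths$vcf), genome)
  write_skip_log(classified, file.path(cfg$outdir, "skip_log.tsv"))
  sfs <- variant_sfs(classified, filter = filt)
  write_tsv(sfs, file.path(cfg$outdir, "sfs.tsv"), params = tsv_params)

  spectra <- list()
  result <- NULL
  if (cfg$preset %in% c("null-selftest", "late-vs-early")) {
    test_c <- setup$compartments[[setup$test]]
    ref_c <- setup$compartments[[setup$ref]]
    st <- tabulate_spectrum(classified, test_c, genome, filter = filt)
    sr <- tabulate_spectrum(classified, ref_c, genome, filter = filt)
    if (!is.null(drop)) {
      st <- exclude_types(st, drop); sr <- exclude_types(sr, drop)
    }
    spectra <- list(test = st, ref = sr)
    result <- enrichment_test(st, sr, alpha = cfg$alpha,
                              convention = cfg$convention)
    write_enrichment(result,
                     file.path(cfg$outdir, "enrichment.tsv"), tsv_params)
  } else if (cfg$preset == "hotspot-bins") {
    result <- scored_bin_enrichment(
      classified, genome, scored = setup$scored,
      reference = setup$compartments$reference,
      edges = seq_len(3) + 0.5, mode = "breaks",
      collapse = TRUE, drop = drop, alpha = cfg$alpha,
      convention = cfg$convention, filter = filt)
    write_tsv(bin_class_summary(result, "C>G"),
              file.path(cfg$outdir, "hotspot_bins_CG.tsv"), tsv_params)
  } else if (cfg$preset == "matched-timing") {
    unmatched_test <- tabulate_spectrum(classified, setup$test_comp, genome,
                                        filter = filt)
    unmatched_ref <- tabulate_spectrum(classified, setup$ref_comp, genome,
                                       filter = filt)
    spectra <- list(test = unmatched_test, ref = unmatched_ref)
    unmatched <- enrichment_test(collapse_to_classes(unmatched_test),
                                 collapse_to_classes(unmatched_ref),
                                 alpha = cfg$alpha,
                                 convention = cfg$convention)
    matched <- matched_comparison(classified, genome, setup$test_comp,
                                  setup$ref_comp, setup$scored,
                                  window_width = cfg$window_width,
                                  n_bins = 5, seed = cfg$seed,
                                  collapse = TRUE, drop = drop,
                                  alpha = cfg$alpha,
                                  convention = cfg$convention,
                                  filter = filt)
    result <- list(unmatched = unmatched, matched = matched)
    write_enrichment(unmatched,
                     file.path(cfg$outdir, "unmatched_enrichment.tsv"),
                     tsv_params)
    write_enrichment(matched$result,
                     file.path(cfg$outdir, "matched_enrichment.tsv"),
                     tsv_params)
  }
  for (nm in names(spectra)) {
    write_spectrum(spectra[[nm]],
                   file.path(cfg$outdir, paste0("spectrum_", nm, ".tsv")),
                   tsv_params)
  }

  manifest <- list(
    package = "mutspectra",
    version = as.character(packageVersion("mutspectra")),
    config = unclass(cfg),
    inputs = setNames(as.list(md5sum(unlist(paths))),
                      basename(unlist(paths))),
    n_variant_observations = nrow(cohort$variants)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = cfg, cohort = cohort, spectra = spectra,
                 result = result, sfs = sfs, files = paths))
}
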