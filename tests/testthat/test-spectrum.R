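# a 22-bp genome and a hand-written 10-record VCF (one triallelic site)
# whose classification is worked out by hand in the comments
spectrum_fixture <- function() {
  #        1234567890123456789012 (pos 21 ensures a GAA/TTC opportunity)
  g <- tiny_genome(chr1 = "TACGTGCATTGCAACGTTGAAC")
  vcf <- withr::local_tempfile(fileext = ".vcf",
                               .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=22>",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1\t.\tT\tA\t.\t.\tAC=1;AN=1000",    # no left flank -> skip
    "chr1\t3\t.\tC\tT,G\t.\t.\tAC=1,2;AN=1000", # ACG>ATG and ACG>AGG
    "chr1\t5\t.\tT\tG\t.\t.\tAC=4;AN=1000",    # GTG>GGG
    "chr1\t7\t.\tC\tA\t.\t.\tAC=3;AN=1000",    # GCA>GAA
    "chr1\t10\t.\tT\tC\t.\t.\tAC=1;AN=1000",   # TTG>TCG
    "chr1\t12\t.\tC\tA\t.\t.\tAC=998;AN=1000", # alt-major: TTC>TGC, derived 2
    "chr1\t15\t.\tC\tT\t.\t.\tAC=500;AN=1000", # 50% tie -> skip
    "chr1\t17\t.\tT\tA\t.\t.\tAC=9;AN=1000",   # GTT>GAT
    "chr1\t19\t.\tG\tA\t.\t.\tAC=1;AN=1000",   # TGA,A -> TCA>TTA
    "chr1\t22\t.\tC\tA\t.\t.\tAC=1;AN=1000"    # no right flank -> skip
  ), vcf)
  list(genome = g, vcf = vcf)
}

test_that("hand-classified VCF tabulates exactly, with the triallelic site counted twice", {
  fx <- spectrum_fixture()
  v <- read_variants(fx$vcf)
  expect_equal(nrow(v), 11L)  # 10 records, one with two alts
  comp <- whole_compartment(fx$genome)
  spec <- tabulate_spectrum(v, comp, fx$genome)
  expected <- c("ACG>ATG" = 1, "ACG>AGG" = 1, "GTG>GGG" = 1,
                "GCA>GAA" = 1, "TTG>TCG" = 1, "TTC>TGC" = 1,
                "GTT>GAT" = 1, "TCA>TTA" = 1)
  got <- setNames(spec$S, spec$type)
  expect_equal(got[names(expected)], expected)
  expect_equal(sum(spec$S), 8)
  skips <- attr(spec, "skips")
  expect_equal(sum(skips$N), 3L)
  expect_setequal(skips$skip, c("no_flank", "ambiguous_polarization"))
  # the two derived alleles at position 3 landed on the same context
  expect_equal(sum(spec$S[spec$context == "ACG"]), 2)
})

test_that("zero variants give an all-zero table with flagged relative diversities", {
  g <- tiny_genome(chr1 = strrep("ACGT", 50))
  spec <- tabulate_spectrum(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), ac = integer(0), an = integer(0)),
    whole_compartment(g), g)
  expect_true(all(spec$S == 0))
  expect_equal(spectrum_totals(spec)$D, 0)
  expect_true(all(is.na(spec$r)))
})

test_that("frequency filters agree with an independent count of the stream", {
  fx <- spectrum_fixture()
  v <- read_variants(fx$vcf)
  cl <- classify_variants(v, fx$genome)
  keep <- frequency_filter(max_count = 2L)
  spec <- tabulate_spectrum(cl, whole_compartment(fx$genome), fx$genome,
                            filter = keep)
  # oracle: classified observations with polarized derived count <= 2
  oracle <- sum(!is.na(cl$type) & cl$derived_ac <= 2L)
  expect_equal(sum(spec$S), oracle)
  expect_equal(sum(spec$S), 5)
  # max_freq bound is exclusive: derived_ac/an < 0.004 keeps counts 1-3
  spec2 <- tabulate_spectrum(cl, whole_compartment(fx$genome), fx$genome,
                             filter = frequency_filter(max_freq = 0.004))
  expect_equal(sum(spec2$S),
               sum(!is.na(cl$type) & cl$derived_ac / cl$an < 0.004))
  expect_error(frequency_filter(min_count = 5, max_count = 2))
})

test_that("site frequency spectrum histogram and fractions", {
  fx <- spectrum_fixture()
  cl <- classify_variants(read_variants(fx$vcf), fx$genome)
  sfs <- variant_sfs(cl)
  # derived counts of the 8 classified observations: 1,2,4,3,1,2,9,1
  expect_equal(sfs$n_variants[match(c(1L, 2L, 3L, 4L, 9L),
                                    sfs$allele_count)],
               c(3L, 2L, 1L, 1L, 1L))
  fr <- sfs_fractions(sfs)
  expect_equal(unname(fr["singleton"]), 3 / 8)
  expect_equal(unname(fr["doubleton"]), 2 / 8)
  # trivial cases
  tiny <- variant_sfs(data.frame(ac = c(1L, 1L, 2L), an = 10L))
  expect_equal(as.data.frame(tiny),
               data.frame(allele_count = c(1L, 2L), n_variants = c(2L, 1L)),
               ignore_attr = TRUE)
  empty <- variant_sfs(data.frame(ac = integer(0), an = integer(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(variant_sfs(data.frame(x = 1)), "allele-count")
})

test_that("normalization identity holds on every emitted table", {
  # sum_i r_i * (O_i / O_tot) == 1 whenever S_tot > 0
  for (seed in c(11L, 12L, 13L)) {
    fx <- quick_cohort(seed = seed, rate = 0.004, length = 5e4)
    spec <- tabulate_spectrum(fx$sim$variants, fx$comp, fx$genome)
    tt <- spectrum_totals(spec)
    expect_equal(sum(spec$r * spec$O / tt$O_tot), 1, tolerance = 1e-12)
    cls <- collapse_to_classes(spec)
    expect_equal(sum(cls$r * cls$O / attr(cls, "O_tot")), 1,
                 tolerance = 1e-12)
    noCpG <- exclude_types(spec, "cpg")
    expect_equal(sum(noCpG$r * noCpG$O / attr(noCpG, "O_tot")), 1,
                 tolerance = 1e-12)
  }
})

test_that("relative diversities are invariant to rescaling all opportunities", {
  withr::with_seed(21, {
    S <- rpois(96L, 40)
    O <- sample(5000:20000, 96L, TRUE)
    a <- spectrum_from_counts(S, O, "a")
    b <- spectrum_from_counts(S, O * 3, "b")
    expect_equal(a$r, b$r, tolerance = 1e-12)
  })
})

test_that("tabulation is order-independent", {
  fx <- quick_cohort(seed = 31, rate = 0.004, length = 5e4)
  v <- fx$sim$variants
  shuffled <- v[withr::with_seed(32, sample(nrow(v))), ]
  s1 <- tabulate_spectrum(v, fx$comp, fx$genome)
  s2 <- tabulate_spectrum(shuffled, fx$comp, fx$genome)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("class collapse conserves totals and matches direct recomputation", {
  withr::with_seed(41, {
    S <- rpois(96L, 25)
    O <- sample(2000:9000, 96L, TRUE)
    spec <- spectrum_from_counts(S, O, "x")
    cls <- collapse_to_classes(spec)
    expect_equal(sum(cls$S), sum(spec$S))
    expect_equal(sum(cls$O), sum(spec$O))
    expect_equal(attr(cls, "D"), attr(spec, "D"))
    # recomputation oracle from the raw counts
    catalog <- build_catalog()
    for (cl_name in mutation_classes()) {
      i <- catalog$class == cl_name
      expect_equal(cls$S[cls$type == cl_name], sum(S[i]))
      expect_equal(cls$d[cls$type == cl_name], sum(S[i]) / sum(O[i]))
    }
    # all counts concentrated in one class
    S1 <- ifelse(catalog$class == "C>T", S, 0)
    one <- collapse_to_classes(spectrum_from_counts(S1, O, "y"))
    expect_equal(one$S[one$type == "C>T"], sum(S1))
    expect_equal(sum(one$S[one$type != "C>T"]), 0)
  })
})

test_that("excluding the CpG set recomputes totals over the remaining 84 types", {
  fx <- quick_cohort(seed = 51, rate = 0.004, length = 5e4)
  spec <- tabulate_spectrum(fx$sim$variants, fx$comp, fx$genome)
  noCpG <- exclude_types(spec, "cpg")
  expect_equal(nrow(noCpG), 84L)
  keep <- !(spec$type %in% cpg_types())
  # recomputation oracle: totals and relative diversities over kept types
  expect_equal(attr(noCpG, "S_tot"), sum(spec$S[keep]))
  expect_equal(attr(noCpG, "O_tot"), sum(spec$O[keep]))
  D84 <- sum(spec$S[keep]) / sum(spec$O[keep])
  expect_equal(noCpG$r, (spec$S[keep] / spec$O[keep]) / D84,
               tolerance = 1e-12)
  # dropping nothing is the identity
  expect_identical(as.data.frame(exclude_types(spec, character(0))),
                   as.data.frame(spec))
  expect_error(exclude_types(spec, "XXX>YYY"), "not catalog types")
})

test_that("spectrum tables reverse-complement bit-identically", {
  fx <- quick_cohort(seed = 61, rate = 0.004, length = 4e4)
  spec <- tabulate_spectrum(fx$sim$variants, fx$comp, fx$genome)
  rc <- revcomp_dataset(fx$genome, fx$sim$variants, fx$comp)
  spec_rc <- tabulate_spectrum(rc$variants, rc$comp, rc$genome)
  expect_identical(spec$S, spec_rc$S)
  expect_identical(spec$O, spec_rc$O)
  expect_identical(spec$d, spec_rc$d)
  expect_identical(spec$r, spec_rc$r)
})

test_that("spectrum TSV round-trips through the comment-block format", {
  dir <- withr::local_tempdir()
  fx <- quick_cohort(seed = 71, rate = 0.004, length = 3e4)
  spec <- tabulate_spectrum(fx$sim$variants, fx$comp, fx$genome)
  p <- file.path(dir, "spec.tsv")
  write_spectrum(spec, p, params = list(seed = 71))
  back <- read_tsv(p)
  expect_equal(back$S, spec$S)
  expect_equal(back$d, spec$d, tolerance = 1e-12)
  expect_true(any(grepl("^# compartment", readLines(p))))
})
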