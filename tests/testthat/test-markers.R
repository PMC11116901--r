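marker_fixture <- function(seed = 90, del_a = 0L) {
  g <- small_genome(seed = seed)
  res <- apply_reciprocal_translocation(g, small_exchange(del_a = del_a),
                                        "mk")
  calls <- small_comparison(res)
  list(res = res, calls = calls)
}

test_that("designed pairs are codominant: each amplifies only its template", {
  fx <- marker_fixture()
  ms <- design_breakpoint_markers(fx$res$wt, fx$res$mt, fx$calls[1, ],
                                  name = "T23")
  for (p in c(ms$wt_pair, ms$mt_pair)) {
    expect_equal(nchar(p$seq), 20L)
    expect_gte(p$gc, 0.40); expect_lte(p$gc, 0.60)
    expect_gte(p$tm, 55); expect_lte(p$tm, 65)
  }
  wt_on_wt <- insilico_pcr(fx$res$wt, ms$wt_pair)
  wt_on_mt <- insilico_pcr(fx$res$mt, ms$wt_pair)
  mt_on_wt <- insilico_pcr(fx$res$wt, ms$mt_pair)
  mt_on_mt <- insilico_pcr(fx$res$mt, ms$mt_pair)
  expect_equal(nrow(wt_on_wt), 1L); expect_equal(nrow(wt_on_mt), 0L)
  expect_equal(nrow(mt_on_wt), 0L); expect_equal(nrow(mt_on_mt), 1L)
  expect_equal(wt_on_wt$length, ms$expected$wt)
  expect_equal(mt_on_mt$length, ms$expected$mt)
  expect_gte(abs(ms$expected$wt - ms$expected$mt), 100L)
  # heterozygote template yields both amplicons
  het <- insilico_pcr(list(fx$res$wt, fx$res$mt), ms$wt_pair)
  het2 <- insilico_pcr(list(fx$res$wt, fx$res$mt), ms$mt_pair)
  expect_equal(nrow(het), 1L); expect_equal(nrow(het2), 1L)
})

test_that("specificity holds across random design instances", {
  g <- small_genome(seed = 91)
  for (seed in 1:5) {
    sp <- random_reciprocal_event(g, seed = 300 + seed, deletions = 0:10,
                                  margin = 3000L)
    res <- apply_reciprocal_translocation(g, sp, "spec")
    calls <- small_comparison(res)
    ms <- design_breakpoint_markers(res$wt, res$mt, calls[1, ])
    expect_equal(nrow(insilico_pcr(res$mt, ms$wt_pair)), 0L)
    expect_equal(nrow(insilico_pcr(res$wt, ms$mt_pair)), 0L)
  }
})

test_that("infeasible junction geometry is reported as a design failure", {
  fx <- marker_fixture(seed = 92)
  bp <- fx$calls[1, ]
  bp$mt_junction <- 100L   # 100 bp from the chromosome start
  expect_error(design_breakpoint_markers(fx$res$wt, fx$res$mt, bp),
               class = "tl_design_error")
  raw <- fx$calls[1, ]; raw$mt_junction <- NA_integer_
  expect_error(design_breakpoint_markers(fx$res$wt, fx$res$mt, raw),
               class = "tl_design_error")
})

test_that("in-silico PCR matches a brute-force scan and deduplicates", {
  g <- small_genome(seed = 93)
  tmpl <- substr(g$seq[[1]], 1, 1000)
  f <- substr(tmpl, 101, 120)
  r_site <- substr(tmpl, 581, 600)
  r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r_site)))
  toy <- tl_genome(c(T1 = tmpl))
  got <- insilico_pcr(toy, c(f, r), max_product = 1000L)
  oracle <- brute_pcr(tmpl, f, r, max_product = 1000L)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, sort(oracle$start))
  expect_equal(got$length, 500L)
  # identical F and R with two convergent sites: products deduplicated
  got2 <- insilico_pcr(toy, c(f, f), max_product = 1000L)
  oracle2 <- brute_pcr(tmpl, f, f, max_product = 1000L)
  expect_equal(nrow(got2), nrow(unique(oracle2)))
  # a single mismatch abolishes the product (exact-match model)
  f_mm <- paste0(substr(f, 1, 10),
                 chartr("ACGT", "CAGT", substr(f, 11, 11)),
                 substr(f, 12, 20))
  expect_equal(nrow(insilico_pcr(toy, c(f_mm, r))), 0L)
})

test_that("population genotyping partitions individuals into three classes", {
  fx <- marker_fixture(seed = 94)
  ms1 <- design_breakpoint_markers(fx$res$wt, fx$res$mt, fx$calls[1, ],
                                   name = "J1")
  ms2 <- design_breakpoint_markers(fx$res$wt, fx$res$mt, fx$calls[2, ],
                                   name = "J2")
  f1 <- karyotype_config(4, translocation_locus("T23", "reciprocal",
                                                c("Chr2", "Chr3"), "het"))
  pop <- simulate_cross(f1, f1, 237, seed = 11)
  gt <- genotype_population(pop, list(ms1, ms2), fx$res$wt, fx$res$mt,
                            event_columns = "T23")
  expect_equal(unique(gt$counts$n), 237L)
  expect_equal(gt$counts$homozygous_WT + gt$counts$heterozygous_TL +
               gt$counts$homozygous_TL, c(237L, 237L))
  # both markers of the event agree on every individual
  expect_length(gt$excluded, 0L)
  # the amplicon-pattern -> class map is a bijection on the three classes
  pats <- unique(gt$calls[, c("wt_amplicon", "mt_amplicon", "call")])
  expect_lte(nrow(pats), 3L)
  expect_equal(nrow(unique(pats[, c("wt_amplicon", "mt_amplicon")])),
               nrow(pats))
  # truth-genotype input maps NN to homozygous wild type
  one <- pop[1, ]; one$T23 <- "NN"
  g1 <- genotype_population(one, list(ms1), fx$res$wt, fx$res$mt, "T23")
  expect_equal(g1$calls$call, "homozygous_WT")
})

test_that("primer panel export has one row per primer", {
  fx <- marker_fixture(seed = 95)
  ms <- design_breakpoint_markers(fx$res$wt, fx$res$mt, fx$calls[1, ])
  f <- tempfile(fileext = ".tsv")
  write_primer_panel(ms, f)
  panel <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(panel), 4L)
  expect_true(all(c("seq", "chrom", "pos", "strand", "tm", "gc")
                  %in% names(panel)))
})
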