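test_that("length is conserved up to designed edits", {
  g <- small_genome()
  # blunt exchange, no edits
  r0 <- apply_reciprocal_translocation(g, small_exchange(), "blunt")
  expect_equal(genome_length(r0$mt), genome_length(r0$wt))
  # deletions and an insertion
  r1 <- apply_reciprocal_translocation(
    g, small_exchange(del_a = 7L, del_b = 12L, ins_a = "GGCGG"), "edited")
  expect_equal(genome_length(r1$mt), genome_length(r1$wt) - 7L - 12L + 5L)
  # retained micro-homology motif removes one motif copy
  r2 <- apply_reciprocal_translocation(
    g, small_exchange(motif_a = "TTTAT"), "mh")
  expect_equal(genome_length(r2$mt), genome_length(r2$wt) - 5L)
})

test_that("truth segment maps tile each mutant chromosome byte-exactly", {
  g <- small_genome(seed = 202)
  res <- apply_complex_translocation(
    g, list(small_exchange(del_a = 25L, del_b = 24L,
                           chr_a = "Chr1", pos_a = 20000L,
                           chr_b = "Chr2", pos_b = 9000L),
            small_exchange(del_a = 1L, del_b = 4L,
                           chr_a = "Chr2", pos_a = 4000L,
                           chr_b = "Chr4", pos_b = 15000L)),
    "chain")
  for (chrom in names(res$truth$chrom_map))
    expect_identical(rebuild_from_truth(res$truth, res$wt, chrom),
                     res$mt$seq[[chrom]], label = chrom)
  # insertion junctions tile too
  ri <- apply_reciprocal_translocation(
    g, small_exchange(ins_a = "ACGTACGT"), "ins")
  for (chrom in names(ri$truth$chrom_map))
    expect_identical(rebuild_from_truth(ri$truth, ri$wt, chrom),
                     ri$mt$seq[[chrom]])
})

test_that("micro-homology motif is written on both WT flanks and retained once", {
  g <- small_genome(seed = 303)
  res <- apply_reciprocal_translocation(g, small_exchange(motif_a = "TTTAT"),
                                        "mh")
  j <- res$truth$junctions[res$truth$junctions$mh_len == 5L, ]
  expect_equal(nrow(j), 1L)
  # both wild-type flanks carry the motif immediately at the break
  expect_identical(substr(res$wt$seq[[j$left_chr]], j$left_end - 4L,
                          j$left_end), "TTTAT")
  expect_identical(substr(res$wt$seq[[j$right_chr]], j$right_start,
                          j$right_start + 4L), "TTTAT")
  # the mutant junction spans exactly one copy
  mt <- res$mt$seq[[j$mt_chrom]]
  expect_identical(substr(mt, j$boundary - 4L, j$boundary), "TTTAT")
  expect_false(substr(mt, j$boundary + 1L, j$boundary + 5L) == "TTTAT")
})

test_that("chained complex events produce 3 derived chromosomes and 4 junctions", {
  g <- small_genome(seed = 404)
  res <- apply_complex_translocation(
    g, list(small_exchange(chr_a = "Chr1", pos_a = 20000L,
                           chr_b = "Chr2", pos_b = 9000L),
            small_exchange(chr_a = "Chr2", pos_a = 4000L,
                           chr_b = "Chr4", pos_b = 15000L)),
    "chain")
  expect_equal(res$truth$kind, "complex_chain")
  derived <- setdiff(res$mt$karyotype$chrom, g$karyotype$chrom)
  expect_length(derived, 3L)
  expect_setequal(derived, c("Chr1^2", "Chr2^4", "Chr4^2"))
  expect_equal(nrow(res$truth$junctions), 4L)
  # one derived chromosome carries two junctions
  expect_equal(max(table(res$truth$junctions$mt_chrom)), 2L)
})

test_that("disjoint exchange pairs are equivalent to independent reciprocals", {
  g <- small_genome(seed = 505)
  specs <- list(small_exchange(chr_a = "Chr1", pos_a = 12000L,
                               chr_b = "Chr2", pos_b = 18000L),
                small_exchange(chr_a = "Chr3", pos_a = 9000L,
                               chr_b = "Chr4", pos_b = 21000L))
  both <- apply_complex_translocation(g, specs, "two")
  expect_equal(sort(both$truth$events$kind), c("reciprocal", "reciprocal"))
  one <- apply_reciprocal_translocation(g, specs[[1]], "one")
  shared <- c("Chr1^2", "Chr2^1")
  expect_identical(both$mt$seq[shared], one$mt$seq[shared])
})

test_that("invalid specifications are rejected", {
  g <- small_genome()
  expect_error(apply_complex_translocation(g, list(small_exchange()), "x"),
               ">= 2 exchange specs")
  expect_error(apply_reciprocal_translocation(
    g, small_exchange(chr_a = "Chr9"), "x"), "no such chromosome")
  expect_error(apply_reciprocal_translocation(
    g, exchange_spec("Chr1", 1L, "Chr2", 500L), "x"), "strictly inside")
  expect_error(exchange_spec("Chr1", 10, "Chr1", 20), "distinct")
  expect_error(junction_edit(del_prox = -1), ">= 0")
  # deletion spanning past the retained segment
  expect_error(apply_reciprocal_translocation(
    g, exchange_spec("Chr1", 100L, "Chr2", 15000L,
                     edit_a = junction_edit(del_prox = 200L)), "x"),
    "spans past")
  # conflicting chained claims: second cut inside a deleted gap
  expect_error(apply_complex_translocation(
    g, list(small_exchange(del_a = 50L, chr_a = "Chr1", pos_a = 12000L,
                           chr_b = "Chr2", pos_b = 9000L),
            small_exchange(chr_a = "Chr1", pos_a = 11980L,
                           chr_b = "Chr4", pos_b = 9000L)), "x"),
    "not covered")
})

test_that("truth records round-trip through JSON and BED output is one interval per junction", {
  g <- small_genome(seed = 606)
  res <- apply_reciprocal_translocation(g, small_exchange(del_a = 3L), "rt")
  js <- tempfile(fileext = ".json")
  write_truth(res$truth, js)
  back <- read_truth(js)
  expect_equal(back$event_id, res$truth$event_id)
  expect_equal(as.data.frame(back$junctions),
               as.data.frame(res$truth$junctions))
  expect_equal(lapply(back$chrom_map, as.data.frame),
               lapply(res$truth$chrom_map, as.data.frame))
  bed <- utils::read.table(sub("\\.json$", ".bed", js), sep = "\t")
  expect_equal(nrow(bed), 2L)   # one interval per derived-chromosome junction
  expect_equal(bed$V3 - bed$V2, rep(1L, 2L))
  expect_setequal(bed$V2, res$truth$junctions$canonical_pos)
})

test_that("random event specs are deterministic and respect margins", {
  g <- small_genome()
  s1 <- random_reciprocal_event(g, seed = 9, margin = 3000L)
  s2 <- random_reciprocal_event(g, seed = 9, margin = 3000L)
  expect_identical(s1, s2)
  expect_true(s1$pos_a >= 3000L && s1$pos_a <= 27000L)
  expect_false(s1$chr_a == s1$chr_b)
})
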