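junctions_for <- function(res, ...) {
  calls <- small_comparison(res)
  characterize_junctions(calls, res$wt, res$mt, ...)
}

test_that("a blunt exchange reports an identity junction", {
  g <- small_genome(seed = 71)
  res <- apply_reciprocal_translocation(g, small_exchange(), "blunt")
  rep <- junctions_for(res)
  expect_equal(rep$deletion_left, c(0L, 0L))
  expect_equal(rep$deletion_right, c(0L, 0L))
  expect_equal(rep$insertion_seq, c("", ""))
  expect_equal(rep$microhomology_len, c(0L, 0L))
  expect_equal(rep$joining_class, c("blunt", "blunt"))
})

test_that("3 bp deletions with a TTTAT motif are recovered exactly", {
  g <- small_genome(seed = 72)
  res <- apply_reciprocal_translocation(
    g, small_exchange(del_a = 3L, del_b = 3L, motif_a = "TTTAT"), "mta_like")
  rep <- junctions_for(res)
  mh <- rep[rep$microhomology_len > 0L, ]
  expect_equal(nrow(mh), 1L)
  expect_equal(mh$microhomology_seq, "TTTAT")
  expect_equal(mh$microhomology_len, 5L)
  expect_equal(mh$joining_class, "microhomology_mediated")
  # both donors lost 3 bp at each junction
  expect_equal(rep$deletion_left, c(3L, 3L))
  expect_equal(rep$deletion_right, c(3L, 3L))
})

test_that("asymmetric deletion sizes land on the correct donor side", {
  g <- small_genome(seed = 73)
  res <- apply_complex_translocation(
    g, list(small_exchange(del_a = 25L, del_b = 24L,
                           chr_a = "Chr1", pos_a = 20000L,
                           chr_b = "Chr2", pos_b = 9000L),
            small_exchange(del_a = 4L, del_b = 4L,
                           chr_a = "Chr3", pos_a = 9000L,
                           chr_b = "Chr4", pos_b = 21000L)),
    "mtb_like")
  rep <- junctions_for(res)
  del_by_chrom <- stats::setNames(rep$deletion_left, rep$mt_chrom)
  expect_equal(del_by_chrom[["Chr1^2"]], 25L)
  expect_equal(del_by_chrom[["Chr2^1"]], 24L)
  expect_equal(del_by_chrom[["Chr3^4"]], 4L)
  expect_equal(del_by_chrom[["Chr4^3"]], 4L)
  expect_true(all(rep$joining_class == "blunt"))
  sm <- summarize_junctions(rep)
  expect_equal(sum(sm$n_junctions), 4L)
  expect_equal(min(sm$deletion_min), 4L)
  expect_equal(max(sm$deletion_max), 25L)
})

test_that("chained-event deletions cover the 1-25 bp range", {
  g <- small_genome(seed = 74)
  res <- apply_complex_translocation(
    g, list(small_exchange(del_a = 25L, del_b = 24L,
                           chr_a = "Chr1", pos_a = 20000L,
                           chr_b = "Chr2", pos_b = 9000L),
            small_exchange(del_a = 1L, del_b = 4L,
                           chr_a = "Chr2", pos_a = 4000L,
                           chr_b = "Chr4", pos_b = 15000L)),
    "mtc_like")
  rep <- junctions_for(res)
  expect_setequal(rep$deletion_left, c(25L, 24L, 1L, 4L))
  sm <- summarize_junctions(rep)
  expect_equal(sm$deletion_min, 1L)
  expect_equal(sm$deletion_max, 25L)
})

test_that("reported micro-homology is maximal", {
  g <- small_genome(seed = 75)
  res <- apply_reciprocal_translocation(g, small_exchange(motif_a = "GATTA"),
                                        "mh")
  calls <- small_comparison(res)
  rep <- characterize_junctions(calls, res$wt, res$mt)
  j <- rep[rep$microhomology_len > 0L, ]
  cl <- calls[calls$mt_chrom == j$mt_chrom, ]
  A <- res$wt$seq[[j$left_chr]]; B <- res$wt$seq[[j$right_chr]]
  mt <- res$mt$seq[[j$mt_chrom]]
  s_r <- j$mt_junction + 1L                 # first base of the placed motif
  e_l <- j$mt_junction + j$microhomology_len
  # one more base left: right source context no longer matches
  expect_false(substr(mt, s_r - 1L, s_r - 1L) ==
               substr(B, cl$right_start - 1L, cl$right_start - 1L))
  # one more base right: left source context no longer matches
  expect_false(substr(mt, e_l + 1L, e_l + 1L) ==
               substr(A, cl$left_full_end + 1L, cl$left_full_end + 1L))
})

test_that("the joining-class threshold is configurable", {
  g <- small_genome(seed = 76)
  res <- apply_reciprocal_translocation(g, small_exchange(motif_a = "CAT"),
                                        "mh3")
  rep2 <- junctions_for(res, mh_threshold = 2L)
  rep4 <- junctions_for(res, mh_threshold = 4L)
  expect_true("microhomology_mediated" %in% rep2$joining_class)
  expect_false("microhomology_mediated" %in% rep4$joining_class)
  expect_error(junctions_for(res, flank = 10L), "flank")
})

test_that("junction edits round-trip through the full caller (randomized)", {
  g <- small_genome(seed = 80)
  for (seed in 1:6) {
    sp <- random_reciprocal_event(g, seed = 100 + seed, deletions = 0:25,
                                  margin = 3000L)
    res <- apply_reciprocal_translocation(g, sp, paste0("rt", seed))
    rep <- junctions_for(res)
    tj <- res$truth$junctions
    m <- match(rep$mt_chrom, tj$mt_chrom)
    expect_equal(rep$deletion_left, tj$gap_left[m], label = paste("s", seed))
    expect_equal(rep$deletion_right, tj$gap_right[m],
                 label = paste("s", seed))
    expect_equal(rep$microhomology_len, tj$mh_len[m])
    expect_equal(rep$insertion_seq, tj$insertion[m])
  }
})
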