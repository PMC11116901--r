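het_recip <- function(n = 1L, a = 0.5)
  lapply(seq_len(n), function(i)
    translocation_locus(paste0("T", i), "reciprocal",
                        paste0("Chr", c(2 * i - 1, 2 * i)), "het", a = a))

test_that("diakinesis configurations match multivalent counting rules", {
  one <- karyotype_config(11, het_recip(1))
  expect_equal(predict_diakinesis_configuration(one)[c("bivalents",
                                                       "quadrivalents")],
               list(bivalents = 9L, quadrivalents = 1L))
  two <- karyotype_config(11, het_recip(2))
  expect_equal(predict_diakinesis_configuration(two)[c("bivalents",
                                                       "quadrivalents")],
               list(bivalents = 7L, quadrivalents = 2L))
  hom <- karyotype_config(11, list(translocation_locus(
    "T1", "reciprocal", c("Chr1", "Chr2"), "hom")))
  expect_equal(predict_diakinesis_configuration(hom)$bivalents, 11L)
  expect_equal(predict_diakinesis_configuration(
    karyotype_config(11))$bivalents, 11L)
  chain <- karyotype_config(11, list(translocation_locus(
    "TC", "complex_chain", c("Chr1", "Chr5", "Chr11"), "het")))
  dk <- predict_diakinesis_configuration(chain)
  expect_equal(dk$bivalents, 8L)
  expect_equal(dk$quadrivalents, 0L)
  expect_equal(as.integer(as.character(dk$multivalents$size)), 6L)
})

test_that("gamete enumeration follows the alternate/adjacent model", {
  forced <- karyotype_config(11, het_recip(1, a = 1))
  gf <- enumerate_gametes(forced)
  expect_equal(sum(gf$probability), 1)
  expect_equal(sort(gf$probability[gf$balanced]), c(0.5, 0.5))
  half <- enumerate_gametes(karyotype_config(11, het_recip(1, a = 0.5)))
  expect_equal(sum(half$probability[half$balanced]), 0.5)
  two <- enumerate_gametes(karyotype_config(11, het_recip(2, a = 0.5)))
  expect_equal(nrow(two), 9L)
  expect_equal(sum(two$probability), 1)
  bal <- two[two$balanced, ]
  expect_equal(nrow(bal), 4L)               # {N,T} x {N,T}
  expect_equal(bal$probability, rep(1 / 16, 4L))
  expect_equal(sum(bal$probability), 0.25)
  # chains require an explicit segregation table unless the default is asked
  chain_cfg <- karyotype_config(11, list(translocation_locus(
    "TC", "complex_chain", c("Chr1", "Chr5", "Chr11"), "het")))
  expect_error(enumerate_gametes(chain_cfg), "segregation table")
  gch <- enumerate_gametes(chain_cfg, use_default_chain_table = TRUE)
  expect_equal(sum(gch$probability[gch$balanced]), 1 / 10)
})

test_that("expected F2 segregation gives 1:1 (k=1), 1:3 (k=2) and 1:2:1 per event", {
  e1 <- expected_f2_segregation(karyotype_config(11, het_recip(1)))
  expect_equal(e1$normal_vs_semisterile, c(1, 1))
  expect_equal(e1$genotype_ratio, c(NN = 1, NT = 2, TT = 1))
  expect_equal(e1$p_fertile, 0.5)
  e2 <- expected_f2_segregation(karyotype_config(11, het_recip(2)))
  expect_equal(e2$normal_vs_semisterile, c(1, 3))
  expect_equal(e2$p_fertile, 0.25)
  expect_equal(sum(e2$zygote_classes$probability), 1)
  expect_equal(sum(e2$zygote_classes$probability[
    !e2$zygote_classes$semisterile]), 0.25)
  e0 <- expected_f2_segregation(karyotype_config(11))
  expect_equal(e0$p_fertile, 1)
})

test_that("simulated crosses agree with theory and honor parental genotypes", {
  f1 <- karyotype_config(11, het_recip(1))
  pop <- simulate_cross(f1, f1, 237, seed = 11)
  expect_equal(nrow(pop), 237L)
  expect_equal(sum(table(pop$T1)), 237L)
  pop2 <- simulate_cross(f1, f1, 237, seed = 11)
  expect_identical(pop, pop2)
  big <- simulate_cross(f1, f1, 100000, seed = 12)
  het_frac <- mean(big$T1 == "NT")
  se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(het_frac - 0.5), 3 * se)
  # wild type x homozygous translocated: all offspring heterozygous
  wt <- karyotype_config(11, list(translocation_locus(
    "T1", "reciprocal", c("Chr1", "Chr2"), "wt")))
  hom <- karyotype_config(11, list(translocation_locus(
    "T1", "reciprocal", c("Chr1", "Chr2"), "hom")))
  f1x <- simulate_cross(wt, hom, 50, seed = 13)
  expect_true(all(f1x$T1 == "NT"))
  expect_true(all(f1x$phenotype == "semi_sterile"))
})

test_that("sterility predictions invert exactly and respond monotonically", {
  k1 <- karyotype_config(11, het_recip(1, a = 0.5))
  expect_equal(predict_sterility_and_seed_reduction(k1)$pollen_sterility, 0.5)
  inv <- karyotype_config(11, het_recip(1, a = 0.5193))
  expect_equal(predict_sterility_and_seed_reduction(inv)$pollen_sterility,
               0.4807)
  expect_equal(predict_sterility_and_seed_reduction(
    karyotype_config(11))$pollen_sterility, 0)
  s_low <- predict_sterility_and_seed_reduction(
    karyotype_config(11, het_recip(2, a = 0.6)))$pollen_sterility
  s_high <- predict_sterility_and_seed_reduction(
    karyotype_config(11, het_recip(2, a = 0.4)))$pollen_sterility
  expect_lt(s_low, s_high)
  expect_equal(predict_sterility_and_seed_reduction(
    karyotype_config(11, het_recip(2, a = 0.5)))$pollen_sterility, 0.75)
})

test_that("the alternate-frequency estimator inverts the sterility model", {
  expect_equal(estimate_alternate_frequency(0.5, k = 1)$a_hat, 0.5)
  expect_equal(estimate_alternate_frequency(0.75, k = 2)$a_hat, 0.5)
  est <- estimate_alternate_frequency(0.7429, k = 2, n_scored = 10000)
  expect_equal(est$a_hat, sqrt(0.2571), tolerance = 1e-12)
  expect_equal(round(est$a_hat, 3), 0.507)
  expect_true(est$ci[1] < est$a_hat && est$a_hat < est$ci[2])
  expect_warning(estimate_alternate_frequency(1, k = 1), "degenerate")
  expect_error(estimate_alternate_frequency(1.2, k = 1), "\\[0, 1\\]")
})

test_that("gamete and zygote distributions always sum to one", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(1:3, 1)
    as <- runif(k)
    cfg <- karyotype_config(11, lapply(seq_len(k), function(i)
      translocation_locus(paste0("T", i), "reciprocal",
                          paste0("Chr", c(2 * i - 1, 2 * i)), "het",
                          a = as[i])))
    gam <- enumerate_gametes(cfg)
    expect_equal(sum(gam$probability), 1)
    expect_equal(sum(gam$probability[gam$balanced]), prod(as),
                 tolerance = 1e-12)
    ez <- expected_f2_segregation(cfg)
    expect_equal(sum(ez$zygote_classes$probability), 1)
    expect_equal(ez$p_fertile, 0.5^k)
  }
})
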