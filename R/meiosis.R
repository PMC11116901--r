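#' Describe a translocation locus in a karyotype
#'
#' @param name event name (used as the genotype column label).
#' @param kind `"reciprocal"` (one exchange, quadrivalent in heterozygotes)
#'   or `"complex_chain"` (chained exchanges over >= 3 chromosomes, a single
#'   larger multivalent in heterozygotes).
#' @param chromosomes donor chromosome ids involved.
#' @param zygosity `"het"`, `"hom"` (homozygous translocated) or `"wt"`.
#' @param a alternate-segregation frequency for this multivalent in a
#'   heterozygote (probability of a balanced disjunction), in \[0, 1\].
#'   Classical expectation for a quadrivalent with random 2:2 disjunction is
#'   0.5.
#' @param balanced_fraction for `complex_chain` events only: probability that
#'   a random gamete is balanced. The default `NULL` requires an explicit
#'   value unless `use_default_chain_table = TRUE` is passed to the consuming
#'   function, in which case uniform 3:3 segregation of a hexavalent is
#'   assumed (balanced fraction 1/10); chain predictions are model-dependent
#'   and flagged as such.
#' @return a list of class `tl_locus`.
#' @export
translocation_locus <- function(name, kind = c("reciprocal", "complex_chain"),
                                chromosomes = c("ChrA", "ChrB"),
                                zygosity = c("het", "hom", "wt"),
                                a = 0.5, balanced_fraction = NULL) {
  kind <- match.arg(kind)
  zygosity <- match.arg(zygosity)
  if (a < 0 || a > 1) stop("alternate frequency a must be in [0, 1]")
  if (kind == "reciprocal" && length(chromosomes) != 2L)
    stop("a reciprocal locus involves exactly 2 chromosomes")
  if (kind == "complex_chain" && length(chromosomes) < 3L)
    stop("a complex chain involves >= 3 chromosomes")
  structure(list(name = name, kind = kind, chromosomes = chromosomes,
                 zygosity = zygosity, a = a,
                 balanced_fraction = balanced_fraction),
            class = "tl_locus")
}

#' Karyotype configuration of an individual
#'
#' @param n_pairs number of chromosome pairs (11 for watermelon).
#' @param loci list of [translocation_locus()] carried by the individual.
#' @return a list of class `tl_karyotype`.
#' @export
karyotype_config <- function(n_pairs = 11L, loci = list()) {
  if (inherits(loci, "tl_locus")) loci <- list(loci)
  stopifnot(all(vapply(loci, inherits, logical(1), "tl_locus")))
  chroms <- unlist(lapply(loci, `[[`, "chromosomes"))
  if (anyDuplicated(chroms))
    stop("loci must involve distinct chromosome sets; ",
         "model a shared chromosome as a single complex_chain locus")
  used <- length(unique(chroms))
  if (used > n_pairs) stop("loci involve more chromosomes than the karyotype")
  structure(list(n_pairs = as.integer(n_pairs), loci = loci),
            class = "tl_karyotype")
}

.het_loci <- function(config)
  Filter(function(l) l$zygosity == "het", config$loci)

#' Predict the diakinesis pairing configuration
#'
#' Each heterozygous reciprocal translocation consumes two chromosome pairs
#' into one quadrivalent; a heterozygous chained complex event over c
#' chromosomes forms one multivalent of 2c chromosomes. Homozygous events
#' pair as normal bivalents.
#'
#' @param config a [karyotype_config()].
#' @return list with `bivalents`, `quadrivalents`, `multivalents`
#'   (data.frame of size/count for multivalents larger than bivalents).
#' @export
predict_diakinesis_configuration <- function(config) {
  stopifnot(inherits(config, "tl_karyotype"))
  het <- .het_loci(config)
  sizes <- vapply(het, function(l) 2L * length(l$chromosomes), integer(1))
  pairs_used <- sum(vapply(het, function(l) length(l$chromosomes),
                           integer(1)))
  mv <- if (length(sizes))
    as.data.frame(table(size = sizes), responseName = "count") else
    data.frame(size = integer(), count = integer())
  list(bivalents = config$n_pairs - pairs_used,
       quadrivalents = sum(sizes == 4L),
       multivalents = mv)
}

.locus_balanced_fraction <- function(locus, use_default_chain_table = FALSE) {
  if (locus$kind == "reciprocal") return(locus$a)
  if (!is.null(locus$balanced_fraction)) return(locus$balanced_fraction)
  if (!use_default_chain_table)
    stop("chained complex events need an explicit segregation table ",
         "(balanced_fraction); pass use_default_chain_table = TRUE to ",
         "assume uniform 3:3 hexavalent segregation (balanced fraction ",
         "1/10). Chain predictions are model-dependent.")
  # uniform 3:3 disjunction of a hexavalent: 10 equiprobable splits, one of
  # which is the balanced {all-normal | all-translocated} split
  1 / 10
}

#' Enumerate gamete classes of a translocation heterozygote
#'
#' For each heterozygous event, a gamete carries the normal set (N), the
#' translocated set (T), or an unbalanced combination (U): P(N) = P(T) = b/2
#' and P(U) = 1 - b, where b is the event's balanced (alternate) segregation
#' frequency. Independent events combine multiplicatively; a gamete is
#' balanced iff it is balanced at every event.
#'
#' @param config a [karyotype_config()].
#' @param use_default_chain_table see [translocation_locus()].
#' @return a data.frame of class `tl_gametes`: one column per heterozygous
#'   event (values N/T/U), `probability`, `balanced`.
#' @export
enumerate_gametes <- function(config, use_default_chain_table = FALSE) {
  het <- .het_loci(config)
  if (!length(het))
    return(structure(data.frame(probability = 1, balanced = TRUE),
                     class = c("tl_gametes", "data.frame")))
  per <- lapply(het, function(l) {
    b <- .locus_balanced_fraction(l, use_default_chain_table)
    data.frame(class = c("N", "T", "U"), p = c(b / 2, b / 2, 1 - b))
  })
  grid <- do.call(expand.grid,
                  c(lapply(per, function(d) d$class),
                    list(stringsAsFactors = FALSE)))
  names(grid) <- vapply(het, `[[`, character(1), "name")
  p <- rep(1, nrow(grid))
  for (i in seq_along(per))
    p <- p * per[[i]]$p[match(grid[[i]], per[[i]]$class)]
  grid$probability <- p
  grid$balanced <- apply(grid[, seq_along(het), drop = FALSE], 1L,
                         function(x) all(x != "U"))
  grid <- grid[grid$probability > 0 | TRUE, , drop = FALSE]
  structure(grid, class = c("tl_gametes", "data.frame"))
}

#' Expected F2 segregation from selfing a translocation heterozygote
#'
#' Under the balanced-only viability rule, surviving gametes are the balanced
#' classes renormalized (N and T each 1/2 per event), zygotes form by random
#' union, and a plant is pollen-semi-sterile iff it is heterozygous for at
#' least one event. With k independent events the fully fertile fraction is
#' (1/2)^k, i.e. normal : semi-sterile = 1 : 2^k - 1, and each event
#' segregates NN:NT:TT = 1:2:1.
#'
#' @param config a [karyotype_config()] of the selfed heterozygote.
#' @param use_default_chain_table see [translocation_locus()].
#' @return list with `k` (number of heterozygous events),
#'   `genotype_ratio` (per-event NN:NT:TT), `p_fertile`,
#'   `normal_vs_semisterile` (expected ratio weights), and `zygote_classes`
#'   (data.frame over per-event genotypes with probabilities).
#' @export
expected_f2_segregation <- function(config, use_default_chain_table = FALSE) {
  het <- .het_loci(config)
  k <- length(het)
  # validates chain tables even though the surviving-gamete ratio is symmetric
  for (l in het) .locus_balanced_fraction(l, use_default_chain_table)
  if (k == 0L)
    return(list(k = 0L, genotype_ratio = c(NN = 1, NT = 0, TT = 0),
                p_fertile = 1, normal_vs_semisterile = c(1, 0),
                zygote_classes = data.frame(probability = 1,
                                            semisterile = FALSE)))
  per <- data.frame(g = c("NN", "NT", "TT"), p = c(0.25, 0.5, 0.25))
  grid <- do.call(expand.grid, c(rep(list(per$g), k),
                                 list(stringsAsFactors = FALSE)))
  names(grid) <- vapply(het, `[[`, character(1), "name")
  p <- rep(1, nrow(grid))
  for (i in seq_len(k)) p <- p * per$p[match(grid[[i]], per$g)]
  grid$probability <- p
  grid$semisterile <- apply(grid[, seq_len(k), drop = FALSE], 1L,
                            function(x) any(x == "NT"))
  list(k = k, genotype_ratio = c(NN = 1, NT = 2, TT = 1),
       p_fertile = (1 / 2)^k,
       normal_vs_semisterile = c(1, 2^k - 1),
       zygote_classes = grid)
}

#' Simulate a cross between translocation-carrier parents
#'
#' Offspring are drawn by independently sampling one surviving (balanced)
#' gamete from each parent per event: a heterozygous parent transmits N or T
#' with probability 1/2 each under the balanced-only viability rule, a
#' homozygous translocated parent transmits T, a wild-type parent N.
#' The phenotype is semi-sterile iff the offspring is heterozygous for at
#' least one event.
#'
#' @param parent1,parent2 [karyotype_config()] objects sharing locus names.
#' @param n_offspring number of offspring.
#' @param seed integer seed.
#' @return data.frame of class `tl_population`: `individual`, one genotype
#'   column per event (NN/NT/TT), `phenotype`
#'   (`"normal"`/`"semi_sterile"`).
#' @export
simulate_cross <- function(parent1, parent2, n_offspring, seed) {
  stopifnot(inherits(parent1, "tl_karyotype"),
            inherits(parent2, "tl_karyotype"))
  if (n_offspring < 1L) stop("n_offspring must be >= 1")
  loci <- unique(c(vapply(parent1$loci, `[[`, character(1), "name"),
                   vapply(parent2$loci, `[[`, character(1), "name")))
  if (!length(loci)) stop("no translocation loci to segregate")
  find <- function(cfg, nm) {
    for (l in cfg$loci) if (l$name == nm) return(l)
    translocation_locus(nm, "reciprocal", zygosity = "wt")
  }
  transmit <- function(locus, n) {
    switch(locus$zygosity,
           wt = rep("N", n),
           hom = rep("T", n),
           het = sample(c("N", "T"), n, replace = TRUE))
  }
  out <- with_seed(seed, {
    df <- data.frame(individual = paste0("ind", seq_len(n_offspring)),
                     stringsAsFactors = FALSE)
    for (nm in loci) {
      g1 <- transmit(find(parent1, nm), n_offspring)
      g2 <- transmit(find(parent2, nm), n_offspring)
      al <- paste0(pmin(g1, g2), pmax(g1, g2))   # NN, NT, TT
      df[[nm]] <- al
    }
    df
  })
  het_any <- apply(out[, loci, drop = FALSE], 1L,
                   function(x) any(x == "NT"))
  out$phenotype <- ifelse(het_any, "semi_sterile", "normal")
  class(out) <- c("tl_population", "data.frame")
  out
}

#' Predict pollen sterility and seed-set reduction of a heterozygote
#'
#' Pollen sterility is the unbalanced gamete fraction 1 - prod(b_i) over the
#' individual's heterozygous events (b = alternate frequency for
#' quadrivalents). Seed-set reduction is modelled with the same fraction on
#' the ovule side (symmetric gametophyte model); both values are returned
#' separately so asymmetric viability can be configured.
#'
#' @param config a [karyotype_config()].
#' @param use_default_chain_table see [translocation_locus()].
#' @param ovule_factor multiplier applied to the ovule-side unbalanced
#'   fraction (1 = symmetric).
#' @return list with `pollen_sterility` and `seed_reduction`.
#' @export
predict_sterility_and_seed_reduction <- function(config,
                                                 use_default_chain_table = FALSE,
                                                 ovule_factor = 1) {
  het <- .het_loci(config)
  if (!length(het))
    return(list(pollen_sterility = 0, seed_reduction = 0))
  b <- vapply(het, .locus_balanced_fraction, numeric(1),
              use_default_chain_table)
  s <- 1 - prod(b)
  list(pollen_sterility = s,
       seed_reduction = min(1, s * ovule_factor))
}

#' Estimate the alternate-segregation frequency from observed sterility
#'
#' Inverts the multiplicative sterility model: assuming k independent events
#' with equal alternate frequency a, observed sterility s gives
#' a_hat = (1 - s)^(1/k). The confidence interval transforms an exact
#' binomial (Clopper-Pearson) interval on s computed from `n_scored` pollen
#' grains.
#'
#' @param observed_sterility fraction of sterile pollen in \[0, 1\].
#' @param k number of independent heterozygous events (>= 1).
#' @param n_scored number of pollen grains scored.
#' @param conf_level confidence level for the interval.
#' @return a list of class `tl_a_estimate`: `a_hat`, `ci` (length-2), `k`,
#'   `n_scored`, `observed_sterility`.
#' @export
estimate_alternate_frequency <- function(observed_sterility, k = 1L,
                                         n_scored = 1000L,
                                         conf_level = 0.95) {
  if (observed_sterility < 0 || observed_sterility > 1)
    stop("observed_sterility must be in [0, 1]")
  if (k < 1L) stop("k must be >= 1")
  if (observed_sterility == 1)
    warning("observed sterility of 1 gives a degenerate estimate a_hat = 0")
  x <- round(observed_sterility * n_scored)
  ci_s <- stats::binom.test(x, n_scored, conf.level = conf_level)$conf.int
  a_hat <- (1 - observed_sterility)^(1 / k)
  ci <- sort((1 - ci_s)^(1 / k))
  structure(list(a_hat = a_hat, ci = as.numeric(ci), k = k,
                 n_scored = n_scored,
                 observed_sterility = observed_sterility,
                 conf_level = conf_level),
            class = "tl_a_estimate")
}

#' @export
print.tl_a_estimate <- function(x, ...) {
  cat(sprintf(
    "<tl_a_estimate> a_hat = %.4f (%d%% CI %.4f-%.4f), k = %d, n = %d\n",
    x$a_hat, round(100 * x$conf_level), x$ci[1], x$ci[2], x$k, x$n_scored))
  invisible(x)
}

#' Write a simulated population as TSV
#' @param population a `tl_population`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(population, path) {
  utils::write.table(as.data.frame(population), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
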