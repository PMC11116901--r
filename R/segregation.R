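#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Pearson chi-square with expected counts `total * ratio/sum(ratio)` and NO
#' continuity correction (segregation tables in the crop genetics literature
#' are computed without it; the bundled example tables back-compute exactly
#' only without correction). The result is invariant under rescaling the
#' ratio weights (1:3 and 2:6 are the same hypothesis).
#'
#' @param observed integer vector of class counts (>= 2 classes).
#' @param ratio positive expected ratio weights, same length.
#' @param alpha significance level for the conformity flag.
#' @return an object of class `tl_chisq`: `observed`, `expected`, `ratio`,
#'   `chi2`, `df`, `p_value`, `alpha`, `conforms` (TRUE iff chi2 <= critical
#'   value at alpha; the boundary is inclusive).
#' @examples
#' chisq_gof(c(112, 125), c(1, 1))$chi2   # 0.713
#' @export
chisq_gof <- function(observed, ratio, alpha = 0.05) {
  if (length(observed) < 2L) stop("need at least 2 classes")
  if (length(ratio) != length(observed))
    stop("ratio and observed must have the same length")
  if (any(ratio <= 0)) stop("ratio weights must be positive")
  if (any(observed < 0) || sum(observed) <= 0)
    stop("counts must be non-negative with positive total")
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected == 0)) stop("zero expected count")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  crit <- stats::qchisq(1 - alpha, df)
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 alpha = alpha, conforms = chi2 <= crit),
            class = "tl_chisq")
}

#' @export
print.tl_chisq <- function(x, ...) {
  cat(sprintf(
    "<tl_chisq> obs %s vs ratio %s: chi2 = %.3f (df %d), p = %.4g -> %s\n",
    paste(x$observed, collapse = ":"), paste(x$ratio, collapse = ":"),
    x$chi2, x$df, x$p_value,
    if (x$conforms) "mendelian" else "distorted"))
  invisible(x)
}

#' Classify a segregation test result
#'
#' @param result a `tl_chisq`.
#' @return `"mendelian"` if the observed counts conform to the tested ratio
#'   at the result's significance level (boundary inclusive), else
#'   `"distorted"`.
#' @export
classify_segregation <- function(result) {
  stopifnot(inherits(result, "tl_chisq"))
  if (result$conforms) "mendelian" else "distorted"
}

.pct1 <- function(x, n) {
  # one decimal, half-up (table style), e.g. 112/237 -> "47.3"
  sprintf("%.1f", floor(1000 * x / n + 0.5) / 10)
}

#' Tabulated segregation report
#'
#' One goodness-of-fit row per contrast, with counts, percentages (one
#' decimal, half-up) and the chi-square statistic at three decimals, in the
#' layout of published F2 segregation tables.
#'
#' @param counts data.frame with columns `population`, one count column per
#'   class (any names), in class order matching `ratio`.
#' @param ratio expected ratio weights (single vector applied to all rows) or
#'   a list with one vector per row.
#' @param alpha significance level.
#' @return data.frame with one row per population: `population`, `n`, the
#'   class counts with attached percentages, `chi2` (3 dp), `df`, `p_value`,
#'   `ratio`, `conclusion`.
#' @export
segregation_report <- function(counts, ratio, alpha = 0.05) {
  stopifnot(is.data.frame(counts), "population" %in% names(counts))
  classes <- setdiff(names(counts), "population")
  if (length(classes) < 2L) stop("need at least 2 class-count columns")
  ratios <- if (is.list(ratio)) ratio else
    rep(list(ratio), nrow(counts))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    obs <- as.numeric(counts[i, classes])
    r <- ratios[[i]]
    ct <- chisq_gof(obs, r, alpha)
    n <- sum(obs)
    pretty <- paste0(obs, " (", .pct1(obs, n), "%)")
    out <- data.frame(population = counts$population[i], n = n,
                      stringsAsFactors = FALSE)
    for (j in seq_along(classes)) out[[classes[j]]] <- pretty[j]
    out$chi2 <- round(ct$chi2, 3)
    out$df <- ct$df
    out$p_value <- ct$p_value
    out$ratio <- paste(r, collapse = ":")
    out$conclusion <- classify_segregation(ct)
    out
  })
  do.call(rbind, rows)
}

#' Bundled F2 segregation count tables
#'
#' Published F2 observations for three watermelon translocation-line
#' populations (near-isogenic wild type crossed with the translocation line,
#' selfed): `"pollen"` gives per-population counts of normal vs sterile
#' pollen phenotype plants with the tested ratio; `"markers"` gives
#' three-class codominant marker counts (homozygous wild type, heterozygous,
#' homozygous translocated) per breakpoint marker.
#'
#' @param which `"pollen"` or `"markers"`.
#' @return a data.frame of counts.
#' @export
f2_example_counts <- function(which = c("pollen", "markers")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   switch(which, pollen = "f2_pollen_counts.tsv",
                          markers = "f2_marker_counts.tsv"),
                   package = "translocatr", mustWork = TRUE)
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
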