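#' Call inter-chromosomal translocations from synteny blocks
#'
#' Emits a candidate breakpoint wherever two adjacent blocks on one mutant
#' chromosome derive from different wild-type chromosomes, then groups
#' candidates into events via the graph of wild-type chromosome adjacencies:
#' a connected component over 2 chromosomes is a reciprocal event, over >= 3
#' a chained complex event. Blocks shorter than `min_block_len` are dropped
#' before calling; adjacent same-chromosome blocks with a diagonal jump are
#' recorded as intra-chromosomal anomalies (attribute `"anomalies"`), never
#' called as translocations.
#'
#' @param blocks a `tl_blocks` data.frame from one WT/MT comparison.
#' @param min_block_len minimum block length (bp) on the mutant genome.
#' @return a data.frame of class `tl_calls`, one row per candidate junction:
#'   event id and kind, mutant chromosome, naive junction estimate
#'   (`mt_pos`, 1-based last anchored base of the left block), `ci_width`,
#'   flanking sources and the anchored block-edge coordinates used by
#'   [refine_breakpoint()]. The event table is attached as attribute
#'   `"events"`.
#' @export
call_translocations <- function(blocks, min_block_len = 1000L) {
  if (is.list(blocks) && !is.data.frame(blocks))
    stop("blocks from multiple comparisons must be called one at a time")
  stopifnot(inherits(blocks, "tl_blocks"))
  k <- attr(blocks, "k")
  b <- blocks[blocks$mt_end - blocks$mt_start >= min_block_len, , drop = FALSE]
  cand <- list(); anom <- list()
  if (nrow(b) > 1L) for (i in 2:nrow(b)) {
    if (b$mt_chrom[i] != b$mt_chrom[i - 1L]) next
    l <- b[i - 1L, ]; r <- b[i, ]
    if (l$wt_chrom == r$wt_chrom) {
      if (l$strand != r$strand ||
          abs((r$wt_first - r$mt_first) - (l$wt_last - l$mt_last)) > 0)
        anom[[length(anom) + 1L]] <- data.frame(
          mt_chrom = l$mt_chrom, mt_pos = l$mt_last + k - 1L,
          wt_chrom = l$wt_chrom, note = "intra-chromosomal discontinuity")
      next
    }
    cand[[length(cand) + 1L]] <- data.frame(
      mt_chrom = l$mt_chrom,
      mt_pos = l$mt_last + k - 1L,
      ci_width = max(0L, r$mt_first - l$mt_last - k),
      left_chr = l$wt_chrom, left_strand = l$strand,
      left_wt_anchor = l$wt_last + k - 1L, left_mt_anchor = l$mt_last + k - 1L,
      right_chr = r$wt_chrom, right_strand = r$strand,
      right_wt_anchor = r$wt_first, right_mt_anchor = r$mt_first,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(cand)) do.call(rbind, cand) else
    data.frame(mt_chrom = character(), mt_pos = integer(),
               ci_width = integer(), left_chr = character(),
               left_strand = character(), left_wt_anchor = integer(),
               left_mt_anchor = integer(), right_chr = character(),
               right_strand = character(), right_wt_anchor = integer(),
               right_mt_anchor = integer(), stringsAsFactors = FALSE)

  # group candidates into events over the wild-type adjacency graph
  if (nrow(calls)) {
    chroms <- unique(c(calls$left_chr, calls$right_chr))
    comp <- stats::setNames(seq_along(chroms), chroms)
    for (i in seq_len(nrow(calls))) {
      ca <- comp[[calls$left_chr[i]]]; cb <- comp[[calls$right_chr[i]]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    cid <- match(comp[calls$left_chr], unique(comp))
    calls$event <- cid
    sizes <- vapply(split(c(calls$left_chr, calls$right_chr),
                          c(cid, cid)),
                    function(x) length(unique(x)), integer(1))
    nj <- table(cid)
    kind <- ifelse(sizes >= 3L, "complex_chain",
                   ifelse(nj[names(sizes)] == 2L, "reciprocal", "partial"))
    calls$kind <- kind[as.character(cid)]
    # reciprocal partner: mirrored sources within the event
    calls$paired_with <- NA_integer_
    for (i in seq_len(nrow(calls))) {
      p <- which(calls$event == calls$event[i] &
                 calls$left_chr == calls$right_chr[i] &
                 calls$right_chr == calls$left_chr[i])
      if (length(p) == 1L) calls$paired_with[i] <- p
    }
    ev <- data.frame(event = unique(cid),
                     kind = kind[as.character(unique(cid))],
                     chromosomes = vapply(unique(cid), function(e)
                       paste(sort(unique(c(calls$left_chr[calls$event == e],
                                           calls$right_chr[calls$event == e]))),
                             collapse = ","), character(1)))
  } else {
    calls$event <- integer(0); calls$kind <- character(0)
    calls$paired_with <- integer(0)
    ev <- data.frame(event = integer(), kind = character(),
                     chromosomes = character())
  }
  rownames(calls) <- NULL
  attr(calls, "events") <- ev
  attr(calls, "anomalies") <- if (length(anom)) do.call(rbind, anom) else NULL
  attr(calls, "k") <- k
  class(calls) <- c("tl_calls", "data.frame")
  calls
}

# maximal exact extension; returns number of matching bases
.extend_fwd <- function(mt_seq, mt_from, wt_seq, wt_from, window) {
  wlen <- min(window, nchar(mt_seq) - mt_from, nchar(wt_seq) - wt_from)
  if (wlen <= 0L) return(0L)
  m <- charToRaw(substr(mt_seq, mt_from + 1L, mt_from + wlen))
  w <- charToRaw(substr(wt_seq, wt_from + 1L, wt_from + wlen))
  d <- which(m != w)
  if (length(d)) d[1L] - 1L else wlen
}

.extend_rev <- function(mt_seq, mt_from, wt_seq, wt_from, window) {
  wlen <- min(window, mt_from - 1L, wt_from - 1L)
  if (wlen <= 0L) return(0L)
  m <- charToRaw(substr(mt_seq, mt_from - wlen, mt_from - 1L))
  w <- charToRaw(substr(wt_seq, wt_from - wlen, wt_from - 1L))
  d <- which(m != w)
  if (length(d)) wlen - d[length(d)] else wlen
}

#' Refine translocation breakpoints to base resolution
#'
#' Starting from the anchored edges of the flanking blocks, extends an exact
#' match of the mutant sequence rightward along the left wild-type source and
#' leftward along the right source. If the extensions overlap, the overlap is
#' the junction micro-homology and the canonical junction coordinate is the
#' leftmost equivalent placement on the mutant chromosome; if they leave a
#' gap, the intervening mutant bases are reported as an insertion and
#' `ci_width` is the residual gap, otherwise `ci_width` becomes 0.
#'
#' @param calls a `tl_calls` data.frame.
#' @param wt_genome,mt_genome the compared genomes.
#' @param window maximum extension length (bp).
#' @return `calls` with refinement columns added: `mt_junction` (canonical,
#'   1-based last base from the left source), `left_full_end` and
#'   `left_canonical_end` (wild-type coordinates on the left source),
#'   `right_start` (wild-type coordinate of the first base attributable to
#'   the right source), `mh_len`, `mh_seq`, `insertion`, updated `ci_width`.
#' @export
refine_breakpoints <- function(calls, wt_genome, mt_genome, window = 500L) {
  stopifnot(inherits(calls, "tl_calls"))
  n <- nrow(calls)
  out <- calls
  out$mt_junction <- out$left_full_end <- out$left_canonical_end <-
    out$right_start <- out$mh_len <- NA_integer_
  out$mh_seq <- out$insertion <- NA_character_
  for (i in seq_len(n)) {
    cl <- calls[i, ]
    if (cl$left_strand != "+" || cl$right_strand != "+") next  # flagged only
    mt <- mt_genome$seq[[cl$mt_chrom]]
    A <- wt_genome$seq[[cl$left_chr]]
    B <- wt_genome$seq[[cl$right_chr]]
    if (window < cl$ci_width)
      warning("window smaller than ci_width; clipping extension")
    e1 <- .extend_fwd(mt, cl$left_mt_anchor, A, cl$left_wt_anchor, window)
    e2 <- .extend_rev(mt, cl$right_mt_anchor, B, cl$right_wt_anchor, window)
    e_l <- cl$left_mt_anchor + e1
    alpha_full <- cl$left_wt_anchor + e1
    s_r <- cl$right_mt_anchor - e2
    beta_min <- cl$right_wt_anchor - e2
    h <- e_l - s_r + 1L
    if (h >= 0L) {
      out$mt_junction[i] <- s_r - 1L
      out$mh_len[i] <- h
      out$mh_seq[i] <- substr(mt, s_r, e_l)
      out$insertion[i] <- ""
      out$ci_width[i] <- 0L
      out$left_canonical_end[i] <- alpha_full - h
    } else {
      out$mt_junction[i] <- e_l
      out$mh_len[i] <- 0L
      out$mh_seq[i] <- ""
      out$insertion[i] <- substr(mt, e_l + 1L, s_r - 1L)
      out$ci_width[i] <- s_r - e_l - 1L
      out$left_canonical_end[i] <- alpha_full
    }
    out$left_full_end[i] <- alpha_full
    out$right_start[i] <- beta_min
  }
  out
}

#' Write breakpoint calls as TSV, JSON and BED
#'
#' @param calls a (refined) `tl_calls` data.frame.
#' @param dir output directory.
#' @param prefix file name stem.
#' @return invisibly, the paths written.
#' @export
write_calls <- function(calls, dir, prefix = "breakpoints") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(as.data.frame(calls), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(calls = as.data.frame(calls),
                            events = attr(calls, "events")),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(tsv, js)
  if (!is.null(calls$mt_junction) && nrow(calls)) {
    bed_mt <- file.path(dir, paste0(prefix, ".mt.bed"))
    utils::write.table(
      data.frame(calls$mt_chrom, calls$mt_junction, calls$mt_junction + 1L,
                 paste0("event", calls$event)),
      bed_mt, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    bed_wt <- file.path(dir, paste0(prefix, ".wt.bed"))
    utils::write.table(
      data.frame(chrom = c(calls$left_chr, calls$right_chr),
                 start = c(calls$left_canonical_end, calls$right_start - 1L),
                 end = c(calls$left_canonical_end + 1L, calls$right_start),
                 name = paste0("event", c(calls$event, calls$event))),
      bed_wt, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, bed_mt, bed_wt)
  }
  invisible(paths)
}
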