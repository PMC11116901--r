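# ---- 2-bit k-mer machinery ----------------------------------------------
# k-mers are encoded as base-4 numbers in doubles; k <= 25 keeps codes exact
# (4^25 < 2^53).

.base_codes <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L; m[utf8ToInt("T")] <- 3L
  m
})

.encode_bases <- function(s) .base_codes[utf8ToInt(s)]

# forward and reverse-complement k-mer codes for every start position
.kmer_codes <- function(b, k) {
  n <- length(b) - k + 1L
  if (n < 1L) return(list(fwd = numeric(0), rc = numeric(0)))
  fwd <- numeric(n); rc <- numeric(n)
  for (j in seq_len(k)) {
    bj <- b[j:(j + n - 1L)]
    fwd <- fwd + bj * 4^(k - j)
    rc <- rc + (3 - bj) * 4^(j - 1L)
  }
  list(fwd = fwd, rc = rc)
}

.genome_kmers <- function(genome, k) {
  per <- lapply(genome$seq, function(s) .kmer_codes(.encode_bases(s), k))
  n <- vapply(per, function(x) length(x$fwd), integer(1))
  list(chrom = rep(genome$karyotype$chrom, n),
       pos = unlist(lapply(n, seq_len), use.names = FALSE),
       fwd = unlist(lapply(per, `[[`, "fwd"), use.names = FALSE),
       rc = unlist(lapply(per, `[[`, "rc"), use.names = FALSE))
}

#' Build a unique k-mer anchor index
#'
#' Indexes every k-mer that occurs exactly once on the forward strand of the
#' genome. Reverse-complement hits against the index are still found during
#' chaining and flagged as minus-strand anchors. `k` must be odd so that no
#' k-mer is its own reverse complement.
#'
#' @param genome a `tl_genome`.
#' @param k k-mer length: odd, between 5 and 25 (default 21).
#' @return an object of class `tl_anchor_index`.
#' @export
build_anchor_index <- function(genome, k = 21L) {
  k <- as.integer(k)
  if (k < 5L || k > 25L || k %% 2L == 0L)
    stop("k must be odd and between 5 and 25")
  if (k > min(genome$karyotype$length))
    stop("k exceeds the shortest chromosome")
  km <- .genome_kmers(genome, k)
  dup <- duplicated(km$fwd) | duplicated(km$fwd, fromLast = TRUE)
  keep <- which(!dup)
  structure(list(k = k,
                 code = km$fwd[keep],
                 chrom_levels = genome$karyotype$chrom,
                 chrom = match(km$chrom[keep], genome$karyotype$chrom),
                 pos = km$pos[keep],
                 n_total = length(km$fwd),
                 genome_karyotype = genome$karyotype),
            class = "tl_anchor_index")
}

#' @export
print.tl_anchor_index <- function(x, ...) {
  cat("<tl_anchor_index> k=", x$k, ", ", length(x$code),
      " unique k-mers of ", x$n_total, " (",
      round(100 * length(x$code) / x$n_total, 1), "%)\n", sep = "")
  invisible(x)
}

#' Chain shared unique k-mer anchors into synteny blocks
#'
#' Matches unique k-mers of the mutant genome against a wild-type anchor
#' index and chains co-oriented anchors with consistent diagonal into maximal
#' colinear blocks. A chain is broken when the wild-type chromosome or strand
#' changes, when the distance to the previous anchor exceeds `max_gap` on
#' either genome, or when the alignment diagonal shifts by more than
#' `indel_slack`. Blocks are reported with 0-based half-open coordinates on
#' both genomes, sorted by mutant coordinates, and are non-overlapping on the
#' mutant genome.
#'
#' @param index a `tl_anchor_index` built from the wild-type genome.
#' @param mt_genome the mutant `tl_genome`.
#' @param max_gap maximum distance between consecutive anchors (bp).
#' @param min_anchors minimum anchors per reported block.
#' @param indel_slack maximum tolerated diagonal shift within a block (bp).
#' @return a data.frame of class `tl_blocks` with columns `mt_chrom`,
#'   `mt_start`, `mt_end`, `strand`, `wt_chrom`, `wt_start`, `wt_end`,
#'   `anchor_count`, plus block-edge anchor coordinates used for breakpoint
#'   refinement (`mt_first`, `mt_last`, `wt_first`, `wt_last`, 1-based).
#' @export
chain_anchors <- function(index, mt_genome, max_gap = 2000L,
                          min_anchors = 10L, indel_slack = 50L) {
  stopifnot(inherits(index, "tl_anchor_index"),
            inherits(mt_genome, "tl_genome"))
  k <- index$k
  if (max_gap <= k) stop("max_gap must exceed k")
  km <- .genome_kmers(mt_genome, k)
  dup <- duplicated(km$fwd) | duplicated(km$fwd, fromLast = TRUE)

  hit_f <- match(km$fwd, index$code)
  hit_r <- match(km$rc, index$code)
  use_f <- which(!is.na(hit_f) & !dup)
  use_r <- which(!is.na(hit_r) & !dup & is.na(hit_f))
  idx <- c(hit_f[use_f], hit_r[use_r])
  mt_levels <- mt_genome$karyotype$chrom
  mt_chrom <- match(c(km$chrom[use_f], km$chrom[use_r]), mt_levels)
  mt_pos <- c(km$pos[use_f], km$pos[use_r])
  wt_chrom <- index$chrom[idx]
  wt_pos <- index$pos[idx]
  plus <- rep(c(TRUE, FALSE), c(length(use_f), length(use_r)))
  n <- length(mt_pos)
  if (n == 0L) return(.empty_blocks(k))

  ord <- order(mt_chrom * 2^32 + mt_pos)
  mt_chrom <- mt_chrom[ord]; mt_pos <- mt_pos[ord]
  wt_chrom <- wt_chrom[ord]; wt_pos <- wt_pos[ord]
  plus <- plus[ord]

  same <- c(FALSE, mt_chrom[-1] == mt_chrom[-n] &
                   wt_chrom[-1] == wt_chrom[-n] & plus[-1] == plus[-n])
  dmt <- c(NA_real_, mt_pos[-1] - mt_pos[-n])
  dwt <- c(NA_real_, wt_pos[-1] - wt_pos[-n])
  dir_ok <- ifelse(plus, dwt > 0, dwt < 0)
  ok <- same & dmt <= max_gap & abs(dwt) <= max_gap & dir_ok &
    abs(abs(dwt) - dmt) <= indel_slack
  ok[is.na(ok)] <- FALSE
  chain <- cumsum(!ok)

  first <- which(!ok)                       # chain start indices
  last <- c(first[-1L] - 1L, n)             # chain end indices
  size <- last - first + 1L
  keep <- size >= min_anchors
  first <- first[keep]; last <- last[keep]; size <- size[keep]
  if (!length(first)) return(.empty_blocks(k))
  # within a chain mt_pos is ascending; wt_pos ascending on + / descending on -
  wlo <- ifelse(plus[first], wt_pos[first], wt_pos[last])
  whi <- ifelse(plus[first], wt_pos[last], wt_pos[first])
  blocks <- data.frame(
    mt_chrom = mt_levels[mt_chrom[first]],
    mt_start = mt_pos[first] - 1L, mt_end = mt_pos[last] + k - 1L,
    strand = ifelse(plus[first], "+", "-"),
    wt_chrom = index$chrom_levels[wt_chrom[first]],
    wt_start = wlo - 1L, wt_end = whi + k - 1L,
    anchor_count = size,
    mt_first = mt_pos[first], mt_last = mt_pos[last],
    wt_first = wt_pos[first], wt_last = wt_pos[last],
    stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$mt_chrom, blocks$mt_start), , drop = FALSE]
  rownames(blocks) <- NULL
  # adjacent blocks may share up to k-1 bp (or a micro-homology) on the
  # mutant genome; trim starts so reported intervals do not overlap
  if (nrow(blocks) > 1L) {
    for (i in 2:nrow(blocks)) {
      if (blocks$mt_chrom[i] == blocks$mt_chrom[i - 1L])
        blocks$mt_start[i] <- max(blocks$mt_start[i], blocks$mt_end[i - 1L])
    }
  }
  attr(blocks, "k") <- k
  class(blocks) <- c("tl_blocks", "data.frame")
  blocks
}

.empty_blocks <- function(k) {
  b <- data.frame(mt_chrom = character(), mt_start = integer(),
                  mt_end = integer(), strand = character(),
                  wt_chrom = character(), wt_start = integer(),
                  wt_end = integer(), anchor_count = integer(),
                  mt_first = integer(), mt_last = integer(),
                  wt_first = integer(), wt_last = integer(),
                  stringsAsFactors = FALSE)
  attr(b, "k") <- k
  class(b) <- c("tl_blocks", "data.frame")
  b
}

#' Write synteny blocks as a PAF-like TSV
#' @param blocks a `tl_blocks` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  cols <- c("mt_chrom", "mt_start", "mt_end", "strand",
            "wt_chrom", "wt_start", "wt_end", "anchor_count")
  utils::write.table(blocks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
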