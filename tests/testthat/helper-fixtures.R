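# Shared in-code fixtures. Unit tests run on a small 4 x 30 kb karyotype;
# the desk-scale 11 x 200 kb conditions are exercised in test-acceptance.R.

small_genome <- function(seed = 101, n = 4L, len = 30000L, gc = 0.35) {
  generate_wt_genome(n, len, gc, seed = seed)
}

# a mid-chromosome reciprocal exchange on the small genome
small_exchange <- function(del_a = 0L, del_b = 0L, ins_a = "", motif_a = "",
                           chr_a = "Chr2", pos_a = 12000L,
                           chr_b = "Chr3", pos_b = 18000L) {
  exchange_spec(chr_a, pos_a, chr_b, pos_b,
                edit_a = junction_edit(del_prox = del_a, insertion = ins_a,
                                       motif = motif_a),
                edit_b = junction_edit(del_prox = del_b))
}

# full small-scale comparison: returns wt, mt, truth, refined calls
small_comparison <- function(res, k = 21L, max_gap = 2000L,
                             min_anchors = 10L, min_block_len = 1000L) {
  idx <- build_anchor_index(res$wt, k = k)
  blocks <- chain_anchors(idx, res$mt, max_gap = max_gap,
                          min_anchors = min_anchors)
  calls <- call_translocations(blocks, min_block_len = min_block_len)
  refine_breakpoints(calls, res$wt, res$mt)
}

# reconstruct a mutant chromosome from its truth segment map + junction
# insertions (tiling invariant oracle)
rebuild_from_truth <- function(truth, wt, chrom) {
  segs <- truth$chrom_map[[chrom]]
  juncs <- truth$junctions[truth$junctions$mt_chrom == chrom, , drop = FALSE]
  juncs <- juncs[order(juncs$boundary), , drop = FALSE]
  parts <- character(0)
  for (i in seq_len(nrow(segs))) {
    if (i > 1L && nzchar(juncs$insertion[i - 1L]))
      parts <- c(parts, juncs$insertion[i - 1L])
    parts <- c(parts, substr(wt$seq[[segs$source[i]]], segs$start[i],
                             segs$end[i]))
  }
  paste(parts, collapse = "")
}

# compare called junctions against truth at base precision
junctions_match_truth <- function(calls, truth) {
  key <- function(chrom, pos) paste(chrom, pos)
  setequal(key(truth$junctions$mt_chrom, truth$junctions$canonical_pos),
           key(calls$mt_chrom, calls$mt_junction))
}

# brute-force longest-common-substring segmentation oracle (tiny inputs).
# Greedily removes the longest substring of mt_seq that occurs in any wt
# chromosome, until shorter than min_len; returns mt intervals + wt source.
lcs_segments <- function(wt_seqs, mt_seq, min_len = 100L) {
  n <- nchar(mt_seq)
  covered <- rep(FALSE, n)
  segs <- list()
  all_subs <- function(s, L) {
    m <- nchar(s)
    if (m < L) return(character(0))
    substring(s, 1:(m - L + 1L), L:m)
  }
  repeat {
    # uncovered runs of mt
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    open <- which(!runs$values & runs$lengths >= min_len)
    if (!length(open)) break
    best <- NULL
    for (oi in open) {
      frag <- substr(mt_seq, starts[oi], ends[oi])
      # binary search max common length with any wt chromosome
      lo <- min_len; hi <- nchar(frag); best_L <- 0L; best_sub <- NULL
      while (lo <= hi) {
        mid <- (lo + hi) %/% 2L
        subs <- all_subs(frag, mid)
        hit <- NULL
        for (w in names(wt_seqs)) {
          inw <- subs %in% all_subs(wt_seqs[[w]], mid)
          if (any(inw)) { hit <- list(w = w, s = subs[which(inw)[1L]]); break }
        }
        if (!is.null(hit)) { best_L <- mid; best_sub <- hit; lo <- mid + 1L }
        else hi <- mid - 1L
      }
      if (best_L > 0L && (is.null(best) || best_L > best$L))
        best <- list(L = best_L, sub = best_sub, frag_start = starts[oi],
                     frag = frag)
    }
    if (is.null(best)) break
    at <- regexpr(best$sub$s, best$frag, fixed = TRUE)[1L]
    mt_s <- best$frag_start + at - 1L
    wt_at <- regexpr(best$sub$s, wt_seqs[[best$sub$w]], fixed = TRUE)[1L]
    segs[[length(segs) + 1L]] <- data.frame(
      mt_start = mt_s, mt_end = mt_s + best$L - 1L,
      wt_chrom = best$sub$w, wt_start = wt_at,
      stringsAsFactors = FALSE)
    covered[mt_s:(mt_s + best$L - 1L)] <- TRUE
  }
  out <- do.call(rbind, segs)
  out[order(out$mt_start), , drop = FALSE]
}

# brute-force in-silico PCR oracle: exact scan of every position
brute_pcr <- function(seq, f, r, max_product = 2000L) {
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  sites <- function(p) {
    hits <- integer(0)
    L <- nchar(p)
    for (i in seq_len(nchar(seq) - L + 1L))
      if (substr(seq, i, i + L - 1L) == p) hits <- c(hits, i)
    hits
  }
  prods <- list()
  for (p in unique(c(f, r))) for (q in unique(c(f, r))) {
    for (s1 in sites(p)) for (s2 in sites(rc(q))) {
      e2 <- s2 + nchar(q) - 1L
      if (s2 >= s1 && e2 - s1 + 1L <= max_product &&
          e2 - s1 + 1L >= nchar(p))
        prods[[length(prods) + 1L]] <- c(start = s1, end = e2)
    }
  }
  if (!length(prods)) return(data.frame(start = integer(), end = integer()))
  unique(as.data.frame(do.call(rbind, prods)))
}
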