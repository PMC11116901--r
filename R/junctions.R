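#' Characterize refined translocation junctions
#'
#' For each refined breakpoint call, reports the deletion suffered by each
#' wild-type donor at the junction, any inserted sequence, and the junction
#' micro-homology with its joining-class assignment.
#'
#' Deletions are measured as wild-type coverage gaps: `deletion_left` is the
#' number of left-donor bases between the last base matched at this junction
#' and the donor's resumption elsewhere in the mutant genome (the reciprocal
#' partner junction), `deletion_right` symmetrically for the right donor.
#' This reproduces the per-recombinant-chromosome deletion sizes used in
#' breakpoint sequencing studies. Micro-homology is the maximal exact
#' sequence at the join present at the breakpoint flank of both donors
#' (capped at 50 bp); the junction is classed `microhomology_mediated` when
#' its length reaches `mh_threshold` (default 2 bp; a single shared base is
#' uninformative), otherwise `blunt`.
#'
#' @param calls refined `tl_calls` (all junctions from one WT/MT comparison;
#'   partner junctions are needed to measure deletions).
#' @param wt_genome,mt_genome the compared genomes.
#' @param flank flank length available for junction analysis (>= 50 bp).
#' @param mh_threshold minimum micro-homology length for the
#'   micro-homology-mediated class.
#' @return a data.frame of class `tl_junctions` with one row per junction:
#'   `event`, `mt_chrom`, `mt_junction`, `left_chr`, `right_chr`,
#'   `deletion_left`, `deletion_right`, `insertion_seq`,
#'   `microhomology_len`, `microhomology_seq`, `joining_class`.
#' @export
characterize_junctions <- function(calls, wt_genome, mt_genome,
                                   flank = 500L, mh_threshold = 2L) {
  stopifnot(inherits(calls, "tl_calls"))
  if (flank < 50L) stop("flank must be >= 50 bp")
  if (is.null(calls$mt_junction) || anyNA(calls$mt_junction))
    stop("calls must be refined first (see refine_breakpoints); ",
         "unresolved confidence intervals cannot be characterized")
  mh_cap <- min(50L, flank)
  ends <- data.frame(chrom = calls$left_chr, pos = calls$left_full_end)
  starts <- data.frame(chrom = calls$right_chr, pos = calls$right_start)
  del_after <- function(chrom, pos) {
    cand <- starts$pos[starts$chrom == chrom & starts$pos > pos]
    if (!length(cand)) return(NA_integer_)
    as.integer(min(cand) - pos - 1L)
  }
  del_before <- function(chrom, pos) {
    cand <- ends$pos[ends$chrom == chrom & ends$pos < pos]
    if (!length(cand)) return(NA_integer_)
    as.integer(pos - max(cand) - 1L)
  }
  mh_len <- pmin(calls$mh_len, mh_cap)
  rep <- data.frame(
    event = calls$event,
    mt_chrom = calls$mt_chrom,
    mt_junction = calls$mt_junction,
    left_chr = calls$left_chr,
    right_chr = calls$right_chr,
    deletion_left = mapply(del_after, calls$left_chr, calls$left_full_end),
    deletion_right = mapply(del_before, calls$right_chr, calls$right_start),
    insertion_seq = calls$insertion,
    microhomology_len = mh_len,
    microhomology_seq = substr(calls$mh_seq, 1L, mh_cap),
    stringsAsFactors = FALSE)
  rep$joining_class <- ifelse(rep$microhomology_len >= mh_threshold,
                              "microhomology_mediated", "blunt")
  rownames(rep) <- NULL
  class(rep) <- c("tl_junctions", "data.frame")
  rep
}

#' Characterize a single junction
#'
#' Convenience wrapper around [characterize_junctions()]. Deletion sizes
#' require the partner junctions of the same comparison; pass them via
#' `all_calls`, otherwise deletions that cannot be measured are `NA`.
#'
#' @param refined one-row refined `tl_calls`.
#' @param wt_genome,mt_genome the compared genomes.
#' @param all_calls all refined calls from the comparison (defaults to
#'   `refined` alone).
#' @inheritParams characterize_junctions
#' @return a one-row `tl_junctions` data.frame.
#' @export
characterize_junction <- function(refined, wt_genome, mt_genome,
                                  flank = 500L, mh_threshold = 2L,
                                  all_calls = refined) {
  full <- characterize_junctions(all_calls, wt_genome, mt_genome,
                                 flank = flank, mh_threshold = mh_threshold)
  i <- which(full$mt_chrom == refined$mt_chrom[1L] &
             full$mt_junction == refined$mt_junction[1L])
  full[i[1L], , drop = FALSE]
}

#' Summarize junction reports per event
#'
#' @param reports a `tl_junctions` data.frame.
#' @return a data.frame with one row per event: junction count, deletion
#'   range (over the per-junction proximal-donor deletions), and counts of
#'   blunt vs micro-homology-mediated junctions.
#' @export
summarize_junctions <- function(reports) {
  stopifnot(inherits(reports, "tl_junctions"), nrow(reports) >= 1L)
  sp <- split(seq_len(nrow(reports)), reports$event)
  out <- lapply(names(sp), function(e) {
    r <- reports[sp[[e]], ]
    data.frame(event = e, n_junctions = nrow(r),
               deletion_min = suppressWarnings(min(r$deletion_left,
                                                   na.rm = TRUE)),
               deletion_max = suppressWarnings(max(r$deletion_left,
                                                   na.rm = TRUE)),
               n_blunt = sum(r$joining_class == "blunt"),
               n_microhomology = sum(r$joining_class ==
                                     "microhomology_mediated"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write junction reports as TSV and JSON
#' @param reports a `tl_junctions` data.frame.
#' @param dir output directory.
#' @param prefix file name stem.
#' @return invisibly, the paths written.
#' @export
write_junctions <- function(reports, dir, prefix = "junctions") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(as.data.frame(reports), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(as.data.frame(reports), js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
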