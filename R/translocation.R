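#' Junction edit specification
#'
#' Describes the NHEJ-style sequence edits applied at one recombinant
#' junction: bases resected from the junction-proximal flank of the retained
#' (left) segment, bases resected from the distal flank of the incoming
#' (right) segment, an inserted sequence, and an optional micro-homology
#' motif. When `motif` is nonempty the generator rewrites both wild-type
#' flanks so the motif abuts the break on each donor, and the derived
#' junction retains exactly one copy of the motif spanning the join.
#'
#' @param del_prox bases removed from the proximal (left) flank (>= 0).
#' @param del_dist bases removed from the distal (right) flank (>= 0).
#' @param insertion inserted nucleotide string (possibly empty, A/C/G/T).
#' @param motif micro-homology motif (possibly empty, A/C/G/T).
#' @return a list of class `tl_junction_edit`.
#' @export
junction_edit <- function(del_prox = 0L, del_dist = 0L, insertion = "",
                          motif = "") {
  if (del_prox < 0 || del_dist < 0) stop("deletions must be >= 0")
  if (grepl("[^ACGT]", insertion)) stop("insertion must be A/C/G/T")
  if (grepl("[^ACGT]", motif)) stop("motif must be A/C/G/T")
  if (nzchar(insertion) && nzchar(motif))
    stop("a junction cannot carry both an insertion and a retained motif")
  structure(list(del_prox = as.integer(del_prox),
                 del_dist = as.integer(del_dist),
                 insertion = insertion, motif = motif),
            class = "tl_junction_edit")
}

#' Reciprocal exchange specification
#'
#' One cut-and-swap between two chromosomes. `pos_a`/`pos_b` are 1-based
#' positions of the last base retained on the proximal segment of each donor.
#' The exchange produces two junctions: the derived chromosome whose proximal
#' part comes from `chr_a` (edited by `edit_a`) and the one whose proximal
#' part comes from `chr_b` (edited by `edit_b`).
#'
#' @param chr_a,chr_b donor chromosome ids.
#' @param pos_a,pos_b 1-based breakpoint positions (last retained base of the
#'   proximal segment), strictly inside the chromosome (>= 2, <= length - 1).
#' @param edit_a edits at the `chr_a`-proximal junction (a [junction_edit()]).
#' @param edit_b edits at the `chr_b`-proximal junction.
#' @return a list of class `tl_exchange`.
#' @export
exchange_spec <- function(chr_a, pos_a, chr_b, pos_b,
                          edit_a = junction_edit(), edit_b = junction_edit()) {
  if (identical(chr_a, chr_b)) stop("exchange requires two distinct chromosomes")
  stopifnot(inherits(edit_a, "tl_junction_edit"),
            inherits(edit_b, "tl_junction_edit"))
  structure(list(chr_a = chr_a, pos_a = as.integer(pos_a),
                 chr_b = chr_b, pos_b = as.integer(pos_b),
                 edit_a = edit_a, edit_b = edit_b),
            class = "tl_exchange")
}

# ---- internal segment-map engine ---------------------------------------

# a derived chromosome: list(segs = data.frame(source, start, end),
#                            juncs = list of junction records between segs)
.init_state <- function(genome) {
  ders <- lapply(seq_len(nrow(genome$karyotype)), function(i) {
    list(segs = data.frame(source = genome$karyotype$chrom[i], start = 1L,
                           end = genome$karyotype$length[i],
                           stringsAsFactors = FALSE),
         juncs = list())
  })
  names(ders) <- genome$karyotype$chrom
  list(wt = genome$seq, ders = ders,
       protected = data.frame(chrom = character(), pos = integer()),
       rewrites = data.frame(chrom = character(), pos = integer(),
                             base = character(), stringsAsFactors = FALSE))
}

.locate <- function(state, chrom, pos) {
  for (nm in names(state$ders)) {
    segs <- state$ders[[nm]]$segs
    hit <- which(segs$source == chrom & segs$start <= pos & segs$end >= pos)
    if (length(hit)) return(list(der = nm, seg = hit[1L]))
  }
  stop("position ", chrom, ":", pos,
       " is not covered by any retained segment (conflicting exchange specs?)")
}

# split a derived chromosome at WT position `pos` inside segment `i`;
# returns list(head=, tail=) each a (segs, juncs) pair
.split_der <- function(der, i, pos) {
  segs <- der$segs
  if (pos < segs$start[i] || pos >= segs$end[i])
    stop("breakpoint ", segs$source[i], ":", pos,
         " must fall strictly inside a retained segment")
  head_segs <- segs[seq_len(i), , drop = FALSE]
  head_segs$end[i] <- pos
  tail_segs <- segs[i:nrow(segs), , drop = FALSE]
  tail_segs$start[1L] <- pos + 1L
  list(head = list(segs = head_segs,
                   juncs = der$juncs[seq_len(max(i - 1L, 0L))]),
       tail = list(segs = tail_segs,
                   juncs = der$juncs[seq_along(der$juncs) >= i]))
}

.join <- function(head, junc, tail) {
  list(segs = rbind(head$segs, tail$segs),
       juncs = c(head$juncs, list(junc), tail$juncs))
}

.mark_protected <- function(state, chrom, from, to) {
  state$protected <- rbind(state$protected,
                           data.frame(chrom = chrom, pos = from:to))
  state
}

.rewrite_wt <- function(state, chrom, pos, replacement) {
  s <- state$wt[[chrom]]
  substr(s, pos, pos + nchar(replacement) - 1L) <- replacement
  state$wt[[chrom]] <- s
  state$rewrites <- rbind(state$rewrites,
                          data.frame(chrom = chrom,
                                     pos = pos:(pos + nchar(replacement) - 1L),
                                     base = strsplit(replacement, "")[[1]],
                                     stringsAsFactors = FALSE))
  state
}

# build one junction record + apply flank trims and motif rewrites
.make_junction <- function(state, head, tail, edit, exch_id) {
  hs <- head$segs; ts <- tail$segs
  li <- nrow(hs)
  left_chr <- hs$source[li]
  left_end <- hs$end[li] - edit$del_prox
  if (left_end < hs$start[li])
    stop("proximal deletion of ", edit$del_prox,
         " bp spans past the retained segment on ", left_chr)
  hs$end[li] <- left_end
  right_chr <- ts$source[1L]
  right_start <- ts$start[1L] + edit$del_dist
  if (right_start > ts$end[1L])
    stop("distal deletion of ", edit$del_dist,
         " bp spans past the retained segment on ", right_chr)
  mh <- nchar(edit$motif)
  if (mh > 0L) {
    if (left_end - mh < 1L || right_start + mh - 1L > ts$end[1L])
      stop("micro-homology motif does not fit inside the junction flanks")
    state <- .rewrite_wt(state, left_chr, left_end - mh + 1L, edit$motif)
    state <- .rewrite_wt(state, right_chr, right_start, edit$motif)
    state <- .mark_protected(state, left_chr, left_end - mh + 1L, left_end)
    state <- .mark_protected(state, right_chr, right_start,
                             right_start + mh - 1L)
  }
  ts$start[1L] <- right_start + mh   # one motif copy retained (left copy)
  junc <- list(exchange = exch_id, left_chr = left_chr, left_end = left_end,
               right_chr = right_chr, right_start = right_start,
               del_prox = edit$del_prox, del_dist = edit$del_dist,
               insertion = edit$insertion, mh_len = mh, motif = edit$motif)
  list(state = state, head = list(segs = hs, juncs = head$juncs),
       tail = list(segs = ts, juncs = tail$juncs), junc = junc)
}

.apply_exchange <- function(state, sp, exch_id) {
  la <- .locate(state, sp$chr_a, sp$pos_a)
  lb <- .locate(state, sp$chr_b, sp$pos_b)
  if (la$der == lb$der)
    stop("both breakpoints fall on the same derived chromosome; ",
         "an exchange needs two distinct molecules")
  da <- .split_der(state$ders[[la$der]], la$seg, sp$pos_a)
  db <- .split_der(state$ders[[lb$der]], lb$seg, sp$pos_b)
  ja <- .make_junction(state, da$head, db$tail, sp$edit_a, exch_id)
  state <- ja$state
  jb <- .make_junction(state, db$head, da$tail, sp$edit_b, exch_id)
  state <- jb$state
  new1 <- .join(ja$head, ja$junc, ja$tail)
  new2 <- .join(jb$head, jb$junc, jb$tail)
  state$ders[[la$der]] <- NULL
  state$ders[[lb$der]] <- NULL
  state$ders[[paste0(".tmp", exch_id, "a")]] <- new1
  state$ders[[paste0(".tmp", exch_id, "b")]] <- new2
  state
}

.derived_name <- function(der) {
  segs <- der$segs
  if (nrow(segs) == 1L) return(segs$source[1L])
  paste0(segs$source[1L], "^", sub("^Chr", "", segs$source[2L]))
}

# assemble one derived chromosome; returns list(seq=, juncs=df of mt coords)
.assemble <- function(state, der) {
  parts <- character(0)
  pos <- 0L
  jt <- list()
  for (i in seq_len(nrow(der$segs))) {
    if (i > 1L) {
      j <- der$juncs[[i - 1L]]
      boundary <- pos
      if (nzchar(j$insertion)) {
        parts <- c(parts, j$insertion)
        pos <- pos + nchar(j$insertion)
      }
      jt[[length(jt) + 1L]] <- data.frame(
        boundary = boundary, canonical_pos = boundary - j$mh_len,
        exchange = j$exchange,
        left_chr = j$left_chr, left_end = j$left_end,
        right_chr = j$right_chr, right_start = j$right_start,
        del_prox = j$del_prox, del_dist = j$del_dist,
        insertion = j$insertion, mh_len = j$mh_len, motif = j$motif,
        stringsAsFactors = FALSE)
    }
    s <- der$segs[i, ]
    parts <- c(parts, substr(state$wt[[s$source]], s$start, s$end))
    pos <- pos + (s$end - s$start + 1L)
  }
  list(seq = paste(parts, collapse = ""),
       juncs = if (length(jt)) do.call(rbind, jt) else NULL)
}

.is_protected <- function(state, chrom, pos) {
  any(state$protected$chrom == chrom & state$protected$pos == pos)
}

.other_base <- function(forbidden) {
  ok <- setdiff(c("A", "C", "G", "T"), forbidden)
  if (!length(ok)) stop("no admissible replacement base at a junction flank")
  ok[1L]
}

.char_at <- function(s, i) substr(s, i, i)

# Enforce that every designed junction is sequence-unambiguous: an exact-match
# extension from either flank must stop exactly at the designed breakpoint
# (plus the designed motif). Chance single-base homology is removed by
# rewriting one WT base adjacent to the break; the mutant is rebuilt and all
# junctions re-checked until stable.
.sanitize <- function(state, max_iter = 100L) {
  # One rewrite per pass, with the mutant reassembled in between. A wild-type
  # base adjacent to a break may be constrained by more than one junction
  # (e.g. both junctions of a reciprocal exchange with a 1 bp deletion), so
  # the replacement base is chosen against the union of all constraints on
  # that position.
  for (iter in seq_len(max_iter)) {
    built <- lapply(state$ders, function(d) .assemble(state, d))
    # collect every stop constraint: the wild-type base at `target` must
    # differ from the mutant base `forbid`, else exact-match extension runs
    # past the designed breakpoint
    cons <- list()
    for (nm in names(built)) {
      jt <- built[[nm]]$juncs
      if (is.null(jt)) next
      mt <- built[[nm]]$seq
      for (r in seq_len(nrow(jt))) {
        j <- jt[r, ]
        ilen <- nchar(j$insertion)
        cont <- j$left_end + 1L
        if (cont <= nchar(state$wt[[j$left_chr]]) &&
            j$boundary + 1L <= nchar(mt))
          cons[[length(cons) + 1L]] <- list(
            chrom = j$left_chr, pos = cont,
            forbid = .char_at(mt, j$boundary + 1L), side = "left",
            alt_chrom = j$right_chr, alt_pos = j$right_start + j$mh_len,
            ins = ilen > 0L, der = nm)
        prev <- j$right_start - 1L
        srm1 <- j$boundary - j$mh_len + ilen
        if (prev >= 1L && srm1 >= 1L)
          cons[[length(cons) + 1L]] <- list(
            chrom = j$right_chr, pos = prev,
            forbid = .char_at(mt, srm1), side = "right",
            alt_chrom = j$left_chr, alt_pos = j$left_end - j$mh_len,
            ins = ilen > 0L, der = nm)
      }
    }
    if (!length(cons)) return(state)
    viol <- Filter(function(cn)
      .char_at(state$wt[[cn$chrom]], cn$pos) == cn$forbid, cons)
    if (!length(viol)) return(state)
    v <- viol[[1L]]
    forbidden <- vapply(
      Filter(function(cn) cn$chrom == v$chrom && cn$pos == v$pos, cons),
      `[[`, character(1), "forbid")
    if (!.is_protected(state, v$chrom, v$pos)) {
      cur <- .char_at(state$wt[[v$chrom]], v$pos)
      state <- .rewrite_wt(state, v$chrom, v$pos,
                           .other_base(c(cur, forbidden)))
    } else if (!v$ins) {
      # the flank base is motif-protected: edit the wild-type origin of the
      # offending mutant base instead
      if (v$alt_pos < 1L || .is_protected(state, v$alt_chrom, v$alt_pos))
        stop("cannot sanitize junction on ", v$der,
             ": both flank bases are motif-protected")
      alt_forbid <- vapply(
        Filter(function(cn) cn$chrom == v$alt_chrom && cn$pos == v$alt_pos,
               cons), `[[`, character(1), "forbid")
      cur <- .char_at(state$wt[[v$alt_chrom]], v$alt_pos)
      state <- .rewrite_wt(state, v$alt_chrom, v$alt_pos,
                           .other_base(c(cur, v$forbid, alt_forbid,
                                         .char_at(state$wt[[v$chrom]],
                                                  v$pos))))
    } else stop("insertion at junction on ", v$der,
                " coincides with a motif-protected flank")
  }
  stop("junction sanitization did not converge")
}

# component decomposition of exchanges over donor chromosomes
.event_components <- function(specs) {
  chroms <- unique(unlist(lapply(specs, function(s) c(s$chr_a, s$chr_b))))
  comp <- stats::setNames(seq_along(chroms), chroms)
  for (s in specs) {
    ca <- comp[[s$chr_a]]; cb <- comp[[s$chr_b]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  split(names(comp), comp)
}

.apply_translocation <- function(genome, specs, event_id, sanitize = TRUE) {
  stopifnot(inherits(genome, "tl_genome"))
  for (s in specs) {
    for (side in c("a", "b")) {
      chr <- s[[paste0("chr_", side)]]; pos <- s[[paste0("pos_", side)]]
      if (!chr %in% genome$karyotype$chrom) stop("no such chromosome: ", chr)
      len <- genome$karyotype$length[genome$karyotype$chrom == chr]
      if (pos < 2L || pos > len - 1L)
        stop("breakpoint ", chr, ":", pos,
             " must be strictly inside the chromosome (2..length-1)")
    }
  }
  state <- .init_state(genome)
  for (i in seq_along(specs)) state <- .apply_exchange(state, specs[[i]], i)
  if (sanitize) state <- .sanitize(state)

  # final naming and WT-karyotype ordering
  nms <- vapply(state$ders, .derived_name, character(1))
  if (anyDuplicated(nms)) stop("derived chromosome names collide: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  names(state$ders) <- nms
  first_src <- vapply(state$ders, function(d) d$segs$source[1L], character(1))
  ord <- order(match(first_src, genome$karyotype$chrom))
  state$ders <- state$ders[ord]

  built <- lapply(state$ders, function(d) .assemble(state, d))
  mt <- tl_genome(vapply(built, `[[`, character(1), "seq"))

  chrom_map <- lapply(state$ders, function(d) {
    data.frame(source = d$segs$source, start = d$segs$start,
               end = d$segs$end, strand = "+", stringsAsFactors = FALSE)
  })
  jlist <- lapply(names(built), function(nm) {
    jt <- built[[nm]]$juncs
    if (is.null(jt)) return(NULL)
    cbind(data.frame(mt_chrom = nm, stringsAsFactors = FALSE), jt)
  })
  junctions <- do.call(rbind, Filter(Negate(is.null), jlist))
  rownames(junctions) <- NULL

  # expected analyzer-measured coverage gaps per junction
  starts <- data.frame(chrom = junctions$right_chr, pos = junctions$right_start)
  fs <- vapply(state$ders, function(d) d$segs$source[1L], character(1))
  starts <- rbind(starts, data.frame(chrom = fs, pos = 1L))
  ends <- data.frame(chrom = junctions$left_chr, pos = junctions$left_end)
  le <- vapply(state$ders, function(d) d$segs$source[nrow(d$segs)], character(1))
  lp <- vapply(state$ders, function(d) d$segs$end[nrow(d$segs)], integer(1))
  ends <- rbind(ends, data.frame(chrom = le, pos = lp))
  gap_after <- function(chrom, pos) {
    cand <- starts$pos[starts$chrom == chrom & starts$pos > pos]
    if (!length(cand)) return(NA_integer_)
    as.integer(min(cand) - pos - 1L)
  }
  gap_before <- function(chrom, pos) {
    cand <- ends$pos[ends$chrom == chrom & ends$pos < pos]
    if (!length(cand)) return(NA_integer_)
    as.integer(pos - max(cand) - 1L)
  }
  junctions$gap_left <- mapply(gap_after, junctions$left_chr,
                               junctions$left_end)
  junctions$gap_right <- mapply(gap_before, junctions$right_chr,
                                junctions$right_start)

  comps <- .event_components(specs)
  events <- data.frame(
    component = seq_along(comps),
    kind = vapply(comps, function(ch)
      if (length(ch) >= 3L) "complex_chain" else "reciprocal", character(1)),
    chromosomes = vapply(comps, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)

  truth <- structure(
    list(event_id = event_id, kind = if (nrow(events) == 1L) events$kind[1L]
         else "multiple", events = events,
         chrom_map = chrom_map, junctions = junctions,
         wt_rewrites = state$rewrites,
         wt_length = genome_length(genome), mt_length = genome_length(mt)),
    class = "tl_truth")
  list(mt = mt, wt = tl_genome(state$wt), truth = truth)
}

#' Apply a reciprocal translocation to a genome
#'
#' Replaces the two donor chromosomes by two derived chromosomes, each the
#' proximal segment of one donor joined to the distal segment of the other,
#' with the junction edits given in the exchange specification. If a junction
#' carries a micro-homology motif, both wild-type flanks are rewritten so the
#' motif abuts the break on each donor, and the derived junction retains one
#' copy. By default the generator also *sanitizes* junctions: single wild-type
#' bases adjacent to each break are rewritten where a chance match would make
#' the breakpoint sequence-ambiguous, so that truth coordinates, deletion
#' sizes and micro-homology are exactly recoverable (see the methods
#' vignette).
#'
#' @param genome a wild-type `tl_genome`.
#' @param spec an [exchange_spec()].
#' @param event_id event identifier string.
#' @param sanitize enforce sequence-unambiguous junctions (default TRUE).
#' @return a list with elements `mt` (mutant genome), `wt` (wild-type genome,
#'   possibly with rewritten junction flanks) and `truth` (a `tl_truth`
#'   record: derived chromosome segment maps, junction table with mutant
#'   coordinates, designed edits and expected coverage gaps).
#' @export
apply_reciprocal_translocation <- function(genome, spec, event_id = "event1",
                                           sanitize = TRUE) {
  stopifnot(inherits(spec, "tl_exchange"))
  .apply_translocation(genome, list(spec), event_id, sanitize)
}

#' Apply a chained or multiple translocation to a genome
#'
#' Applies two or more exchanges in order. Exchanges sharing a chromosome form
#' a chained complex event (the later cut falls on a derived chromosome
#' produced by an earlier exchange, as in a Chr1-Chr5-Chr11 chain); disjoint
#' exchanges are equivalent to independent reciprocal applications.
#'
#' @inheritParams apply_reciprocal_translocation
#' @param specs ordered list of [exchange_spec()] (length >= 2).
#' @return see [apply_reciprocal_translocation()].
#' @export
apply_complex_translocation <- function(genome, specs, event_id = "event1",
                                        sanitize = TRUE) {
  if (inherits(specs, "tl_exchange") || length(specs) < 2L)
    stop("a complex event needs >= 2 exchange specs; ",
         "use apply_reciprocal_translocation() for a single exchange")
  stopifnot(all(vapply(specs, inherits, logical(1), "tl_exchange")))
  .apply_translocation(genome, specs, event_id, sanitize)
}

#' Draw a random reciprocal exchange specification
#'
#' Used to generate randomized truth sets: two distinct chromosomes are
#' picked, breakpoints are drawn uniformly at least `margin` bp from the
#' chromosome ends, and each junction receives a proximal-flank deletion drawn
#' from `deletions`.
#'
#' @param genome a `tl_genome`.
#' @param seed integer seed.
#' @param deletions integer vector to sample deletion sizes from.
#' @param margin minimum distance of breakpoints from chromosome ends (bp).
#' @return an [exchange_spec()].
#' @export
random_reciprocal_event <- function(genome, seed, deletions = 0:25,
                                    margin = 10000L) {
  kt <- genome$karyotype
  with_seed(seed, {
    ch <- sample(kt$chrom, 2L)
    len <- kt$length[match(ch, kt$chrom)]
    pos <- vapply(len, function(L)
      sample(seq.int(margin, L - margin), 1L), numeric(1))
    dels <- sample(deletions, 2L, replace = TRUE)
    exchange_spec(ch[1L], pos[1L], ch[2L], pos[2L],
                  edit_a = junction_edit(del_prox = dels[1L]),
                  edit_b = junction_edit(del_prox = dels[2L]))
  })
}

#' @export
print.tl_truth <- function(x, ...) {
  cat("<tl_truth> event '", x$event_id, "' (", x$kind, "): ",
      nrow(x$junctions), " junctions on ",
      length(x$chrom_map), " derived chromosomes\n", sep = "")
  print(x$junctions[, c("mt_chrom", "canonical_pos", "left_chr", "left_end",
                        "right_chr", "right_start", "del_prox", "del_dist",
                        "mh_len")], row.names = FALSE)
  invisible(x)
}

#' Write a truth record to JSON and BED
#'
#' The JSON file carries the full truth record (segment maps, junction table,
#' wild-type rewrites). The BED file has one 0-based half-open interval per
#' junction on the mutant genome, covering the first base to the right of the
#' canonical (leftmost-placement) breakpoint.
#'
#' @param truth a `tl_truth`.
#' @param json_path output JSON path.
#' @param bed_path output BED path (default: same stem, .bed).
#' @return invisibly, the JSON path.
#' @export
write_truth <- function(truth, json_path,
                        bed_path = sub("\\.json$", ".bed", json_path)) {
  stopifnot(inherits(truth, "tl_truth"))
  payload <- unclass(truth)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  j <- truth$junctions
  bed <- data.frame(chrom = j$mt_chrom, start = j$canonical_pos,
                    end = j$canonical_pos + 1L,
                    name = paste0(truth$event_id, "_j", seq_len(nrow(j))))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(json_path)
}

#' Read a truth record from JSON
#' @param json_path path written by [write_truth()].
#' @return a `tl_truth`.
#' @export
read_truth <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  x$chrom_map <- lapply(x$chrom_map, as.data.frame)
  structure(x, class = "tl_truth")
}
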