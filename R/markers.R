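#' Primer design rules
#'
#' Defaults: primer length 20 (18-24 searched), GC 40-60%, melting
#' temperature by the Wallace rule (2 degrees per A/T, 4 per G/C) within
#' 55-65, amplicons 150-1000 bp with a gel-resolvable WT/MT size difference
#' of at least 100 bp. Primer uniqueness is exact-occurrence based: at most
#' one occurrence per genome, counting both strands.
#'
#' @param length preferred primer length.
#' @param length_range searched primer lengths.
#' @param gc_range allowed GC fraction range.
#' @param tm_range allowed Wallace melting temperature range (degrees C).
#' @param amplicon_range allowed product size range (bp).
#' @param min_size_diff minimum WT/MT amplicon size difference (bp).
#' @param max_product maximum product size scanned during in-silico PCR (bp).
#' @return a list of class `tl_primer_rules`.
#' @export
primer_rules <- function(length = 20L, length_range = c(18L, 24L),
                         gc_range = c(0.40, 0.60), tm_range = c(55, 65),
                         amplicon_range = c(150L, 1000L),
                         min_size_diff = 100L, max_product = 1500L) {
  structure(list(length = length, length_range = length_range,
                 gc_range = gc_range, tm_range = tm_range,
                 amplicon_range = amplicon_range,
                 min_size_diff = min_size_diff, max_product = max_product),
            class = "tl_primer_rules")
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.gc_frac <- function(s) {
  v <- utf8ToInt(s)
  sum(v == 71L | v == 67L) / length(v)
}

#' Wallace-rule melting temperature
#' @param s primer sequence.
#' @return Tm in degrees C: 2(A+T) + 4(G+C).
#' @export
tm_wallace <- function(s) {
  v <- utf8ToInt(s)
  gcn <- sum(v == 71L | v == 67L)
  2 * (length(v) - gcn) + 4 * gcn
}

# occurrences of `seq` in a DNAStringSet, both strands
.count_sites <- function(seq, sset)
  sum(Biostrings::vcountPattern(seq, sset)) +
  sum(Biostrings::vcountPattern(.revcomp(seq), sset))

.primer_ok <- function(seq, rules, wt_set, mt_set) {
  gc <- .gc_frac(seq)
  if (gc < rules$gc_range[1] || gc > rules$gc_range[2]) return(FALSE)
  tm <- tm_wallace(seq)
  if (tm < rules$tm_range[1] || tm > rules$tm_range[2]) return(FALSE)
  if (.count_sites(seq, wt_set) > 1L) return(FALSE)
  if (.count_sites(seq, mt_set) > 1L) return(FALSE)
  TRUE
}

.design_fail <- function(msg)
  stop(errorCondition(paste0("marker design failed: ", msg),
                      class = c("tl_design_error", "error", "condition")))

.new_primer <- function(name, seq, chrom, start, strand)
  list(name = name, seq = seq, chrom = chrom, start = start, strand = strand,
       tm = tm_wallace(seq), gc = .gc_frac(seq))

# find a forward primer whose 3' end lies in [hi_end - span, hi_end],
# or a reverse primer starting in [lo_start, lo_start + span]
.scan_primer <- function(seq_str, chrom, anchor, dir, rules, wt_set, mt_set,
                         name, span = 150L) {
  L <- rules$length
  for (off in 0:span) {
    if (dir == "F") {
      end <- anchor - off
      start <- end - L + 1L
      if (start < 1L) break
      cand <- substr(seq_str, start, end)
      if (.primer_ok(cand, rules, wt_set, mt_set))
        return(.new_primer(name, cand, chrom, start, "+"))
    } else {
      start <- anchor + off
      end <- start + L - 1L
      if (end > nchar(seq_str)) break
      site <- substr(seq_str, start, end)
      cand <- .revcomp(site)
      if (.primer_ok(cand, rules, wt_set, mt_set))
        return(.new_primer(name, cand, chrom, start, "-"))
    }
  }
  NULL
}

#' Design a codominant breakpoint-spanning marker set
#'
#' For one refined breakpoint, designs a nonrecombinant pair (WT-F/R spanning
#' the wild-type breakpoint position on the left donor chromosome) and a
#' recombinant pair (MT-F/R spanning the junction on the derived chromosome).
#' Each primer must be unique per genome; a pair only amplifies templates on
#' which both primers sit convergently on one chromosome within the product
#' bound, so the WT pair amplifies only nonrecombinant templates and the MT
#' pair only recombinant templates. Together they type all three genotype
#' classes.
#'
#' @param wt_genome,mt_genome the compared genomes.
#' @param breakpoint one refined row of a `tl_calls` data.frame.
#' @param rules a [primer_rules()].
#' @param name marker name stem.
#' @return a list of class `tl_marker_set`: `wt_pair` and `mt_pair` (each
#'   F/R primers), expected amplicon lengths, and the breakpoint reference.
#' @export
design_breakpoint_markers <- function(wt_genome, mt_genome, breakpoint,
                                      rules = primer_rules(),
                                      name = "marker") {
  if (is.null(breakpoint$mt_junction) || is.na(breakpoint$mt_junction[1L]))
    .design_fail("breakpoint must be refined first")
  bp <- breakpoint[1L, ]
  wt_set <- Biostrings::DNAStringSet(wt_genome$seq)
  mt_set <- Biostrings::DNAStringSet(mt_genome$seq)
  mt_seq <- mt_genome$seq[[bp$mt_chrom]]
  wt_seq <- wt_genome$seq[[bp$left_chr]]
  J <- bp$mt_junction
  pa <- bp$left_canonical_end
  L <- rules$length
  pl_mt <- max(rules$amplicon_range[1] + 100L, 350L)
  pl_wt <- pl_mt + max(rules$min_size_diff, 250L)
  if (pl_wt > rules$amplicon_range[2])
    pl_wt <- rules$amplicon_range[2]
  if (pl_wt - pl_mt < rules$min_size_diff)
    .design_fail("amplicon range too narrow for a resolvable size difference")

  geom_ok <- function(center, seq_str, pl)
    center - pl >= 1L && center + pl <= nchar(seq_str)
  if (!geom_ok(J, mt_seq, pl_mt))
    .design_fail(paste0("junction at ", bp$mt_chrom, ":", J,
                        " is within one product length of a chromosome end"))
  if (!geom_ok(pa, wt_seq, pl_wt))
    .design_fail(paste0("wild-type breakpoint at ", bp$left_chr, ":", pa,
                        " is within one product length of a chromosome end"))

  mt_f <- .scan_primer(mt_seq, bp$mt_chrom, J - 30L, "F", rules,
                       wt_set, mt_set, paste0(name, "-MT-F"))
  if (is.null(mt_f)) .design_fail("no unique MT forward primer in the window")
  mt_r <- .scan_primer(mt_seq, bp$mt_chrom, mt_f$start + pl_mt - L, "R",
                       rules, wt_set, mt_set, paste0(name, "-MT-R"))
  if (is.null(mt_r) || mt_r$start <= J)
    .design_fail("no unique MT reverse primer spanning the junction")
  wt_f <- .scan_primer(wt_seq, bp$left_chr, pa - 30L, "F", rules,
                       wt_set, mt_set, paste0(name, "-WT-F"))
  if (is.null(wt_f)) .design_fail("no unique WT forward primer in the window")
  wt_r <- .scan_primer(wt_seq, bp$left_chr, wt_f$start + pl_wt - L, "R",
                       rules, wt_set, mt_set, paste0(name, "-WT-R"))
  if (is.null(wt_r) || wt_r$start <= pa)
    .design_fail("no unique WT reverse primer spanning the breakpoint")

  exp_mt <- mt_r$start + L - 1L - mt_f$start + 1L
  exp_wt <- wt_r$start + L - 1L - wt_f$start + 1L
  if (abs(exp_wt - exp_mt) < rules$min_size_diff)
    .design_fail("amplicon sizes not gel-resolvable")
  if (exp_mt < rules$amplicon_range[1] || exp_wt > rules$amplicon_range[2])
    .design_fail("amplicon size outside the allowed range")

  ms <- structure(
    list(name = name,
         event = if (!is.null(bp$event)) bp$event else NA,
         breakpoint = list(mt_chrom = bp$mt_chrom, mt_junction = J,
                           wt_chrom = bp$left_chr, wt_pos = pa),
         wt_pair = list(F = wt_f, R = wt_r),
         mt_pair = list(F = mt_f, R = mt_r),
         expected = list(wt = exp_wt, mt = exp_mt),
         rules = rules),
    class = "tl_marker_set")
  # verify codominant specificity on the design templates
  pw <- insilico_pcr(wt_genome, ms$wt_pair, rules$max_product)
  pm <- insilico_pcr(mt_genome, ms$wt_pair, rules$max_product)
  qw <- insilico_pcr(wt_genome, ms$mt_pair, rules$max_product)
  qm <- insilico_pcr(mt_genome, ms$mt_pair, rules$max_product)
  if (nrow(pw) != 1L || nrow(pm) != 0L || nrow(qw) != 0L || nrow(qm) != 1L)
    .design_fail("designed pairs are not template-specific")
  ms
}

#' @export
print.tl_marker_set <- function(x, ...) {
  cat("<tl_marker_set> ", x$name, " @ ", x$breakpoint$mt_chrom, ":",
      x$breakpoint$mt_junction, "\n", sep = "")
  for (p in c(x$wt_pair, x$mt_pair))
    cat(sprintf("  %-12s %s  %s:%d (%s)  Tm %.0f  GC %.0f%%\n", p$name,
                p$seq, p$chrom, p$start, p$strand, p$tm, 100 * p$gc))
  cat("  expected amplicons: WT ", x$expected$wt, " bp, MT ",
      x$expected$mt, " bp\n", sep = "")
  invisible(x)
}

#' Exact-match in-silico PCR
#'
#' Reports every product formed by a full-length exact binding of the two
#' primers on opposite strands of one chromosome, convergent, separated by at
#' most `max_product` bp. Mismatch-tolerant annealing is not modelled: a
#' single mismatch yields no product. Products are deduplicated by
#' coordinates.
#'
#' @param template a `tl_genome` or a list of them (e.g. the two haplotypes
#'   of a diploid individual).
#' @param primer_pair list with primers `F` and `R` (see
#'   [design_breakpoint_markers()]), or a character vector of two sequences.
#' @param max_product maximum product length (bp).
#' @return data.frame with columns `template`, `chrom`, `start`, `end`,
#'   `length` (1-based inclusive coordinates).
#' @export
insilico_pcr <- function(template, primer_pair, max_product = 1500L) {
  genomes <- if (inherits(template, "tl_genome")) list(template) else template
  stopifnot(all(vapply(genomes, inherits, logical(1), "tl_genome")))
  if (is.character(primer_pair))
    primer_pair <- list(F = list(seq = primer_pair[1]),
                        R = list(seq = primer_pair[2]))
  seqs <- unique(c(primer_pair$F$seq, primer_pair$R$seq))
  out <- list()
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    gname <- if (!is.null(names(genomes))) names(genomes)[gi] else
      paste0("template", gi)
    for (chrom in g$karyotype$chrom) {
      subj <- Biostrings::DNAString(g$seq[[chrom]])
      for (pseq in seqs) {
        fwd <- Biostrings::start(Biostrings::matchPattern(pseq, subj))
        if (!length(fwd)) next
        for (qseq in seqs) {
          rcq <- .revcomp(qseq)
          rev_m <- Biostrings::matchPattern(rcq, subj)
          rev_end <- Biostrings::end(rev_m)
          rev_start <- Biostrings::start(rev_m)
          if (!length(rev_end)) next
          for (s1 in fwd) for (j in seq_along(rev_end)) {
            e2 <- rev_end[j]
            if (rev_start[j] >= s1 && e2 - s1 + 1L <= max_product &&
                e2 - s1 + 1L >= nchar(pseq))
              out[[length(out) + 1L]] <- data.frame(
                template = gname, chrom = chrom, start = s1, end = e2,
                length = e2 - s1 + 1L, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(template = character(), chrom = character(),
                      start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out)[, c("template", "chrom", "start",
                                        "end", "length")])
  res <- res[order(res$template, res$chrom, res$start, res$end), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# amplicon presence (wt pair, mt pair) for a genotype class at one marker
.class_pattern <- function(genotype, marker, wt_genome, mt_genome) {
  tmpl <- switch(genotype,
                 NN = list(wt_genome),
                 NT = list(wt_genome, mt_genome),
                 TT = list(mt_genome),
                 stop("unknown genotype class: ", genotype))
  c(wt = nrow(insilico_pcr(tmpl, marker$wt_pair,
                           marker$rules$max_product)) > 0L,
    mt = nrow(insilico_pcr(tmpl, marker$mt_pair,
                           marker$rules$max_product)) > 0L)
}

.pattern_call <- function(wt_amp, mt_amp) {
  if (wt_amp && mt_amp) "heterozygous_TL"
  else if (wt_amp) "homozygous_WT"
  else if (mt_amp) "homozygous_TL"
  else "no_call"
}

#' Genotype a population with codominant breakpoint markers
#'
#' Runs in-silico PCR of each marker's WT and MT pairs on every individual's
#' diploid template and calls genotypes from amplicon presence: WT amplicon
#' only = homozygous wild type, both = heterozygous translocation, MT
#' amplicon only = homozygous translocation. Individuals whose calls conflict
#' across the two markers of one reciprocal event are flagged
#' recombinant-discordant and excluded from the counts.
#'
#' @param individuals data.frame with a column `individual` and one genotype
#'   column per event (values `NN`/`NT`/`TT`), as produced by
#'   [simulate_cross()]; the per-event genotype defines the individual's
#'   diploid template (NN = two wild-type haplotypes, etc.).
#' @param markers list of `tl_marker_set`, each tagged with the event its
#'   genotype column refers to via `event_column`.
#' @param wt_genome,mt_genome parental genomes.
#' @param event_columns character vector mapping each marker to a genotype
#'   column of `individuals` (recycled).
#' @return a list of class `tl_genotyping`: `calls` (long data.frame:
#'   individual, marker, amplicon pattern, call), `counts` (per-marker
#'   three-class counts), `excluded` (discordant individuals).
#' @export
genotype_population <- function(individuals, markers, wt_genome, mt_genome,
                                event_columns) {
  if (inherits(markers, "tl_marker_set")) markers <- list(markers)
  event_columns <- rep_len(event_columns, length(markers))
  calls <- list()
  for (mi in seq_along(markers)) {
    mk <- markers[[mi]]
    col <- event_columns[mi]
    if (!col %in% names(individuals))
      stop("individuals table lacks genotype column '", col, "'")
    pat <- lapply(c(NN = "NN", NT = "NT", TT = "TT"), .class_pattern,
                  marker = mk, wt_genome = wt_genome, mt_genome = mt_genome)
    g <- individuals[[col]]
    if (!all(g %in% c("NN", "NT", "TT")))
      stop("unknown genotype class labels in column '", col, "'")
    wt_amp <- vapply(g, function(x) pat[[x]][["wt"]], logical(1))
    mt_amp <- vapply(g, function(x) pat[[x]][["mt"]], logical(1))
    calls[[mi]] <- data.frame(
      individual = individuals$individual, marker = mk$name, event = col,
      wt_amplicon = wt_amp, mt_amplicon = mt_amp,
      call = mapply(.pattern_call, wt_amp, mt_amp),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  # discordance across markers of one event
  excluded <- character(0)
  for (ev in unique(calls$event)) {
    sub <- calls[calls$event == ev, ]
    if (length(unique(sub$marker)) < 2L) next
    tab <- tapply(sub$call, sub$individual,
                  function(x) length(unique(x)) > 1L)
    excluded <- union(excluded, names(tab)[tab])
  }
  kept <- calls[!calls$individual %in% excluded, ]
  counts <- do.call(rbind, lapply(split(kept, kept$marker), function(d) {
    data.frame(marker = d$marker[1L], n = nrow(d),
               homozygous_WT = sum(d$call == "homozygous_WT"),
               heterozygous_TL = sum(d$call == "heterozygous_TL"),
               homozygous_TL = sum(d$call == "homozygous_TL"),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  structure(list(calls = calls, counts = counts, excluded = excluded),
            class = "tl_genotyping")
}

#' @export
print.tl_genotyping <- function(x, ...) {
  cat("<tl_genotyping> ", length(unique(x$calls$individual)),
      " individuals, ", length(unique(x$calls$marker)), " markers",
      if (length(x$excluded)) paste0(" (", length(x$excluded),
                                     " discordant excluded)") else "",
      "\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write a primer panel as TSV
#' @param markers list of `tl_marker_set` (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primer_panel <- function(markers, path) {
  if (inherits(markers, "tl_marker_set")) markers <- list(markers)
  rows <- lapply(markers, function(m) {
    do.call(rbind, lapply(c(m$wt_pair, m$mt_pair), function(p)
      data.frame(marker = m$name, name = p$name, seq = p$seq,
                 chrom = p$chrom, pos = p$start, strand = p$strand,
                 tm = p$tm, gc = round(p$gc, 3),
                 expected_wt = m$expected$wt, expected_mt = m$expected$mt,
                 stringsAsFactors = FALSE)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
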