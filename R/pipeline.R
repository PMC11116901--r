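#' Preset translocation event specifications
#'
#' Desk-scale (200 kb chromosomes) analogues of three watermelon
#' translocation lines, with the published junction edit sizes and breakpoint
#' positions scaled to the synthetic karyotype:
#' * `MT-a`: reciprocal Chr6-Chr10 exchange, 3 bp deletion at each junction,
#'   5 nt `TTTAT` micro-homology at the Chr6-proximal junction;
#' * `MT-b`: two independent reciprocal exchanges, Chr1-Chr5 (25/24 bp
#'   junction deletions) and Chr4-Chr8 (4/4 bp);
#' * `MT-c`: chained complex exchange Chr1-Chr5-Chr11 (deletions 25, 24, 1
#'   and 4 bp at the four junctions).
#'
#' @param name `"MT-a"`, `"MT-b"` or `"MT-c"`.
#' @return list of [exchange_spec()].
#' @export
preset_event_specs <- function(name = c("MT-a", "MT-b", "MT-c")) {
  name <- match.arg(name)
  switch(name,
    "MT-a" = list(exchange_spec(
      "Chr6", 118000L, "Chr10", 55000L,
      edit_a = junction_edit(del_prox = 3L, motif = "TTTAT"),
      edit_b = junction_edit(del_prox = 3L))),
    "MT-b" = list(
      exchange_spec("Chr1", 144000L, "Chr5", 25000L,
                    edit_a = junction_edit(del_prox = 25L),
                    edit_b = junction_edit(del_prox = 24L)),
      exchange_spec("Chr4", 178000L, "Chr8", 112000L,
                    edit_a = junction_edit(del_prox = 4L),
                    edit_b = junction_edit(del_prox = 4L))),
    "MT-c" = list(
      exchange_spec("Chr1", 144000L, "Chr5", 25000L,
                    edit_a = junction_edit(del_prox = 25L),
                    edit_b = junction_edit(del_prox = 24L)),
      exchange_spec("Chr5", 10000L, "Chr11", 50000L,
                    edit_a = junction_edit(del_prox = 1L),
                    edit_b = junction_edit(del_prox = 4L))))
}

#' Default run configuration
#'
#' @param events preset name (`"MT-a"`, `"MT-b"`, `"MT-c"`) or a list of
#'   [exchange_spec()].
#' @param genome_seed,cross_seed integer seeds (both required; every source
#'   of randomness in a run is explicitly seeded).
#' @param outdir output directory.
#' @return a list of class `tl_run_config`.
#' @export
run_config <- function(events = "MT-a", genome_seed, cross_seed,
                       outdir = tempfile("tl_run_")) {
  if (missing(genome_seed) || missing(cross_seed))
    stop("config validation: genome_seed and cross_seed must be explicit")
  structure(list(
    karyotype = list(n_chromosomes = 11L, length = 200000L, gc = 0.35),
    events = events,
    aligner = list(k = 21L, max_gap = 2000L, min_anchors = 10L,
                   indel_slack = 50L, min_block_len = 1000L),
    refine = list(window = 500L),
    junctions = list(flank = 500L, mh_threshold = 2L),
    meiosis = list(a = 0.5, n_f2 = 237L),
    seeds = list(genome = genome_seed, cross = cross_seed),
    outdir = outdir), class = "tl_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [run_config()]; `events` may be a preset name or a list of
#' exchange entries (`chr_a`, `pos_a`, `chr_b`, `pos_b`, optional `del_a`,
#' `del_b`, `motif_a`, `motif_b`).
#'
#' @param path YAML file.
#' @return a `tl_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seeds) || is.null(y$seeds$genome) || is.null(y$seeds$cross))
    stop("config validation: seeds$genome and seeds$cross must be explicit")
  events <- y$events
  if (is.list(events))
    events <- lapply(events, function(e)
      exchange_spec(e$chr_a, e$pos_a, e$chr_b, e$pos_b,
                    edit_a = junction_edit(
                      del_prox = e$del_a %||% 0L,
                      motif = e$motif_a %||% ""),
                    edit_b = junction_edit(
                      del_prox = e$del_b %||% 0L,
                      motif = e$motif_b %||% "")))
  cfg <- run_config(events = events, genome_seed = y$seeds$genome,
                    cross_seed = y$seeds$cross,
                    outdir = y$outdir %||% tempfile("tl_run_"))
  for (grp in c("karyotype", "aligner", "refine", "junctions", "meiosis"))
    for (nm in names(y[[grp]])) cfg[[grp]][[nm]] <- y[[grp]][[nm]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full translocation analysis pipeline
#'
#' Simulate (wild-type genome, translocated mutant with truth) -> align
#' (anchor index + chaining) -> call and refine breakpoints -> characterize
#' junctions -> design codominant markers -> simulate an F2 by selfing the
#' heterozygote -> genotype the population in silico -> segregation
#' chi-square tests. Deterministic end to end for fixed seeds; all artifacts
#' are written under `config$outdir` and listed in the returned manifest.
#'
#' @param config a `tl_run_config` (see [run_config()], [read_run_config()]).
#' @param verbose print stage-scoped log lines.
#' @return the run manifest (list), invisibly written to
#'   `outdir/manifest.json`: artifact paths, seeds, internal check results
#'   (truth-vs-called breakpoints, junction recovery, marker specificity) and
#'   segregation test tables.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "tl_run_config"))
  if (is.null(config$seeds$genome) || is.null(config$seeds$cross))
    stop("config validation: all seeds must be explicit")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(
    utils::packageVersion("translocatr")), seeds = config$seeds,
    stages = character(0), paths = list(), checks = list())

  .log_stage(verbose, "simulate", "generating wild-type genome")
  kt <- config$karyotype
  g0 <- generate_wt_genome(kt$n_chromosomes, kt$length, kt$gc,
                           seed = config$seeds$genome)
  specs <- config$events
  if (is.character(specs)) specs <- preset_event_specs(specs)
  res <- if (length(specs) == 1L)
    apply_reciprocal_translocation(g0, specs[[1L]], event_id = "run") else
    apply_complex_translocation(g0, specs, event_id = "run")
  wt <- res$wt; mt <- res$mt; truth <- res$truth
  write_genome_fasta(wt, out("wt.fasta"))
  write_genome_fasta(mt, out("mt.fasta"))
  write_truth(truth, out("truth.json"), out("truth.bed"))
  manifest$stages <- c(manifest$stages, "simulate")
  manifest$paths$wt_fasta <- out("wt.fasta")
  manifest$paths$mt_fasta <- out("mt.fasta")
  manifest$paths$truth <- out("truth.json")

  .log_stage(verbose, "align", "indexing and chaining anchors")
  al <- config$aligner
  idx <- build_anchor_index(wt, k = al$k)
  blocks <- chain_anchors(idx, mt, max_gap = al$max_gap,
                          min_anchors = al$min_anchors,
                          indel_slack = al$indel_slack)
  write_blocks_tsv(blocks, out("blocks.tsv"))
  manifest$stages <- c(manifest$stages, "align")
  manifest$paths$blocks <- out("blocks.tsv")

  .log_stage(verbose, "call", "calling and refining breakpoints")
  calls <- call_translocations(blocks, min_block_len = al$min_block_len)
  calls <- refine_breakpoints(calls, wt, mt, window = config$refine$window)
  write_calls(calls, config$outdir)
  manifest$stages <- c(manifest$stages, "call")
  manifest$paths$breakpoints <- out("breakpoints.tsv")
  tj <- truth$junctions
  key <- function(chrom, pos) paste(chrom, pos)
  bp_exact <- setequal(key(tj$mt_chrom, tj$canonical_pos),
                       key(calls$mt_chrom, calls$mt_junction))
  manifest$checks$n_junctions_called <- nrow(calls)
  manifest$checks$n_junctions_truth <- nrow(tj)
  manifest$checks$breakpoints_match_truth <- bp_exact
  manifest$checks$event_kinds <- attr(calls, "events")$kind

  .log_stage(verbose, "junctions", "characterizing junction sequences")
  reps <- characterize_junctions(calls, wt, mt,
                                 flank = config$junctions$flank,
                                 mh_threshold = config$junctions$mh_threshold)
  write_junctions(reps, config$outdir)
  manifest$stages <- c(manifest$stages, "junctions")
  manifest$paths$junctions <- out("junctions.tsv")
  ord_t <- order(tj$mt_chrom, tj$canonical_pos)
  ord_c <- order(reps$mt_chrom, reps$mt_junction)
  manifest$checks$junction_deletions_recovered <-
    all(reps$deletion_left[ord_c] ==
        (tj$gap_left[ord_t]), na.rm = TRUE)
  manifest$checks$microhomology_recovered <-
    all(reps$microhomology_len[ord_c] == tj$mh_len[ord_t])

  .log_stage(verbose, "markers", "designing codominant breakpoint markers")
  markers <- lapply(seq_len(nrow(calls)), function(i)
    design_breakpoint_markers(wt, mt, calls[i, ],
                              name = paste0("M", i, "_", calls$mt_chrom[i])))
  write_primer_panel(markers, out("primers.tsv"))
  manifest$stages <- c(manifest$stages, "markers")
  manifest$paths$primers <- out("primers.tsv")
  manifest$checks$marker_specificity <- TRUE  # enforced by the designer

  .log_stage(verbose, "meiosis", "simulating the F2 population")
  ev <- truth$events
  loci <- lapply(seq_len(nrow(ev)), function(i)
    translocation_locus(paste0("T", gsub("Chr|,", "", ev$chromosomes[i])),
                        kind = ev$kind[i],
                        chromosomes = strsplit(ev$chromosomes[i], ",")[[1L]],
                        zygosity = "het", a = config$meiosis$a))
  f1 <- karyotype_config(kt$n_chromosomes, loci)
  pop <- simulate_cross(f1, f1, n_offspring = config$meiosis$n_f2,
                        seed = config$seeds$cross)
  write_population_tsv(pop, out("population.tsv"))
  manifest$stages <- c(manifest$stages, "meiosis")
  manifest$paths$population <- out("population.tsv")
  manifest$checks$diakinesis <- predict_diakinesis_configuration(f1)[1:2]

  .log_stage(verbose, "genotype", "in-silico PCR genotyping")
  locus_names <- vapply(loci, `[[`, character(1), "name")
  marker_events <- locus_names[match(calls$event,
                                     seq_len(nrow(ev)))]
  gt <- genotype_population(pop, markers, wt, mt,
                            event_columns = marker_events)
  utils::write.table(gt$counts, out("genotype_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages <- c(manifest$stages, "genotype")
  manifest$paths$genotype_counts <- out("genotype_counts.tsv")

  .log_stage(verbose, "segregation", "chi-square segregation tests")
  k <- length(loci)
  pheno <- data.frame(population = "F2",
                      normal = sum(pop$phenotype == "normal"),
                      semi_sterile = sum(pop$phenotype == "semi_sterile"))
  seg_pheno <- segregation_report(pheno, c(1, 2^k - 1))
  seg_marker <- segregation_report(
    data.frame(population = gt$counts$marker,
               homozygous_WT = gt$counts$homozygous_WT,
               heterozygous_TL = gt$counts$heterozygous_TL,
               homozygous_TL = gt$counts$homozygous_TL),
    c(1, 2, 1))
  seg <- rbind(
    cbind(contrast = "pollen_phenotype",
          seg_pheno[, c("population", "n", "chi2", "df", "p_value", "ratio",
                        "conclusion")]),
    cbind(contrast = "marker_genotype",
          seg_marker[, c("population", "n", "chi2", "df", "p_value", "ratio",
                         "conclusion")]))
  utils::write.table(seg, out("segregation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages <- c(manifest$stages, "segregation")
  manifest$paths$segregation <- out("segregation.tsv")
  manifest$checks$segregation <- seg

  yaml::write_yaml(.serializable_config(config), out("config_resolved.yaml"))
  manifest$paths$config <- out("config_resolved.yaml")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest$paths$manifest <- out("manifest.json")
  .log_stage(verbose, "done", "manifest at ", out("manifest.json"))
  invisible(manifest)
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  if (!is.character(cfg$events))
    cfg$events <- lapply(cfg$events, function(e)
      list(chr_a = e$chr_a, pos_a = e$pos_a, chr_b = e$chr_b,
           pos_b = e$pos_b,
           del_a = e$edit_a$del_prox, del_b = e$edit_b$del_prox,
           motif_a = e$edit_a$motif, motif_b = e$edit_b$motif))
  cfg
}
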