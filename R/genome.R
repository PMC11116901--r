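#' Construct a genome object
#'
#' A genome is an ordered set of named chromosome sequences restricted to the
#' A/C/G/T alphabet, together with a karyotype manifest (chromosome id and
#' length). This is the in-memory stand-in for a chromosome-scale assembly.
#'
#' @param seq named character vector of chromosome sequences (A/C/G/T only).
#' @return an object of class `tl_genome`: a list with elements `seq` (named
#'   character vector) and `karyotype` (data.frame with columns `chrom`,
#'   `length`).
#' @export
tl_genome <- function(seq) {
  if (length(seq) == 0L) stop("genome must contain at least one chromosome")
  ids <- names(seq)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(ids)) stop("chromosome ids must be unique")
  lens <- nchar(seq)
  if (any(lens == 0L)) stop("all chromosome sequences must be nonempty")
  if (any(grepl("[^ACGT]", seq)))
    stop("sequences must use the A/C/G/T alphabet only")
  structure(
    list(seq = seq,
         karyotype = data.frame(chrom = ids, length = as.integer(lens),
                                stringsAsFactors = FALSE)),
    class = "tl_genome")
}

#' @export
print.tl_genome <- function(x, ...) {
  cat("<tl_genome> ", nrow(x$karyotype), " chromosomes, ",
      format(sum(x$karyotype$length), big.mark = ","), " bp total\n", sep = "")
  print(utils::head(x$karyotype, 12), row.names = FALSE)
  invisible(x)
}

#' Total genome length in bp
#' @param genome a `tl_genome`.
#' @return integer total length.
#' @export
genome_length <- function(genome) sum(genome$karyotype$length)

#' GC fraction per chromosome
#' @param genome a `tl_genome`.
#' @return named numeric vector of per-chromosome GC fractions.
#' @export
gc_content <- function(genome) {
  vapply(genome$seq, function(s) {
    v <- utf8ToInt(s)
    sum(v == 71L | v == 67L) / length(v)
  }, numeric(1))
}

# Run expr with a private, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

#' Generate a random wild-type genome
#'
#' Draws each base independently with P(G) = P(C) = `gc`/2. Deterministic for
#' a fixed seed. The default desk-scale karyotype used throughout the package
#' is 11 chromosomes of 200 kb at GC 0.35, a scaled-down analogue of an
#' 11-pseudochromosome cucurbit assembly.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param lengths integer vector of chromosome lengths in bp (recycled to
#'   `n_chromosomes`); each must be >= 10000.
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return a `tl_genome` with chromosomes named `Chr1` ... `ChrN`.
#' @examples
#' g <- generate_wt_genome(2, 1e4, gc = 0.35, seed = 1)
#' gc_content(g)
#' @export
generate_wt_genome <- function(n_chromosomes, lengths, gc = 0.35, seed) {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1)
    stop("n_chromosomes must be >= 1")
  n_chromosomes <- as.integer(n_chromosomes)
  lengths <- as.integer(rep_len(lengths, n_chromosomes))
  if (any(lengths < 10000L)) stop("each chromosome length must be >= 10 kb")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    stop("gc must be strictly between 0 and 1")
  codes <- utf8ToInt("ACGT")                    # 65 67 71 84
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- with_seed(seed, {
    vapply(lengths, function(L)
      intToUtf8(codes[sample.int(4L, L, replace = TRUE, prob = prob)]),
      character(1))
  })
  names(seq) <- paste0("Chr", seq_len(n_chromosomes))
  tl_genome(seq)
}

#' Write a genome to FASTA
#'
#' Sequences are wrapped at 60 columns. Output is byte-identical across calls
#' for identical genomes.
#'
#' @param genome a `tl_genome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return a `tl_genome`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e)))
  seq <- as.character(x)
  # keep only the first word of each header, as assemblers do
  names(seq) <- sub("\\s.*$", "", names(seq))
  tl_genome(seq)
}
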