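#' Genome specification for the synthetic cohort generator
#'
#' A `genome_spec` fixes the coordinate system every synthetic cohort is
#' built on: chromosome names and lengths, gene intervals (0-based,
#' half-open), and the seed from which the ancestral sequence is drawn.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param genes Optional data.frame with columns `name`, `chrom`, `start`,
#'   `end` (0-based half-open). Intervals must lie inside their chromosome.
#' @param seed Integer seed controlling the ancestral sequence.
#'
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, genes = NULL, seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   names(chrom_lengths))
  if (any(is.na(chrom_lengths)) || any(chrom_lengths <= 0L))
    stop("invalid genome spec: chromosome lengths must be positive")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicate chromosome name")
  if (is.null(genes)) {
    genes <- data.frame(name = character(), chrom = character(),
                        start = integer(), end = integer())
  } else {
    genes <- as.data.frame(genes)
    stopifnot(all(c("name", "chrom", "start", "end") %in% names(genes)))
    if (any(!genes$chrom %in% names(chrom_lengths)))
      stop("gene on unknown chromosome")
    if (any(genes$start < 0L) || any(genes$end <= genes$start) ||
        any(genes$end > chrom_lengths[genes$chrom]))
      stop("gene interval outside its chromosome")
    if (anyDuplicated(genes$name)) stop("duplicate gene name")
  }
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_lengths), "chromosomes,",
      sum(as.numeric(x$chrom_lengths)), "bp,",
      nrow(x$genes), "genes, seed", x$seed, "\n")
  invisible(x)
}

#' Default desk-scale genome specification
#'
#' A scaled-down S. cerevisiae-like karyotype: five chromosomes, with the
#' smallest named after the real chromosomes (I, III, VI) that are
#' preferentially duplicated in aneuploid isolates, and a regular tiling of
#' 1-kb genes with 3-kb intergenic gaps. As in the real karyotype, no
#' single chromosome dominates the genome, which keeps the median-frame
#' coverage normalization robust to single-chromosome aneuploidy.
#'
#' @param scale Multiplier applied to every chromosome length.
#' @param seed Seed for the ancestral sequence.
#' @return A [genome_spec()].
#' @export
default_genome_spec <- function(scale = 1, seed = 1L) {
  lens <- round(c(chrI = 12000, chrIII = 16000, chrVI = 14000,
                  chrII = 26000, chrIV = 24000) * scale)
  genes <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(1000L, lens[[ch]] - 2000L, by = 4000L)
    data.frame(name = sprintf("%s_g%02d", sub("^chr", "", ch),
                              seq_along(starts)),
               chrom = ch, start = starts, end = starts + 1000L)
  }))
  genome_spec(lens, genes, seed = seed)
}

DNA_BASES <- c("A", "C", "G", "T")

## split a sequence string into a per-base character vector
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste0(x, collapse = "")
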