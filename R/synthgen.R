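#' Simulate the ancestral (reference) genome
#'
#' Draws one uniform random nucleotide sequence per chromosome of the spec.
#' The spec's seed makes the ancestor reproducible; the same spec always
#' yields byte-identical sequences.
#'
#' @param spec A [genome_spec()].
#' @return Named character vector, one sequence string per chromosome.
#' @export
simulate_ancestor <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  vapply(names(spec$chrom_lengths), function(ch) {
    chars_seq(sample(DNA_BASES, spec$chrom_lengths[[ch]], replace = TRUE))
  }, character(1))
}

## Set the RNG to a derived stream and return a restorer. Keeps all
## generator randomness keyed to explicit seeds without touching the
## caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Evolve a haplotype from a reference at a given divergence
#'
#' Places `Binomial(L, divergence)` substitutions uniformly at random on
#' each chromosome; substituted bases are drawn uniformly from the three
#' alternatives. No indels: the downstream statistics in scope are
#' substitution-based, so coordinates are preserved.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param divergence Expected substitutions per site, in `[0, 0.05]`.
#' @param seed Integer seed.
#' @return List with `seq` (named character vector) and `substitutions`
#'   (data.table: chrom, pos (1-based), ref, alt).
#' @export
evolve_haplotype <- function(reference, divergence, seed) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.05)
    stop("divergence must be in [0, 0.05]")
  mutate_sequences(reference, divergence, seed)
}

## Uniform substitution process shared by conspecific haplotype evolution
## and donor-genome generation (which needs divergences above the
## conspecific range).
mutate_sequences <- function(reference, divergence, seed) {
  rng <- local_rng(seed)
  on.exit(rng())
  subs <- vector("list", length(reference))
  seqs <- reference
  for (i in seq_along(reference)) {
    ch <- names(reference)[i]
    x <- seq_chars(reference[[i]])
    L <- length(x)
    n <- stats::rbinom(1L, L, divergence)
    if (n > 0L) {
      pos <- sort(sample.int(L, n))
      old <- x[pos]
      ## draw replacement uniformly among the three alternative bases
      alt_idx <- sample.int(3L, n, replace = TRUE)
      new <- vapply(seq_len(n), function(k)
        setdiff(DNA_BASES, old[k])[alt_idx[k]], character(1))
      x[pos] <- new
      subs[[i]] <- data.table::data.table(chrom = ch, pos = pos,
                                          ref = old, alt = new)
    }
    seqs[[i]] <- chars_seq(x)
  }
  subs <- if (all(vapply(subs, is.null, logical(1))))
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character())
  else data.table::rbindlist(subs)
  list(seq = seqs, substitutions = subs)
}

#' Combine two haplotypes into a diploid genome
#'
#' The diploid's true heterozygous sites are exactly the positions at which
#' the two haplotypes differ; they are tabulated as ground truth.
#'
#' @param hapA,hapB Named character vectors over the same chromosomes.
#' @return List with `hapA`, `hapB`, and `het_sites`
#'   (data.table: chrom, pos, a, b).
#' @export
make_diploid <- function(hapA, hapB) {
  if (!identical(names(hapA), names(hapB)) ||
      !identical(nchar(hapA), nchar(hapB)))
    stop("haplotypes must cover the same chromosomes at the same lengths")
  het <- lapply(names(hapA), function(ch) {
    a <- seq_chars(hapA[[ch]]); b <- seq_chars(hapB[[ch]])
    pos <- which(a != b)
    data.table::data.table(chrom = ch, pos = pos, a = a[pos], b = b[pos])
  })
  list(hapA = hapA, hapB = hapB, het_sites = data.table::rbindlist(het))
}

#' Plant aneuploidy, gene CNVs and alien fragments into a diploid genome
#'
#' Chromosome copy numbers and tandem gene copy factors only alter the
#' coverage model (pileup depth); alien fragments replace sequence on both
#' haplotypes with the donor's sequence over the same interval, so fragment
#' presence is a property of the isolate, matching how carriers are reported.
#'
#' @param diploid Output of [make_diploid()].
#' @param spec The [genome_spec()] the genome was built on.
#' @param basal_ploidy Basal ploidy of the isolate (1-4).
#' @param chrom_copies Named integer vector of absolute chromosome copy
#'   numbers; defaults to `basal_ploidy` everywhere. Must be >= 0.
#' @param gene_factors Named numeric vector of per-gene tandem copy factors
#'   (1 = unchanged, 0 = deleted, 2 = doubled, ...). Must be >= 0.
#' @param aliens data.frame of fragments to plant: columns `donor`, `chrom`,
#'   `start`, `end` (0-based half-open, length >= 1000), non-overlapping.
#' @param donor_seqs Named list of donor genomes (named character vectors on
#'   the same coordinates) supplying replacement sequence.
#' @return An `isolate_genome`: haplotypes, copy-number state and a truth
#'   record of everything planted.
#' @export
plant_features <- function(diploid, spec, basal_ploidy = 2L,
                           chrom_copies = NULL, gene_factors = NULL,
                           aliens = NULL, donor_seqs = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  chroms <- names(spec$chrom_lengths)
  cc <- stats::setNames(rep(as.numeric(basal_ploidy), length(chroms)), chroms)
  if (!is.null(chrom_copies)) {
    if (any(chrom_copies < 0)) stop("chromosome copy number < 0")
    cc[names(chrom_copies)] <- chrom_copies
  }
  gf <- stats::setNames(rep(1, nrow(spec$genes)), spec$genes$name)
  if (!is.null(gene_factors)) {
    if (any(gene_factors < 0)) stop("gene copy factor < 0")
    if (any(!names(gene_factors) %in% spec$genes$name))
      stop("unknown gene in gene_factors")
    gf[names(gene_factors)] <- gene_factors
  }
  hapA <- diploid$hapA; hapB <- diploid$hapB
  if (is.null(aliens)) {
    aliens <- data.frame(donor = character(), chrom = character(),
                         start = integer(), end = integer())
  } else {
    aliens <- as.data.frame(aliens)
    if (any(aliens$end - aliens$start < 1000))
      stop("alien fragments must be >= 1 kb")
    for (ch in unique(aliens$chrom)) {
      iv <- aliens[aliens$chrom == ch, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
        stop("overlapping alien fragments")
      if (any(iv$end > spec$chrom_lengths[[ch]]) || any(iv$start < 0))
        stop("alien fragment outside chromosome")
    }
    for (i in seq_len(nrow(aliens))) {
      d <- aliens$donor[i]
      if (is.null(donor_seqs[[d]])) stop("donor sequence missing: ", d)
      ch <- aliens$chrom[i]
      frag <- substr(donor_seqs[[d]][[ch]], aliens$start[i] + 1L, aliens$end[i])
      substr(hapA[[ch]], aliens$start[i] + 1L, aliens$end[i]) <- frag
      substr(hapB[[ch]], aliens$start[i] + 1L, aliens$end[i]) <- frag
    }
  }
  structure(list(
    hapA = hapA, hapB = hapB, spec = spec,
    basal_ploidy = as.integer(basal_ploidy),
    chrom_copies = cc, gene_factors = gf, aliens = aliens,
    het_sites = diploid$het_sites
  ), class = "isolate_genome")
}

#' Simulate a site pileup table for one isolate
#'
#' Per-site depth is Poisson with mean
#' `mean_depth * local copy number / basal ploidy`, where the local copy
#' number is the chromosome copy count times the gene copy factor at sites
#' inside amplified or deleted genes. Read bases are drawn from the two true
#' alleles in equal proportion; with probability `error_rate` a read reports
#' a uniform random base instead.
#'
#' @param genome An `isolate_genome` from [plant_features()].
#' @param reference Named character vector: the reference (ancestor) genome
#'   supplying the `ref` column.
#' @param mean_depth Mean coverage at basal copy number (>= 1).
#' @param error_rate Per-read error probability in `[0, 0.05]`.
#' @param seed Integer seed.
#' @return data.table: chrom, pos (1-based), ref, depth, A, C, G, T.
#' @export
simulate_pileups <- function(genome, reference, mean_depth, error_rate, seed) {
  stopifnot(inherits(genome, "isolate_genome"))
  if (mean_depth < 1) stop("mean depth must be >= 1")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error rate must be in [0, 0.05]")
  rng <- local_rng(seed)
  on.exit(rng())
  spec <- genome$spec
  out <- vector("list", length(spec$chrom_lengths))
  for (i in seq_along(spec$chrom_lengths)) {
    ch <- names(spec$chrom_lengths)[i]
    L <- spec$chrom_lengths[[i]]
    a1 <- seq_chars(genome$hapA[[ch]])
    a2 <- seq_chars(genome$hapB[[ch]])
    refb <- seq_chars(reference[[ch]])
    copy <- rep(genome$chrom_copies[[ch]], L)
    g <- spec$genes[spec$genes$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(g))) {
      f <- genome$gene_factors[[g$name[j]]]
      if (f != 1) copy[(g$start[j] + 1L):g$end[j]] <-
          copy[(g$start[j] + 1L):g$end[j]] * f
    }
    depth <- stats::rpois(L, mean_depth * copy / genome$basal_ploidy)
    counts <- rmultinom_sites(depth, a1, a2, error_rate)
    out[[i]] <- data.table::data.table(
      chrom = ch, pos = seq_len(L), ref = refb, depth = depth,
      A = counts[, 1L], C = counts[, 2L], G = counts[, 3L], T = counts[, 4L])
  }
  data.table::rbindlist(out)
}

## Vectorized multinomial base counts: sites grouped by genotype so each
## group shares one probability vector; counts drawn as sequential
## conditional binomials.
rmultinom_sites <- function(depth, a1, a2, error_rate) {
  n <- length(depth)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, DNA_BASES))
  geno <- paste0(pmin(a1, a2), pmax(a1, a2))
  for (g in unique(geno)) {
    idx <- which(geno == g)
    al <- c(substr(g, 1, 1), substr(g, 2, 2))
    p <- rep(error_rate / 4, 4)
    names(p) <- DNA_BASES
    p[al[1]] <- p[al[1]] + (1 - error_rate) / 2
    p[al[2]] <- p[al[2]] + (1 - error_rate) / 2
    rem <- depth[idx]
    left <- 1
    for (b in 1:3) {
      pk <- if (left > 0) min(p[b] / left, 1) else 0
      k <- stats::rbinom(length(idx), rem, pk)
      counts[idx, b] <- k
      rem <- rem - k
      left <- left - p[b]
    }
    counts[idx, 4L] <- rem
  }
  counts
}

#' Simulate a flow-cytometry relative DNA content value
#'
#' Emulates the per-isolate relative DNA content D (haploid reference = 1):
#' the true basal ploidy plus Gaussian measurement noise, truncated to be
#' positive.
#'
#' @param ploidy Basal ploidy in `{1, 2, 3, 4}`.
#' @param noise_sd Standard deviation of the measurement noise.
#' @param seed Integer seed.
#' @return A single positive numeric D value.
#' @export
simulate_flow_D <- function(ploidy, noise_sd = 0.05, seed = 1L) {
  if (!ploidy %in% 1:4) stop("ploidy must be in {1,2,3,4}")
  rng <- local_rng(seed)
  on.exit(rng())
  repeat {
    d <- ploidy + stats::rnorm(1L, 0, noise_sd)
    if (d > 0) return(d)
  }
}
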