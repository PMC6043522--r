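#' Simulate a multi-species donor/reference library
#'
#' Generates donor genomes on the same coordinate system as the reference by
#' applying the uniform substitution process at each taxon's divergence.
#' Conspecific entries (divergence below 1.7%, the maximum divergence
#' observed between S. cerevisiae lineages) serve as the scan's reference
#' strains; congeneric and outside-genus entries are introgression/HGT
#' donor candidates.
#'
#' @param reference Named character vector: the ancestral genome.
#' @param taxa data.frame with columns `taxon`, `tag` (one of
#'   `"conspecific"`, `"congeneric"`, `"outside_genus"`) and `divergence`.
#'   Conspecific divergence must be <= 0.017; donors must be in
#'   `[0.05, 0.40]`.
#' @param seed Integer seed.
#' @return A `reference_library`: list with `seqs` (named list of genomes)
#'   and `taxa` (data.table).
#' @export
simulate_donor_library <- function(reference, taxa, seed = 1L) {
  taxa <- data.table::as.data.table(taxa)
  stopifnot(all(c("taxon", "tag", "divergence") %in% names(taxa)))
  if (!any(taxa$tag == "conspecific"))
    stop("library must contain at least one conspecific reference")
  bad <- (taxa$tag == "conspecific" & taxa$divergence > 0.017) |
    (taxa$tag != "conspecific" &
       (taxa$divergence < 0.05 | taxa$divergence > 0.40))
  if (any(bad)) stop("taxon divergence outside allowed range: ",
                     paste(taxa$taxon[bad], collapse = ", "))
  rng <- local_rng(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(taxa))
  rng()
  seqs <- lapply(seq_len(nrow(taxa)), function(i) {
    if (taxa$divergence[i] == 0) reference
    else mutate_sequences(reference, taxa$divergence[i], sub_seeds[i])$seq
  })
  names(seqs) <- taxa$taxon
  structure(list(seqs = seqs, taxa = taxa), class = "reference_library")
}

default_library_taxa <- function() {
  data.frame(
    taxon = c("Scer_ref", "Scer_alt", "Spar", "Smik", "Klac", "Tdel"),
    tag = c("conspecific", "conspecific", "congeneric", "congeneric",
            "outside_genus", "outside_genus"),
    divergence = c(0, 0.008, 0.10, 0.15, 0.25, 0.30))
}

#' Simulate a full wild/domesticated cohort with ground truth
#'
#' Emulates the statistical structure of a yeast domestication cohort:
#' homozygous wild isolates grouped into divergent lineages (pairwise
#' divergence up to ~1.7%), domesticated isolates formed by outcrossing two
#' related wild haplotypes (heterozygosity up to ~0.5%), aneuploidy with a
#' bias towards small chromosomes, tandem gene copy-number changes, alien
#' fragments copied in from congeneric or outside-genus donors, Poisson
#' read-depth noise and uniform base-call errors. Everything planted is
#' recorded as ground truth.
#'
#' @param spec A [genome_spec()].
#' @param n_wild,n_domesticated Isolate counts per ecological group.
#' @param n_wild_lineages,n_dom_lineages Number of lineages per group;
#'   isolates are assigned round-robin.
#' @param wild_divergence Range (min, max) of per-lineage divergence from
#'   the ancestor; pairwise wild divergence is about the sum of two draws.
#' @param outcross_divergence Range of divergence between the two parental
#'   haplotypes of a domestication event (the expected heterozygosity of
#'   its isolates).
#' @param dom_founder_lineages Number of wild lineages the domestication
#'   events descend from. The default (1) emulates the strong domestication
#'   bottleneck: only a small fraction of the ancestral population founded
#'   the domesticated group, so its lineage diversity is well below the
#'   wild group's.
#' @param dom_amplified_gene Gene amplified preferentially in domesticated
#'   isolates (factor 2, probability `dom_cnv_rate`), emulating the
#'   fermentation-gene amplifications of domesticated lineages. `NULL`
#'   picks the first gene of the largest chromosome; `NA` disables.
#' @param dom_cnv_rate Probability a domesticated isolate amplifies
#'   `dom_amplified_gene`.
#' @param within_lineage_divergence Extra divergence applied independently
#'   to every isolate, keeping lineage mates distinct but tightly clustered.
#' @param aneuploidy_rate Probability an isolate is aneuploid.
#' @param small_chrom_bias If TRUE, aneuploid chromosomes are chosen with
#'   probability proportional to 1/length, mirroring the observed enrichment
#'   of extra copies on the smallest chromosomes.
#' @param gene_cnv_rate Probability an isolate carries one tandem gene CNV
#'   (factor drawn from 0, 2, 3).
#' @param aliens Optional data.frame of fragments to plant: `donor`,
#'   `chrom`, `start`, `end`, `carriers` (comma-separated isolate ids or
#'   integer count of random domesticated carriers). `NULL` plants the
#'   default two fragments (one congeneric, one outside-genus, 2-3
#'   domesticated carriers each); `NA` plants none.
#' @param library_taxa Taxa table for [simulate_donor_library()].
#' @param mean_depth Mean sequencing depth at basal copy number.
#' @param error_rate Per-read base error probability.
#' @param flow_noise_sd Gaussian noise of the flow-cytometry D value.
#' @param seed Master seed; all other randomness is derived from it.
#' @return A `synthetic_cohort`: spec, reference, isolate table, genomes,
#'   pileups, donor library, and a `truth` record.
#' @export
simulate_cohort <- function(spec = default_genome_spec(),
                            n_wild = 10L, n_domesticated = 10L,
                            n_wild_lineages = 10L, n_dom_lineages = 5L,
                            wild_divergence = c(0.001, 0.0085),
                            outcross_divergence = c(0.001, 0.005),
                            dom_founder_lineages = 1L,
                            dom_amplified_gene = NULL,
                            dom_cnv_rate = 0.9,
                            within_lineage_divergence = 2e-4,
                            aneuploidy_rate = 0.32,
                            small_chrom_bias = TRUE,
                            gene_cnv_rate = 0.3,
                            aliens = NULL,
                            library_taxa = default_library_taxa(),
                            mean_depth = 80, error_rate = 0.002,
                            flow_noise_sd = 0.05,
                            seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  n_wild_lineages <- min(n_wild_lineages, n_wild)
  n_dom_lineages <- if (n_domesticated > 0L)
    min(n_dom_lineages, n_domesticated) else 0L
  rng <- local_rng(seed)
  draw_seed <- function(n = 1L) sample.int(.Machine$integer.max - 1L, n)

  reference <- simulate_ancestor(spec)
  library <- simulate_donor_library(reference, library_taxa,
                                    seed = draw_seed())

  ## wild lineage haplotypes
  wl_div <- stats::runif(n_wild_lineages, wild_divergence[1],
                         wild_divergence[2])
  wl_seeds <- draw_seed(n_wild_lineages)
  wild_haps <- lapply(seq_len(n_wild_lineages), function(i)
    evolve_haplotype(reference, wl_div[i], wl_seeds[i])$seq)

  ## domestication events, founded from a restricted subset of wild
  ## lineages (the bottleneck). One ancestral outcross created a shared
  ## pair of parental haplotypes; each domesticated lineage descends from
  ## that pair with a little extra divergence, so the heterozygous sites
  ## of the founding cross keep segregating in every domesticated lineage
  ## (the shared-polymorphism signature of common admixed ancestry).
  dom_events <- list()
  if (n_dom_lineages > 0L) {
    n_founders <- min(dom_founder_lineages, n_wild_lineages)
    base <- wild_haps[[sample.int(n_founders, 1L)]]
    ## total parental divergence (the isolate heterozygosity target) is
    ## budgeted between the founding cross and the per-lineage layer
    d_total <- stats::runif(1L, outcross_divergence[1],
                            outcross_divergence[2])
    lineage_extra <- min(1e-3, d_total / 4)
    d_cross <- d_total - 2 * lineage_extra
    s <- draw_seed(2L)
    founderA <- evolve_haplotype(base, d_cross / 2, s[1])$seq
    founderB <- evolve_haplotype(base, d_cross / 2, s[2])$seq
    dom_events <- lapply(seq_len(n_dom_lineages), function(i) {
      sl <- draw_seed(2L)
      list(parentA = evolve_haplotype(founderA, lineage_extra, sl[1])$seq,
           parentB = evolve_haplotype(founderB, lineage_extra, sl[2])$seq,
           divergence = d_total)
    })
  }

  ids <- c(if (n_wild > 0L) sprintf("W%02d", seq_len(n_wild)),
           if (n_domesticated > 0L) sprintf("D%02d", seq_len(n_domesticated)))
  groups <- c(rep("wild", n_wild), rep("domesticated", n_domesticated))
  lineage <- c(
    if (n_wild > 0L)
      sprintf("CHN-%d", ((seq_len(n_wild) - 1L) %% n_wild_lineages) + 1L),
    if (n_domesticated > 0L)
      sprintf("DOM-%d", ((seq_len(n_domesticated) - 1L) %% n_dom_lineages) + 1L))
  n <- length(ids)

  ## per-isolate karyotype events
  chroms <- names(spec$chrom_lengths)
  w <- if (small_chrom_bias) 1 / as.numeric(spec$chrom_lengths)
       else rep(1, length(chroms))
  aneu <- stats::runif(n) < aneuploidy_rate
  aneu_events <- lapply(seq_len(n), function(i) {
    if (!aneu[i]) return(NULL)
    k <- 1L + stats::rbinom(1L, 1L, 0.3)
    chs <- sample(chroms, k, prob = w)
    delta <- sample(c(-1L, 1L, 2L), k, replace = TRUE,
                    prob = c(0.05, 0.80, 0.15))
    stats::setNames(delta, chs)
  })
  if (is.null(dom_amplified_gene) && nrow(spec$genes) > 0L) {
    big <- names(which.max(spec$chrom_lengths))
    dom_amplified_gene <- spec$genes$name[spec$genes$chrom == big][1L]
  }
  cnv_events <- lapply(seq_len(n), function(i) {
    ev <- numeric(0)
    if (nrow(spec$genes) > 0L && stats::runif(1) < gene_cnv_rate) {
      g <- sample(spec$genes$name, 1L)
      ev[g] <- sample(c(0, 2, 3), 1L, prob = c(0.3, 0.5, 0.2))
    }
    ## domestication-associated amplification (fermentation-gene analogue)
    if (groups[i] == "domesticated" && length(dom_amplified_gene) == 1L &&
        !is.na(dom_amplified_gene) && stats::runif(1) < dom_cnv_rate)
      ev[dom_amplified_gene] <- 2
    if (length(ev)) ev else NULL
  })

  ## alien fragments (planted in domesticated isolates by default)
  alien_tab <- resolve_alien_spec(aliens, spec, library,
                                  ids[groups == "domesticated"])

  iso_seeds <- matrix(draw_seed(4L * n), nrow = n)
  rng()

  genomes <- vector("list", n)
  pileups <- vector("list", n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    if (groups[i] == "wild") {
      base <- wild_haps[[match(lineage[i], sprintf("CHN-%d",
                                                   seq_len(n_wild_lineages)))]]
      hap <- evolve_haplotype(base, within_lineage_divergence,
                              iso_seeds[i, 1])$seq
      dip <- make_diploid(hap, hap)
    } else {
      ev <- dom_events[[match(lineage[i], sprintf("DOM-%d",
                                                  seq_len(n_dom_lineages)))]]
      s2 <- iso_seeds[i, 1]
      hapA <- evolve_haplotype(ev$parentA, within_lineage_divergence, s2)$seq
      hapB <- evolve_haplotype(ev$parentB, within_lineage_divergence,
                               s2 + 1L)$seq
      dip <- make_diploid(hapA, hapB)
    }
    cc <- NULL
    if (!is.null(aneu_events[[i]]))
      cc <- 2L + aneu_events[[i]]
    my_aliens <- alien_tab[alien_tab$carrier == ids[i],
                           c("donor", "chrom", "start", "end"), drop = FALSE]
    genomes[[i]] <- plant_features(
      dip, spec, basal_ploidy = 2L, chrom_copies = cc,
      gene_factors = cnv_events[[i]],
      aliens = if (nrow(my_aliens)) my_aliens else NULL,
      donor_seqs = library$seqs)
    pileups[[i]] <- simulate_pileups(genomes[[i]], reference, mean_depth,
                                     error_rate, iso_seeds[i, 2])
    D[i] <- simulate_flow_D(2L, flow_noise_sd, iso_seeds[i, 3])
  }
  names(genomes) <- names(pileups) <- ids

  isolates <- data.table::data.table(
    id = ids, group = groups, lineage = lineage,
    basal_ploidy = 2L, D = D)
  truth <- list(
    lineage_divergence = stats::setNames(wl_div, sprintf("CHN-%d",
                                         seq_len(n_wild_lineages))),
    parental_divergence = stats::setNames(
      vapply(dom_events, `[[`, numeric(1), "divergence"),
      if (n_dom_lineages > 0L) sprintf("DOM-%d", seq_len(n_dom_lineages))),
    chrom_copies = do.call(rbind, lapply(genomes, `[[`, "chrom_copies")),
    gene_factors = do.call(rbind, lapply(genomes, `[[`, "gene_factors")),
    aliens = alien_tab,
    het_sites = lapply(genomes, `[[`, "het_sites"))
  structure(list(spec = spec, reference = reference, isolates = isolates,
                 genomes = genomes, pileups = pileups, library = library,
                 truth = truth, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

## Expand the user-facing alien specification into one row per
## (fragment, carrier). Default: two fragments on the largest chromosome,
## one congeneric and one outside-genus donor, 2-3 domesticated carriers.
resolve_alien_spec <- function(aliens, spec, library, dom_ids) {
  empty <- data.frame(fragment = character(), donor = character(),
                      chrom = character(), start = integer(),
                      end = integer(), carrier = character())
  if (length(aliens) == 1L && !is.data.frame(aliens) && is.na(aliens))
    return(empty)
  if (is.null(aliens)) {
    if (length(dom_ids) < 2L) return(empty)
    big <- names(which.max(spec$chrom_lengths))
    cong <- library$taxa$taxon[library$taxa$tag == "congeneric"][1]
    outg <- library$taxa$taxon[library$taxa$tag == "outside_genus"][1]
    aliens <- data.frame(
      donor = c(cong, outg), chrom = big,
      start = c(10000L, 20000L), end = c(12500L, 23500L),
      carriers = c(min(3L, length(dom_ids)), 2L))
    if (any(aliens$end > spec$chrom_lengths[[big]]))
      stop("default alien fragments do not fit this genome spec; ",
           "pass an explicit `aliens` table")
  }
  aliens <- as.data.frame(aliens)
  rows <- lapply(seq_len(nrow(aliens)), function(i) {
    carr <- aliens$carriers[i]
    ids <- if (is.numeric(carr)) {
      if (carr > length(dom_ids)) stop("not enough isolates for carriers")
      dom_ids[((i - 1L) + seq_len(carr) - 1L) %% length(dom_ids) + 1L]
    } else strsplit(as.character(carr), ",")[[1]]
    data.frame(fragment = sprintf("frag%02d", i), donor = aliens$donor[i],
               chrom = aliens$chrom[i], start = aliens$start[i],
               end = aliens$end[i], carrier = ids)
  })
  do.call(rbind, rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$isolates), "isolates (",
      sum(x$isolates$group == "wild"), "wild,",
      sum(x$isolates$group == "domesticated"), "domesticated ), genome",
      sum(as.numeric(x$spec$chrom_lengths)), "bp, seed", x$seed, "\n")
  invisible(x)
}

#' Consensus assemblies of a synthetic cohort
#'
#' Returns one haplotype per isolate (the first), standing in for the de
#' novo assembly the introgression scan runs on; alien fragments are planted
#' on both haplotypes so either represents fragment presence.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Named list of named character vectors (isolate -> chromosome).
#' @export
cohort_assemblies <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(cohort$genomes, `[[`, "hapA")
}
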