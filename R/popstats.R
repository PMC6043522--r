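#' Nucleotide diversity and Watterson's theta for a group
#'
#' Each diploid call is expanded to two allele copies (heterozygous IUPAC
#' codes contribute one copy of each allele). A variant site qualifies when
#' at least `min_group_coverage` (default 80%) of the group's isolates are
#' non-missing there. Per-site diversity is the mean pairwise difference
#' over the allele copies present; pi is the sum over qualifying sites
#' divided by (qualifying variant sites + `invariant_sites`), so that a
#' genome-scale per-site quantity is recovered even though the matrix holds
#' only variant sites. Watterson's theta uses the count of segregating
#' qualifying sites and the harmonic number for `k = 2 x group size` allele
#' copies, over the same denominator.
#'
#' @param mat A `genotype_matrix`.
#' @param members Isolate ids of the group (>= 2).
#' @param min_group_coverage Minimum non-missing fraction per site.
#' @param invariant_sites Count of callable invariant sites to add to the
#'   denominator (0 gives per-variant-site quantities).
#' @return List: `group_size`, `n_alleles`, `S`, `pi`, `theta`,
#'   `analyzed_sites`.
#' @export
nucleotide_diversity <- function(mat, members, min_group_coverage = 0.80,
                                 invariant_sites = 0) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (length(members) < 2L) stop("group must have at least 2 isolates")
  if (!all(members %in% mat$isolates)) stop("unknown isolate in group")
  m <- mat$calls[members, , drop = FALSE]
  nonN <- m != "N"
  qual <- colMeans(nonN) >= min_group_coverage
  pi_sum <- 0
  S <- 0L
  for (j in which(qual)) {
    al <- as.vector(expand_alleles(m[, j]))
    al <- al[!is.na(al)]
    k <- length(al)
    if (k < 2L) next
    tab <- table(al)
    if (length(tab) > 1L) S <- S + 1L
    ## mean pairwise difference = 1 - sum(choose(n_a,2)) / choose(k,2)
    same <- sum(tab * (tab - 1) / 2)
    pi_sum <- pi_sum + (1 - same / (k * (k - 1) / 2))
  }
  denom <- sum(qual) + invariant_sites
  if (denom <= 0) stop("no analyzable sites")
  k_alleles <- 2L * length(members)
  a_k <- sum(1 / seq_len(k_alleles - 1L))
  list(group_size = length(members), n_alleles = k_alleles, S = S,
       pi = pi_sum / denom, theta = S / a_k / denom,
       analyzed_sites = denom)
}

#' Partition polymorphisms between two groups
#'
#' Classifies each retained site as a shared polymorphism (segregating in
#' both groups), a fixed difference (each group monomorphic for different
#' alleles), or a private polymorphism of one group. Sites with less than
#' `min_nonmissing` (default 75%) valid data over the pooled pair are
#' removed, as are singleton sites (a non-major allele carried by exactly
#' one isolate of the pooled pair). In `"ambiguity"` mode heterozygous
#' IUPAC codes are valid data and a site may carry more than two alleles;
#' in `"biallelic"` mode heterozygous calls are treated as missing and
#' sites with more than two alleles are excluded.
#'
#' @param mat A `genotype_matrix`.
#' @param groupA,groupB Disjoint isolate id vectors, each >= 2.
#' @param min_nonmissing Minimum valid-data fraction per site (pooled).
#' @param drop_singletons Remove singleton sites before classification.
#' @param mode `"ambiguity"` or `"biallelic"`.
#' @return List: `counts` (shared, fixed, privateA, privateB),
#'   `analyzed_sites`.
#' @export
polymorphism_partition <- function(mat, groupA, groupB,
                                   min_nonmissing = 0.75,
                                   drop_singletons = TRUE,
                                   mode = c("ambiguity", "biallelic")) {
  stopifnot(inherits(mat, "genotype_matrix"))
  mode <- match.arg(mode)
  if (length(intersect(groupA, groupB)) > 0L)
    stop("groups must be disjoint")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 isolates")
  mA <- mat$calls[groupA, , drop = FALSE]
  mB <- mat$calls[groupB, , drop = FALSE]
  if (mode == "biallelic") {
    mA[!mA %in% DNA_BASES] <- "N"
    mB[!mB %in% DNA_BASES] <- "N"
  }
  counts <- c(shared = 0L, fixed = 0L, privateA = 0L, privateB = 0L)
  analyzed <- 0L
  for (j in seq_len(ncol(mA))) {
    callsA <- mA[, j]; callsB <- mB[, j]
    pooled <- c(callsA, callsB)
    valid <- pooled != "N"
    if (mean(valid) < min_nonmissing) next
    alA <- as.vector(expand_alleles(callsA)); alA <- alA[!is.na(alA)]
    alB <- as.vector(expand_alleles(callsB)); alB <- alB[!is.na(alB)]
    alleles <- unique(c(alA, alB))
    if (mode == "biallelic" && length(alleles) > 2L) next
    if (drop_singletons && length(alleles) > 1L) {
      ## carrier isolates per allele over the pooled pair
      al_po <- expand_alleles(pooled)
      carr <- vapply(alleles, function(a)
        sum(al_po[1L, ] == a | al_po[2L, ] == a, na.rm = TRUE), numeric(1))
      major <- alleles[which.max(carr)]
      if (any(carr[alleles != major] == 1L)) next
    }
    analyzed <- analyzed + 1L
    polyA <- length(unique(alA)) > 1L
    polyB <- length(unique(alB)) > 1L
    if (polyA && polyB) counts["shared"] <- counts["shared"] + 1L
    else if (polyA) counts["privateA"] <- counts["privateA"] + 1L
    else if (polyB) counts["privateB"] <- counts["privateB"] + 1L
    else if (length(alA) && length(alB) && alA[1L] != alB[1L])
      counts["fixed"] <- counts["fixed"] + 1L
  }
  list(counts = counts, analyzed_sites = analyzed)
}

#' Shared-polymorphism percentage of a partition
#'
#' The share of classified sites (shared + fixed + private in either group)
#' that are shared polymorphisms, as a percentage.
#'
#' @param partition Output of [polymorphism_partition()].
#' @return Percentage (0-100), or `NA` with a warning when no site was
#'   classified.
#' @export
shared_fraction <- function(partition) {
  ct <- partition$counts
  denom <- sum(ct)
  if (denom == 0L) {
    warning("no classified sites; shared fraction undefined")
    return(NA_real_)
  }
  unname(ct["shared"] / denom * 100)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, for relating per-isolate
#' heterozygosity to phenotypes such as sporulation rate or spore
#' viability.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Spearman rho, or `NA` with a warning for a constant vector.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
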