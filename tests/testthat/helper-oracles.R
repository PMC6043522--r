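# Independent brute-force oracles used to pin the population-genetic
# statistics, plus small fixture builders. Oracles follow the definitions
# directly (explicit double loops), not the package's vectorized paths.

IUPAC_PAIRS <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

oracle_expand <- function(call) {
  if (call %in% c("A", "C", "G", "T")) return(c(call, call))
  if (call %in% names(IUPAC_PAIRS)) {
    p <- IUPAC_PAIRS[[call]]
    return(c(substr(p, 1, 1), substr(p, 2, 2)))
  }
  c(NA_character_, NA_character_)
}

# average pairwise difference per site over allele copies, via an explicit
# loop over all copy pairs; denominator = qualifying sites + invariant
oracle_pi <- function(m, min_cov = 0.80, invariant_sites = 0) {
  total <- 0
  qualifying <- 0L
  for (j in seq_len(ncol(m))) {
    calls <- m[, j]
    if (mean(calls != "N") < min_cov) next
    copies <- unlist(lapply(calls, oracle_expand))
    copies <- copies[!is.na(copies)]
    if (length(copies) < 2) next
    qualifying <- qualifying + 1L
    diff <- 0L; pairs <- 0L
    for (a in seq_len(length(copies) - 1)) for (b in (a + 1):length(copies)) {
      pairs <- pairs + 1L
      if (copies[a] != copies[b]) diff <- diff + 1L
    }
    total <- total + diff / pairs
  }
  total / (qualifying + invariant_sites)
}

oracle_segregating <- function(m, min_cov = 0.80) {
  S <- 0L
  for (j in seq_len(ncol(m))) {
    calls <- m[, j]
    if (mean(calls != "N") < min_cov) next
    copies <- unlist(lapply(calls, oracle_expand))
    copies <- copies[!is.na(copies)]
    if (length(unique(copies)) > 1) S <- S + 1L
  }
  S
}

oracle_theta <- function(S, n_allele_copies, sites) {
  S / sum(1 / seq_len(n_allele_copies - 1)) / sites
}

# Spearman rho as Pearson correlation of average ranks, from first
# principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# site-by-site enumeration of the shared/fixed/private definitions
oracle_partition <- function(mA, mB, min_nonmissing = 0.75,
                             drop_singletons = TRUE,
                             mode = "ambiguity") {
  counts <- c(shared = 0L, fixed = 0L, privateA = 0L, privateB = 0L)
  for (j in seq_len(ncol(mA))) {
    a <- mA[, j]; b <- mB[, j]
    if (mode == "biallelic") {
      a[!a %in% c("A", "C", "G", "T")] <- "N"
      b[!b %in% c("A", "C", "G", "T")] <- "N"
    }
    pooled <- c(a, b)
    if (mean(pooled != "N") < min_nonmissing) next
    copiesA <- unlist(lapply(a, oracle_expand)); copiesA <- copiesA[!is.na(copiesA)]
    copiesB <- unlist(lapply(b, oracle_expand)); copiesB <- copiesB[!is.na(copiesB)]
    alleles <- unique(c(copiesA, copiesB))
    if (mode == "biallelic" && length(alleles) > 2) next
    if (drop_singletons && length(alleles) > 1) {
      carriers <- sapply(alleles, function(al)
        sum(sapply(pooled, function(cl) al %in% oracle_expand(cl))))
      major <- alleles[which.max(carriers)]
      if (any(carriers[alleles != major] == 1)) next
    }
    polyA <- length(unique(copiesA)) > 1
    polyB <- length(unique(copiesB)) > 1
    if (polyA && polyB) counts["shared"] <- counts["shared"] + 1L
    else if (polyA) counts["privateA"] <- counts["privateA"] + 1L
    else if (polyB) counts["privateB"] <- counts["privateB"] + 1L
    else if (length(copiesA) && length(copiesB) &&
             copiesA[1] != copiesB[1])
      counts["fixed"] <- counts["fixed"] + 1L
  }
  counts
}

# random genotype matrix with hom, het and missing calls
random_matrix <- function(n_iso = 12, n_sites = 150, seed = 1,
                          p_het = 0.15, p_missing = 0.05) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_iso))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  m <- matrix(rep(ref, each = n_iso), n_iso, n_sites,
              dimnames = list(ids, NULL))
  for (j in seq_len(n_sites)) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref[j]), 1)
    carriers <- sample(n_iso, sample(1:n_iso, 1))
    for (i in carriers) {
      r <- runif(1)
      m[i, j] <- if (r < p_het) {
        p <- paste0(min(ref[j], alt), max(ref[j], alt))
        names(IUPAC_PAIRS)[match(p, IUPAC_PAIRS)]
      } else if (r < p_het + 0.5) alt else ref[j]
    }
    miss <- runif(n_iso) < p_missing
    m[miss, j] <- "N"
  }
  sites <- data.table::data.table(chrom = "chr1", pos = seq_len(n_sites),
                                  ref = ref,
                                  missing_fraction = colMeans(m == "N"))
  colnames(m) <- paste(sites$chrom, sites$pos, sep = ":")
  structure(list(calls = m, sites = sites, isolates = ids),
            class = "genotype_matrix")
}

# genotype call table straight from a pair of haplotype strings (perfect
# calls, bypassing the pileup layer) for fast matrix construction
calls_from_haplotypes <- function(hapA, hapB, reference) {
  rows <- lapply(names(reference), function(ch) {
    a <- strsplit(hapA[[ch]], "")[[1]]
    b <- strsplit(hapB[[ch]], "")[[1]]
    r <- strsplit(reference[[ch]], "")[[1]]
    call <- ifelse(a == b, a,
                   names(IUPAC_PAIRS)[match(paste0(pmin(a, b), pmax(a, b)),
                                            IUPAC_PAIRS)])
    data.table::data.table(chrom = ch, pos = seq_along(r), ref = r,
                           call = call)
  })
  data.table::rbindlist(rows)
}

# small shared cohort, built once per test run
tiny_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- simulate_cohort(
        spec = default_genome_spec(), n_wild = 4, n_domesticated = 4,
        n_wild_lineages = 4, n_dom_lineages = 2, mean_depth = 50,
        seed = 20260901)
    memo
  }
})
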