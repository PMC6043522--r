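test_that("pi and theta match closed forms on hand-built matrices", {
  ## two identical homozygous isolates -> pi = 0
  m0 <- random_matrix(2, 10, seed = 1)
  m0$calls[2, ] <- m0$calls[1, ]
  expect_equal(nucleotide_diversity(m0, m0$isolates)$pi, 0)

  ## two haplotype-like isolates differing at 2 of 100 callable sites
  ids <- c("a", "b")
  m <- matrix("A", 2, 100, dimnames = list(ids, NULL))
  m[2, 1:2] <- "G"
  sites <- data.table::data.table(chrom = "c", pos = 1:100, ref = "A",
                                  missing_fraction = 0)
  colnames(m) <- paste("c", 1:100, sep = ":")
  mat <- structure(list(calls = m, sites = sites, isolates = ids),
                   class = "genotype_matrix")
  d <- nucleotide_diversity(mat, ids)
  ## allele copies 2+2: pairwise diff at a divergent site = 4/6
  expect_equal(d$pi, 2 * (4 / 6) / 100)
  ## Watterson: S = 2, k = 4 copies, 100 sites
  expect_equal(d$theta, oracle_theta(2, 4, 100))
  expect_equal(oracle_theta(3, 4, 100), 3 / (1 + 1 / 2 + 1 / 3) / 100,
               tolerance = 1e-12)

  expect_error(nucleotide_diversity(mat, "a"), "at least 2")
})

test_that("pi equals the brute-force allele-copy double loop", {
  for (seed in 1:4) {
    mat <- random_matrix(10, 80, seed = seed)
    got <- nucleotide_diversity(mat, mat$isolates, invariant_sites = 500)
    expect_equal(got$pi, oracle_pi(mat$calls, 0.80, invariant_sites = 500),
                 tolerance = 1e-12)
    expect_equal(got$S, oracle_segregating(mat$calls, 0.80))
  }
})

test_that("pi and theta recover the simulated divergence across replicate cohorts", {
  ## homozygous isolates at divergence d from a shared ancestor: expected
  ## pairwise difference 2d(1-d) + (2/3)d^2
  d <- 0.005
  L <- 20000L
  ## pairwise difference of two copies drawn from distinct isolates, times
  ## the chance two of the 8 expanded copies come from distinct isolates
  expected <- (6 / 7) * (2 * d * (1 - d) + (2 / 3) * d^2)
  pis <- vapply(1:20, function(rep) {
    spec <- genome_spec(c(chrI = L), seed = 1000L + rep)
    anc <- simulate_ancestor(spec)
    haps <- lapply(1:4, function(i)
      evolve_haplotype(anc, d, seed = rep * 10L + i)$seq)
    calls <- lapply(haps, function(h) calls_from_haplotypes(h, h, anc))
    names(calls) <- sprintf("I%d", 1:4)
    mat <- build_matrix(calls, max_site_missing = 0)
    invariant <- L - nrow(mat$sites)
    nucleotide_diversity(mat, mat$isolates,
                         invariant_sites = invariant)$pi
  }, numeric(1))
  sem <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * sem + 1e-4)
})

test_that("polymorphism partitioning follows the shared/fixed/private rules", {
  mk <- function(callsA, callsB) {
    ids <- c(sprintf("a%d", seq_along(callsA)),
             sprintf("b%d", seq_along(callsB)))
    m <- matrix(c(callsA, callsB), ncol = 1, dimnames = list(ids, "c:1"))
    sites <- data.table::data.table(chrom = "c", pos = 1L, ref = "A",
                                    missing_fraction = mean(m == "N"))
    list(mat = structure(list(calls = m, sites = sites, isolates = ids),
                         class = "genotype_matrix"),
         A = ids[seq_along(callsA)], B = ids[-seq_along(callsA)])
  }
  ## fixed difference
  x <- mk(c("A", "A"), c("G", "G"))
  p <- polymorphism_partition(x$mat, x$A, x$B, drop_singletons = FALSE)
  expect_equal(unname(p$counts["fixed"]), 1L)
  ## shared polymorphism on the 8-allele toy
  x <- mk(c("A", "G", "A", "G"), c("A", "G", "A", "A"))
  p <- polymorphism_partition(x$mat, x$A, x$B, drop_singletons = FALSE)
  expect_equal(unname(p$counts["shared"]), 1L)
  ## singleton variant -> site excluded
  x <- mk(c("A", "A"), c("G", "A"))
  p <- polymorphism_partition(x$mat, x$A, x$B, drop_singletons = TRUE)
  expect_equal(sum(p$counts), 0L)
  expect_equal(p$analyzed_sites, 0L)

  expect_error(polymorphism_partition(x$mat, x$A, c(x$A[1], x$B[1])),
               "disjoint")
})

test_that("partitions match enumeration and are symmetric under group swap", {
  for (seed in 5:7) {
    mat <- random_matrix(12, 100, seed = seed)
    A <- mat$isolates[1:6]; B <- mat$isolates[7:12]
    for (mode in c("ambiguity", "biallelic")) {
      got <- polymorphism_partition(mat, A, B, mode = mode)
      want <- oracle_partition(mat$calls[A, ], mat$calls[B, ], mode = mode)
      expect_equal(got$counts, want)
      rev <- polymorphism_partition(mat, B, A, mode = mode)
      expect_equal(unname(rev$counts[c("shared", "fixed")]),
                   unname(got$counts[c("shared", "fixed")]))
      expect_equal(unname(rev$counts["privateA"]),
                   unname(got$counts["privateB"]))
      expect_equal(unname(rev$counts["privateB"]),
                   unname(got$counts["privateA"]))
    }
  }
})

test_that("shared fraction reflects population history", {
  expect_equal(shared_fraction(list(counts = c(shared = 0, fixed = 2,
                                               privateA = 1, privateB = 1))),
               0)
  expect_equal(shared_fraction(list(counts = c(shared = 1, fixed = 1,
                                               privateA = 1, privateB = 1))),
               25)
  expect_warning(sf <- shared_fraction(list(counts = c(shared = 0, fixed = 0,
                                                       privateA = 0,
                                                       privateB = 0))),
                 "undefined")
  expect_true(is.na(sf))

  ## two samples from one panmictic pool share far more polymorphism than
  ## two long-isolated pools, at equal sample sizes
  set.seed(42)
  n_sites <- 300
  panmictic <- random_matrix(12, n_sites, seed = 8, p_het = 0, p_missing = 0)
  A <- panmictic$isolates[1:6]; B <- panmictic$isolates[7:12]
  sf_pan <- shared_fraction(polymorphism_partition(panmictic, A, B))

  ## isolated pools: disjoint variant sites per pool
  m <- matrix("A", 12, n_sites,
              dimnames = list(panmictic$isolates, colnames(panmictic$calls)))
  for (j in 1:100) m[sample(1:6, 3), j] <- "G"
  for (j in 151:250) m[sample(7:12, 3), j] <- "T"
  isolated <- panmictic
  isolated$calls <- m
  sf_iso <- shared_fraction(polymorphism_partition(isolated, A, B))
  expect_gt(sf_pan, sf_iso + 30)
})

test_that("rank correlation equals the brute-force rank formula", {
  x <- 1:10
  expect_equal(rank_correlation(x, rev(x)), -1)
  expect_equal(rank_correlation(x, x), 1)
  ## toy 5-point set with a tie
  x5 <- c(1, 2, 2, 4, 5); y5 <- c(3, 1, 5, 2, 4)
  expect_equal(rank_correlation(x5, y5), oracle_spearman(x5, y5))
  set.seed(9)
  xr <- rnorm(20); yr <- xr + rnorm(20)
  expect_equal(rank_correlation(xr, yr), oracle_spearman(xr, yr))
  expect_warning(r <- rank_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(rank_correlation(1:3, 1:4), "equal length")
})
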