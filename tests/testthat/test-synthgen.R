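test_that("ancestral genomes have the requested size and are seed-deterministic", {
  spec <- genome_spec(c(chrI = 10000L), seed = 1L)
  anc <- simulate_ancestor(spec)
  expect_equal(unname(nchar(anc)), 10000L)
  expect_true(all(strsplit(anc[[1]], "")[[1]] %in% c("A", "C", "G", "T")))
  expect_identical(anc, simulate_ancestor(spec))

  spec2 <- genome_spec(c(chrI = 10000L), seed = 2L)
  anc2 <- simulate_ancestor(spec2)
  mismatch <- mean(strsplit(anc[[1]], "")[[1]] != strsplit(anc2[[1]], "")[[1]])
  ## two uniform random sequences differ at 3/4 of positions
  sigma <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(mismatch - 0.75), 3 * sigma)
})

test_that("invalid genome specs are rejected", {
  expect_error(genome_spec(c(chrI = 0L)), "positive")
  expect_error(genome_spec(c(10000L)), "named")
  expect_error(genome_spec(c(chrI = 1000L),
                           genes = data.frame(name = "g", chrom = "chrI",
                                              start = 500L, end = 1500L)),
               "outside")
})

test_that("haplotype evolution places a binomial number of substitutions", {
  spec <- genome_spec(c(chrI = 100000L), seed = 3L)
  anc <- simulate_ancestor(spec)
  h0 <- evolve_haplotype(anc, 0, seed = 1L)
  expect_identical(h0$seq, anc)
  expect_equal(nrow(h0$substitutions), 0L)

  h <- evolve_haplotype(anc, 0.01, seed = 4L)
  n <- nrow(h$substitutions)
  sigma <- sqrt(100000 * 0.01 * 0.99)
  expect_lt(abs(n - 1000), 3 * sigma)
  ## truth table is exact
  a <- strsplit(anc[[1]], "")[[1]]
  b <- strsplit(h$seq[[1]], "")[[1]]
  expect_identical(which(a != b), h$substitutions$pos)

  expect_error(evolve_haplotype(anc, 0.06, seed = 1L), "divergence")
  expect_error(evolve_haplotype(anc, -0.01, seed = 1L), "divergence")
})

test_that("two haplotypes at 0.8% each sit near 1.6% apart (coincident hits corrected)", {
  spec <- genome_spec(c(chrI = 100000L), seed = 5L)
  anc <- simulate_ancestor(spec)
  h1 <- evolve_haplotype(anc, 0.008, seed = 6L)$seq
  h2 <- evolve_haplotype(anc, 0.008, seed = 7L)$seq
  d <- mean(strsplit(h1[[1]], "")[[1]] != strsplit(h2[[1]], "")[[1]])
  ## P(differ) = 2p(1-p) + (2/3)p^2 for independent uniform substitutions
  expected <- 2 * 0.008 * 0.992 + (2 / 3) * 0.008^2
  sigma <- sqrt(expected * (1 - expected) / 100000)
  expect_lt(abs(d - expected), 3 * sigma)
})

test_that("diploids record their heterozygous sites exactly", {
  spec <- genome_spec(c(chrI = 50000L), seed = 8L)
  anc <- simulate_ancestor(spec)
  dip0 <- make_diploid(anc, anc)
  expect_equal(nrow(dip0$het_sites), 0L)

  h <- evolve_haplotype(anc, 0.01, seed = 9L)
  dip <- make_diploid(anc, h$seq)
  a <- strsplit(anc[[1]], "")[[1]]
  b <- strsplit(h$seq[[1]], "")[[1]]
  expect_identical(dip$het_sites$pos, which(a != b))
  dens <- nrow(dip$het_sites) / 50000
  expect_lt(abs(dens - 0.01), 3 * sqrt(0.01 * 0.99 / 50000))

  expect_error(make_diploid(anc, c(chrI = "ACGT")), "length")
})

test_that("planted features are recorded and shape the coverage model", {
  spec <- genome_spec(c(chrI = 20000L, chrII = 30000L),
                      genes = data.frame(name = "g1", chrom = "chrII",
                                         start = 10000L, end = 12000L),
                      seed = 10L)
  anc <- simulate_ancestor(spec)
  dip <- make_diploid(anc, anc)
  donor <- list(don = evolve_haplotype(anc, 0.05, seed = 11L)$seq)
  g <- plant_features(dip, spec, chrom_copies = c(chrI = 3L),
                      gene_factors = c(g1 = 2),
                      aliens = data.frame(donor = "don", chrom = "chrII",
                                          start = 20000L, end = 22000L),
                      donor_seqs = donor)
  expect_equal(unname(g$chrom_copies["chrI"]), 3)
  expect_equal(unname(g$gene_factors["g1"]), 2)

  ## alien segment has the donor sequence, so ~95% identity to original
  seg_new <- substr(g$hapA[["chrII"]], 20001, 22000)
  seg_old <- substr(anc[["chrII"]], 20001, 22000)
  idt <- mean(strsplit(seg_new, "")[[1]] == strsplit(seg_old, "")[[1]])
  expect_lt(abs(idt - 0.95), 3 * sqrt(0.05 * 0.95 / 2000))

  p <- simulate_pileups(g, anc, mean_depth = 60, error_rate = 0, seed = 12L)
  mdep <- median(p[p$chrom == "chrII" & (p$pos <= 10000 | p$pos > 12000), depth])
  ## chrI at 3 copies of basal 2 -> 1.5x depth
  expect_lt(abs(mean(p[p$chrom == "chrI", depth]) / 60 - 1.5), 0.05)
  ## doubled gene -> 2x depth
  expect_lt(abs(mean(p[p$chrom == "chrII" & pos > 10000 & pos <= 12000, depth])
                / 60 - 2), 0.1)
  expect_lt(abs(mdep / 60 - 1), 0.1)

  expect_error(plant_features(dip, spec, chrom_copies = c(chrI = -1L)),
               "copy number")
  expect_error(plant_features(dip, spec,
                              aliens = data.frame(donor = "don", chrom = "chrII",
                                                  start = c(100L, 900L),
                                                  end = c(1200L, 2000L)),
                              donor_seqs = donor),
               "overlapping")
})

test_that("pileup counts follow the multinomial read model", {
  spec <- genome_spec(c(chrI = 5000L), seed = 13L)
  anc <- simulate_ancestor(spec)
  h <- evolve_haplotype(anc, 0.02, seed = 14L)
  g <- plant_features(make_diploid(anc, h$seq), spec)
  p <- simulate_pileups(g, anc, mean_depth = 200, error_rate = 0, seed = 15L)

  ## homozygous sites: all reads carry the single allele
  hom_pos <- setdiff(seq_len(5000), g$het_sites$pos)
  cnt <- as.matrix(p[hom_pos, c("A", "C", "G", "T")])
  expect_true(all(rowSums(cnt > 0) == 1))

  ## heterozygous sites: the hapA allele draws ~1/2 of the pooled reads
  het <- p[g$het_sites$pos]
  hetm <- as.matrix(het[, c("A", "C", "G", "T")])
  a_allele <- g$het_sites$a
  a_reads <- hetm[cbind(seq_len(nrow(het)), match(a_allele, colnames(hetm)))]
  frac <- sum(a_reads) / sum(het$depth)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(het$depth)))

  expect_identical(p, simulate_pileups(g, anc, 200, 0, seed = 15L))
  expect_error(simulate_pileups(g, anc, 0.5, 0, 1L), "depth")
  expect_error(simulate_pileups(g, anc, 50, 0.2, 1L), "error")
})

test_that("flow-cytometry D values reflect basal ploidy", {
  expect_equal(simulate_flow_D(2L, noise_sd = 0, seed = 1L), 2.0)
  expect_equal(simulate_flow_D(1L, noise_sd = 0, seed = 1L), 1.0)
  d <- vapply(1:1000, function(i) simulate_flow_D(2L, 0.05, seed = i),
              numeric(1))
  expect_lt(abs(mean(d) - 2.0), 0.01)
  expect_error(simulate_flow_D(5L, 0.05, 1L), "ploidy")
})

test_that("cohorts are byte-deterministic and carry consistent truth", {
  co <- tiny_cohort()
  co2 <- simulate_cohort(
    spec = default_genome_spec(), n_wild = 4, n_domesticated = 4,
    n_wild_lineages = 4, n_dom_lineages = 2, mean_depth = 50,
    seed = 20260901)
  expect_identical(co$pileups, co2$pileups)
  expect_identical(co$genomes, co2$genomes)

  ## every planted alien is recoverable by direct sequence comparison
  for (i in seq_len(nrow(co$truth$aliens))) {
    al <- co$truth$aliens[i, ]
    asm <- co$genomes[[al$carrier]]$hapA
    planted <- substr(asm[[al$chrom]], al$start + 1, al$end)
    donor <- substr(co$library$seqs[[al$donor]][[al$chrom]],
                    al$start + 1, al$end)
    expect_identical(planted, donor)
  }
  ## wild isolates are fully homozygous
  for (id in co$isolates$id[co$isolates$group == "wild"])
    expect_equal(nrow(co$truth$het_sites[[id]]), 0L)
})
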