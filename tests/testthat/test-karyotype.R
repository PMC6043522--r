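make_pileup <- function(depths_by_chrom) {
  data.table::rbindlist(lapply(names(depths_by_chrom), function(ch) {
    d <- depths_by_chrom[[ch]]
    data.table::data.table(chrom = ch, pos = seq_along(d), ref = "A",
                           depth = d, A = d, C = 0L, G = 0L, T = 0L)
  }))
}

test_that("frame values normalize by the genome-wide median frame depth", {
  p <- make_pileup(list(c1 = rep(50, 5000), c2 = rep(50, 3000)))
  fr <- frame_values(p)
  expect_equal(nrow(fr), 8L)
  expect_true(all(fr$value == 1))

  ## scaling all depths leaves every value unchanged
  p2 <- make_pileup(list(c1 = rep(500, 5000), c2 = rep(500, 3000)))
  expect_equal(frame_values(p2)$value, fr$value)

  ## a partial tail window is averaged over its own length
  p3 <- make_pileup(list(c1 = rep(40, 2500)))
  fr3 <- frame_values(p3)
  expect_equal(fr3$end[3], 2500)
  expect_equal(fr3$value[3], 1)

  ## amplified chromosome doubles its frame values
  p4 <- make_pileup(list(c1 = rep(50, 5000), c2 = rep(100, 2000)))
  fr4 <- frame_values(p4)
  expect_equal(fr4[fr4$chrom == "c2", value], rep(2, 2))
})

test_that("Vo is the median frame value, robust to outlier frames", {
  fr <- data.table::data.table(chrom = "c", start = 0:2 * 1000,
                               end = 1:3 * 1000, depth = 1,
                               value = c(1.4, 1.5, 1.6))
  expect_equal(unname(chromosome_vo(fr)), 1.5)
  fr2 <- data.table::data.table(chrom = "c", start = 0:99 * 1000,
                                end = 1:100 * 1000, depth = 1,
                                value = c(rep(1, 99), 10))
  expect_equal(unname(chromosome_vo(fr2)), 1)
})

test_that("the flow-cytometry adjustment is exact arithmetic", {
  expect_equal(adjust_va(2.0, 1.5), 1.0)
  expect_equal(adjust_va(1.0, 1.0), 0.0)
  expect_equal(adjust_va(2.0, 0.6), -0.8)
  expect_error(adjust_va(0, 1.5), "positive")
})

test_that("chromosome classification follows the printed Va bins", {
  expect_equal(classify_chromosome(1.0)$delta, 1)
  expect_equal(classify_chromosome(-0.8)$delta, -1)
  expect_equal(classify_chromosome(0.0)$delta, 0)
  expect_equal(classify_chromosome(2.0)$delta, 2)
  expect_false(any(classify_chromosome(c(1.0, -0.8, 0, 2.0))$ambiguous))

  ## gap values: nearest bin, ambiguous flag, ties to the lower bin
  g <- classify_chromosome(0.55)
  expect_equal(g$delta, 0)
  expect_true(g$ambiguous)
  expect_equal(classify_chromosome(0.58)$delta, 1)
  expect_true(classify_chromosome(0.58)$ambiguous)
  expect_equal(classify_chromosome(3.5)$delta, 2)
  expect_true(classify_chromosome(3.5)$ambiguous)

  ## piecewise-constant and monotone nondecreasing
  va <- seq(-2, 3, by = 0.01)
  deltas <- classify_chromosome(va)$delta
  expect_true(all(diff(deltas) >= 0))
  expect_error(classify_chromosome(NaN), "NA")
})

test_that("partial-chromosome events need a long deviant run on a euploid chromosome", {
  mkframes <- function(values) {
    n <- length(values)
    data.table::data.table(chrom = "c", start = (0:(n - 1)) * 1000,
                           end = (1:n) * 1000, depth = values * 50,
                           value = values)
  }
  ## uniform chromosome: nothing
  fr <- mkframes(rep(1, 200))
  expect_equal(nrow(detect_partial(fr, 2, c(c = 0))), 0L)

  ## one 60-frame amplified run -> one +0.5 call over the run
  v <- rep(1, 200); v[51:110] <- 1.5
  part <- detect_partial(mkframes(v), 2, c(c = 0))
  expect_equal(nrow(part), 1L)
  expect_equal(part$call, 0.5)
  expect_equal(part$start, 50000)
  expect_equal(part$end, 110000)

  ## two separated runs -> two calls; a short run is ignored
  v2 <- rep(1, 300); v2[11:70] <- 1.5; v2[201:260] <- 0.4; v2[291:300] <- 1.5
  part2 <- detect_partial(mkframes(v2), 2, c(c = 0))
  expect_equal(nrow(part2), 2L)
  expect_equal(part2$call, c(0.5, -0.5))

  ## no partial calls on an aneuploid chromosome
  expect_equal(nrow(detect_partial(mkframes(v), 2, c(c = 1))), 0L)
})

test_that("aneuploidy patterns are canonical and countable", {
  expect_equal(aneuploidy_pattern(c(chrI = 0, chrII = 0)), "")
  expect_equal(aneuploidy_pattern(c(chrI = 1, chrIII = 1, chrIV = 0)),
               "chrI:+1;chrIII:+1")
  expect_equal(aneuploidy_pattern(c(chrII = -1)), "chrII:-1")
  s <- count_aneuploidy_patterns(c("", "chrI:+1", "chrI:+1", "chrII:-1", ""))
  expect_equal(s$n_patterns, 2L)
  expect_equal(s$n_aneuploid, 3L)
  expect_equal(s$n_euploid, 2L)
})

test_that("gene values take the per-base median across frames", {
  fr <- data.table::data.table(chrom = "c", start = c(0, 1000),
                               end = c(1000, 2000), depth = 1,
                               value = c(1.0, 2.0))
  ## gene inside one frame
  expect_equal(gene_value(fr, "c", 1200, 1800), 2.0)
  ## 600 bp in frame 1, 400 bp in frame 2 -> majority frame value
  expect_equal(gene_value(fr, "c", 400, 1400), 1.0)
  ## 500/500 split -> midpoint convention
  expect_equal(gene_value(fr, "c", 500, 1500), 1.5)
  expect_error(gene_value(fr, "c", 100, 100), "1 bp")
})

test_that("tail fitting returns ordered empirical percentiles", {
  set.seed(1)
  u <- runif(1e5)
  t <- fit_tails(u)
  expect_equal(unname(t), c(0.01, 0.05, 0.95, 0.99), tolerance = 0.01)
  expect_true(all(diff(t) > 0))
  expect_equal(unname(default_tails()), c(0.34, 0.73, 1.2, 1.74))
  expect_error(fit_tails(rep(1, 200)), "degenerate")
  expect_error(fit_tails(runif(50)), "at least 100")
})

test_that("CNV discretization follows the tail cut-offs and is monotone", {
  t <- default_tails()
  expect_equal(discretize(0.2, t), 0)
  expect_equal(discretize(0.5, t), 0.5)
  expect_equal(discretize(1.0, t), 1)
  expect_equal(discretize(1.5, t), 2)
  expect_equal(discretize(2.0, t), 3)
  ## boundary conventions
  expect_equal(discretize(0.34, t), 0.5)
  expect_equal(discretize(1.2, t), 1)
  expect_equal(discretize(1.74, t), 2)
  v <- seq(0, 3, by = 0.01)
  expect_true(all(diff(discretize(v, t)) >= 0))
  expect_error(discretize(NA, t), "NA")
  expect_error(discretize(1, c(left1 = 1, left5 = 0.5, right5 = 2,
                               right1 = 3)),
               "increasing")
})

test_that("group CNV tests flag separated groups at P < 0.01", {
  same <- cnv_group_test(c(1, 1.1, 0.9, 1), c(1, 1.05, 0.95, 1))
  expect_false(same$significant)

  a <- c(1.02, 0.98, 1.01, 0.99, 1.03, 0.97, 1.0, 1.02, 0.98, 1.01)
  b <- a + 1
  sep <- cnv_group_test(a, b)
  expect_lt(sep$p, 0.01)
  expect_true(sep$significant)
  expect_equal(cnv_group_test(b, a)$p, sep$p)

  tt <- cnv_group_test(a, b, test = "ttest")
  expect_lt(tt$p, 0.01)

  tied <- cnv_group_test(rep(1, 5), rep(1, 5))
  expect_equal(tied$p, 1)
  expect_true(tied$tied)
  expect_error(cnv_group_test(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("planted chromosome gains are recovered through the Vo/Va chain", {
  spec <- genome_spec(c(chrA = 20000L, chrB = 30000L), seed = 51L)
  anc <- simulate_ancestor(spec)
  g <- plant_features(make_diploid(anc, anc), spec,
                      chrom_copies = c(chrA = 3L))
  p <- simulate_pileups(g, anc, mean_depth = 60, error_rate = 0, seed = 52L)
  calls <- call_chromosomes(frame_values(p), D = 2.0)
  expect_equal(calls$delta[calls$chrom == "chrA"], 1)
  expect_equal(calls$delta[calls$chrom == "chrB"], 0)
  expect_equal(calls$vo[calls$chrom == "chrA"], 1.5, tolerance = 0.05)

  ## scaling depth leaves the calls unchanged
  p2 <- data.table::copy(p)
  p2[, depth := depth * 7L]
  calls2 <- call_chromosomes(frame_values(p2), D = 2.0)
  expect_equal(calls2$vo, calls$vo)
  expect_equal(calls2$delta, calls$delta)
})
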