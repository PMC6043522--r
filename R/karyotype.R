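#' Normalized copy values in 1000-bp frames
#'
#' Averages read depth in nonoverlapping frames and normalizes by the
#' genome-wide median frame depth, so 1.0 marks the basal copy number. A
#' partial last frame is averaged over its own length. The result is
#' invariant to rescaling all depths by a constant.
#'
#' @param pileup Pileup table (chrom, pos, depth, ...).
#' @param frame Frame size in bp (default 1000).
#' @return data.table: chrom, start (0-based), end, depth, value.
#' @export
frame_values <- function(pileup, frame = 1000L) {
  p <- data.table::as.data.table(pileup)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(p)))
  fr <- p[, .(depth = mean(depth)),
          by = .(chrom, start = (pos - 1L) %/% frame * frame)]
  lens <- p[, .(chrom_len = max(pos)), by = chrom]
  fr <- merge(fr, lens, by = "chrom")
  data.table::setorder(fr, chrom, start)
  fr[, end := pmin(start + frame, chrom_len)]
  fr[, chrom_len := NULL]
  med <- stats::median(fr$depth)
  if (med <= 0) stop("genome-wide median frame depth is zero")
  fr[, value := depth / med]
  data.table::setcolorder(fr, c("chrom", "start", "end", "depth", "value"))
  fr[]
}

#' Per-chromosome original copy value Vo
#'
#' The median frame value of the chromosome; the median is robust to
#' segmental amplifications and local artifacts.
#'
#' @param frames Frame table from [frame_values()] (may contain several
#'   chromosomes).
#' @return Named numeric vector of Vo per chromosome.
#' @export
chromosome_vo <- function(frames) {
  fr <- data.table::as.data.table(frames)
  v <- fr[, .(vo = stats::median(value)), by = chrom]
  stats::setNames(v$vo, v$chrom)
}

#' Flow-cytometry adjustment of the copy value
#'
#' `Va = D * (Vo - 1)`: the coverage-derived copy deviation rescaled by the
#' isolate's relative DNA content per cell, D (haploid reference = 1), so
#' that one extra chromosome in a diploid gives Va near 1 regardless of
#' basal ploidy.
#'
#' @param D Relative DNA content (> 0).
#' @param vo Original copy value(s).
#' @return Va value(s).
#' @export
adjust_va <- function(D, vo) {
  if (any(D <= 0)) stop("D must be positive")
  D * (vo - 1)
}

#' Discrete chromosome copy-number change from Va
#'
#' The printed classification bins: Va < -0.7 -> one copy missing (-1);
#' -0.6 <= Va <= 0.5 -> no change (0); 0.6 <= Va <= 1.6 -> one extra copy
#' (+1); 1.7 <= Va <= 2.6 -> two extra copies (+2). Values falling in the
#' gaps between printed bins are assigned to the nearest bin boundary
#' (ties to the lower bin) and flagged ambiguous, as are values above 2.6
#' (assigned +2).
#'
#' @param va Numeric vector of Va values (no NaN).
#' @return data.frame: va, delta, ambiguous.
#' @export
classify_chromosome <- function(va) {
  if (any(is.na(va))) stop("Va contains NA/NaN")
  delta <- numeric(length(va))
  ambiguous <- logical(length(va))
  for (i in seq_along(va)) {
    v <- va[i]
    if (v < -0.7) { delta[i] <- -1
    } else if (v >= -0.6 && v <= 0.5) { delta[i] <- 0
    } else if (v >= 0.6 && v <= 1.6) { delta[i] <- 1
    } else if (v >= 1.7 && v <= 2.6) { delta[i] <- 2
    } else if (v > 2.6) { delta[i] <- 2; ambiguous[i] <- TRUE
    } else {
      ## gap between printed bins: nearest boundary, ties downward
      bounds <- rbind(c(-0.7, -1), c(-0.6, 0), c(0.5, 0),
                      c(0.6, 1), c(1.6, 1), c(1.7, 2))
      dist <- abs(bounds[, 1] - v)
      ## ties (exact midpoints) go to the lower bin
      delta[i] <- bounds[which(dist <= min(dist) + 1e-9)[1L], 2]
      ambiguous[i] <- TRUE
    }
  }
  data.frame(va = va, delta = delta, ambiguous = ambiguous)
}

#' Chromosome copy-number calls for one isolate
#'
#' Combines [chromosome_vo()], [adjust_va()] and [classify_chromosome()].
#'
#' @param frames Frame table from [frame_values()].
#' @param D Relative DNA content of the isolate.
#' @return data.table: chrom, vo, va, delta, ambiguous.
#' @export
call_chromosomes <- function(frames, D) {
  vo <- chromosome_vo(frames)
  va <- adjust_va(D, vo)
  cl <- classify_chromosome(unname(va))
  data.table::data.table(chrom = names(vo), vo = unname(vo),
                         va = cl$va, delta = cl$delta,
                         ambiguous = cl$ambiguous)
}

#' Partial-chromosome amplification/deletion calls
#'
#' On a chromosome whose whole-chromosome delta is 0, a contiguous run of
#' at least `min_frames` frames (default 50, i.e. 50 kb) whose run-median
#' Va falls in a nonzero bin is called a partial event: +0.5 for
#' amplification, -0.5 for deletion.
#'
#' @param frames Frame table for one or more chromosomes.
#' @param D Relative DNA content.
#' @param deltas Named vector of whole-chromosome deltas (from
#'   [call_chromosomes()]); partial calls are only made where delta == 0.
#' @param min_frames Minimum run length in frames.
#' @return data.table: chrom, start, end, call (+0.5 / -0.5), median_va.
#' @export
detect_partial <- function(frames, D, deltas, min_frames = 50L) {
  fr <- data.table::as.data.table(frames)
  out <- list()
  for (ch in unique(fr$chrom)) {
    if (is.na(deltas[ch]) || deltas[ch] != 0) next
    f <- fr[chrom == ch][order(start)]
    va <- adjust_va(D, f$value)
    cls <- classify_chromosome(va)$delta
    r <- rle(sign(cls))
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0 || r$lengths[k] < min_frames) next
      rows <- idx_start[k]:idx_end[k]
      med <- stats::median(va[rows])
      if (classify_chromosome(med)$delta == 0) next
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = f$start[idx_start[k]], end = f$end[idx_end[k]],
        call = 0.5 * r$values[k], median_va = med)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), call = numeric(),
                                  median_va = numeric()))
  data.table::rbindlist(out)
}

#' Canonical aneuploidy pattern of an isolate
#'
#' Nonzero chromosome deltas joined in chromosome order, e.g.
#' `"chrI:+1;chrIII:+1"`; euploid isolates yield the empty pattern `""`.
#'
#' @param deltas Named numeric vector of per-chromosome deltas.
#' @return Single pattern string.
#' @export
aneuploidy_pattern <- function(deltas) {
  nz <- deltas[deltas != 0]
  if (!length(nz)) return("")
  paste(sprintf("%s:%+g", names(nz), nz), collapse = ";")
}

#' Count distinct aneuploidy patterns in a cohort
#'
#' @param patterns Character vector of per-isolate patterns from
#'   [aneuploidy_pattern()].
#' @return List: `n_patterns` (distinct nonempty), `n_aneuploid`,
#'   `n_euploid`, `table` of pattern frequencies.
#' @export
count_aneuploidy_patterns <- function(patterns) {
  nonempty <- patterns[patterns != ""]
  list(n_patterns = length(unique(nonempty)),
       n_aneuploid = length(nonempty),
       n_euploid = sum(patterns == ""),
       table = sort(table(nonempty), decreasing = TRUE))
}

#' Relative copy value of a gene
#'
#' Every base of the open reading frame inherits the value of its frame;
#' the gene value is the median over those per-base values (even counts
#' take the midpoint of the two central values).
#'
#' @param frames Frame table from [frame_values()].
#' @param chrom,start,end Gene interval (0-based half-open, length >= 1).
#' @return Numeric gene value.
#' @export
gene_value <- function(frames, chrom, start, end) {
  if (end - start < 1L) stop("gene must be at least 1 bp")
  fr <- data.table::as.data.table(frames)
  sel <- fr$chrom == chrom & fr$end > start & fr$start < end
  f <- fr[which(sel)]
  if (nrow(f) == 0L) stop("gene interval not covered by frames")
  w <- pmin(f$end, end) - pmax(f$start, start)
  stats::median(rep(f$value, w))
}

#' Gene values for all genes of a spec
#'
#' @param frames Frame table.
#' @param genes data.frame: name, chrom, start, end.
#' @return data.table: gene, value.
#' @export
gene_values <- function(frames, genes) {
  data.table::data.table(
    gene = genes$name,
    value = vapply(seq_len(nrow(genes)), function(i)
      gene_value(frames, genes$chrom[i], genes$start[i], genes$end[i]),
      numeric(1)))
}

#' Empirical tail thresholds of the cohort gene-value distribution
#'
#' The 1st, 5th, 95th and 99th percentiles of all gene values across the
#' cohort, which bound the discrete CNV levels. `default_tails()` returns
#' the cut-offs fitted on the original 254-isolate cohort
#' (0.34, 0.73, 1.2, 1.74).
#'
#' @param values Numeric vector of gene values (>= 100).
#' @return Named numeric vector: left1, left5, right5, right1.
#' @export
fit_tails <- function(values) {
  if (length(values) < 100L) stop("need at least 100 gene values")
  if (stats::sd(values) == 0)
    stop("degenerate constant gene-value distribution")
  q <- stats::quantile(values, c(0.01, 0.05, 0.95, 0.99), names = FALSE)
  if (any(diff(q) <= 0)) stop("tail thresholds are not strictly increasing")
  stats::setNames(q, c("left1", "left5", "right5", "right1"))
}

#' @rdname fit_tails
#' @export
default_tails <- function() {
  c(left1 = 0.34, left5 = 0.73, right5 = 1.2, right1 = 1.74)
}

#' Discretize a gene value into a CNV level
#'
#' Levels: 0 (complete deletion) below the 1% left tail; 0.5 (partial
#' deletion) up to the 5% left tail; 1 (normal) between the 5% tails;
#' 2 (two-fold duplication) up to the 1% right tail; 3 (three-or-more-fold
#' duplication, the open top bin coded by its minimum) above it.
#'
#' @param value Numeric vector of gene values (no NaN).
#' @param thresholds Named vector from [fit_tails()] or [default_tails()].
#' @return Numeric vector of levels in `{0, 0.5, 1, 2, 3}`.
#' @export
discretize <- function(value, thresholds = default_tails()) {
  t <- thresholds
  stopifnot(all(c("left1", "left5", "right5", "right1") %in% names(t)))
  if (!(t[["left1"]] < t[["left5"]] && t[["left5"]] < t[["right5"]] &&
        t[["right5"]] < t[["right1"]]))
    stop("invalid thresholds: must be strictly increasing")
  if (any(is.na(value))) stop("value contains NA/NaN")
  ifelse(value < t[["left1"]], 0,
    ifelse(value < t[["left5"]], 0.5,
      ifelse(value <= t[["right5"]], 1,
        ifelse(value <= t[["right1"]], 2, 3))))
}

#' Group difference test for a gene's copy values
#'
#' Wilcoxon rank-sum (default) or Student's t test between two groups of
#' per-isolate gene values; significance is declared at P < 0.01. When all
#' values are tied across both groups the test is undefined and P = 1 is
#' returned with `tied = TRUE`.
#'
#' @param valuesA,valuesB Numeric vectors, each >= 3 values.
#' @param test `"wilcoxon"` or `"ttest"`.
#' @param alpha Significance level (default 0.01).
#' @return List: `p`, `significant`, `test`, `tied`.
#' @export
cnv_group_test <- function(valuesA, valuesB,
                           test = c("wilcoxon", "ttest"), alpha = 0.01) {
  test <- match.arg(test)
  if (length(valuesA) < 3L || length(valuesB) < 3L)
    stop("each group needs at least 3 values")
  pooled <- c(valuesA, valuesB)
  if (length(unique(pooled)) == 1L)
    return(list(p = 1, significant = FALSE, test = test, tied = TRUE))
  p <- if (test == "wilcoxon")
    suppressWarnings(stats::wilcox.test(valuesA, valuesB)$p.value)
  else stats::t.test(valuesA, valuesB)$p.value
  list(p = p, significant = p < alpha, test = test, tied = FALSE)
}
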