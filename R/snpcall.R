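IUPAC_HET <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
IUPAC_HET_ALLELES <- stats::setNames(names(IUPAC_HET), IUPAC_HET)

#' Expand a genotype call to its allele pair
#'
#' Homozygous calls expand to two copies of the base, IUPAC heterozygous
#' codes to their two encoded bases, `N` to two `NA`s.
#'
#' @param call Character vector of genotype calls.
#' @return 2-row character matrix of allele copies (columns = calls).
#' @export
expand_alleles <- function(call) {
  out <- matrix(NA_character_, 2L, length(call))
  hom <- call %in% DNA_BASES
  out[1L, hom] <- out[2L, hom] <- call[hom]
  het <- call %in% names(IUPAC_HET_ALLELES)
  if (any(het)) {
    pair <- IUPAC_HET_ALLELES[call[het]]
    out[1L, het] <- substr(pair, 1L, 1L)
    out[2L, het] <- substr(pair, 2L, 2L)
  }
  out
}

het_code <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  unname(IUPAC_HET[key])
}

#' Call genotypes from a pileup table
#'
#' Implements the depth and allele-fraction filter stack: a site is missing
#' (`N`) when its depth is below `min_depth` (default 15) or above
#' `max_depth_factor` times the isolate's median depth (default 4x, the
#' signature of collapsed repeats); otherwise the top allele is called
#' homozygous when it holds at least `hom_fraction` (default 80%) of the
#' reads, and the top two alleles are called heterozygous (IUPAC code) when
#' the second allele holds at least `het_fraction` (default 20%). A third
#' allele at or above `het_fraction` marks an artifact and yields `N`. An
#' exact 50/50 tie between the top two alleles is heterozygous.
#'
#' @param pileup data.table/data.frame: chrom, pos, ref, depth, A, C, G, T.
#' @param median_depth Isolate median depth; computed from `pileup` when
#'   NULL.
#' @param min_depth,max_depth_factor,hom_fraction,het_fraction Filter
#'   thresholds as above.
#' @return data.table: chrom, pos, ref, call.
#' @export
call_genotypes <- function(pileup, median_depth = NULL, min_depth = 15L,
                           max_depth_factor = 4, hom_fraction = 0.80,
                           het_fraction = 0.20) {
  p <- data.table::as.data.table(pileup)
  stopifnot(all(c("chrom", "pos", "ref", "depth", "A", "C", "G", "T")
                %in% names(p)))
  cnt <- as.matrix(p[, c("A", "C", "G", "T"), with = FALSE])
  if (any(rowSums(cnt) > p$depth))
    stop("malformed pileup: allele counts exceed depth")
  if (is.null(median_depth)) median_depth <- stats::median(p$depth)
  if (median_depth <= 0) stop("median depth must be positive")

  n <- nrow(p)
  ## top three alleles per site, ties broken by base order (A<C<G<T)
  tmp <- cnt
  i1 <- max.col(tmp, ties.method = "first")
  top1 <- tmp[cbind(seq_len(n), i1)]
  tmp[cbind(seq_len(n), i1)] <- -1L
  i2 <- max.col(tmp, ties.method = "first")
  top2 <- tmp[cbind(seq_len(n), i2)]
  tmp[cbind(seq_len(n), i2)] <- -1L
  i3 <- max.col(tmp, ties.method = "first")
  top3 <- tmp[cbind(seq_len(n), i3)]
  f1 <- top1 / p$depth
  f2 <- top2 / p$depth
  f3 <- top3 / p$depth

  call <- rep("N", n)
  ok <- p$depth >= min_depth & p$depth <= max_depth_factor * median_depth
  hom <- ok & f1 >= hom_fraction & f3 < het_fraction
  het <- ok & !hom & f2 >= het_fraction & f3 < het_fraction
  b1 <- DNA_BASES[i1]
  b2 <- DNA_BASES[i2]
  call[hom] <- b1[hom]
  call[het] <- het_code(b1[het], b2[het])
  data.table::data.table(chrom = p$chrom, pos = p$pos, ref = p$ref,
                         call = call)
}

#' Call a single site
#'
#' Convenience scalar wrapper around [call_genotypes()].
#'
#' @param chrom,pos,ref Site coordinates and reference base.
#' @param counts Named vector of read counts for A, C, G, T.
#' @param depth Total read depth (defaults to `sum(counts)`).
#' @param median_depth Isolate median depth.
#' @param ... Thresholds passed on to [call_genotypes()].
#' @return A single genotype call string.
#' @export
call_genotype <- function(counts, median_depth, chrom = "chr", pos = 1L,
                          ref = "A", depth = sum(counts), ...) {
  full <- stats::setNames(rep(0L, 4L), DNA_BASES)
  full[names(counts)] <- counts
  counts <- full
  p <- data.table::data.table(chrom = chrom, pos = pos, ref = ref,
                              depth = depth, A = counts[["A"]],
                              C = counts[["C"]], G = counts[["G"]],
                              T = counts[["T"]])
  call_genotypes(p, median_depth = median_depth, ...)$call
}

#' Build the cohort SNP matrix
#'
#' Combines per-isolate genotype calls on a shared coordinate system into
#' an isolate x site matrix. Only variant sites are retained: a site where
#' at least one non-missing call differs from the reference or from another
#' isolate. Sites whose missing (`N`) fraction exceeds
#' `max_site_missing` (default 10%) are dropped. Sites are ordered by
#' (chrom, pos).
#'
#' @param calls Named list of per-isolate call tables from
#'   [call_genotypes()]; names are isolate ids.
#' @param max_site_missing Maximum tolerated per-site N fraction.
#' @return A `genotype_matrix`: list with `calls` (character matrix,
#'   isolates x sites), `sites` (data.table: chrom, pos, ref,
#'   missing_fraction), `isolates`.
#' @export
build_matrix <- function(calls, max_site_missing = 0.10) {
  if (is.null(names(calls)) || anyDuplicated(names(calls)))
    stop("calls must be a uniquely named list of isolate call tables")
  ids <- names(calls)
  key <- NULL
  for (i in seq_along(calls)) {
    k <- paste(calls[[i]]$chrom, calls[[i]]$pos)
    if (is.null(key)) key <- k
    else if (!identical(key, k))
      stop("isolates do not share a coordinate system")
  }
  tmpl <- calls[[1L]]
  m <- do.call(rbind, lapply(calls, `[[`, "call"))
  rownames(m) <- ids

  nonN <- m != "N"
  n_nonN <- colSums(nonN)
  ## variant: some non-N call differs from the reference base (two isolates
  ## differing from each other implies at least one differs from reference)
  variant <- colSums(nonN & (m != rep(tmpl$ref, each = nrow(m)))) > 0L
  miss_frac <- 1 - n_nonN / nrow(m)
  keep <- variant & miss_frac <= max_site_missing
  sites <- data.table::data.table(chrom = tmpl$chrom, pos = tmpl$pos,
                                  ref = tmpl$ref,
                                  missing_fraction = miss_frac)[keep]
  m <- m[, keep, drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord]
  m <- m[, ord, drop = FALSE]
  colnames(m) <- paste(sites$chrom, sites$pos, sep = ":")
  structure(list(calls = m, sites = sites, isolates = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$isolates), "isolates x",
      nrow(x$sites), "variant sites\n")
  invisible(x)
}

#' Per-isolate heterozygosity ratio
#'
#' The ratio of heterozygous (IUPAC-coded) genotype calls to the number of
#' callable (non-N) sites, the desk-scale analogue of the ratio of
#' heterozygous SNPs to the consensus genome size.
#'
#' @param calls A call table from [call_genotypes()] (all genotyped sites,
#'   not just variants).
#' @param callable_site_count Denominator; defaults to the number of non-N
#'   calls in `calls`.
#' @return Heterozygosity ratio (numeric scalar).
#' @export
heterozygosity <- function(calls, callable_site_count = NULL) {
  cl <- if (is.data.frame(calls)) calls$call else calls
  if (is.null(callable_site_count)) callable_site_count <- sum(cl != "N")
  if (callable_site_count <= 0) stop("callable site count must be positive")
  sum(cl %in% names(IUPAC_HET_ALLELES)) / callable_site_count
}

#' Export a genotype matrix as VCF v4.2
#'
#' One record per site; heterozygous IUPAC codes are expanded to `0/1`
#' (or `1/2` when neither allele is the reference), homozygous non-reference
#' calls to `1/1`, missing to `./.`. Multi-allelic sites list every observed
#' alternate allele.
#'
#' @param mat A `genotype_matrix`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_vcf <- function(mat, file) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (nrow(mat$sites) == 0L) stop("empty matrix")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=yeastpopgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", mat$isolates), collapse = "\t")), con)
  for (j in seq_len(nrow(mat$sites))) {
    ref <- mat$sites$ref[j]
    al <- expand_alleles(mat$calls[, j])
    alt <- sort(setdiff(unique(as.vector(al)), c(ref, NA)))
    idx <- function(b) ifelse(b == ref, 0L, match(b, alt))
    gt <- ifelse(is.na(al[1L, ]), "./.",
                 paste(pmin(idx(al[1L, ]), idx(al[2L, ])),
                       pmax(idx(al[1L, ]), idx(al[2L, ])), sep = "/"))
    writeLines(paste(c(mat$sites$chrom[j], mat$sites$pos[j], ".", ref,
                       if (length(alt)) paste(alt, collapse = ",") else ".",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a VCF written by [export_vcf()] back into a genotype matrix
#'
#' @param file VCF path.
#' @return A `genotype_matrix`.
#' @export
import_vcf <- function(file) {
  ln <- readLines(file)
  hdr <- ln[startsWith(ln, "#CHROM")]
  if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  ids <- cols[-(1:9)]
  body <- ln[!startsWith(ln, "#")]
  rec <- data.table::fread(text = body, header = FALSE, sep = "\t",
                           colClasses = list(character = 1))
  calls <- matrix("N", length(ids), nrow(rec),
                  dimnames = list(ids, NULL))
  for (j in seq_len(nrow(rec))) {
    ref <- rec[[4L]][j]
    alt <- if (rec[[5L]][j] == ".") character() else
      strsplit(rec[[5L]][j], ",", fixed = TRUE)[[1]]
    alleles <- c(ref, alt)
    gts <- as.character(rec[j, -(1:9), with = FALSE])
    a <- strsplit(gts, "/", fixed = TRUE)
    calls[, j] <- vapply(a, function(g) {
      if (any(g == ".")) return("N")
      b <- alleles[as.integer(g) + 1L]
      if (b[1] == b[2]) b[1] else het_code(b[1], b[2])
    }, character(1))
  }
  sites <- data.table::data.table(chrom = rec[[1L]], pos = rec[[2L]],
                                  ref = rec[[4L]],
                                  missing_fraction = colMeans(calls == "N"))
  colnames(calls) <- paste(sites$chrom, sites$pos, sep = ":")
  structure(list(calls = calls, sites = sites, isolates = ids),
            class = "genotype_matrix")
}
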