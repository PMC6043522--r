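#' Sample one haplotype from a diploid genotype matrix
#'
#' Resolves every heterozygous IUPAC call to one of its two encoded bases,
#' chosen uniformly and independently; homozygous and missing calls pass
#' through unchanged. This is one replicate of repeated random haplotype
#' sampling (RRHS), which builds trees from unphased diploid data.
#'
#' @param mat A `genotype_matrix` or a character matrix of calls.
#' @param seed Integer seed.
#' @return Character matrix of the same shape with no heterozygous codes.
#' @export
sample_haplotype <- function(mat, seed) {
  m <- if (inherits(mat, "genotype_matrix")) mat$calls else mat
  rng <- local_rng(seed)
  on.exit(rng())
  idx <- which(m %in% names(IUPAC_HET_ALLELES))
  if (length(idx)) {
    pair <- IUPAC_HET_ALLELES[m[idx]]
    pick <- stats::rbinom(length(idx), 1L, 0.5) + 1L
    m[idx] <- substr(pair, pick, pick)
  }
  m
}

#' Pairwise p-distances with pairwise deletion
#'
#' Proportion of mismatching sites among sites where both rows are non-N.
#' Pairs with zero comparable sites are set to `NA` and reported with a
#' warning, never silently imputed.
#'
#' @param m Character matrix (isolates x sites), free of heterozygous codes
#'   or not (every non-equal pair of non-N calls counts as a mismatch).
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
p_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  nonN <- m != "N"
  undefined <- character()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- nonN[i, ] & nonN[j, ]
    nc <- sum(ok)
    if (nc == 0L) {
      d[i, j] <- d[j, i] <- NA_real_
      undefined <- c(undefined, paste(rownames(m)[c(i, j)], collapse = "/"))
    } else {
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  if (length(undefined))
    warning("no comparable sites for pair(s): ",
            paste(undefined, collapse = ", "))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] that validates the input (symmetric,
#' zero diagonal, no NaN/NA) and clamps negative branch lengths to zero.
#' Triangle-inequality violations are counted and attached as the
#' `triangle_violations` attribute rather than silently corrected.
#'
#' @param d Symmetric numeric matrix with zero diagonal, n >= 3.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(is.na(d)) || any(is.nan(d))) stop("distance matrix contains NaN/NA")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  viol <- 0L
  n <- nrow(d)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (d[i, j] > d[i, k] + d[k, j] + 1e-12) viol <- viol + 1L
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "triangle_violations") <- viol
  tr
}

## canonical bipartition keys for every edge of an unrooted phylo tree;
## the side not containing `ref_tip` identifies the split
edge_splits <- function(tree, ref_tip) {
  tips <- tree$tip.label
  n <- length(tips)
  keys <- character(nrow(tree$edge))
  desc <- vector("list", max(tree$edge))
  for (t in seq_len(n)) desc[[t]] <- tips[t]
  ## postorder accumulation of the tip set below each node
  po <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    par <- po$edge[r, 1L]; chi <- po$edge[r, 2L]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  for (r in seq_len(nrow(tree$edge))) {
    chi <- tree$edge[r, 2L]
    side <- desc[[chi]]
    if (ref_tip %in% side) side <- setdiff(tips, side)
    keys[r] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' RRHS majority-rule consensus tree
#'
#' Runs `replicates` rounds of random haplotype sampling, builds one
#' neighbor-joining tree per replicate from pairwise-deletion p-distances,
#' and summarizes them in a majority-rule consensus: bipartitions present
#' in more than 50% of replicate trees are retained, annotated with their
#' support (% of replicates) and with branch lengths averaged over the
#' replicates containing the split. Terminal branch lengths are averaged
#' over all replicates.
#'
#' @param mat A `genotype_matrix` (>= 3 isolates).
#' @param replicates Number of RRHS replicates (default 100).
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param keep_trees Keep the per-replicate tree archive.
#' @return A `consensus_tree`: list with `tree` (phylo; `node.label` =
#'   supports), `supports` (data.table: split, support, mean_length),
#'   `replicates`, `triangle_violations`, and optionally `trees`.
#' @export
rrhs_consensus <- function(mat, replicates = 100L, seed = 1L,
                           keep_trees = FALSE) {
  m <- if (inherits(mat, "genotype_matrix")) mat$calls else mat
  if (nrow(m) < 3L) stop("need at least 3 isolates")
  if (replicates < 1L) stop("replicates must be >= 1")
  ids <- rownames(m)
  ref_tip <- sort(ids)[1L]
  trees <- vector("list", replicates)
  viol <- 0L
  split_count <- new.env(parent = emptyenv())
  split_lensum <- new.env(parent = emptyenv())
  for (r in seq_len(replicates)) {
    h <- sample_haplotype(m, seed + r)
    tr <- nj_tree(p_distance(h))
    viol <- viol + attr(tr, "triangle_violations")
    keys <- edge_splits(tr, ref_tip)
    for (e in seq_along(keys)) {
      k <- keys[e]
      split_count[[k]] <- (if (is.null(split_count[[k]])) 0L
                           else split_count[[k]]) + 1L
      split_lensum[[k]] <- (if (is.null(split_lensum[[k]])) 0
                            else split_lensum[[k]]) + tr$edge.length[e]
    }
    trees[[r]] <- tr
  }
  class(trees) <- "multiPhylo"

  cons <- ape::consensus(trees, p = 0.5)
  cons$edge.length <- rep(0, nrow(cons$edge))
  keys <- edge_splits(cons, ref_tip)
  support <- numeric(nrow(cons$edge))
  for (e in seq_along(keys)) {
    cnt <- split_count[[keys[e]]]
    if (is.null(cnt)) cnt <- 0L
    support[e] <- 100 * cnt / replicates
    cons$edge.length[e] <- if (cnt > 0L)
      split_lensum[[keys[e]]] / cnt else 0
  }
  ## enforce strict majority: collapse any internal edge at exactly 50%
  internal <- cons$edge[, 2L] > length(cons$tip.label)
  if (any(internal & support <= 50)) {
    cons$edge.length[internal & support <= 50] <- 0
    cons <- ape::di2multi(cons, tol = 1e-15)
    keys <- edge_splits(cons, ref_tip)
    support <- vapply(keys, function(k) {
      cnt <- split_count[[k]]; if (is.null(cnt)) 0 else 100 * cnt / replicates
    }, numeric(1))
    internal <- cons$edge[, 2L] > length(cons$tip.label)
  }
  ## node labels: support of the edge leading to each internal node
  nn <- cons$Nnode
  node.label <- rep("", nn)
  for (e in which(internal)) {
    node.label[cons$edge[e, 2L] - length(cons$tip.label)] <-
      format(round(support[e], 1))
  }
  cons$node.label <- node.label
  sup_tab <- data.table::data.table(
    split = keys[internal], support = support[internal],
    mean_length = cons$edge.length[internal])
  out <- list(tree = cons, supports = sup_tab, replicates = replicates,
              triangle_violations = viol)
  if (keep_trees) out$trees <- trees
  structure(out, class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("RRHS consensus over", x$replicates, "replicates;",
      length(x$tree$tip.label), "isolates;",
      nrow(x$supports), "majority splits (min support",
      if (nrow(x$supports)) min(x$supports$support) else NA, "%)\n")
  invisible(x)
}
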