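#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's internal sequence
#' representation (named character vector, one string per sequence).
#'
#' @param file Path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta`: named character vector. `write_fasta`: `file`,
#'   invisibly.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read and write BED intervals
#'
#' Plain 0-based half-open BED with an optional fourth name column.
#'
#' @param file Path.
#' @param bed data.frame with columns chrom, start, end and optionally
#'   name.
#' @return `read_bed`: data.table (chrom, start, end, name). `write_bed`:
#'   `file`, invisibly.
#' @export
read_bed <- function(file) {
  b <- data.table::fread(file, header = FALSE)
  if (ncol(b) < 3L) stop("malformed BED: fewer than 3 columns")
  b <- b[, 1:min(4L, ncol(b)), with = FALSE]
  data.table::setnames(b, c("chrom", "start", "end", "name")[seq_len(ncol(b))])
  if (any(b$end <= b$start)) stop("malformed BED: end <= start")
  b[]
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, file) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  data.table::fwrite(data.table::as.data.table(bed)[, cols, with = FALSE],
                     file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Read and write newick trees
#'
#' @param file Path.
#' @param tree A `phylo` object (or `consensus_tree`, whose annotated tree
#'   is written: supports as internal node labels, mean lengths as branch
#'   lengths).
#' @return `read_newick`: `phylo`. `write_newick`: `file`, invisibly.
#' @export
read_newick <- function(file) ape::read.tree(file)

#' @rdname read_newick
#' @export
write_newick <- function(tree, file) {
  if (inherits(tree, "consensus_tree")) tree <- tree$tree
  ape::write.tree(tree, file)
  invisible(file)
}

#' Read and write pileup tables
#'
#' Tab-separated site pileups: chrom, pos (1-based), ref, depth, A, C, G,
#' T.
#'
#' @param file Path.
#' @param pileup Pileup table.
#' @return `read_pileup_table`: data.table. `write_pileup_table`: `file`,
#'   invisibly.
#' @export
read_pileup_table <- function(file) {
  p <- data.table::fread(file, header = TRUE)
  need <- c("chrom", "pos", "ref", "depth", "A", "C", "G", "T")
  if (!all(need %in% names(p)))
    stop("malformed pileup table: need columns ",
         paste(need, collapse = ", "))
  p[, `:=`(chrom = as.character(chrom), ref = as.character(ref))]
  p[]
}

#' @rdname read_pileup_table
#' @export
write_pileup_table <- function(pileup, file) {
  data.table::fwrite(pileup, file, sep = "\t")
  invisible(file)
}

#' Read and write the genotype matrix as TSV
#'
#' Isolate x site table of IUPAC-coded calls; the first three columns hold
#' chrom, pos and ref, one column per isolate follows.
#'
#' @param mat A `genotype_matrix`.
#' @param file Path.
#' @return `read_genotype_matrix`: `genotype_matrix`.
#'   `write_genotype_matrix`: `file`, invisibly.
#' @export
write_genotype_matrix <- function(mat, file) {
  stopifnot(inherits(mat, "genotype_matrix"))
  tab <- data.table::data.table(chrom = mat$sites$chrom,
                                pos = mat$sites$pos, ref = mat$sites$ref)
  for (id in mat$isolates) tab[[id]] <- mat$calls[id, ]
  data.table::fwrite(tab, file, sep = "\t")
  invisible(file)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(file) {
  tab <- data.table::fread(file, header = TRUE,
                           colClasses = list(character = c("chrom", "ref")))
  ids <- setdiff(names(tab), c("chrom", "pos", "ref"))
  m <- t(as.matrix(tab[, ids, with = FALSE]))
  rownames(m) <- ids
  sites <- data.table::data.table(chrom = tab$chrom, pos = tab$pos,
                                  ref = tab$ref,
                                  missing_fraction = colMeans(m == "N"))
  colnames(m) <- paste(sites$chrom, sites$pos, sep = ":")
  structure(list(calls = m, sites = sites, isolates = ids),
            class = "genotype_matrix")
}
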