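#!/usr/bin/env Rscript
# RRHS consensus phylogeny: resolve every heterozygous genotype randomly
# to one allele, build one neighbor-joining tree per replicate from
# pairwise-deletion p-distances, and summarize 100 replicates in a
# majority-rule consensus with split supports and mean branch lengths.

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cohort <- make_study_cohort()
calls <- lapply(cohort$pileups, call_genotypes)
mat <- build_matrix(calls)

cat("RRHS consensus over 100 replicates...\n")
cons <- rrhs_consensus(mat, replicates = 100L, seed = STUDY_SEED)
print(cons)

write_newick(cons, file.path(results_dir(), "consensus.nwk"))
cat("  wrote results/consensus.nwk\n")
write_table(cons$supports, "splits.tsv")

## do lineage mates cluster? report the support of each lineage's split
iso <- cohort$isolates
ids <- sort(iso$id)
for (lin in unique(iso$lineage)) {
  side <- iso$id[iso$lineage == lin]
  if (length(side) < 2 || length(side) > nrow(iso) - 2) next
  if (ids[1] %in% side) side <- setdiff(ids, side)
  key <- paste(sort(side), collapse = "|")
  sup <- cons$supports$support[cons$supports$split == key]
  cat(sprintf("  lineage %s: split support %s\n", lin,
              if (length(sup)) sprintf("%.0f%%", sup) else "(not in consensus)"))
}
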