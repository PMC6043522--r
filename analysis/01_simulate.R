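#!/usr/bin/env Rscript
# Build the synthetic wild/domesticated cohort that all later stages
# analyze: 10 homozygous wild isolates in 10 lineages (pairwise divergence
# up to ~1.7%), 10 domesticated isolates formed by outcrossing related
# wild haplotypes (heterozygosity up to ~0.5%), with planted aneuploidy,
# gene CNVs and two alien fragments from a congeneric and an
# outside-genus donor.

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cat("Simulating cohort (seed", STUDY_SEED, ")...\n")
cohort <- make_study_cohort()
print(cohort)

write_table(cohort$isolates, "isolates.tsv")
write_table(cohort$truth$aliens, "truth_aliens.tsv")
write_fasta(cohort$reference, file.path(results_dir(), "reference.fasta"))
write_bed(cohort$spec$genes[, c("chrom", "start", "end", "name")],
          file.path(results_dir(), "genes.bed"))

aneu <- cohort$truth$chrom_copies - 2L
n_aneu <- sum(rowSums(aneu != 0) > 0)
cat(sprintf("Planted: %d/%d aneuploid isolates, %d gene-CNV events, %d alien fragments\n",
            n_aneu, nrow(cohort$isolates),
            sum(cohort$truth$gene_factors != 1),
            length(unique(cohort$truth$aliens$fragment))))
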