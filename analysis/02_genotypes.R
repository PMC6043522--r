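#!/usr/bin/env Rscript
# Genotype every isolate from its site pileups with the depth and
# allele-fraction filter stack (N below depth 15 or above 4x the isolate
# median; homozygous at >= 80% top-allele reads; IUPAC heterozygous at
# >= 20% second-allele reads), build the cohort SNP matrix under the 10%
# per-site N rule, and profile per-isolate heterozygosity.

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cohort <- make_study_cohort()
cat("Calling genotypes...\n")
calls <- lapply(cohort$pileups, call_genotypes)
mat <- build_matrix(calls)
print(mat)

het <- data.table::data.table(
  id = names(calls),
  group = cohort$isolates$group,
  heterozygosity = vapply(calls, heterozygosity, numeric(1)))
write_table(het, "heterozygosity.tsv")
write_genotype_matrix(mat, file.path(results_dir(), "snp_matrix.tsv"))
export_vcf(mat, file.path(results_dir(), "snps.vcf"))
cat("  wrote results/snp_matrix.tsv, results/snps.vcf\n")

avg <- het[, .(mean_het = mean(heterozygosity)), by = group]
print(avg)
cat(sprintf("Mean heterozygosity: wild %.4f%%, domesticated %.4f%% (the wild << domesticated contrast)\n",
            100 * avg$mean_het[avg$group == "wild"],
            100 * avg$mean_het[avg$group == "domesticated"]))
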