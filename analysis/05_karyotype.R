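#!/usr/bin/env Rscript
# Karyotype and gene copy number: normalized 1000-bp coverage frames, the
# flow-cytometry-adjusted chromosome calls (Va = D x (Vo - 1) with the
# printed bins), cohort aneuploidy patterns, per-gene CNV values
# discretized by the cohort's empirical tails, and wild-vs-domesticated
# CNV tests at P < 0.01.

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cohort <- make_study_cohort()
iso <- cohort$isolates
frames <- lapply(cohort$pileups, frame_values)

chrom_calls <- data.table::rbindlist(lapply(iso$id, function(id)
  cbind(id = id, call_chromosomes(frames[[id]], iso$D[iso$id == id]))))
write_table(chrom_calls, "chromosome_calls.tsv")

patterns <- vapply(iso$id, function(i) {
  cc <- chrom_calls[chrom_calls$id == i]
  aneuploidy_pattern(stats::setNames(cc$delta, cc$chrom))
}, character(1))
ps <- count_aneuploidy_patterns(patterns)
cat(sprintf("Aneuploidy: %d/%d isolates, %d distinct patterns\n",
            ps$n_aneuploid, nrow(iso), ps$n_patterns))
truth_delta <- cohort$truth$chrom_copies - 2L
agree <- mean(vapply(iso$id, function(i) {
  cc <- chrom_calls[chrom_calls$id == i]
  all(cc$delta == truth_delta[i, cc$chrom])
}, logical(1)))
cat(sprintf("  isolates whose full karyotype matches planted truth: %.0f%%\n",
            100 * agree))

gvals <- data.table::rbindlist(lapply(iso$id, function(id)
  cbind(id = id, gene_values(frames[[id]], cohort$spec$genes))))
tails <- fit_tails(gvals$value)
cat("Fitted cohort tails:", paste(sprintf("%.2f", tails), collapse = ", "),
    "(printed study defaults: 0.34, 0.73, 1.2, 1.74)\n")
gvals[, level := discretize(value, default_tails())]
write_table(gvals, "gene_cnv.tsv")
cat(sprintf("  non-normal gene levels: %d of %d gene x isolate values\n",
            sum(gvals$level != 1), nrow(gvals)))

wildv <- iso$id[iso$group == "wild"]
domv <- iso$id[iso$group == "domesticated"]
sig <- data.table::rbindlist(lapply(unique(gvals$gene), function(g) {
  tst <- cnv_group_test(gvals[gene == g & id %in% wildv, value],
                        gvals[gene == g & id %in% domv, value])
  data.table::data.table(gene = g, p = tst$p, significant = tst$significant)
}))
write_table(sig, "cnv_significance.tsv")
cat(sprintf("Genes with significant wild/domesticated CNV difference (P < 0.01): %d\n",
            sum(sig$significant)))
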