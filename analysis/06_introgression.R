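#!/usr/bin/env Rscript
# Introgression/HGT scan: sliding-window (1000/500 bp) identity of every
# assembly against the conspecific references, stage-1 candidates at
# < 95% identity over >= 1 kb, stage-2 refinement at < 93% over >= 1.5 kb
# with single-carrier short fragments removed, then donor assignment from
# the multi-species library (congeneric donor -> introgression,
# outside-genus -> HGT, no donor >= 65% -> unknown).

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cohort <- make_study_cohort()
cat("Scanning", nrow(cohort$isolates), "assemblies...\n")
res <- scan_cohort(cohort_assemblies(cohort), cohort$library)
print(res$fragments)
write_table(res$fragments, "fragments.tsv")

truth <- unique(cohort$truth$aliens[, c("fragment", "donor", "chrom",
                                        "start", "end")])
recovered <- sum(vapply(seq_len(nrow(truth)), function(i)
  any(res$fragments$chrom == truth$chrom[i] &
        abs(res$fragments$start - truth$start[i]) <= 500 &
        abs(res$fragments$end - truth$end[i]) <= 500 &
        res$fragments$donor == truth$donor[i]), logical(1)))
cat(sprintf("Recovered %d/%d planted fragments with boundaries within one window step\n",
            recovered, nrow(truth)))
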