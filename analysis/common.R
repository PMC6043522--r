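# Shared study-cohort construction for the numbered analysis drivers.
# Every driver regenerates the same cohort from one seed, so each script
# is independently runnable and all outputs are reproducible.

library(yeastpopgen)

STUDY_SEED <- as.integer(Sys.getenv("COHORT_SEED", "1"))

make_study_cohort <- function(seed = STUDY_SEED) {
  ## 5 wild and 5 domesticated lineages with two isolates each: enough
  ## isolates per lineage that lineage-specific variants are not removed
  ## as singletons by the polymorphism partition
  simulate_cohort(
    spec = default_genome_spec(),
    n_wild = 10L, n_domesticated = 10L,
    n_wild_lineages = 5L, n_dom_lineages = 5L,
    mean_depth = 80, error_rate = 0.002,
    seed = seed)
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_table <- function(x, name) {
  p <- file.path(results_dir(), name)
  data.table::fwrite(x, p, sep = "\t")
  cat("  wrote", p, "\n")
  p
}
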