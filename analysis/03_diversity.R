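#!/usr/bin/env Rscript
# Partition sequence variation: nucleotide diversity (pi) and Watterson's
# theta per ecological group (sites qualifying when >= 80% of the group is
# non-missing), the shared/fixed/private polymorphism partition between
# the wild and domesticated groups (75% nonmissing rule, singletons
# removed, IUPAC codes valid), and a rank correlation of heterozygosity
# with a synthetic sporulation-like phenotype.

source(file.path(dirname(sub("^--file=", "",
  grep("^--file=", commandArgs(FALSE), value = TRUE)[1])), "common.R"))

cohort <- make_study_cohort()
calls <- lapply(cohort$pileups, call_genotypes)
mat <- build_matrix(calls)
iso <- cohort$isolates
wild <- iso$id[iso$group == "wild"]
dom <- iso$id[iso$group == "domesticated"]

## per-site denominators need the callable invariant sites too
callable <- vapply(calls, function(x) sum(x$call != "N"), numeric(1))
invariant <- max(round(mean(callable)) - nrow(mat$sites), 0)

div <- data.table::rbindlist(lapply(
  list(wild = wild, domesticated = dom), function(members) {
    d <- nucleotide_diversity(mat, members, invariant_sites = invariant)
    data.table::data.table(n = d$group_size, S = d$S, pi = d$pi,
                           theta = d$theta)
  }), idcol = "group")
print(div)
write_table(div, "diversity.tsv")

part <- polymorphism_partition(mat, wild, dom)
sf <- shared_fraction(part)
cat(sprintf("Polymorphism partition (wild vs domesticated): shared %d, fixed %d, private %d/%d -> %.1f%% shared\n",
            part$counts[["shared"]], part$counts[["fixed"]],
            part$counts[["privateA"]], part$counts[["privateB"]], sf))
write_table(data.table::data.table(
  pair = "wild/domesticated", t(part$counts),
  analyzed_sites = part$analyzed_sites, shared_pct = sf),
  "polymorphism_partition.tsv")

## shared polymorphism between two domesticated groups (common admixed
## ancestry) versus between two groups of long-isolated wild lineages --
## the domesticated >> wild sharing contrast
half <- function(ids, lin) {
  lins <- unique(lin)
  ids[lin %in% lins[seq_len(floor(length(lins) / 2))]]
}
dom_lin <- iso$lineage[match(dom, iso$id)]
domA <- half(dom, dom_lin); domB <- setdiff(dom, domA)
wild_lin <- iso$lineage[match(wild, iso$id)]
wildA <- half(wild, wild_lin); wildB <- setdiff(wild, wildA)
sf_dom <- shared_fraction(polymorphism_partition(mat, domA, domB))
sf_wild <- shared_fraction(polymorphism_partition(mat, wildA, wildB))
cat(sprintf("Shared polymorphisms: domesticated/domesticated %.1f%% vs wild/wild %.1f%%\n",
            sf_dom, sf_wild))

## synthetic phenotype: sporulation declines with heterozygosity, plus
## measurement noise -- the negative rank correlation the study reports
## between sexuality and heterozygosity
het <- vapply(calls, heterozygosity, numeric(1))
set.seed(STUDY_SEED)
sporulation <- pmax(0, 0.8 - 120 * het + rnorm(length(het), 0, 0.12))
rho <- rank_correlation(het, sporulation)
cat(sprintf("Spearman rho (heterozygosity vs synthetic sporulation rate): %.2f\n", rho))
write_table(data.table::data.table(id = names(het), heterozygosity = het,
                                   sporulation = sporulation),
            "phenotype.tsv")
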