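---
title: "Methods: population genomics of yeast domestication from pileup data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of yeast domestication from pileup data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`yeastpopgen` implements, as reusable and testable R functions, the
computational procedures used in population-genomic surveys that contrast
wild and domesticated *Saccharomyces cerevisiae*: genotype calling from
site pileups with an allele-fraction filter stack, heterozygosity
profiling, RRHS consensus phylogenetics, diversity and polymorphism
partitioning, flow-cytometry-adjusted aneuploidy and gene copy-number
calling, and a windowed introgression/HGT scan. Because the procedures are
ordinarily run on hundreds of resequenced genomes, the package ships a
synthetic cohort generator with complete ground truth so that every stage
can be exercised and validated at desk scale.

## The genotype model

The pipeline's entry contract is a per-isolate site pileup: chromosome,
1-based position, reference base, read depth, and read counts per base.
Base-quality filtering is assumed to have happened upstream (during
mapping), so counts are taken at face value. A site's genotype is called
by a fixed rule stack:

* **missing (`N`)** when depth < 15 or depth > 4 × the isolate's median
  depth (the high tail marks collapsed repeats and duplications);
* **homozygous** for the top allele when it carries ≥ 80% of reads;
* **heterozygous**, encoded as the IUPAC ambiguity code of the top two
  alleles, when the second allele carries ≥ 20% of reads;
* **missing** otherwise, and also when a *third* allele reaches 20% —
  a two-allele rule cannot describe such a pileup, and at depth ≥ 15 a
  triallelic signal indicates an artifact rather than a genotype.

An exact 50/50 tie is heterozygous (the 20% rule is satisfied
symmetrically); at exactly 80/20 the homozygous rule is applied first.
The cohort SNP matrix keeps variant sites only (some non-missing call
differs from the reference) and drops sites with more than 10% missing
calls. Heterozygosity is reported as heterozygous calls over callable
(non-`N`) sites — the computable desk-scale analogue of "heterozygous
SNPs per consensus genome size".

## RRHS consensus phylogenetics

Unphased diploid data cannot be fed directly to a tree builder. Repeated
random haplotype sampling (RRHS) resolves every heterozygous call to one
of its two alleles, uniformly and independently, and repeats this (100
replicates by default). Each replicate yields a homozygous matrix, a
pairwise-deletion p-distance matrix, and an unrooted neighbor-joining
tree (negative branch lengths clamped to zero). The replicates are
summarized in a majority-rule consensus: bipartitions present in more
than half of the replicate trees, annotated with their frequency as
support and with branch lengths averaged over the replicates containing
the split; terminal branches average over all replicates.

The per-replicate tree engine is neighbor-joining rather than a
likelihood search: the protocol of interest here is RRHS plus consensus
summarization, and any builder satisfying the newick contract can be
substituted. Replicate *r* uses seed `seed + r`, so any single replicate
can be reproduced in isolation. Distance matrices are validated, not
repaired: asymmetry and NaN are errors, and triangle-inequality
violations are counted and reported on the result object.

A property of RRHS worth knowing: isolates of one clonal, highly
heterozygous lineage resolve their shared heterozygous sites
*independently* in each replicate, which inflates their apparent pairwise
distance by about half the heterozygosity. Lineages whose true divergence
is comparable to that noise floor may fail to reach majority support even
though deeply divergent lineages resolve at 100%; the analysis drivers
report both outcomes.

## Diversity and polymorphism partitioning

For a group of isolates, each diploid call expands to two allele copies
(heterozygous codes contribute one copy of each allele). A site is
analyzed when at least 80% of the group is non-missing there. Nucleotide
diversity π sums the per-site mean pairwise difference over allele copies
and divides by analyzed variant sites plus the callable invariant-site
count supplied by the caller — the matrix holds only variant sites, so
the invariant count restores a genome-scale per-site quantity.
Watterson's θ uses the segregating-site count with the harmonic number
for k = 2 × group size allele copies, over the same denominator.

Between two groups, each retained site (≥ 75% valid data over the pooled
pair; heterozygous IUPAC codes count as valid; singleton variants —
carried by exactly one isolate of the pooled pair — removed) is
classified as a **shared polymorphism** (segregating in both groups), a
**fixed difference** (each group monomorphic for different alleles), or
a **private polymorphism** of one group. In `ambiguity` mode a site may
carry more than two alleles; `biallelic` mode treats heterozygous calls
as missing and skips multi-allelic sites. The shared percentage is
reported over all classified sites of the pair — the denominator behind
published shared-polymorphism percentages is not standardized, so this
package's convention is declared rather than asserted to match any
particular one. Spearman correlation (average ranks for ties) relates
heterozygosity to phenotypes.

## Karyotype and gene copy number

Read depth is averaged in nonoverlapping 1000-bp frames and normalized by
the genome-wide **median** frame depth, making every value a copy number
relative to the basal ploidy (1.0 = basal) and leaving all downstream
calls invariant to global depth rescaling. A partial tail frame is
averaged over its own length. No GC or positional bias correction is
applied: the synthetic coverage model is unbiased by construction, and at
desk scale such corrections would fit noise.

Per chromosome, the original copy value Vo is the median frame value —
robust against segmental events. The flow-cytometry adjustment
**Va = D × (Vo − 1)**, with D the isolate's relative DNA content per cell
(haploid = 1), converts a relative coverage deviation into an absolute
copy-number deviation: one extra chromosome in a diploid (Vo = 1.5,
D = 2) gives Va = 1 regardless of basal ploidy. Va is classified with the
published bins: < −0.7 → one copy lost; [−0.6, 0.5] → no change;
[0.6, 1.6] → one extra copy; [1.7, 2.6] → two extra copies. The bins
leave narrow gaps and an open top; values there are assigned to the
nearest boundary's bin (exact midpoints to the lower bin) or to +2 above
2.6, and flagged *ambiguous* so downstream consumers can treat them
specially. On chromosomes called euploid, a contiguous run of at least 50
frames (50 kb) whose run-median Va falls in a nonzero bin is reported as
a partial-chromosome event (±0.5). The 50-frame floor is this package's
convention: published karyotype figures show ±0.5 calls without stating a
criterion, and 50 kb excludes single-gene CNVs while catching arm-scale
events.

Gene copy values take the per-base median over the open reading frame
(each base inherits its frame's value; even counts take the midpoint of
the two central values), and are discretized by empirical tails of the
cohort's gene-value distribution — 1st/5th/95th/99th percentiles, or the
published defaults 0.34/0.73/1.2/1.74 fitted on a 254-isolate cohort:
level 0 (complete deletion) below the 1% left tail, 0.5 up to the 5% left
tail, 1 (normal) between the 5% tails, 2 up to the 1% right tail, 3
(three-or-more-fold, the open top bin coded by its minimum) above it.
Tail fitting on a small synthetic cohort produces much narrower tails
than the published defaults — with few planted CNVs, the 1st and 99th
percentiles sit close to 1.0 — so the drivers discretize with the
published defaults and print the fitted values alongside for comparison.
Group differences per gene use the Wilcoxon rank-sum test by default
(Student's t on request) with significance at P < 0.01; an all-tied
comparison is reported as P = 1 with a flag rather than an error.

## The introgression/HGT scan

Assemblies are scanned in 1000-bp windows every 500 bp against the
conspecific references of a multi-species library. The identity engine
anchors each window by exact 15-mer seed matches (Aho–Corasick over all
window k-mers), lets seed hits vote for diagonals, and scores the best
diagonals by ungapped column comparison — the package's mutation model is
substitution-only, so a banded extension around an anchor reduces to its
diagonal. Identity is matched columns over aligned columns; coverage is
the aligned fraction of the window. A window with identity < 65% *and*
coverage < 30% is treated as a deletion and its identity set to 0.

Candidates are maximal runs of windows whose best conspecific identity
falls below 95%, spanning ≥ 1 kb. Because a window overlapping a
fragment boundary by only a few hundred bases can still dip below 95%,
candidate ends are trimmed in 500-bp blocks whose own anchored identity
is at or above the threshold; this keeps recovered boundaries within one
window step (500 bp) of the true changepoint. Stage two raises the bar to
mean conspecific identity < 93% (deletion windows excluded from the mean
— they carry no alignment signal) and length ≥ 1.5 kb, unifies candidates
from different isolates whose intervals overlap by at least half of the
shorter one, and drops fragments below 3 kb (2 × the length floor)
carried by a single isolate — published filters name "short
single-isolate fragments" without quantifying either term, so both
operationalizations are declared here. Donors are assigned per fragment
as the non-conspecific taxon with the highest mean window identity of at
least 65%: an outside-genus donor classes the fragment as HGT, a
congeneric donor as introgression, and no donor above the floor as
unknown. The 93% threshold is applied to the whole-fragment mean, not per
window; published methods do not state which, and the fragment mean is
robust to single noisy windows.

## The synthetic cohort generator

The generator emulates the statistical structure of a domestication
cohort on a scaled-down genome (default: five chromosomes, 92 kb total,
with small chromosomes named I, III and VI and 1-kb genes every 4 kb).
As in the real karyotype no chromosome dominates the genome, which the
median-frame normalization depends on. All randomness flows from one
seed; identical seeds give byte-identical cohorts, and every planted
feature is recorded as ground truth.

* **Wild isolates** are fully homozygous diploids in lineages diverged
  0.1–0.85% from a common ancestor (pairwise up to ~1.7%, the maximum
  divergence observed between conspecific lineages), with 0.02%
  within-lineage divergence keeping lineage mates distinct.
* **Domesticated isolates** descend from a single founding outcross of
  two haplotypes from one wild lineage — the strong domestication
  bottleneck — with total parental divergence drawn from 0.1–0.5% (the
  observed heterozygosity range), budgeted between the founding cross
  and a small per-lineage layer. Because every domesticated lineage
  inherits the founding cross's heterozygous sites, those sites keep
  segregating in all domesticated lineages, reproducing the high shared
  polymorphism among domesticated groups next to near-zero sharing
  between wild lineages.
* **Aneuploidy** hits an isolate with probability 0.32 (the observed
  aneuploid fraction), choosing chromosomes with probability ∝ 1/length
  (the small-chromosome bias), mostly +1 with occasional +2 and rare −1
  (chromosome loss is rare in the real cohort).
* **Gene CNVs**: one random gene per affected isolate at factor 0, 2 or
  3; additionally one designated gene is amplified preferentially in
  domesticated isolates, the analogue of fermentation-gene
  amplifications, giving the group CNV test a true positive.
* **Alien fragments** replace sequence on both haplotypes with the donor
  genome's sequence over the same interval (fragment presence is a
  property of the isolate, which is how carriers are reported); donors
  sit at 5–40% divergence, congeneric or outside-genus.
* **Pileups**: per-site depth ~ Poisson(mean depth × local copy number /
  basal ploidy), where the local copy number is the chromosome copy count
  times the gene factor; read bases are multinomial over the two true
  alleles with a uniform error floor. Coverage is simulated per site, not
  per read — no mapping stage is in scope, and the pileup table is the
  pipeline's entry contract. Flow-cytometry D is the true ploidy plus
  Gaussian noise (sd 0.05), truncated positive.

The mutation model is uniform substitution without indels; the
statistics in scope are substitution-based, and coordinates stay aligned
across the whole cohort, which is also why the scan's identity engine
needs no gapped alignment. This is the main respect in which passing
tests understate real data: indels, repeats, mapping artifacts and GC
bias are absent, so the filter stack's robustness to them is not
demonstrated here — only the correctness of every rule on data satisfying
its model.

## Problem sizes and numerical conventions

The analysis drivers use 20 isolates (5 wild and 5 domesticated lineages,
two isolates each — enough per lineage that lineage variants are not
removed as pooled singletons) at 80× depth on the 92-kb genome; the test
suite uses the same genome at 50× with smaller cohorts, 10–25 RRHS
replicates for unit tests and 100 for the structured-cohort check, and
twenty 2×3-isolate null cohorts for the scan's specificity. Percentile
thresholds use R's default quantile definition. Medians of even counts
take midpoints. Genotype ties in allele ordering break by base order
(A < C < G < T). All intervals are 0-based half-open internally; pileup
and VCF positions are 1-based.

## Known limitations

RRHS support values measure resolution stability under haplotype
sampling, not bootstrap support over sites. The scan's seed-and-diagonal
identity engine assumes collinearity; rearranged or gapped homology would
need a gapped aligner behind the same window-identity contract. The
partition's shared-percentage denominator and the single-isolate-fragment
rule are declared conventions, and comparisons against published
percentages should expect convention-level differences. Tail fitting
requires a cohort with real CNV spread; on clean cohorts the fitted tails
collapse toward 1.0 and the published defaults should be used instead.
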