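#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its default, grouped by
#' stage. Defaults are the published values of the filter stack wherever
#' one exists.
#'
#' @return Nested named list of stage settings.
#' @export
pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "call", "stats", "phylo", "karyotype", "scan"),
    simulate = list(
      n_wild = 10L, n_domesticated = 10L,
      n_wild_lineages = 10L, n_dom_lineages = 5L,
      mean_depth = 80, error_rate = 0.002, flow_noise_sd = 0.05,
      genome_scale = 1, write_pileups = FALSE),
    call = list(
      min_depth = 15L, max_depth_factor = 4, hom_fraction = 0.80,
      het_fraction = 0.20, max_site_missing = 0.10),
    stats = list(
      min_group_coverage = 0.80, min_nonmissing = 0.75,
      drop_singletons = TRUE, mode = "ambiguity"),
    phylo = list(replicates = 100L),
    karyotype = list(
      frame_size = 1000L, tails = "fit", test = "wilcoxon", alpha = 0.01),
    scan = list(
      stage1_identity = 95, stage1_min_len = 1000L,
      final_identity = 93, final_min_len = 1500L,
      window = 1000L, step = 500L, k = 15L)
  )
}

## merge user settings over defaults, rejecting unknown keys at any level
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Load a pipeline configuration from a YAML file
#'
#' Settings in the file override the defaults of [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param file YAML path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return Validated configuration list.
#' @export
load_config <- function(file = NULL, overrides = NULL) {
  cfg <- pipeline_config()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg$call, {
    if (min_depth < 0) stop("invalid config: min_depth must be >= 0")
    if (max_depth_factor <= 0)
      stop("invalid config: max_depth_factor must be > 0")
    if (hom_fraction < 0.5 || hom_fraction > 1)
      stop("invalid config: hom_fraction must be in [0.5, 1]")
    if (het_fraction < 0 || het_fraction > 0.5)
      stop("invalid config: het_fraction must be in [0, 0.5]")
  })
  if (cfg$simulate$mean_depth < 1)
    stop("invalid config: mean_depth must be >= 1")
  if (cfg$phylo$replicates < 1)
    stop("invalid config: replicates must be >= 1")
  if (!cfg$karyotype$tails %in% c("default", "fit"))
    stop("invalid config: tails must be 'default' or 'fit'")
  if (!cfg$karyotype$test %in% c("wilcoxon", "ttest"))
    stop("invalid config: test must be 'wilcoxon' or 'ttest'")
  bad <- setdiff(cfg$stages,
                 c("simulate", "call", "stats", "phylo", "karyotype", "scan"))
  if (length(bad)) stop("invalid config: unknown stage ", bad[1])
  invisible(cfg)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Composes the stages in the study's order - simulate, genotype calling,
#' population statistics, RRHS phylogeny, karyotype/CNV, introgression
#' scan - writing every stage's tables under `out_dir` together with a run
#' manifest (resolved configuration, package version, md5 checksum of every
#' output). All randomness derives from `config$seed`, so a manifest
#' suffices to reproduce any output byte for byte.
#'
#' @param config Configuration from [pipeline_config()] or [load_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the key in-memory objects (`cohort`,
#'   `matrix`, `het`, `stats`, `consensus`, `karyotype`, `fragments`) and
#'   the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  res <- list()
  paths <- character()
  emit <- function(x, name, writer) {
    p <- file.path(out_dir, name)
    writer(x, p)
    paths <<- c(paths, p)
    p
  }

  if (!"simulate" %in% config$stages)
    stop("stage 'simulate' is required: this pipeline runs on synthetic cohorts")
  say("[simulate] cohort (seed %d)", config$seed)
  sc <- config$simulate
  cohort <- simulate_cohort(
    spec = default_genome_spec(scale = sc$genome_scale),
    n_wild = sc$n_wild, n_domesticated = sc$n_domesticated,
    n_wild_lineages = sc$n_wild_lineages,
    n_dom_lineages = sc$n_dom_lineages,
    mean_depth = sc$mean_depth, error_rate = sc$error_rate,
    flow_noise_sd = sc$flow_noise_sd, seed = config$seed)
  res$cohort <- cohort
  emit(cohort$isolates, "isolates.tsv",
       function(x, p) data.table::fwrite(x, p, sep = "\t"))
  emit(cohort$reference, "reference.fasta", write_fasta)
  emit(cohort$truth$aliens, "truth_aliens.tsv",
       function(x, p) data.table::fwrite(x, p, sep = "\t"))
  if (isTRUE(sc$write_pileups))
    for (id in cohort$isolates$id)
      emit(cohort$pileups[[id]], sprintf("pileup_%s.tsv", id),
           write_pileup_table)

  calls <- NULL
  if ("call" %in% config$stages) {
    say("[call] genotypes for %d isolates", nrow(cohort$isolates))
    cc <- config$call
    calls <- lapply(cohort$pileups, call_genotypes,
                    min_depth = cc$min_depth,
                    max_depth_factor = cc$max_depth_factor,
                    hom_fraction = cc$hom_fraction,
                    het_fraction = cc$het_fraction)
    mat <- build_matrix(calls, max_site_missing = cc$max_site_missing)
    het <- data.table::data.table(
      id = names(calls),
      heterozygosity = vapply(calls, heterozygosity, numeric(1)))
    res$matrix <- mat
    res$het <- het
    emit(mat, "snp_matrix.tsv", write_genotype_matrix)
    emit(het, "heterozygosity.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
    if (nrow(mat$sites) > 0L) emit(mat, "snps.vcf", export_vcf)
  }

  if ("stats" %in% config$stages && !is.null(res$matrix)) {
    say("[stats] diversity and polymorphism partition")
    st <- config$stats
    iso <- cohort$isolates
    wild <- iso$id[iso$group == "wild"]
    dom <- iso$id[iso$group == "domesticated"]
    callable <- vapply(calls, function(x) sum(x$call != "N"), numeric(1))
    invariant <- round(mean(callable)) - nrow(res$matrix$sites)
    groups <- list(wild = wild, domesticated = dom)
    div <- data.table::rbindlist(lapply(names(groups), function(g) {
      if (length(groups[[g]]) < 2L) return(NULL)
      d <- nucleotide_diversity(res$matrix, groups[[g]],
                                min_group_coverage = st$min_group_coverage,
                                invariant_sites = max(invariant, 0))
      data.table::data.table(group = g, n = d$group_size, S = d$S,
                             pi = d$pi, theta = d$theta,
                             analyzed_sites = d$analyzed_sites)
    }))
    res$stats <- list(diversity = div)
    emit(div, "diversity.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
    if (length(wild) >= 2L && length(dom) >= 2L) {
      part <- polymorphism_partition(res$matrix, wild, dom,
                                     min_nonmissing = st$min_nonmissing,
                                     drop_singletons = st$drop_singletons,
                                     mode = st$mode)
      ptab <- data.table::data.table(
        pair = "wild/domesticated",
        shared = part$counts[["shared"]], fixed = part$counts[["fixed"]],
        privateA = part$counts[["privateA"]],
        privateB = part$counts[["privateB"]],
        analyzed_sites = part$analyzed_sites,
        shared_pct = suppressWarnings(shared_fraction(part)))
      res$stats$partition <- ptab
      emit(ptab, "polymorphism_partition.tsv",
           function(x, p) data.table::fwrite(x, p, sep = "\t"))
    }
  }

  if ("phylo" %in% config$stages && !is.null(res$matrix) &&
      length(res$matrix$isolates) >= 3L && nrow(res$matrix$sites) >= 1L) {
    say("[phylo] RRHS consensus (%d replicates)", config$phylo$replicates)
    cons <- rrhs_consensus(res$matrix, replicates = config$phylo$replicates,
                           seed = config$seed)
    res$consensus <- cons
    emit(cons, "consensus.nwk", write_newick)
    emit(cons$supports, "splits.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
  }

  if ("karyotype" %in% config$stages) {
    say("[karyotype] chromosome and gene CNV calls")
    ky <- config$karyotype
    iso <- cohort$isolates
    frames <- lapply(cohort$pileups, frame_values, frame = ky$frame_size)
    chrom_calls <- data.table::rbindlist(lapply(iso$id, function(id) {
      cbind(id = id, call_chromosomes(frames[[id]], iso$D[iso$id == id]))
    }))
    gvals <- data.table::rbindlist(lapply(iso$id, function(id) {
      cbind(id = id, gene_values(frames[[id]], cohort$spec$genes))
    }))
    thresholds <- if (ky$tails == "default") default_tails()
      else fit_tails(gvals$value)
    gvals[, level := discretize(value, thresholds)]
    patterns <- vapply(iso$id, function(i) {
      cc <- chrom_calls[chrom_calls$id == i]
      aneuploidy_pattern(stats::setNames(cc$delta, cc$chrom))
    }, character(1))
    wildv <- iso$id[iso$group == "wild"]
    domv <- iso$id[iso$group == "domesticated"]
    sig <- NULL
    if (length(wildv) >= 3L && length(domv) >= 3L) {
      sig <- data.table::rbindlist(lapply(unique(gvals$gene), function(g) {
        tst <- cnv_group_test(gvals[gene == g & id %in% wildv, value],
                              gvals[gene == g & id %in% domv, value],
                              test = ky$test, alpha = ky$alpha)
        data.table::data.table(gene = g, p = tst$p,
                               significant = tst$significant,
                               tied = tst$tied)
      }))
    }
    res$karyotype <- list(chrom_calls = chrom_calls, gene_values = gvals,
                          thresholds = thresholds, patterns = patterns,
                          pattern_summary = count_aneuploidy_patterns(patterns),
                          significance = sig)
    emit(chrom_calls, "chromosome_calls.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
    emit(gvals, "gene_cnv.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
    if (!is.null(sig))
      emit(sig, "cnv_significance.tsv",
           function(x, p) data.table::fwrite(x, p, sep = "\t"))
  }

  if ("scan" %in% config$stages) {
    say("[scan] introgression/HGT windows")
    sn <- config$scan
    scan <- scan_cohort(cohort_assemblies(cohort), cohort$library,
                        stage1_identity = sn$stage1_identity,
                        stage1_min_len = sn$stage1_min_len,
                        final_identity = sn$final_identity,
                        final_min_len = sn$final_min_len,
                        window = sn$window, step = sn$step, k = sn$k)
    res$fragments <- scan$fragments
    emit(scan$fragments, "fragments.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
  }

  manifest <- list(
    package = "yeastpopgen",
    version = as.character(utils::packageVersion("yeastpopgen")),
    config = config,
    outputs = lapply(stats::setNames(nm = basename(paths)), function(b)
      unname(tools::md5sum(file.path(out_dir, b)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  say("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(res)
}
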