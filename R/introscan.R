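## Sliding-window grid over one chromosome: `window`-bp windows every
## `step` bp (0-based half-open); tail windows shorter than `min_tail`
## are dropped.
window_grid <- function(len, window = 1000L, step = 500L, min_tail = 200L) {
  starts <- seq.int(0L, max(0L, len - 1L), by = step)
  ends <- pmin(starts + window, len)
  keep <- ends - starts >= min_tail & (starts == 0L | ends > starts)
  ## drop redundant tail windows fully contained in the previous one
  keep <- keep & !duplicated(ends)
  data.table::data.table(start = starts[keep], end = ends[keep])
}

#' Sliding-window identity of an assembly against reference taxa
#'
#' Computes, for every 1000-bp window (500-bp step) of the query assembly
#' and every requested taxon of the library, the best anchored identity and
#' aligned coverage on the homologous chromosome. Windows where identity
#' < `del_identity` (65%) and coverage < `del_coverage` (30%) are regarded
#' as deletions and their identity is set to 0 (`deleted = TRUE`).
#'
#' @param assembly Named character vector (chromosome -> sequence).
#' @param library A `reference_library` from [simulate_donor_library()] (or
#'   a list with `seqs` and `taxa`).
#' @param taxa Taxon names to scan against (default: all in the library).
#' @param window,step Window and step size in bp.
#' @param k Seed k-mer length for anchoring.
#' @param del_identity,del_coverage Deletion-rule thresholds.
#' @return data.table: chrom, start, end, taxon, identity, coverage,
#'   deleted.
#' @export
window_identity <- function(assembly, library, taxa = NULL,
                            window = 1000L, step = 500L, k = 15L,
                            del_identity = 65, del_coverage = 0.30) {
  if (is.null(taxa)) taxa <- library$taxa$taxon
  if (!length(taxa)) stop("empty reference set")
  out <- list()
  for (ch in names(assembly)) {
    qchars_all <- seq_chars(assembly[[ch]])
    qlen <- length(qchars_all)
    grid <- window_grid(qlen, window, step)
    ## one exact k-mer matching pass per (chromosome, taxon); windows then
    ## aggregate the seed hits falling inside them
    qdna <- Biostrings::DNAString(assembly[[ch]])
    if (qlen >= k) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(
        qdna, start = seq_len(qlen - k + 1L), width = k))
    } else pd <- NULL
    for (t in taxa) {
      s <- library$seqs[[t]][[ch]]
      if (is.null(s)) next
      ref_len <- nchar(s)
      rchars <- seq_chars(s)
      if (!is.null(pd)) {
        starts <- Biostrings::startIndex(
          Biostrings::matchPDict(pd, Biostrings::DNAString(s)))
        qpos <- rep(seq_len(qlen - k + 1L), lengths(starts))
        dg <- unlist(starts, use.names = FALSE) - qpos
      } else { qpos <- integer(); dg <- integer() }
      idt <- numeric(nrow(grid)); cov <- numeric(nrow(grid))
      for (i in seq_len(nrow(grid))) {
        ws <- grid$start[i]; we <- grid$end[i]
        w <- we - ws
        sel <- findInterval(c(ws, we - k + 1L), qpos)
        if (sel[2L] <= sel[1L]) next
        dsel <- dg[(sel[1L] + 1L):sel[2L]]
        tab <- sort(table(dsel), decreasing = TRUE)
        best_i <- 0; best_c <- 0
        for (d in utils::head(as.integer(names(tab)), 3L)) {
          ## window position j (1..w) maps to ref position ws + j + d
          lo <- max(1L, 1L - ws - d)
          hi <- min(w, ref_len - ws - d)
          if (hi < lo) next
          ov <- hi - lo + 1L
          m <- sum(qchars_all[ws + (lo:hi)] == rchars[ws + (lo:hi) + d])
          ii <- 100 * m / ov; cc <- ov / w
          if (ii * cc > best_i * best_c || best_c == 0) {
            best_i <- ii; best_c <- cc
          }
        }
        idt[i] <- best_i; cov[i] <- best_c
      }
      deleted <- idt < del_identity & cov < del_coverage
      idt[deleted] <- 0
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = grid$start, end = grid$end, taxon = t,
        identity = idt, coverage = cov, deleted = deleted)
    }
  }
  data.table::rbindlist(out)
}

## segment_identity with the reference pre-converted (hot path)
segment_identity <- function(qchars, refdna, rchars, ref_len,
                                    k = 15L, max_diagonals = 3L) {
  w <- length(qchars)
  if (w < k) return(c(0, 0))
  q <- Biostrings::DNAString(chars_seq(qchars))
  kmers <- Biostrings::DNAStringSet(q, start = seq_len(w - k + 1L), width = k)
  hits <- Biostrings::matchPDict(Biostrings::PDict(kmers), refdna)
  starts <- Biostrings::startIndex(hits)
  qpos <- rep(seq_len(w - k + 1L), lengths(starts))
  rpos <- unlist(starts, use.names = FALSE)
  if (!length(qpos)) return(c(0, 0))
  dg_tab <- sort(table(rpos - qpos), decreasing = TRUE)
  top <- utils::head(as.integer(names(dg_tab)), max_diagonals)
  best_i <- 0; best_c <- 0
  for (dg in top) {
    lo <- max(1L, 1L - dg)
    hi <- min(w, ref_len - dg)
    if (hi < lo) next
    ov <- hi - lo + 1L
    idt <- 100 * sum(qchars[lo:hi] == rchars[(lo:hi) + dg]) / ov
    cov <- ov / w
    if (idt * cov > best_i * best_c || best_c == 0) {
      best_i <- idt; best_c <- cov
    }
  }
  c(best_i, best_c)
}

#' Stage-1 candidate intervals from conspecific window identities
#'
#' Merges runs of overlapping windows whose best conspecific identity falls
#' below `stage1_identity` (95%) into maximal intervals and keeps those
#' spanning at least `stage1_min_len` (1 kb). Interval ends are then
#' trimmed in `step`-bp blocks whose own anchored identity is at or above
#' the threshold, so candidate boundaries track the true divergence
#' changepoint to within one window step.
#'
#' @param hits Window-identity table (conspecific taxa only) from
#'   [window_identity()].
#' @param assembly The query assembly (for boundary trimming).
#' @param library The reference library.
#' @param stage1_identity,stage1_min_len Stage-1 thresholds.
#' @param step Window step (bp).
#' @param k Seed k-mer length.
#' @return data.table: chrom, start, end, length, mean_identity (mean best
#'   conspecific identity over non-deleted windows).
#' @export
scan_candidates <- function(hits, assembly, library,
                            stage1_identity = 95, stage1_min_len = 1000L,
                            step = 500L, k = 15L) {
  h <- data.table::as.data.table(hits)
  cons_taxa <- intersect(unique(h$taxon),
                         library$taxa$taxon[library$taxa$tag == "conspecific"])
  h <- h[taxon %in% cons_taxa]
  if (nrow(h) == 0L) stop("no conspecific windows in hits")
  best <- h[, .(identity = max(identity), deleted = all(deleted)),
            by = .(chrom, start, end)]
  data.table::setorder(best, chrom, start)
  out <- list()
  for (ch in unique(best$chrom)) {
    b <- best[chrom == ch]
    low <- b$identity < stage1_identity
    r <- rle(low)
    iend <- cumsum(r$lengths); istart <- iend - r$lengths + 1L
    for (kk in seq_along(r$values)) {
      if (!r$values[kk]) next
      s <- b$start[istart[kk]]; e <- max(b$end[istart[kk]:iend[kk]])
      ## trim boundary blocks that match the conspecific references
      tr <- trim_boundaries(ch, s, e, assembly, library, cons_taxa,
                            stage1_identity, step, k)
      s <- tr[1L]; e <- tr[2L]
      if (e - s < stage1_min_len) next
      rows <- istart[kk]:iend[kk]
      idt <- b$identity[rows][!b$deleted[rows]]
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = s, end = e, length = e - s,
        mean_identity = if (length(idt)) mean(idt) else 0)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), length = integer(),
                                  mean_identity = numeric()))
  data.table::rbindlist(out)
}

## shrink [s, e) by `step`-bp blocks at either end while a block's best
## conspecific identity is at or above the stage-1 threshold
trim_boundaries <- function(ch, s, e, assembly, library, cons_taxa,
                            threshold, step, k) {
  qchars_all <- seq_chars(assembly[[ch]])
  refs <- lapply(cons_taxa, function(t) {
    seqs <- library$seqs[[t]][[ch]]
    list(dna = Biostrings::DNAString(seqs), chars = seq_chars(seqs),
         len = nchar(seqs))
  })
  block_id <- function(bs, be) {
    qc <- qchars_all[(bs + 1L):be]
    max(vapply(refs, function(r)
      segment_identity(qc, r$dna, r$chars, r$len, k)[1L], numeric(1)))
  }
  while (e - s >= 2L * step &&
         block_id(s, s + step) >= threshold) s <- s + step
  while (e - s >= 2L * step &&
         block_id(e - step, e) >= threshold) e <- e - step
  c(s, e)
}

#' Stage-2 fragment refinement across isolates
#'
#' Applies the raised thresholds (mean conspecific identity < 93%, length
#' >= 1.5 kb), unifies candidates from different isolates whose intervals
#' overlap by at least half of the shorter interval, and removes short
#' fragments (< 2 x `final_min_len`) occurring in a single isolate.
#'
#' @param candidates Named list (isolate id -> candidate table from
#'   [scan_candidates()]).
#' @param final_identity,final_min_len Stage-2 thresholds.
#' @param drop_single_isolate_short Drop short single-carrier fragments.
#' @return data.table: fragment, chrom, start, end, length, mean_identity,
#'   carriers (comma-separated), n_carriers.
#' @export
refine_fragments <- function(candidates, final_identity = 93,
                             final_min_len = 1500L,
                             drop_single_isolate_short = TRUE) {
  rows <- list()
  for (iso in names(candidates)) {
    cd <- data.table::as.data.table(candidates[[iso]])
    if (nrow(cd) == 0L) next
    cd <- cd[length >= final_min_len & mean_identity < final_identity]
    if (nrow(cd)) rows[[iso]] <- cbind(cd, carrier = iso)
  }
  empty <- data.table::data.table(
    fragment = character(), chrom = character(), start = integer(),
    end = integer(), length = integer(), mean_identity = numeric(),
    carriers = character(), n_carriers = integer())
  if (!length(rows)) return(empty)
  all <- data.table::rbindlist(rows)
  data.table::setorder(all, chrom, start)
  ## single-linkage clustering of intervals overlapping >= 50% of the
  ## shorter interval
  all[, cluster := 0L]
  ncl <- 0L
  for (i in seq_len(nrow(all))) {
    assigned <- 0L
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (all$chrom[j] != all$chrom[i]) next
      ov <- min(all$end[i], all$end[j]) - max(all$start[i], all$start[j])
      if (ov >= 0.5 * min(all$length[i], all$length[j])) {
        assigned <- all$cluster[j]; break
      }
    }
    if (assigned == 0L) { ncl <- ncl + 1L; assigned <- ncl }
    data.table::set(all, i, "cluster", assigned)
  }
  frags <- all[, .(
    chrom = chrom[1L], start = min(start), end = max(end),
    mean_identity = mean(mean_identity),
    carriers = paste(sort(unique(carrier)), collapse = ","),
    n_carriers = length(unique(carrier))), by = cluster]
  frags[, length := end - start]
  if (drop_single_isolate_short)
    frags <- frags[!(n_carriers == 1L & length < 2L * final_min_len)]
  if (nrow(frags) == 0L) return(empty)
  data.table::setorder(frags, chrom, start)
  frags[, fragment := sprintf("frag%03d", .I)]
  frags[, cluster := NULL]
  data.table::setcolorder(frags, c("fragment", "chrom", "start", "end",
                                   "length", "mean_identity", "carriers",
                                   "n_carriers"))
  frags[]
}

#' Donor assignment and classification of alien fragments
#'
#' For each fragment, the mean non-deleted window identity against every
#' non-conspecific taxon of the library is computed on a carrier's
#' assembly. The donor is the taxon with the highest mean identity of at
#' least `min_identity` (65%); the fragment is classed `HGT` when the donor
#' is outside the genus, `introgression` when congeneric, and `unknown`
#' when no taxon reaches the floor.
#'
#' @param fragments Fragment table from [refine_fragments()].
#' @param assemblies Named list of assemblies (isolate -> genome).
#' @param library The reference library.
#' @param min_identity Donor identity floor (%).
#' @param window,step,k Scan parameters.
#' @return `fragments` with added columns donor, donor_identity, class.
#' @export
assign_donor <- function(fragments, assemblies, library, min_identity = 65,
                         window = 1000L, step = 500L, k = 15L) {
  fr <- data.table::as.data.table(fragments)
  donors <- library$taxa[library$taxa$tag != "conspecific", ]
  fr[, `:=`(donor = NA_character_, donor_identity = NA_real_,
            class = "unknown")]
  for (i in seq_len(nrow(fr))) {
    carrier <- strsplit(fr$carriers[i], ",", fixed = TRUE)[[1]][1L]
    asm <- assemblies[[carrier]]
    seg <- stats::setNames(
      list(substr(asm[[fr$chrom[i]]], fr$start[i] + 1L, fr$end[i])),
      fr$chrom[i])
    hits <- window_identity(seg, library, taxa = donors$taxon,
                            window = window, step = step, k = k)
    means <- hits[deleted == FALSE,
                  .(identity = mean(identity)), by = taxon]
    means <- means[identity >= min_identity]
    if (nrow(means)) {
      best <- means[which.max(identity)]
      tag <- donors$tag[match(best$taxon, donors$taxon)]
      data.table::set(fr, i, "donor", best$taxon)
      data.table::set(fr, i, "donor_identity", best$identity)
      data.table::set(fr, i, "class",
                      if (tag == "outside_genus") "HGT" else "introgression")
    }
  }
  fr[]
}

#' Full introgression/HGT scan of a cohort
#'
#' Runs the two-stage scan on every assembly: sliding-window conspecific
#' identity, stage-1 candidates (95% / 1 kb), stage-2 refinement across
#' isolates (93% / 1.5 kb, single-carrier short fragments dropped), then
#' donor assignment and classification.
#'
#' @param assemblies Named list of assemblies (isolate -> named character
#'   vector of chromosome sequences).
#' @param library A `reference_library`.
#' @param stage1_identity,stage1_min_len,final_identity,final_min_len
#'   Scan thresholds.
#' @param window,step,k Window parameters.
#' @return List: `fragments` (classified fragment table), `candidates`
#'   (per-isolate stage-1 candidates).
#' @export
scan_cohort <- function(assemblies, library,
                        stage1_identity = 95, stage1_min_len = 1000L,
                        final_identity = 93, final_min_len = 1500L,
                        window = 1000L, step = 500L, k = 15L) {
  cons <- library$taxa$taxon[library$taxa$tag == "conspecific"]
  candidates <- lapply(assemblies, function(asm) {
    hits <- window_identity(asm, library, taxa = cons,
                            window = window, step = step, k = k)
    scan_candidates(hits, asm, library, stage1_identity, stage1_min_len,
                    step = step, k = k)
  })
  frags <- refine_fragments(candidates, final_identity, final_min_len)
  if (nrow(frags))
    frags <- assign_donor(frags, assemblies, library,
                          window = window, step = step, k = k)
  list(fragments = frags, candidates = candidates)
}
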