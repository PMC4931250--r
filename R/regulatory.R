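#' The 11-state chromatin vocabulary
#'
#' Default state labels for segmentations consumed by this package,
#' following common joint chromatin-state models learned at 200-bp
#' resolution from histone-mark ChIP-seq.
#'
#' @export
chromatin_states <- function() {
  c("Active_TSS", "Weak_TSS", "Flanking_TSS",
    "Strong_transcription", "Weak_transcription",
    "Genic_enhancer", "Active_enhancer_1", "Active_enhancer_2",
    "Weak_enhancer", "Repressed_polycomb", "Quiescent_low")
}

#' Default enhancer state labels
#' @export
enhancer_states <- function() {
  c("Genic_enhancer", "Active_enhancer_1", "Active_enhancer_2", "Weak_enhancer")
}

#' Active (enhancer or promoter) state labels
#' @export
active_states <- function() {
  c("Active_TSS", "Weak_TSS", "Flanking_TSS", enhancer_states())
}

# Convert a BED-convention (0-based half-open) segmentation data.frame to
# GRanges (1-based closed).
seg_to_granges <- function(seg) {
  GenomicRanges::GRanges(seg$chrom,
                         IRanges::IRanges(seg$start + 1L, seg$end),
                         state = seg$state)
}

granges_to_bed <- function(gr, name = NULL) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             state = name %||% gr$state,
             stringsAsFactors = FALSE)
}

#' Merge contiguous enhancer-state bins into maximal runs
#'
#' Intervals whose state belongs to `labels` are merged when adjacent or
#' overlapping; any non-enhancer state breaks a run. Input is BED
#' convention (0-based half-open).
#'
#' @param segmentation data.frame: chrom, start, end, state.
#' @param labels enhancer state labels (default [enhancer_states()]).
#' @return data.frame of maximal runs: chrom, start, end, length.
#' @export
merge_enhancer_runs <- function(segmentation, labels = enhancer_states()) {
  unknown <- setdiff(unique(segmentation$state), chromatin_states())
  check_that(length(unknown) == 0,
             "unknown state label(s) %s; vocabulary: %s",
             paste(unknown, collapse = ", "),
             paste(chromatin_states(), collapse = ", "))
  sub <- segmentation[segmentation$state %in% labels, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer()))
  }
  gr <- GenomicRanges::reduce(seg_to_granges(sub))  # merges abutting runs
  out <- granges_to_bed(gr, name = NA)[, c("chrom", "start", "end")]
  out$length <- out$end - out$start
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify enhancer runs as stretch / typical / intermediate
#'
#' Stretch enhancers are long (>= `stretch_min_bp`, default 3 kb) runs of
#' enhancer chromatin; typical enhancers are runs at or below
#' `typical_max_bp` (default 800 bp, around the median enhancer size);
#' lengths in between are labelled intermediate. Both boundaries are
#' inclusive. Alternatively `stretch_quantile` calls the longest fraction
#' of runs stretch (robustness mode).
#'
#' @param runs data.frame from [merge_enhancer_runs()].
#' @param stretch_min_bp stretch threshold (bp).
#' @param typical_max_bp typical threshold (bp).
#' @param stretch_quantile optional fraction in (0,1); when set, the
#'   longest `stretch_quantile` fraction of runs is called stretch.
#' @return runs with a `class` column.
#' @export
classify_enhancers <- function(runs, stretch_min_bp = 3000,
                               typical_max_bp = 800,
                               stretch_quantile = NULL) {
  len <- runs$end - runs$start
  if (!is.null(stretch_quantile)) {
    cut <- quantile(len, 1 - stretch_quantile, names = FALSE)
    cls <- ifelse(len >= cut, "stretch",
                  ifelse(len <= typical_max_bp, "typical", "intermediate"))
  } else {
    cls <- ifelse(len >= stretch_min_bp, "stretch",
                  ifelse(len <= typical_max_bp, "typical", "intermediate"))
  }
  out <- runs
  out$length <- len
  out$class <- cls
  out
}

#' Flag tissue-specific enhancer intervals
#'
#' An interval is tissue-specific when, in EVERY other tissue provided,
#' the fraction of its bases overlapping active chromatin (enhancer or
#' promoter states) is at most `max_shared_fraction`.
#'
#' @param enhancers classified runs (chrom, start, end, ...).
#' @param other_segmentations list of segmentation data.frames.
#' @param max_shared_fraction sharing threshold (default 0.1).
#' @param labels active-state labels checked in other tissues.
#' @return enhancers with a logical `tissue_specific` column.
#' @export
tissue_specific_filter <- function(enhancers, other_segmentations,
                                   max_shared_fraction = 0.1,
                                   labels = active_states()) {
  check_that(length(other_segmentations) >= 1,
             "need at least one other tissue")
  gr <- GenomicRanges::GRanges(enhancers$chrom,
                               IRanges::IRanges(enhancers$start + 1L,
                                                enhancers$end))
  specific <- rep(TRUE, nrow(enhancers))
  for (seg in other_segmentations) {
    act <- seg[seg$state %in% labels, , drop = FALSE]
    if (nrow(act) == 0) next
    agr <- GenomicRanges::reduce(seg_to_granges(act))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, agr))
    shared <- numeric(nrow(enhancers))
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(agr)[S4Vectors::subjectHits(ov)]))
      shared_dt <- data.table::data.table(i = S4Vectors::queryHits(ov), w = w)
      agg <- shared_dt[, list(w = sum(w)), by = "i"]
      shared[agg$i] <- agg$w
    }
    frac <- shared / IRanges::width(gr)
    specific <- specific & (frac <= max_shared_fraction)
  }
  out <- enhancers
  out$tissue_specific <- specific
  out
}

#' Count LD neighbours of each variant
#'
#' Number of other variants within +/- `window_bp` whose dosage r2 with
#' the focal variant is at least `r2`. Self is excluded.
#'
#' @param G sample x variant dosage matrix.
#' @param variants data.frame: variant_id, chrom, pos (columns of G).
#' @param r2 threshold (default 0.8).
#' @param window_bp window half-width (default 1e6).
#' @return named integer vector of neighbour counts.
#' @export
ld_neighbour_count <- function(G, variants, r2 = 0.8, window_bp = 1e6) {
  counts <- setNames(integer(nrow(variants)), variants$variant_id)
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    gmat <- G[, v$variant_id, drop = FALSE]
    sds <- apply(gmat, 2, sd)
    ok <- sds > 0
    m <- nrow(v)
    rr2 <- matrix(0, m, m)
    if (any(ok)) rr2[ok, ok] <- suppressWarnings(cor(gmat[, ok, drop = FALSE]))^2
    within <- abs(outer(v$pos, v$pos, `-`)) <= window_bp
    hit <- rr2 >= r2 & within
    diag(hit) <- FALSE
    counts[v$variant_id] <- rowSums(hit, na.rm = TRUE)
  }
  counts
}

#' Distance from each variant to its nearest TSS
#'
#' Used to annotate the SNP universe for matched-null sampling.
#'
#' @param variants data.frame: chrom, pos.
#' @param genes data.frame: chrom, tss.
#' @return numeric vector of distances (1e9 for chromosomes without genes).
#' @export
nearest_tss_distance <- function(variants, genes) {
  out <- rep(1e9, nrow(variants))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    tss <- sort(genes$tss[genes$chrom == ch])
    if (!length(tss)) next
    pos <- variants$pos[vi]
    k <- findInterval(pos, tss)
    lo <- ifelse(k >= 1, abs(pos - tss[pmax(k, 1)]), Inf)
    hi <- ifelse(k < length(tss), abs(tss[pmin(k + 1, length(tss))] - pos), Inf)
    out[vi] <- pmin(lo, hi)
  }
  out
}

# Bin assignments used for matched-null sampling.
matching_bins <- function(ann, maf_bin = 0.02, tss_bin = 0.5,
                          ld_breaks = c(0, 1, 5, 20, 100, Inf)) {
  maf_b <- floor(ann$maf / maf_bin)
  tss_b <- floor(log10(ann$tss_dist + 1) / tss_bin)
  ld_b <- findInterval(ann$ld_count, ld_breaks)
  paste(maf_b, tss_b, ld_b, sep = "|")
}

#' Matched-null enrichment of SNPs in interval features
#'
#' Compares the number of test SNPs overlapping `features` with the
#' overlap counts of `n_null_sets` random SNP sets drawn from `universe`,
#' where each null SNP is matched to its test SNP on minor allele
#' frequency, distance to the nearest TSS, and LD-neighbour count (binned;
#' bins configurable). Null sets are drawn without replacement within a
#' set. fold = observed / mean(null); empirical p = (1 + #\{null >=
#' observed\}) / (n_null_sets + 1).
#'
#' When a SNP's matched pool is smaller than `min_pool` the bins are
#' widened stepwise (doubled widths, then the LD bin dropped, then
#' MAF/TSS bins dropped); if the pool is still too small the function
#' errors, naming the SNP.
#'
#' @param test_snps character vector of variant ids (subset of universe).
#' @param features data.frame chrom, start, end (BED convention).
#' @param universe data.frame: variant_id, chrom, pos, maf, tss_dist,
#'   ld_count.
#' @param n_null_sets number of null sets (default 1000).
#' @param min_pool minimum matched-pool size (default 500; lower it for
#'   small universes).
#' @param seed RNG seed.
#' @param maf_bin,tss_bin MAF / log10-TSS-distance bin widths.
#' @return list of class `enrichment_result`: n_observed, null_mean, fold,
#'   empirical_p, n_null_sets, n_test, pool_sizes.
#' @export
matched_null_enrichment <- function(test_snps, features, universe,
                                    n_null_sets = 1000L, min_pool = 500L,
                                    seed = 1L, maf_bin = 0.02, tss_bin = 0.5) {
  check_that(all(test_snps %in% universe$variant_id),
             "all test SNPs must be in the universe")
  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start + 1L,
                                                features$end))
  ug <- GenomicRanges::GRanges(universe$chrom,
                               IRanges::IRanges(universe$pos, universe$pos))
  in_feat <- suppressWarnings(GenomicRanges::countOverlaps(ug, fg)) > 0
  names(in_feat) <- universe$variant_id
  n_obs <- sum(in_feat[test_snps])

  # matched candidate pools, with stepwise bin widening: exact bins, then
  # doubled widths, then the LD bin dropped with 4x widths, then no bins
  bin_levels <- list(
    matching_bins(universe, maf_bin, tss_bin),
    matching_bins(universe, 2 * maf_bin, 2 * tss_bin),
    matching_bins(universe, 4 * maf_bin, 4 * tss_bin, ld_breaks = c(0, Inf)),
    rep("all", nrow(universe)))
  pools <- vector("list", length(test_snps))
  ti <- match(test_snps, universe$variant_id)
  for (k in seq_along(test_snps)) {
    pool <- integer(0)
    for (bins in bin_levels) {
      pool <- setdiff(which(bins == bins[ti[k]]), ti[k])
      if (length(pool) >= min_pool) break
    }
    check_that(length(pool) >= min_pool,
               "matched pool for SNP %s has %d candidates (< min_pool %d)",
               test_snps[k], length(pool), min_pool)
    pools[[k]] <- pool
  }

  null_counts <- with_seed(seed, {
    vapply(seq_len(n_null_sets), function(b) {
      used <- integer(0)
      cnt <- 0L
      for (k in sample(seq_along(pools))) {   # random SNP order per set
        avail <- setdiff(pools[[k]], used)
        pick <- if (length(avail)) avail[sample.int(length(avail), 1)] else
          pools[[k]][sample.int(length(pools[[k]]), 1)]
        used <- c(used, pick)
        cnt <- cnt + as.integer(in_feat[pick])
      }
      cnt
    }, integer(1))
  })
  null_mean <- mean(null_counts)
  structure(list(
    n_observed = n_obs,
    null_mean = null_mean,
    fold = if (null_mean > 0) n_obs / null_mean else
      if (n_obs == 0) 0 else Inf,
    empirical_p = (1 + sum(null_counts >= n_obs)) / (n_null_sets + 1),
    n_null_sets = n_null_sets,
    n_test = length(test_snps),
    pool_sizes = lengths(pools)
  ), class = "enrichment_result")
}

#' Enrichment stratified by specificity decile and enhancer class
#'
#' Runs [matched_null_enrichment()] separately for each specificity decile
#' of the best-per-gene eQTL SNPs, against stretch and typical enhancer
#' features. Deciles with fewer than 10 SNPs are reported with a
#' low-power flag.
#'
#' @param best_eqtls data.frame: gene_id, variant_id (one SNP per gene).
#' @param deciles named integer vector: decile per gene_id.
#' @param enhancers classified enhancer set (needs `class` column).
#' @param universe annotated universe (see [matched_null_enrichment()]).
#' @param classes enhancer classes tested (default stretch and typical).
#' @param ... passed to [matched_null_enrichment()].
#' @return data.frame: decile, class, n_snps, n_observed, null_mean, fold,
#'   empirical_p, low_power.
#' @export
stratified_enrichment <- function(best_eqtls, deciles, enhancers, universe,
                                  classes = c("stretch", "typical"), ...) {
  dec <- deciles[best_eqtls$gene_id]
  rows <- list()
  for (d in sort(unique(dec[!is.na(dec)]))) {
    snps <- best_eqtls$variant_id[!is.na(dec) & dec == d]
    for (cl in classes) {
      feats <- enhancers[enhancers$class == cl, , drop = FALSE]
      r <- matched_null_enrichment(snps, feats, universe, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        decile = d, class = cl, n_snps = length(snps),
        n_observed = r$n_observed, null_mean = r$null_mean, fold = r$fold,
        empirical_p = r$empirical_p, low_power = length(snps) < 10,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
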