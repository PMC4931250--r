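#' Filter allelic count rows for mapping bias and degenerate fractions
#'
#' Removes sample x SNP rows whose variant fails the mappability mask
#' (simulated read coverage outside the acceptance band, ENCODE-style
#' blacklist, proximity to an indel) or whose reference-allele fraction
#' falls outside the open interval (`fracref_bounds`). Every variant in
#' `counts` must be present in `mask`; silent pass-through of unmasked
#' variants is forbidden.
#'
#' @param counts data.frame: sample_id, variant_id, ref, alt, ref_count,
#'   alt_count, allele_pair (and optionally strand).
#' @param mask data.frame: variant_id, simulated_coverage, blacklisted,
#'   near_indel.
#' @param coverage_band inclusive acceptance band for simulated coverage
#'   (default c(193, 202), matching a 101-bp paired-end read design).
#' @param fracref_bounds open bounds on fracRef (default c(0.01, 0.99)).
#' @return filtered counts; attribute `removed` holds the dropped rows
#'   with a `reason` column.
#' @export
apply_ase_filters <- function(counts, mask,
                              coverage_band = c(193, 202),
                              fracref_bounds = c(0.01, 0.99)) {
  missing <- setdiff(unique(counts$variant_id), mask$variant_id)
  check_that(length(missing) == 0,
             "variants missing from mask: %s%s",
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ..." else "")
  m <- mask[match(counts$variant_id, mask$variant_id), ]
  total <- counts$ref_count + counts$alt_count
  fracref <- counts$ref_count / total
  reason <- rep(NA_character_, nrow(counts))
  reason[total <= 0] <- "zero_coverage"
  bad_cov <- m$simulated_coverage < coverage_band[1] |
    m$simulated_coverage > coverage_band[2]
  reason[is.na(reason) & bad_cov] <- "simulated_coverage"
  reason[is.na(reason) & m$blacklisted] <- "blacklisted"
  reason[is.na(reason) & m$near_indel] <- "near_indel"
  out_of_bounds <- fracref <= fracref_bounds[1] | fracref >= fracref_bounds[2]
  reason[is.na(reason) & out_of_bounds] <- "fracref_bounds"
  keep <- is.na(reason)
  removed <- counts[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!keep]
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Merge forward/reverse strand quantifications
#'
#' Sums reference and alternate counts over strands within each
#' (sample, variant) before any statistics are computed.
#'
#' @param counts data.frame possibly holding a `strand` column.
#' @return counts aggregated to one row per sample x variant.
#' @export
merge_strands <- function(counts) {
  if (!"strand" %in% names(counts)) return(counts)
  dt <- data.table::as.data.table(counts)
  out <- dt[, list(ref_count = sum(ref_count), alt_count = sum(alt_count)),
            by = c(setdiff(names(counts), c("strand", "ref_count", "alt_count")))]
  as.data.frame(out)
}

#' Expected reference-allele fraction per sample and allele pair
#'
#' Reference-allele mapping bias depends on the ordered ref/alt pair
#' (A->G and G->A differ), so the null fracRef is estimated per sample
#' and per ordered allele pair as sum(ref) / sum(total) over the group's
#' SNPs. To stop high-coverage SNPs dominating the estimate, SNPs whose
#' total coverage lies strictly above the sample's `pct`-th coverage
#' percentile are first down-sampled to `downsample_cov` total reads by
#' a seeded hypergeometric draw (sampling reads without replacement, so
#' the expectation of fracRef is preserved). The thinned counts are used
#' only for this expectation, never for the per-SNP test.
#'
#' @param counts filtered, strand-merged count rows.
#' @param downsample_cov target coverage after thinning (default 30).
#' @param pct coverage percentile above which rows are thinned (default 75).
#' @param seed RNG seed for the hypergeometric draws.
#' @return data.frame: sample_id, allele_pair, expected_fracref, n_snps.
#' @export
expected_fracref <- function(counts, downsample_cov = 30, pct = 75, seed = 1L) {
  total <- counts$ref_count + counts$alt_count
  ref_ds <- counts$ref_count
  tot_ds <- total
  with_seed(seed, {
    for (s in unique(counts$sample_id)) {
      idx <- which(counts$sample_id == s)
      cutoff <- quantile(total[idx], pct / 100, type = 7, names = FALSE)
      thin <- idx[total[idx] > cutoff & total[idx] > downsample_cov]
      for (i in thin) {
        ref_ds[i] <- rhyper(1, counts$ref_count[i], counts$alt_count[i],
                            downsample_cov)
        tot_ds[i] <- downsample_cov
      }
    }
  })
  dt <- data.table::data.table(sample_id = counts$sample_id,
                               allele_pair = counts$allele_pair,
                               ref = ref_ds, tot = tot_ds)
  agg <- dt[, list(expected_fracref = sum(ref) / sum(tot), n_snps = .N),
            by = c("sample_id", "allele_pair")]
  as.data.frame(agg)
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' p = sum of P(X = k) over all k whose point probability does not exceed
#' that of the observed count (within a small relative tolerance for
#' floating-point safety), X ~ Binomial(total, p0). This matches the
#' classical definition of the two-sided exact test; a central alternative
#' (2 x min tail, capped at 1) is available via `method`.
#'
#' @param ref_count observed reference reads.
#' @param total total reads (>= 1).
#' @param p0 null fracRef in (0, 1).
#' @param method "minlik" (default) or "central".
#' @return two-sided p-value in (0, 1\].
#' @export
binomial_ase_test <- function(ref_count, total, p0, method = c("minlik", "central")) {
  method <- match.arg(method)
  check_that(total >= 1, "total must be >= 1")
  check_that(p0 > 0 && p0 < 1, "null fracRef must be inside (0,1)")
  check_that(ref_count >= 0 && ref_count <= total, "ref_count out of range")
  if (method == "central") {
    lo <- pbinom(ref_count, total, p0)
    hi <- pbinom(ref_count - 1, total, p0, lower.tail = FALSE)
    return(min(1, 2 * min(lo, hi)))
  }
  d <- dbinom(0:total, total, p0)
  obs <- d[ref_count + 1]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Fisher's combined probability test
#'
#' X = -2 * sum(log p) is chi-squared with 2k degrees of freedom under
#' the global null; k = 1 returns the input p unchanged.
#'
#' @param p_values p-values in (0, 1\].
#' @return combined p-value.
#' @export
fisher_combine <- function(p_values) {
  k <- length(p_values)
  check_that(k >= 1, "need at least one p-value")
  check_that(all(p_values > 0 & p_values <= 1),
             "p-values must lie in (0,1]; replace zeros upstream")
  if (k == 1) return(p_values)
  pchisq(-2 * sum(log(p_values)), df = 2 * k, lower.tail = FALSE)
}

#' Per-sample ASE tests and cross-sample combination
#'
#' Full ASE statistical stage: merge strands, estimate the expected
#' fracRef per (sample, allele pair) with down-sampling, run the exact
#' two-sided binomial test for every sample x SNP against its group
#' expectation (on the ORIGINAL, unthinned counts), then Fisher-combine
#' p-values per variant across samples when the variant was tested in at
#' least `min_samples` samples. Storey q-values are computed for the
#' per-sample tests (per sample) and for the combined tests.
#'
#' @param counts filtered AlleleCountTable rows.
#' @param min_samples minimum samples for combination (default 10).
#' @param downsample_cov,pct,seed passed to [expected_fracref()].
#' @param method two-sided method for the binomial test.
#' @return list with `per_sample` (sample_id, variant_id, expected_fracref,
#'   fracref, binomial_p, q) and `per_variant` (variant_id,
#'   n_samples_tested, combined_p, q).
#' @export
combine_across_samples <- function(counts, min_samples = 10L,
                                   downsample_cov = 30, pct = 75, seed = 1L,
                                   method = "minlik") {
  counts <- merge_strands(counts)
  exp_fr <- expected_fracref(counts, downsample_cov, pct, seed)
  key <- paste(counts$sample_id, counts$allele_pair, sep = "\r")
  ekey <- paste(exp_fr$sample_id, exp_fr$allele_pair, sep = "\r")
  e <- exp_fr$expected_fracref[match(key, ekey)]
  total <- counts$ref_count + counts$alt_count
  usable <- !is.na(e) & e > 0 & e < 1 & total >= 1
  per_sample <- data.frame(
    sample_id = counts$sample_id[usable],
    variant_id = counts$variant_id[usable],
    expected_fracref = e[usable],
    fracref = counts$ref_count[usable] / total[usable],
    binomial_p = vapply(which(usable), function(i) {
      binomial_ase_test(counts$ref_count[i], total[i], e[i], method)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  per_sample$q <- NA_real_
  for (s in unique(per_sample$sample_id)) {
    i <- per_sample$sample_id == s
    per_sample$q[i] <- storey_qvalue(per_sample$binomial_p[i])
  }
  dt <- data.table::as.data.table(per_sample)
  comb <- dt[, list(n_samples_tested = .N,
                    combined_p = if (.N >= min_samples)
                      fisher_combine(pmax(binomial_p, 1e-300)) else NA_real_),
             by = "variant_id"]
  comb <- as.data.frame(comb)
  tested <- !is.na(comb$combined_p)
  comb$q <- NA_real_
  if (any(tested)) comb$q[tested] <- storey_qvalue(comb$combined_p[tested])
  list(per_sample = per_sample, per_variant = comb)
}
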