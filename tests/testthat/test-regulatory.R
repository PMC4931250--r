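test_that("enhancer runs merge contiguous bins and break at other states", {
  seg <- data.frame(
    chrom = "chr1",
    start = seq(0, 200 * 17, by = 200)[1:18],
    end = seq(200, 200 * 18, by = 200)[1:18],
    state = c(rep("Active_enhancer_1", 16), "Strong_transcription",
              "Weak_enhancer"),
    stringsAsFactors = FALSE)
  runs <- merge_enhancer_runs(seg)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$length[1], 3200L)   # 16 contiguous 200-bp bins
  expect_equal(runs$length[2], 200L)
  expect_equal(nrow(merge_enhancer_runs(seg, labels = character(0))), 0L)
  seg$state[1] <- "NotAState"
  expect_error(merge_enhancer_runs(seg), "vocabulary")
})

test_that("enhancer classification thresholds are inclusive", {
  runs <- data.frame(chrom = "chr1",
                     start = c(0, 5000, 10000, 20000),
                     end = c(3000, 5800, 11500, 20200))
  cls <- classify_enhancers(runs)
  expect_equal(cls$class, c("stretch", "typical", "intermediate", "typical"))
  # quantile mode calls the longest fraction stretch
  clq <- classify_enhancers(runs, stretch_quantile = 0.25)
  expect_equal(sum(clq$class == "stretch"), 1L)
  expect_equal(clq$class[which.max(clq$length)], "stretch")
})

test_that("tissue-specificity compares base overlap with active states elsewhere", {
  enh <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                    end = c(500, 1500, 3000))
  other <- data.frame(chrom = "chr1",
                      start = c(1000, 2000),
                      end = c(1500, 2050),
                      state = c("Active_enhancer_1", "Weak_TSS"),
                      stringsAsFactors = FALSE)
  out <- tissue_specific_filter(enh, list(other), max_shared_fraction = 0.1)
  expect_equal(out$tissue_specific, c(TRUE, FALSE, TRUE))
  # 2000-3000 shares 50/1000 = 5% <= 10% -> still specific
  out2 <- tissue_specific_filter(enh, list(other), max_shared_fraction = 0.01)
  expect_equal(out2$tissue_specific, c(TRUE, FALSE, FALSE))
})

test_that("interval overlap logic agrees with a per-base oracle on random genomes", {
  set.seed(30)
  for (rep in 1:10) {
    L <- 10000
    n_iv <- 12
    starts <- sort(sample(0:(L - 400), n_iv))
    ends <- pmin(starts + sample(100:400, n_iv, replace = TRUE), L)
    states <- sample(chromatin_states(), n_iv, replace = TRUE)
    # drop overlaps to keep the segmentation valid
    keep <- rep(TRUE, n_iv)
    last_end <- -1
    for (i in seq_len(n_iv)) {
      if (starts[i] < last_end) keep[i] <- FALSE else last_end <- ends[i]
    }
    seg <- data.frame(chrom = "chrZ", start = starts[keep], end = ends[keep],
                      state = states[keep], stringsAsFactors = FALSE)
    runs <- merge_enhancer_runs(seg)
    # per-base oracle
    base <- rep(FALSE, L)
    for (i in seq_len(nrow(seg))) {
      if (seg$state[i] %in% enhancer_states()) {
        base[(seg$start[i] + 1):seg$end[i]] <- TRUE
      }
    }
    cover <- sum(base)
    expect_equal(sum(runs$length), cover)
    r <- rle(base)
    expect_equal(nrow(runs), sum(r$values))
  }
})

test_that("LD neighbour counts match construction", {
  set.seed(31)
  n <- 500
  # block of 20 near-perfect proxies + isolated variant
  g0 <- rbinom(n, 2, 0.4)
  block <- vapply(1:20, function(i) {
    flip <- runif(n) < 0.01
    ifelse(flip, rbinom(n, 2, 0.4), g0)
  }, numeric(n))
  lone <- rbinom(n, 2, 0.4)
  G <- cbind(block, lone)
  colnames(G) <- c(paste0("b", 1:20), "lone")
  variants <- data.frame(variant_id = colnames(G), chrom = "chr1",
                         pos = c(seq(1000, by = 1000, length.out = 20), 500000),
                         stringsAsFactors = FALSE)
  cnt <- ld_neighbour_count(G, variants, r2 = 0.8, window_bp = 1e6)
  expect_true(all(cnt[paste0("b", 1:20)] == 19))
  expect_equal(unname(cnt["lone"]), 0L)
  # a perfect duplicate is always found
  G2 <- cbind(a = g0, b = g0)
  v2 <- data.frame(variant_id = c("a", "b"), chrom = "chr1", pos = c(1, 2))
  expect_equal(unname(ld_neighbour_count(G2, v2)["a"]), 1L)
})

test_that("matched-null enrichment saturates, zeroes and matches bins", {
  set.seed(32)
  m <- 800
  uni <- data.frame(variant_id = paste0("v", 1:m), chrom = "chr1",
                    pos = sort(sample(1:1e6, m)),
                    maf = runif(m, 0.05, 0.5),
                    tss_dist = sample(1:1e5, m),
                    ld_count = sample(0:30, m, replace = TRUE),
                    stringsAsFactors = FALSE)
  test_snps <- sample(uni$variant_id, 40)
  whole <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  r_sat <- matched_null_enrichment(test_snps, whole, uni, n_null_sets = 50,
                                   min_pool = 5, seed = 1)
  expect_equal(r_sat$fold, 1)
  expect_equal(r_sat$empirical_p, 1)
  none <- data.frame(chrom = "chr9", start = 0, end = 100)
  r_none <- matched_null_enrichment(test_snps, none, uni, n_null_sets = 50,
                                    min_pool = 5, seed = 1)
  expect_equal(r_none$n_observed, 0L)
  expect_equal(r_none$fold, 0)
  # impossible pool size -> informative error
  expect_error(matched_null_enrichment(test_snps[1], whole, uni,
                                       n_null_sets = 5, min_pool = 10000),
               "min_pool")
})

test_that("feature randomization gives calibrated folds and super-uniform p", {
  set.seed(33)
  m <- 1200
  uni <- data.frame(variant_id = paste0("v", 1:m), chrom = "chr1",
                    pos = seq(500, by = 800, length.out = m),
                    maf = runif(m, 0.05, 0.5),
                    tss_dist = sample(1:1e5, m, replace = TRUE),
                    ld_count = sample(0:30, m, replace = TRUE),
                    stringsAsFactors = FALSE)
  res <- t(vapply(1:40, function(i) {
    # random features covering ~25% of the universe, independent of tests;
    # 200 test SNPs keep the fold estimate's sampling noise near 12%
    n_f <- 150
    fs <- sort(sample(seq(0, max(uni$pos), by = 400), n_f))
    feats <- data.frame(chrom = "chr1", start = fs, end = fs + 1600)
    test_snps <- sample(uni$variant_id, 200)
    r <- matched_null_enrichment(test_snps, feats, uni, n_null_sets = 60,
                                 min_pool = 10, seed = i)
    c(fold = r$fold, p = r$empirical_p)
  }, numeric(2)))
  expect_gte(mean(res[, "fold"] >= 0.75 & res[, "fold"] <= 1.33), 0.95)
  # super-uniform empirical p under the null
  for (alpha in c(0.1, 0.25, 0.5)) {
    expect_lte(mean(res[, "p"] <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(res)))
  }
})
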