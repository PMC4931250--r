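test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(frac_specific_genes = 1.5), "frac_specific_genes")
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
})

test_that("genotype simulator honours MAF range, LD structure and determinism", {
  cfg <- sim_config(n_samples = 5000L, n_genes = 10L, n_variants = 40L,
                    ld_block_size = 20L, ld_decay = 0, seed = 51L)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  # independence by construction at ld_decay = 0
  expect_lt(ld_r2(g$dosage[, 1], g$dosage[, 2]), 0.01)
  # frequencies near their targets
  expect_true(all(g$variants$maf > 0.02 & g$variants$maf <= 0.52))
  # strong LD at ld_decay = 0.95: adjacent r2 > 0.5
  cfg2 <- sim_config(n_samples = 5000L, n_genes = 10L, n_variants = 10L,
                     ld_block_size = 10L, ld_decay = 0.95, seed = 52L)
  g2 <- simulate_genotypes(cfg2)
  expect_gt(ld_r2(g2$dosage[, 1], g2$dosage[, 2]), 0.5)
  # r2 decays with distance within the block
  r2_near <- ld_r2(g2$dosage[, 1], g2$dosage[, 2])
  r2_far <- ld_r2(g2$dosage[, 1], g2$dosage[, 9])
  expect_gt(r2_near, r2_far)
  # across blocks ~ 0
  cfg3 <- sim_config(n_samples = 5000L, n_genes = 10L, n_variants = 20L,
                     ld_block_size = 10L, ld_decay = 0.95, seed = 53L)
  g3 <- simulate_genotypes(cfg3)
  expect_lt(ld_r2(g3$dosage[, 10], g3$dosage[, 11]), 0.01)
  # determinism
  expect_identical(simulate_genotypes(cfg2)$dosage, g2$dosage)
})

test_that("tissue panel plants specific genes and near-uniform background", {
  cfg <- small_config(seed = 54L, n_genes = 300L)
  p <- simulate_tissue_panel(cfg)
  expect_true(all(p$panel >= 0))
  share <- p$panel[, "muscle"] / rowSums(p$panel)
  planted <- rownames(p$panel) %in% p$specific_gene_truth
  expect_true(all(share[planted] >= 0.9))
  expect_true(all(share[!planted] < 0.9))
  # background entropy near log2(16) = 4 bits: oracle average over the
  # generator's Dirichlet(50) draw is ~3.95
  H_bg <- apply(p$panel[!planted, ] / rowSums(p$panel[!planted, ]), 1,
                entropy_bits)
  expect_gt(mean(H_bg), 3.9)
  expect_lt(mean(H_bg), 4)
  # no specific genes when the fraction is zero
  cfg0 <- small_config(seed = 55L, frac_specific_genes = 0)
  p0 <- simulate_tissue_panel(cfg0)
  share0 <- p0$panel[, "muscle"] / rowSums(p0$panel)
  expect_true(all(share0 < 0.9))
  expect_equal(length(p0$specific_gene_truth), 0L)
})

test_that("expression simulator plants recoverable cis effects", {
  cfg <- small_config(seed = 56L, n_samples = 150L)
  g <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg, g)
  ex <- simulate_expression(g, genes, cfg)
  tr <- ex$eqtl_truth
  expect_true(all(tr$variant_id %in% g$variants$variant_id))
  expect_true(all(tr$gene_id %in% genes$gene_id))
  # noiseless check: beta recovered exactly when regressing the planted
  # component alone
  i <- which(tr$beta == 1)[1]
  y <- ex$expression[, tr$gene_id[i]]
  d <- g$dosage[, tr$variant_id[i]]
  fit <- lm(y ~ d + factor(ex$covariates$batch) + ex$covariates$age +
              ex$covariates$sex)
  expect_lt(abs(coef(fit)[["d"]] - 1), 0.35)
  # sample mismatch is a consistency error
  bad <- sim_config(n_samples = 10L)
  expect_error(simulate_expression(g, genes, bad), "disagree")
})

test_that("latent adjustment removes the planted batch structure", {
  cfg <- small_config(seed = 57L, n_samples = 150L)
  g <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg, g)
  ex <- simulate_expression(g, genes, cfg)
  adj <- latent_factor_adjust(ex$expression, ex$covariates, K = 10, seed = 1)
  r2 <- vapply(seq_len(ncol(adj)), function(j) {
    summary(lm(adj[, j] ~ factor(ex$covariates$batch)))$r.squared
  }, numeric(1))
  expect_lt(mean(r2), 0.01)
})

test_that("allelic counts only cover heterozygotes with NB coverage", {
  cfg <- small_config(seed = 58L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_allele_counts(g, cfg)
  merged <- merge_strands(sim$counts)
  # every counted cell is heterozygous in the genotype matrix
  dos <- g$dosage[cbind(merged$sample_id, merged$variant_id)]
  expect_true(all(dos == 1))
  # mean coverage near coverage_mean
  tot <- merged$ref_count + merged$alt_count
  expect_lt(abs(mean(tot) - cfg$coverage_mean), 3)
  # null variants have mean fracRef ~ 0.5
  nullv <- setdiff(unique(merged$variant_id),
                   c(sim$ase_truth$variant_id, sim$bias_snp_truth))
  fr <- merged$ref_count[merged$variant_id %in% nullv] /
    tot[merged$variant_id %in% nullv]
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 1e-3)
  # planted variants sit near their target fracRef
  pl <- merged[merged$variant_id %in% sim$ase_truth$variant_id, ]
  expect_lt(abs(mean(pl$ref_count / (pl$ref_count + pl$alt_count)) - 0.7), 0.05)
  # mask band: bias SNPs outside [193, 202], others inside
  bias <- sim$mask$variant_id %in% sim$bias_snp_truth
  expect_true(all(sim$mask$simulated_coverage[bias] < 193 |
                    sim$mask$simulated_coverage[bias] > 202))
  expect_true(all(sim$mask$simulated_coverage[!bias] >= 193 &
                    sim$mask$simulated_coverage[!bias] <= 202))
})

test_that("chromatin simulator emits valid, non-overlapping segmentations", {
  cfg <- small_config(seed = 59L, n_genes = 200L, n_variants = 2000L)
  g <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg, g)
  panel <- simulate_tissue_panel(cfg, gene_ids = genes$gene_id)
  sp <- mesi_scores(panel$panel, "muscle")
  genes$decile <- sp$decile[match(genes$gene_id, sp$gene_id)]
  ex <- simulate_expression(g, genes, cfg)
  ch <- simulate_chromatin(genes, g, ex$eqtl_truth, cfg)
  expect_gte(length(ch$segmentations), 3L)   # target + >= 2 others
  for (seg in ch$segmentations) {
    expect_true(all(seg$end > seg$start))
    for (chr in unique(seg$chrom)) {
      s <- seg[seg$chrom == chr, ]
      s <- s[order(s$start), ]
      expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    }
    expect_true(all(seg$state %in% chromatin_states()))
  }
  # planted stretch intervals are >= 3 kb and multiples of 200 bp
  tr <- ch$enhancer_truth
  st <- tr[tr$class == "stretch", ]
  expect_true(all(st$end - st$start >= 3000))
  expect_true(all((st$end - st$start) %% 200 == 0))
})

test_that("phenotype simulator plants detectable trait effects and GO truth", {
  cfg <- small_config(seed = 60L, n_samples = 200L, n_genes = 400L)
  g <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg, g)
  ex <- simulate_expression(g, genes, cfg)
  ph <- simulate_phenotypes(ex$expression, genes, cfg)
  expect_setequal(unique(ph$phenotypes$T2D), c(0, 1))
  expect_true(all(ph$memberships$gene_id %in% genes$gene_id))
  expect_true(all(c("GO_POS", "GO_NEG", "GO_LONG") %in% ph$memberships$term_id))
  # planted T2D genes are enriched for small association p-values
  Y <- transform_quantitative(ph$expression, seed = 1)
  res <- t2d_association(Y, ph$phenotypes$T2D, ex$covariates)
  de <- res$gene_id %in% ph$de_truth$gene_id
  expect_gt(median(-log10(res$p[de])), median(-log10(res$p[!de])))
  expect_gt(mean(res$q[de] <= 0.05), 0.5)
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 61L)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  pa <- simulate_tissue_panel(cfg)
  pb <- simulate_tissue_panel(cfg)
  expect_identical(pa, pb)
  ca <- simulate_allele_counts(a, cfg)
  cb <- simulate_allele_counts(b, cfg)
  expect_identical(ca, cb)
})
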