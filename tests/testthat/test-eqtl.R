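test_that("latent-factor adjustment removes planted structure", {
  set.seed(10)
  n <- 120; G <- 150
  covs <- data.frame(batch = factor(sample(c("b1", "b2", "b3"), n, TRUE)))
  Fm <- matrix(rnorm(n * 3), n, 3)
  lam <- matrix(rnorm(3 * G, 0, 1), 3, G)
  batch_eff <- c(b1 = -1, b2 = 0, b3 = 1)
  Y <- Fm %*% lam + batch_eff[covs$batch] + matrix(rnorm(n * G, sd = 0.7), n, G)
  colnames(Y) <- paste0("g", 1:G)
  adj <- latent_factor_adjust(Y, covs, K = 3, seed = 1)
  # factor correlation largely gone
  r <- abs(cor(Fm, adj))
  expect_lt(mean(r), 0.05)
  # batch no longer predicts residual expression
  r2 <- vapply(1:G, function(j) summary(lm(adj[, j] ~ covs$batch))$r.squared,
               numeric(1))
  expect_lt(mean(r2), 0.01)
  expect_error(latent_factor_adjust(Y, covs, K = n), "smaller")
})

test_that("K=0 reduces the residualization step to covariates only", {
  set.seed(11)
  n <- 50
  covs <- data.frame(age = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  a0 <- latent_factor_adjust(Y, covs, K = 0, seed = 2, final_int = FALSE)
  int1 <- vapply(1:3, function(j) inverse_normal(Y[, j], seed = derive_seed(2, j)),
                 numeric(n))
  expect_equal(unname(a0), unname(residualize(int1, covs)), tolerance = 1e-12)
})

test_that("cis pairing uses a strand-aware anchor with inclusive 1 Mb bounds", {
  genes <- data.frame(
    gene_id = c("gp", "gm", "g2tss"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "-", "+"),
    tss = c("5000000", "5000000", "4000000,4500000"),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = c("at_anchor", "at_edge", "past_edge", "minus_side"),
    chrom = "chr1",
    pos = c(5000000, 6000000, 6000001, 4000000),
    stringsAsFactors = FALSE)
  pr <- cis_pairs(genes, variants)
  gp <- pr$variant_id[pr$gene_id == "gp"]
  expect_true(all(c("at_anchor", "at_edge") %in% gp))
  expect_false("past_edge" %in% gp)
  # multi-TSS + strand: anchor of g2tss is the smallest TSS (4,000,000)
  g2 <- pr$variant_id[pr$gene_id == "g2tss"]
  expect_true("at_anchor" %in% g2)     # 1 Mb from the 4 Mb anchor exactly
  expect_false("at_edge" %in% g2)      # 2 Mb away from the anchor
  # minus-strand gene anchored at the LARGEST tss when multiple exist
  genes_m <- data.frame(gene_id = "gm2", chrom = "chr1", strand = "-",
                        tss = "1000,900000", stringsAsFactors = FALSE)
  prm <- cis_pairs(genes_m, data.frame(variant_id = "v", chrom = "chr1",
                                       pos = 1900000))
  expect_equal(nrow(prm), 1L)   # exactly 1 Mb from the 900,000 anchor
})

test_that("eQTL scan equals the normal-equations oracle and flags low-MAC", {
  set.seed(12)
  n <- 90
  G <- cbind(v1 = rbinom(n, 2, 0.4), v2 = rbinom(n, 2, 0.3),
             v3 = c(rep(0, n - 1), 1))   # MAC 1 -> dropped
  Y <- cbind(g1 = 0.5 * G[, "v1"] + rnorm(n), g2 = rnorm(n))
  pairs <- expand.grid(gene_id = colnames(Y), variant_id = colnames(G),
                       stringsAsFactors = FALSE)
  res <- map_cis_eqtl(Y, G, pairs)
  expect_false("v3" %in% res$variant_id)
  expect_equal(nrow(attr(res, "skipped")), 2L)
  for (i in seq_len(nrow(res))) {
    fit <- summary(lm(Y[, res$gene_id[i]] ~ G[, res$variant_id[i]]))$coefficients
    expect_equal(res$beta[i], fit[2, "Estimate"], tolerance = 1e-10)
    expect_equal(res$p[i], fit[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
  # Y == standardized G -> beta 1 on that scale, p ~ 0
  g <- scale(G[, "v1"])[, 1]
  r1 <- map_cis_eqtl(matrix(g, dimnames = list(NULL, "g")), G[, "v1", drop = FALSE],
                     data.frame(gene_id = "g", variant_id = "v1"))
  expect_equal(r1$beta * sd(G[, "v1"]), 1, tolerance = 1e-10)
  expect_lt(r1$p, 1e-30)
})

test_that("ld_r2 is coding-invariant and near zero for independent variants", {
  set.seed(13)
  g <- rbinom(5000, 2, 0.3)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)
  expect_lt(ld_r2(g, rbinom(5000, 2, 0.3)), 0.01)
  expect_true(is.na(ld_r2(g, rep(1, 5000))))
})

test_that("greedy LD pruning keeps the lowest-p tag of each clump", {
  set.seed(14)
  n <- 400
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.6, a, rbinom(n, 2, 0.4))  # correlated with a
  c_ <- ifelse(runif(n) < 0.6, b, rbinom(n, 2, 0.4)) # correlated with b
  G <- cbind(a = a, b = b, c = c_)
  r_ab <- ld_r2(a, b); r_bc <- ld_r2(b, c_); r_ac <- ld_r2(a, c_)
  # chain construction: both links above the prune threshold, ends below
  expect_true(r_ab >= 0.2 && r_bc >= 0.2 && r_ac < 0.2)
  rec <- data.frame(gene_id = "g", variant_id = c("a", "b", "c"),
                    p = c(0.001, 0.01, 0.05), stringsAsFactors = FALSE)
  pruned <- ld_prune_per_gene(rec, G, threshold = 0.2)
  expect_setequal(pruned$variant_id, c("a", "c"))
  # perfect proxies -> only the lower p kept
  G2 <- cbind(x = a, y = a)
  rec2 <- data.frame(gene_id = "g", variant_id = c("x", "y"), p = c(0.02, 0.01))
  expect_equal(ld_prune_per_gene(rec2, G2)$variant_id, "y")
  # mutually independent -> all kept
  G3 <- cbind(u = rbinom(n, 2, 0.3), v = rbinom(n, 2, 0.3), w = rbinom(n, 2, 0.3))
  rec3 <- data.frame(gene_id = "g", variant_id = c("u", "v", "w"),
                     p = c(0.1, 0.2, 0.3))
  expect_equal(nrow(ld_prune_per_gene(rec3, G3)), 3L)
})

test_that("best per gene takes minimum p with positional tie-break", {
  rec <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                    variant_id = c("v1", "v2", "v3", "v4"),
                    p = c(0.01, 0.02, 0.5, 0.5), stringsAsFactors = FALSE)
  pos <- c(v1 = 100, v2 = 200, v3 = 900, v4 = 150)
  b <- best_per_gene(rec, pos)
  expect_equal(b$variant_id[b$gene_id == "g1"], "v1")
  expect_equal(b$variant_id[b$gene_id == "g2"], "v4")   # tie -> lower coordinate
})

test_that("conditional analysis reduces to the marginal model with no selection", {
  set.seed(15)
  n <- 100
  G <- cbind(gwas = rbinom(n, 2, 0.3), o1 = rbinom(n, 2, 0.3))
  y <- 0.5 * G[, "gwas"] + rnorm(n)
  Y <- matrix(y, dimnames = list(NULL, "g"))
  r <- conditional_gwas_eqtl("gwas", "g", Y, G, stop_p = 1e-10)
  expect_equal(length(r$selected_covariate_variants), 0L)
  expect_equal(r$conditional_p, r$marginal_p)
  fit <- summary(lm(y ~ G[, "gwas"]))$coefficients
  expect_equal(r$marginal_p, fit[2, "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("power rises with effect size and MAF over a simulation grid", {
  set.seed(16)
  n <- 200
  power_at <- function(beta, maf) {
    hits <- replicate(60, {
      g <- rbinom(n, 2, maf)
      if (var(g) == 0) return(NA)
      y <- beta * g + rnorm(n)
      res <- map_cis_eqtl(matrix(y, dimnames = list(NULL, "g")),
                          matrix(g, dimnames = list(NULL, "v")),
                          data.frame(gene_id = "g", variant_id = "v"))
      res$p < 1e-4
    })
    mean(hits, na.rm = TRUE)
  }
  p_small <- power_at(0.2, 0.3)
  p_big <- power_at(0.6, 0.3)
  p_rare <- power_at(0.4, 0.05)
  p_common <- power_at(0.4, 0.4)
  expect_gte(p_big, p_small)
  expect_gte(p_common, p_rare)
})
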