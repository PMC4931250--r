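#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the study conditions the pipeline is designed for: 267 genotyped
#' muscle-biopsy samples, a 16-tissue reference expression panel, common
#' variants (MAF 0.05-0.5) in LD blocks, overdispersed allelic read
#' coverage around 50x, and a handful of latent technical factors.
#'
#' @param n_samples samples with genotypes + expression (default 267).
#' @param n_genes genes (default 2000).
#' @param n_variants variants (default 20000).
#' @param n_tissues tissues in the reference panel (default 16).
#' @param maf_range allele-frequency range for simulated variants.
#' @param ld_block_size variants per LD block (default 50).
#' @param ld_decay haplotype-copying probability between adjacent variants
#'   in a block, in \[0,1); adjacent-variant correlation equals this value.
#' @param frac_specific_genes fraction of genes planted target-tissue
#'   specific in the panel (default 0.05, filling decile 10 halfway).
#' @param frac_eqtl_genes fraction of genes assigned a planted cis effect
#'   (default 0.9; cis regulation is near-ubiquitous in well-powered
#'   muscle studies, and a quarter of the planted effects are zero).
#' @param eqtl_effect_sizes standardized planted betas, cycled over eQTL
#'   genes (default c(0, 0.25, 0.5, 1)); effects are per allele copy on a
#'   unit-variance expression scale.
#' @param ase_effect_fracrefs planted reference-allele fractions for ASE
#'   variants (default 0.7).
#' @param n_ase_variants variants with allelic counts (default 400).
#' @param frac_ase_variants fraction of those with planted imbalance.
#' @param frac_bias_variants fraction planted as mapping-bias artifacts.
#' @param coverage_mean mean allelic read depth (default 50).
#' @param coverage_dispersion negative-binomial size parameter (default 5).
#' @param n_latent_factors latent technical factors in expression.
#' @param batch_levels experimental batches (default 3).
#' @param variant_spacing_bp genomic spacing of variants (default 5000).
#' @param blocks_per_chrom LD blocks per artificial chromosome.
#' @param seed master seed; identical seeds give byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 267L, n_genes = 2000L,
                       n_variants = 20000L, n_tissues = 16L,
                       maf_range = c(0.05, 0.5), ld_block_size = 50L,
                       ld_decay = 0.9, frac_specific_genes = 0.05,
                       frac_eqtl_genes = 0.9,
                       eqtl_effect_sizes = c(0, 0.25, 0.5, 1),
                       ase_effect_fracrefs = 0.7,
                       n_ase_variants = 400L, frac_ase_variants = 0.1,
                       frac_bias_variants = 0.05,
                       coverage_mean = 50, coverage_dispersion = 5,
                       n_latent_factors = 3L, batch_levels = 3L,
                       variant_spacing_bp = 5000L, blocks_per_chrom = 10L,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_variants = as.integer(n_variants),
              n_tissues = as.integer(n_tissues), maf_range = maf_range,
              ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
              frac_specific_genes = frac_specific_genes,
              frac_eqtl_genes = frac_eqtl_genes,
              eqtl_effect_sizes = eqtl_effect_sizes,
              ase_effect_fracrefs = ase_effect_fracrefs,
              n_ase_variants = as.integer(n_ase_variants),
              frac_ase_variants = frac_ase_variants,
              frac_bias_variants = frac_bias_variants,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              n_latent_factors = as.integer(n_latent_factors),
              batch_levels = as.integer(batch_levels),
              variant_spacing_bp = as.integer(variant_spacing_bp),
              blocks_per_chrom = as.integer(blocks_per_chrom),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_that(cfg$n_samples >= 2, "n_samples must be >= 2 (got %d)", cfg$n_samples)
  for (f in c("n_genes", "n_variants", "n_tissues", "ld_block_size",
              "batch_levels", "variant_spacing_bp", "blocks_per_chrom"))
    check_that(cfg[[f]] >= 1, "%s must be positive", f)
  check_that(cfg$n_tissues >= 2, "n_tissues must be >= 2")
  check_that(cfg$maf_range[1] > 0 && cfg$maf_range[2] <= 0.5 &&
               cfg$maf_range[1] <= cfg$maf_range[2],
             "maf_range must lie within (0, 0.5]")
  check_that(cfg$ld_decay >= 0 && cfg$ld_decay < 1, "ld_decay must be in [0,1)")
  for (f in c("frac_specific_genes", "frac_eqtl_genes", "frac_ase_variants",
              "frac_bias_variants"))
    check_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, "%s must be in [0,1]", f)
  check_that(cfg$coverage_mean > 0, "coverage_mean must be positive")
  check_that(cfg$coverage_dispersion > 0, "coverage_dispersion must be positive")
  check_that(all(cfg$ase_effect_fracrefs > 0 & cfg$ase_effect_fracrefs < 1),
             "ase_effect_fracrefs must lie in (0,1)")
  invisible(cfg)
}

#' Simulate genotype dosages with block LD
#'
#' Haplotypes are generated by a copying model: within each LD block a
#' haplotype's latent uniform either copies the previous variant's value
#' (probability `ld_decay`) or is redrawn, and the allele is the indicator
#' that the uniform falls below the variant's allele frequency. Adjacent
#' variants with equal frequencies then have genotype correlation
#' `ld_decay`, decaying geometrically with distance; across blocks
#' variants are independent. Each chromosome holds `blocks_per_chrom`
#' blocks; positions are regularly spaced.
#'
#' @param config [sim_config()].
#' @return list of class `genotype_matrix`: `variants` (variant_id, chrom,
#'   pos, ref, alt, maf, block), `dosage` (sample x variant, hard calls
#'   0/1/2), `sample_ids`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples
  m <- config$n_variants
  bs <- config$ld_block_size
  with_seed(derive_seed(config$seed, 1L), {
    f <- runif(m, config$maf_range[1], config$maf_range[2])
    block <- (seq_len(m) - 1L) %/% bs + 1L
    H <- matrix(0L, nrow = 2L * n, ncol = m)
    u <- numeric(2L * n)
    for (v in seq_len(m)) {
      new_block <- v == 1L || block[v] != block[v - 1L]
      if (new_block) {
        u <- runif(2L * n)
      } else {
        redraw <- runif(2L * n) >= config$ld_decay
        u[redraw] <- runif(sum(redraw))
      }
      H[, v] <- as.integer(u < f[v])
    }
    dosage <- H[seq_len(n) * 2L - 1L, , drop = FALSE] +
      H[seq_len(n) * 2L, , drop = FALSE]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    chrom_of_block <- (block - 1L) %/% config$blocks_per_chrom + 1L
    within <- stats::ave(seq_len(m), chrom_of_block, FUN = seq_along)
    variants <- data.frame(
      variant_id = sprintf("var%05d", seq_len(m)),
      chrom = paste0("chr", chrom_of_block),
      pos = within * config$variant_spacing_bp,
      ref = unname(ref), alt = unname(alt),
      maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2),
      block = block, stringsAsFactors = FALSE)
    dimnames(dosage) <- list(sprintf("S%03d", seq_len(n)), variants$variant_id)
    structure(list(variants = variants, dosage = dosage,
                   sample_ids = rownames(dosage)),
              class = "genotype_matrix")
  })
}

#' Simulate gene annotations on the synthetic genome
#'
#' Places genes uniformly over the chromosomes defined by a simulated
#' genotype set, with random strand and lognormal gene lengths (used by
#' the GO enrichment model's length covariate).
#'
#' @param config [sim_config()].
#' @param genotypes output of [simulate_genotypes()].
#' @return data.frame: gene_id, chrom, strand, tss, length_bp.
#' @export
simulate_genes <- function(config, genotypes) {
  v <- genotypes$variants
  chroms <- unique(v$chrom)
  span <- vapply(chroms, function(ch) max(v$pos[v$chrom == ch]), numeric(1))
  with_seed(derive_seed(config$seed, 2L), {
    chrom <- sample(chroms, config$n_genes, replace = TRUE)
    tss <- floor(runif(config$n_genes, 1, span[chrom]))
    data.frame(
      gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
      chrom = chrom,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      tss = tss,
      length_bp = round(exp(rnorm(config$n_genes, log(20000), 1))),
      stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate a multi-tissue reference expression panel
#'
#' Background genes draw their tissue shares from a concentrated
#' symmetric Dirichlet (near-uniform across tissues, entropy close to
#' log2(n_tissues) bits); planted target-specific genes place >= 90% of
#' their expression in the target tissue. Totals are lognormal FPKM-like
#' values.
#'
#' @param config [sim_config()].
#' @param gene_ids gene identifiers (default gene0001..).
#' @param target_tissue name of the target tissue column.
#' @return list: `panel` (gene x tissue matrix), `specific_gene_truth`
#'   (character vector), `target_tissue`.
#' @export
simulate_tissue_panel <- function(config, gene_ids = NULL,
                                  target_tissue = "muscle") {
  validate_sim_config(config)
  G <- config$n_genes
  Tn <- config$n_tissues
  gene_ids <- gene_ids %||% sprintf("gene%04d", seq_len(G))
  tissues <- c(target_tissue, sprintf("tissue%02d", seq_len(Tn - 1L)))
  with_seed(derive_seed(config$seed, 3L), {
    n_spec <- round(config$frac_specific_genes * G)
    specific <- if (n_spec > 0) sample(gene_ids, n_spec) else character(0)
    shares <- matrix(0, G, Tn, dimnames = list(gene_ids, tissues))
    rdirichlet <- function(n, alpha) {
      x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                  nrow = n, byrow = TRUE)
      x / rowSums(x)
    }
    is_spec <- gene_ids %in% specific
    n_bg <- sum(!is_spec)
    if (n_bg > 0) shares[!is_spec, ] <- rdirichlet(n_bg, rep(50, Tn))
    if (n_spec > 0) {
      tgt <- runif(n_spec, 0.92, 0.98)
      rest <- rdirichlet(n_spec, rep(5, Tn - 1L)) * (1 - tgt)
      shares[is_spec, 1] <- tgt
      shares[is_spec, -1] <- rest
    }
    total <- exp(rnorm(G, log(20), 1.2))
    panel <- shares * total
    list(panel = panel, specific_gene_truth = sort(specific),
         target_tissue = target_tissue)
  })
}

#' Simulate expression with planted cis effects and structure
#'
#' Generates a sample x gene matrix on the transformed (unit-variance
#' Gaussian) scale: planted eQTL genes receive beta x dosage of one cis
#' variant, all genes receive covariate effects (age, sex, batch), shared
#' latent-factor structure, and Gaussian noise whose variance is set to
#' 1 - beta^2 var(dosage) so the planted beta is the standardized effect
#' recoverable after adjustment. An FPKM-like view (2^(value + 5)) is
#' also returned for interfaces that expect non-negative expression.
#'
#' @param genotypes [simulate_genotypes()] output.
#' @param genes [simulate_genes()] output.
#' @param config [sim_config()].
#' @return list: `expression` (transformed scale), `fpkm`, `covariates`
#'   (age, sex, batch), `eqtl_truth` (gene_id, variant_id, beta).
#' @export
simulate_expression <- function(genotypes, genes, config) {
  validate_sim_config(config)
  n <- config$n_samples
  check_that(nrow(genotypes$dosage) == n,
             "genotype samples (%d) disagree with config n_samples (%d)",
             nrow(genotypes$dosage), n)
  G <- config$n_genes
  v <- genotypes$variants
  with_seed(derive_seed(config$seed, 4L), {
    covariates <- data.frame(
      age = round(rnorm(n, 55, 8)),
      sex = sample(0:1, n, replace = TRUE),
      batch = factor(sample(paste0("b", seq_len(config$batch_levels)),
                            n, replace = TRUE)),
      row.names = genotypes$sample_ids)
    n_eqtl <- round(config$frac_eqtl_genes * G)
    eqtl_genes <- sort(sample(genes$gene_id, n_eqtl))
    betas <- rep_len(config$eqtl_effect_sizes, n_eqtl)
    truth <- data.frame(gene_id = eqtl_genes,
                        variant_id = NA_character_,
                        beta = betas, stringsAsFactors = FALSE)
    for (i in seq_len(n_eqtl)) {
      g <- genes[genes$gene_id == eqtl_genes[i], ]
      cand <- which(v$chrom == g$chrom & abs(v$pos - g$tss) <= 2e5)
      if (!length(cand)) cand <- which(v$chrom == g$chrom &
                                         abs(v$pos - g$tss) <= 1e6)
      check_that(length(cand) > 0, "no cis variant for planted gene %s",
                 eqtl_genes[i])
      truth$variant_id[i] <- v$variant_id[sample(cand, 1)]
    }
    K <- config$n_latent_factors
    Fm <- if (K > 0) matrix(rnorm(n * K), n, K) else NULL
    lambda <- if (K > 0) matrix(rnorm(G * K, 0, 0.4), K, G) else NULL
    batch_eff <- matrix(rnorm(config$batch_levels * G, 0, 0.5),
                        config$batch_levels, G)
    age_c <- scale(covariates$age)[, 1]
    sex_c <- covariates$sex - mean(covariates$sex)
    age_coef <- rnorm(G, 0, 0.1)
    sex_coef <- rnorm(G, 0, 0.2)
    Y <- matrix(0, n, G, dimnames = list(genotypes$sample_ids, genes$gene_id))
    bi <- as.integer(covariates$batch)
    noise_sd <- rep(1, G)
    beta_of <- setNames(rep(0, G), genes$gene_id)
    var_of <- setNames(rep(0, G), genes$gene_id)
    beta_of[truth$gene_id] <- truth$beta
    var_of[truth$gene_id] <- apply(
      genotypes$dosage[, truth$variant_id, drop = FALSE], 2, var)
    noise_sd <- sqrt(pmax(0.2, 1 - beta_of^2 * var_of))
    Y <- Y + outer(age_c, age_coef) + outer(sex_c, sex_coef) +
      batch_eff[bi, , drop = FALSE]
    if (K > 0) Y <- Y + Fm %*% lambda
    Y <- Y + sweep(matrix(rnorm(n * G), n, G), 2, noise_sd, `*`)
    has_eff <- truth$beta != 0
    for (i in which(has_eff)) {
      Y[, truth$gene_id[i]] <- Y[, truth$gene_id[i]] +
        truth$beta[i] * genotypes$dosage[, truth$variant_id[i]]
    }
    dimnames(Y) <- list(genotypes$sample_ids, genes$gene_id)
    list(expression = Y, fpkm = 2^(Y + 5), covariates = covariates,
         factors = Fm, eqtl_truth = truth)
  })
}

#' Simulate allelic read counts with planted imbalance and bias artifacts
#'
#' For a subset of variants, every heterozygous sample receives a total
#' allelic depth drawn negative-binomially (mean `coverage_mean`, size
#' `coverage_dispersion`, floored at 1) and a reference count drawn
#' binomially at the variant's true fracRef: 0.5 for null variants, a
#' planted value for ASE variants, and a shifted value (0.85) for
#' mapping-bias artifacts. Counts are split across forward/reverse
#' strands. Bias variants get a simulated-coverage value outside the
#' mask's acceptance band [193, 202] so the coverage filter removes them;
#' all other variants get values inside the band. Small fractions of
#' variants are additionally flagged blacklisted or near an indel.
#'
#' @param genotypes [simulate_genotypes()] output.
#' @param config [sim_config()].
#' @return list: `counts` (sample_id, variant_id, ref, alt, allele_pair,
#'   strand, ref_count, alt_count), `mask` (variant_id,
#'   simulated_coverage, blacklisted, near_indel), `ase_truth`
#'   (variant_id, true_fracref), `bias_snp_truth` (variant ids).
#' @export
simulate_allele_counts <- function(genotypes, config) {
  validate_sim_config(config)
  v <- genotypes$variants
  with_seed(derive_seed(config$seed, 5L), {
    m <- min(config$n_ase_variants, nrow(v))
    vids <- sort(sample(v$variant_id, m))
    n_ase <- round(config$frac_ase_variants * m)
    n_bias <- round(config$frac_bias_variants * m)
    roles <- sample(vids)
    ase_ids <- sort(roles[seq_len(n_ase)])
    bias_ids <- sort(roles[n_ase + seq_len(n_bias)])
    true_fr <- setNames(rep(0.5, m), vids)
    true_fr[ase_ids] <- rep_len(config$ase_effect_fracrefs, n_ase)
    true_fr[bias_ids] <- 0.85   # artifactual skew typical of mapping bias
    rows <- vector("list", m)
    for (k in seq_len(m)) {
      vid <- vids[k]
      het <- which(genotypes$dosage[, vid] == 1)
      if (!length(het)) next
      tot <- pmax(1, rnbinom(length(het), mu = config$coverage_mean,
                             size = config$coverage_dispersion))
      ref_n <- rbinom(length(het), tot, true_fr[vid])
      ref_f <- rbinom(length(het), ref_n, 0.5)
      alt_n <- tot - ref_n
      alt_f <- rbinom(length(het), alt_n, 0.5)
      vi <- v[v$variant_id == vid, ]
      rows[[k]] <- data.frame(
        sample_id = rep(genotypes$sample_ids[het], 2),
        variant_id = vid, ref = vi$ref, alt = vi$alt,
        allele_pair = paste0(vi$ref, vi$alt),
        strand = rep(c("+", "-"), each = length(het)),
        ref_count = c(ref_f, ref_n - ref_f),
        alt_count = c(alt_f, alt_n - alt_f),
        stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- NULL
    sim_cov <- sample(193:202, m, replace = TRUE)
    bias_cov <- sample(c(150:192, 203:250), m, replace = TRUE)
    is_bias <- vids %in% bias_ids
    mask <- data.frame(
      variant_id = vids,
      simulated_coverage = ifelse(is_bias, bias_cov, sim_cov),
      blacklisted = runif(m) < 0.02 & !is_bias,
      near_indel = runif(m) < 0.02 & !is_bias,
      stringsAsFactors = FALSE)
    list(counts = counts,
         mask = mask,
         ase_truth = data.frame(variant_id = ase_ids,
                                true_fracref = unname(true_fr[ase_ids]),
                                stringsAsFactors = FALSE),
         bias_snp_truth = bias_ids)
  })
}

# Greedy non-overlapping placement: candidates (start,end in BED
# convention) are taken in the given priority order; a candidate clashing
# with anything already placed is dropped.
place_nonoverlapping <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  keep <- logical(nrow(cand))
  occ <- list()
  for (ch in unique(cand$chrom)) occ[[ch]] <- cbind(numeric(0), numeric(0))
  for (i in seq_len(nrow(cand))) {
    o <- occ[[cand$chrom[i]]]
    clash <- any(cand$start[i] < o[, 2] & cand$end[i] > o[, 1])
    if (!clash) {
      keep[i] <- TRUE
      occ[[cand$chrom[i]]] <- rbind(o, c(cand$start[i], cand$end[i]))
    }
  }
  cand[keep, , drop = FALSE]
}

#' Simulate chromatin-state segmentations with planted enrichment
#'
#' Emits a target-tissue segmentation plus `n_other_tissues` unrelated
#' ones, on the genome of a simulated genotype set. Stretch enhancers
#' (length >= 3 kb, multiples of 200 bp) are planted over the eQTL
#' variants of genes in each specificity decile with a probability that
#' ramps linearly so that the planted fold enrichment rises from 1
#' (decile 1) to `target_fold` (decile 10) against a background in which
#' a fraction `base_stretch_fraction` of variants sits in stretch
#' enhancers anyway. Typical enhancers (200-800 bp) are placed uniformly,
#' independent of eQTL status. Promoter states are placed at gene TSSs
#' and everything else is quiescent; intervals never overlap within a
#' tissue.
#'
#' @param genes gene annotation with `decile` column (join of
#'   [simulate_genes()] and [mesi_scores()]).
#' @param genotypes [simulate_genotypes()] output.
#' @param eqtl_truth data.frame gene_id, variant_id (planted or mapped
#'   eQTLs to enrich over).
#' @param config [sim_config()].
#' @param target_fold planted decile-10 stretch fold enrichment (default 3).
#' @param base_stretch_fraction background fraction of variants inside
#'   stretch enhancers (default 0.15). The planted placement rates are
#'   calibrated against the realized universe-wide stretch fraction
#'   (background plus planted mass), so the decile-10 fold is `target_fold`
#'   relative to matched nulls drawn from the same universe.
#' @param typical_fraction background fraction of variants inside typical
#'   enhancers (default 0.15).
#' @param n_other_tissues unrelated segmentations (default 2).
#' @param target_tissue name of the target tissue.
#' @return list: `segmentations` (named list of BED-convention
#'   data.frames), `enhancer_truth` (intervals with class and
#'   planted-over-eQTL flag), `target_tissue`.
#' @export
simulate_chromatin <- function(genes, genotypes, eqtl_truth, config,
                               target_fold = 3, base_stretch_fraction = 0.15,
                               typical_fraction = 0.15, n_other_tissues = 2L,
                               target_tissue = "muscle") {
  check_that("decile" %in% names(genes), "genes must carry a decile column")
  v <- genotypes$variants
  chroms <- unique(v$chrom)
  span <- vapply(chroms, function(ch) max(v$pos[v$chrom == ch]) + 10000,
                 numeric(1))
  lam0 <- base_stretch_fraction
  with_seed(derive_seed(config$seed, 6L), {
    build_tissue <- function(planted) {
      # planted: data.frame(chrom, pos) of variants to cover with stretch
      cand <- list()
      if (nrow(planted) > 0) {
        len <- 200L * sample(15:30, nrow(planted), replace = TRUE)
        off <- vapply(len, function(l) 200L * sample.int(l %/% 200L, 1) - 100L,
                      numeric(1))
        start <- pmax(0, floor((planted$pos - off) / 200) * 200)
        cand[[1]] <- data.frame(chrom = planted$chrom, start = start,
                                end = start + len, planted = TRUE,
                                class = "stretch", stringsAsFactors = FALSE)
      }
      # background stretch: enough to put ~lam0 of variants inside
      n_bg <- round(lam0 * nrow(v) / 0.8)
      ch_bg <- sample(chroms, n_bg, replace = TRUE, prob = span / sum(span))
      len_bg <- 200L * sample(15:30, n_bg, replace = TRUE)
      st_bg <- floor(runif(n_bg, 0, span[ch_bg] - len_bg) / 200) * 200
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch_bg, start = st_bg, end = st_bg + len_bg,
        planted = FALSE, class = "stretch", stringsAsFactors = FALSE)
      # typical enhancers, uniform
      n_ty <- round(typical_fraction * nrow(v) / 0.1)
      ch_ty <- sample(chroms, n_ty, replace = TRUE, prob = span / sum(span))
      len_ty <- 200L * sample(1:4, n_ty, replace = TRUE)
      st_ty <- floor(runif(n_ty, 0, span[ch_ty] - len_ty) / 200) * 200
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch_ty, start = st_ty, end = st_ty + len_ty,
        planted = FALSE, class = "typical", stringsAsFactors = FALSE)
      enh <- place_nonoverlapping(do.call(rbind, cand))
      # promoters at TSSs that do not clash with enhancers
      prom <- data.frame(chrom = genes$chrom,
                         start = pmax(0, floor(genes$tss / 200) * 200 - 200),
                         end = floor(genes$tss / 200) * 200 + 200,
                         planted = FALSE, class = "promoter",
                         stringsAsFactors = FALSE)
      all <- place_nonoverlapping(rbind(enh, prom))
      state <- ifelse(all$class == "promoter", "Active_TSS",
                      ifelse(all$class == "stretch", "Active_enhancer_1",
                             "Weak_enhancer"))
      seg <- data.frame(chrom = all$chrom, start = all$start, end = all$end,
                        state = state, stringsAsFactors = FALSE)
      # fill gaps with quiescent state
      fill <- list()
      for (ch in chroms) {
        s <- seg[seg$chrom == ch, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        edges <- c(0, as.vector(rbind(s$start, s$end)), span[ch])
        gs <- edges[seq(1, length(edges), by = 2)]
        ge <- edges[seq(2, length(edges), by = 2)]
        ok <- ge > gs
        fill[[ch]] <- data.frame(chrom = ch, start = gs[ok], end = ge[ok],
                                 state = "Quiescent_low",
                                 stringsAsFactors = FALSE)
      }
      seg <- rbind(seg, do.call(rbind, fill))
      seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
      rownames(seg) <- NULL
      list(seg = seg, enh = all[all$class != "promoter", , drop = FALSE])
    }
    # planted placement over eQTL variants, decile-ramped; the rates are
    # solved against the realized baseline (background + planted mass) so
    # measured folds match the requested ramp
    dec <- setNames(genes$decile, genes$gene_id)[eqtl_truth$gene_id]
    fold_d <- 1 + (target_fold - 1) * (pmax(dec, 1) - 1) / 9
    m_p <- sum(!is.na(dec))
    lam_eff <- lam0
    rate <- rep(0, length(fold_d))
    for (it in 1:25) {
      rate <- pmin(1, pmax(0, (fold_d * lam_eff - lam0) / (1 - lam0)))
      p_d <- rate + (1 - rate) * lam0
      lam_eff <- (sum(p_d[!is.na(dec)]) + (nrow(v) - m_p) * lam0) / nrow(v)
    }
    pick <- !is.na(dec) & runif(length(rate)) < rate
    planted_v <- v[match(eqtl_truth$variant_id[pick], v$variant_id),
                   c("chrom", "pos")]
    target <- build_tissue(planted_v)
    segs <- list()
    segs[[target_tissue]] <- target$seg
    for (tname in paste0("other", seq_len(n_other_tissues))) {
      segs[[tname]] <- build_tissue(planted_v[0, ])$seg
    }
    truth <- target$enh
    names(truth)[names(truth) == "planted"] <- "planted_over_eqtl"
    list(segmentations = segs, enhancer_truth = truth,
         target_tissue = target_tissue)
  })
}

#' Simulate phenotypes, GO memberships and planted trait effects
#'
#' Draws disease status (0/1) and quantitative traits, then plants
#' per-gene effects by shifting expression of chosen genes along the
#' (standardized) trait. A weak effect proportional to each gene's
#' log10 length is added for the quantitative trait across ALL genes, so
#' gene length confounds association power: GO terms made of long genes
#' look enriched unless the enrichment model adjusts for length. GO
#' memberships include planted positive and negative terms (built from
#' the positively / negatively shifted genes), one length-confounded null
#' term whose membership is logistic in gene length, and random null
#' terms.
#'
#' @param expression sample x gene matrix from [simulate_expression()].
#' @param genes annotation with length_bp.
#' @param config [sim_config()].
#' @param frac_de fraction of genes given a trait effect (default 0.05).
#' @param de_beta effect size on the unit-variance expression scale
#'   (default 0.6).
#' @param length_kappa length-confound strength (default 0.25).
#' @param n_null_terms random GO terms (default 30).
#' @return list: `expression` (with effects added), `phenotypes`,
#'   `memberships` (term_id, gene_id), `de_truth`, `go_truth`.
#' @export
simulate_phenotypes <- function(expression, genes, config, frac_de = 0.05,
                                de_beta = 0.6, length_kappa = 0.25,
                                n_null_terms = 30L) {
  n <- nrow(expression)
  gene_ids <- colnames(expression)
  check_that(identical(gene_ids, genes$gene_id),
             "expression columns must match gene annotation order")
  with_seed(derive_seed(config$seed, 7L), {
    t2d <- sample(0:1, n, replace = TRUE)
    glucose <- rnorm(n, 5.5, 0.8) + 1.2 * t2d
    insulin <- exp(rnorm(n, log(60), 0.4))
    bmi <- rnorm(n, 28, 4)
    phen <- data.frame(sample_id = rownames(expression), T2D = t2d,
                       glucose = glucose, insulin = insulin, bmi = bmi,
                       stringsAsFactors = FALSE)
    G <- length(gene_ids)
    n_de <- max(2, round(frac_de * G))
    de_genes <- sample(gene_ids, n_de)
    de_sign <- rep(c(1, -1), length.out = n_de)
    de_truth <- data.frame(gene_id = de_genes, trait = "T2D",
                           beta = de_beta * de_sign, stringsAsFactors = FALSE)
    t_std <- (t2d - mean(t2d)) / sd(t2d)
    E <- expression
    for (i in seq_len(n_de)) {
      E[, de_genes[i]] <- E[, de_genes[i]] + de_truth$beta[i] * t_std
    }
    # length-power confound: every gene picks up a small glucose effect
    # proportional to its (standardized) log length
    L <- log10(genes$length_bp)
    L_std <- (L - mean(L)) / sd(L)
    x_std <- (glucose - mean(glucose)) / sd(glucose)
    E <- E + outer(x_std, length_kappa * L_std)
    # GO terms
    memb <- list()
    pos_genes <- de_genes[de_sign > 0]
    neg_genes <- de_genes[de_sign < 0]
    pad <- function(core, size) {
      unique(c(core, sample(setdiff(gene_ids, core),
                            max(0, size - length(core)))))
    }
    memb[["GO_POS"]] <- pad(pos_genes, length(pos_genes) + 20)
    memb[["GO_NEG"]] <- pad(neg_genes, length(neg_genes) + 20)
    p_long <- stats::plogis(-2.5 + 2 * L_std)
    memb[["GO_LONG"]] <- gene_ids[runif(G) < p_long]
    null_size_max <- max(2L, min(150L, G %/% 4))
    for (k in seq_len(n_null_terms)) {
      memb[[sprintf("GO_NULL%02d", k)]] <-
        sample(gene_ids, sample(min(30L, null_size_max):null_size_max, 1))
    }
    memberships <- data.frame(
      term_id = rep(names(memb), lengths(memb)),
      gene_id = unlist(memb, use.names = FALSE),
      stringsAsFactors = FALSE)
    go_truth <- data.frame(
      term_id = c("GO_POS", "GO_NEG", "GO_LONG"),
      direction = c("+", "-", "confounded_null"),
      stringsAsFactors = FALSE)
    list(expression = E, phenotypes = phen, memberships = memberships,
         de_truth = de_truth, go_truth = go_truth)
  })
}
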