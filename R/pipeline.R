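#' Run the full synthetic-data pipeline
#'
#' Executes every stage in dependency order on a fully simulated dataset:
#' simulate (genotypes, genes, tissue panel, expression, allelic counts,
#' phenotypes, chromatin) -> specificity scoring -> trait association +
#' GO enrichment -> cis-eQTL mapping (latent-factor adjusted) -> ASE ->
#' enhancer classification and matched-null enrichment. All inputs and
#' results are written as TSV/VCF/BED under `out_dir`, together with a
#' YAML manifest recording the configuration, seed, package version and
#' output file checksums. Reruns with the same config are byte-identical.
#'
#' Stage sizes are taken from `config`; the enrichment stage accepts a
#' reduced `n_null_sets`/`min_pool` for quick demonstrations.
#'
#' @param config [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param factors_k latent factors removed before eQTL mapping.
#' @param n_null_sets,min_pool matched-null enrichment parameters.
#' @param fdr_method "BH" or "storey" for eQTL / trait FDR.
#' @return invisibly, a list with every in-memory result.
#' @export
run_pipeline <- function(config, out_dir, factors_k = 10L,
                         n_null_sets = 100L, min_pool = 20L,
                         fdr_method = "BH") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  geno <- simulate_genotypes(config)
  genes <- simulate_genes(config, geno)
  panel <- simulate_tissue_panel(config, gene_ids = genes$gene_id)
  expr <- simulate_expression(geno, genes, config)
  phen <- simulate_phenotypes(expr$expression, genes, config)
  ase_sim <- simulate_allele_counts(geno, config)

  write_vcf(geno, p("genotypes.vcf"))
  write_tsv(genes, p("genes.tsv"))
  write_matrix_tsv(panel$panel, p("tissue_panel.tsv"))
  write_matrix_tsv(t(phen$expression), p("expression.tsv"))
  write_tsv(phen$phenotypes, p("phenotypes.tsv"))
  write_tsv(phen$memberships, p("go_memberships.tsv"))
  write_tsv(ase_sim$counts, p("allele_counts.tsv"))
  write_tsv(ase_sim$mask, p("ase_mask.tsv"))
  write_tsv(expr$eqtl_truth, p("truth_eqtl.tsv"))
  write_tsv(phen$de_truth, p("truth_de.tsv"))
  write_tsv(phen$go_truth, p("truth_go.tsv"))
  write_tsv(ase_sim$ase_truth, p("truth_ase.tsv"))
  write_tsv(data.frame(variant_id = ase_sim$bias_snp_truth), p("truth_bias.tsv"))
  write_tsv(data.frame(gene_id = panel$specific_gene_truth),
            p("truth_specific_genes.tsv"))

  # specificity
  spec <- mesi_scores(panel$panel, panel$target_tissue)
  write_tsv(spec, p("mesi.tsv"))
  genes$decile <- spec$decile[match(genes$gene_id, spec$gene_id)]

  # chromatin (placement uses the scored deciles)
  chrom <- simulate_chromatin(genes, geno, expr$eqtl_truth, config)
  for (tname in names(chrom$segmentations)) {
    write_bed_states(chrom$segmentations[[tname]],
                     p(sprintf("chromatin_%s.bed", tname)))
  }

  # trait association + GO
  Y_t2d <- transform_quantitative(phen$expression, covariates = NULL,
                                  seed = config$seed)
  covs <- expr$covariates
  assoc <- t2d_association(Y_t2d, phen$phenotypes$T2D, covs, fdr_method)
  write_tsv(assoc, p("assoc_t2d.tsv"))
  Yq <- transform_quantitative(phen$expression, covs, seed = config$seed)
  xq <- transform_quantitative(phen$phenotypes$glucose, covs,
                               seed = config$seed + 1L)
  assoc_glu <- quant_trait_association(Yq, xq, fdr_method)
  write_tsv(assoc_glu, p("assoc_glucose.tsv"))
  signed_logp <- setNames(-log10(pmax(assoc_glu$p, 1e-300)) *
                            sign(assoc_glu$beta), assoc_glu$gene_id)
  L <- setNames(log10(genes$length_bp), genes$gene_id)
  go <- go_enrichment(signed_logp, L, phen$memberships)
  write_tsv(go, p("go_enrichment.tsv"))

  # cis-eQTL
  Y_adj <- latent_factor_adjust(phen$expression, covs, K = factors_k,
                                seed = config$seed)
  pairs <- cis_pairs(genes, geno$variants)
  eqtl <- map_cis_eqtl(Y_adj, geno$dosage, pairs, fdr_method = fdr_method)
  write_tsv(eqtl[eqtl$q <= 0.05, ], p("eqtl_significant.tsv"))
  vpos <- setNames(geno$variants$pos, geno$variants$variant_id)
  best <- best_per_gene(eqtl, vpos)
  write_tsv(best, p("eqtl_best_per_gene.tsv"))

  # ASE
  filt <- apply_ase_filters(ase_sim$counts, ase_sim$mask)
  ase_res <- combine_across_samples(filt, seed = config$seed)
  write_tsv(ase_res$per_variant, p("ase_per_variant.tsv"))

  # enhancers + enrichment
  seg <- chrom$segmentations[[chrom$target_tissue]]
  runs <- merge_enhancer_runs(seg)
  enh <- classify_enhancers(runs)
  others <- chrom$segmentations[names(chrom$segmentations) !=
                                  chrom$target_tissue]
  enh <- tissue_specific_filter(enh, others)
  write_bed_states(enh, p("enhancers.bed"), name_col = "class")
  uni <- geno$variants
  uni$tss_dist <- nearest_tss_distance(uni, genes)
  uni$ld_count <- ld_neighbour_count(geno$dosage, uni)
  sig_best <- best[best$q <= 0.05, , drop = FALSE]
  deciles <- setNames(genes$decile, genes$gene_id)
  strat <- stratified_enrichment(sig_best, deciles, enh, uni,
                                 n_null_sets = n_null_sets,
                                 min_pool = min_pool, seed = config$seed)
  write_tsv(strat, p("enrichment_stratified.tsv"))

  manifest <- list(
    package = "muscleqtl",
    version = as.character(packageVersion("muscleqtl")),
    seed = config$seed,
    config = unclass(config),
    files = {
      fl <- sort(list.files(out_dir, full.names = TRUE,
                            pattern = "\\.(tsv|vcf|bed)$"))
      stats::setNames(as.list(unname(tools::md5sum(fl))), basename(fl))
    })
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(list(genotypes = geno, genes = genes, panel = panel,
                 expression = phen$expression, covariates = covs,
                 phenotypes = phen$phenotypes, spec = spec, assoc = assoc,
                 assoc_glucose = assoc_glu, go = go, eqtl = eqtl,
                 best = best, ase = ase_res, enhancers = enh,
                 enrichment = strat, truth = list(
                   eqtl = expr$eqtl_truth, de = phen$de_truth,
                   go = phen$go_truth, ase = ase_sim$ase_truth,
                   bias = ase_sim$bias_snp_truth,
                   specific_genes = panel$specific_gene_truth,
                   enhancers = chrom$enhancer_truth)))
}
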