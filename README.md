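# muscleqtl

Regulatory genomics of tissue-specific gene expression in skeletal muscle
(or any target tissue): an R toolkit for the analyses that connect common
genetic variation, muscle gene expression, and type 2 diabetes biology.

It is aimed at statistical geneticists and computational biologists who
work with expression cohorts (genotypes + RNA-seq + phenotypes) and
chromatin annotation, and who want the bespoke statistical machinery of
such studies as tested, reusable functions rather than one-off scripts.

## What it computes

**Tissue expression specificity (mESI).** From a gene × tissue FPKM panel
(e.g. 16 diverse tissues), per gene *g* with tissue proportions
*p*<sub>g,t</sub> = *x*<sub>g,t</sub> / Σ<sub>t</sub> *x*<sub>g,t</sub>:

- entropy *H*<sub>g</sub> = −Σ<sub>t</sub> *p*<sub>g,t</sub> log₂ *p*<sub>g,t</sub> (bits),
- target-tissue specificity *Q*<sub>g</sub> = *H*<sub>g</sub> − log₂ *p*<sub>g,target</sub>,
- specificity index mESI<sub>g</sub> = 1 − *Q*<sub>g</sub>/max(*Q*), in [0, 1],

with rank-based decile binning (decile 10 = highly, specifically
expressed in the target tissue).

**Trait–expression association.** OLS of inverse-normalised expression on
disease status with covariates (age, sex, batch), and the
double-transformed recipe for quantitative traits (inverse normal →
residualize → inverse normal on both sides). GO enrichment by per-term
logistic regression of membership on the signed −log₁₀ association
p-value with a log₁₀ gene-length covariate that absorbs the
power–length confound, plus top-k ranking and Jaccard redundancy pruning
for presentation.

**cis-eQTL mapping.** Simple regression of latent-factor-adjusted
expression on allele dosage for every variant within 1 Mb of a gene's
most upstream TSS (strand-aware, inclusive bounds), MAC > 5, BH or Storey
FDR; per-gene greedy LD pruning at r² ≥ 0.2; best-per-gene selection; and
iterative conditional analysis of GWAS variants by forward selection of
cis SNPs at a stopping p of 0.0019.

**Allele-specific expression.** Mapping-bias filters (simulated-coverage
band [193, 202], blacklist, indel proximity, 0.01 < fracRef < 0.99),
per-sample per-allele-pair expected fracRef with seeded down-sampling of
top-quartile coverage to 30×, exact two-sided binomial tests, Fisher
combination across ≥ 10 samples, Storey q-values.

**Stretch-enhancer enrichment.** Merging of enhancer chromatin-state runs,
classification as stretch (≥ 3 kb) / typical (≤ 800 bp), tissue-specificity
flagging against other tissues' segmentations, and matched-null SNP
enrichment (nulls matched on MAF, TSS distance and LD-neighbour count;
fold = observed / mean null overlap, empirical p), stratified by mESI
decile.

**Synthetic data.** `sim_config()` + `simulate_*()` generate every input
with planted ground truth (LD-block genotypes, planted cis effects,
tissue panels with planted specific genes, negative-binomial allelic
counts with planted imbalance and mapping-bias artifacts, chromatin
segmentations with a planted decile-ramped stretch-enhancer enrichment,
phenotypes with planted DE genes and GO terms), so every claim the
package makes is testable end to end.

## Worked example

```r
library(muscleqtl)

cfg <- sim_config(n_samples = 100, n_genes = 300, n_variants = 3000, seed = 42)
out <- run_pipeline(cfg, "demo_run", factors_k = 5,
                    n_null_sets = 50, min_pool = 10)

# planted muscle-specific genes land in the top specificity decile
spec <- out$spec
table(spec$decile[spec$gene_id %in% out$truth$specific_genes])
#> 10
#> 15

# estimated eQTL betas track the planted effects
m <- merge(out$eqtl, out$truth$eqtl, by = c("gene_id", "variant_id"))
coef(lm(beta.x ~ beta.y, data = m))[2]
#>    beta.y
#> 0.9007026

# stretch-enhancer enrichment rises with specificity decile
subset(out$enrichment, class == "stretch" & decile %in% c(1, 5, 10),
       select = c(decile, n_snps, fold))
#>    decile n_snps      fold
#> 1       1     13 0.5102041
#> 9       5     13 2.0000000
#> 19     10      6 3.2608696
```

All 15 planted tissue-specific genes score in mESI decile 10; the
regression of estimated on planted eQTL betas has slope ≈ 0.90 (the mild
shrinkage comes from the rank-based inverse normal transform); and the
planted stretch-enhancer enrichment ramp (fold rising toward 3 at decile
10) is visible even at this small demonstration scale — the per-decile
folds are noisy with only ~13 SNPs each; the acceptance script runs the
properly powered version. `demo_run/`
holds every table (VCF, BED, TSVs) plus a YAML manifest with config,
seed and file checksums; rerunning with the same config reproduces every
file byte for byte.

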