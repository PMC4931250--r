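---
title: "Models, parameters and design choices in muscleqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in muscleqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The expression specificity index

For a gene $g$ measured across $T$ tissues (FPKM or any non-negative
unit), the tissue proportions are $p_{g,t} = x_{g,t} / \sum_t x_{g,t}$.
Entropy $H_g = -\sum_t p_{g,t}\log_2 p_{g,t}$ (bits, with
$0\log 0 \equiv 0$) measures how evenly expression spreads across
tissues; $H = \log_2 T$ for perfectly even expression, $0$ for a point
mass. The target-tissue specificity is

$$Q_g = H_g - \log_2 p_{g,\mathrm{target}},$$

which is $0$ exactly when all expression sits in the target tissue and
grows both when expression is even across tissues (large $H$) and when
the target share is small ($-\log_2 p$ large). The published formula
images for this index render as placeholders in the source text we
follow, so the implementation takes the definition from the cited
information-theory specificity literature; the direction is fixed by the
downstream transformation, $\mathrm{mESI}_g = 1 - Q_g/\max_g Q_g$, which
must place target-specific genes near 1. Genes with zero target
expression get $Q = \infty$ and $\mathrm{mESI} = 0$; all-zero rows are
flagged unscorable rather than erroring. No pseudocount is added (none
is described); scores are computed on FPKM by default and are invariant
to any common rescaling of a gene's row, so transcripts-per-million
input gives similar results.

Deciles are equal-count rank bins (sizes differing by at most one);
ties break by a stable sort on gene id so assignment is reproducible.

## Trait association and GO enrichment

Binary-trait association fits, per gene $j$,
$Y_{ij} = \alpha_j + \beta_j T_i + \gamma_j' Z_i + \varepsilon_{ij}$,
where $Y$ is the rank-based inverse normal transform of FPKM (offset
$(r-0.5)/n$; the offset is configurable because the recipe does not pin
it down) and $Z$ holds age, sex and batch. Ties are broken uniformly at
random under a caller-supplied seed — with many identical FPKM values
(zeros especially) a deterministic tie rule would create artifactual
structure. Quantitative traits use the doubly-transformed recipe on both
sides: inverse normal, residualize on $Z$, inverse normal again, then
simple regression. FDR is Benjamini–Hochberg by default with Storey
q-values behind a flag: the Storey estimator is the better calibrated
choice for large, partially non-null families (and is the default in the
ASE stage, where the source procedure names it), while BH is the safer
default for small result sets.

GO enrichment is per-term logistic regression
$\mathrm{logit}\,\pi_j = \alpha + \beta P_j + \gamma L_j$ with $P_j$ the
signed $-\log_{10}$ association p-value and $L_j$ the $\log_{10}$ gene
length. The length covariate exists because longer genes are measured
with more power, so terms composed of long genes look enriched for
small p-values without any biology; the synthetic generator plants
exactly this situation (a term whose membership is logistic in gene
length, with a genome-wide length-proportional trait effect), and the
acceptance suite shows the term is wildly significant without $L$ and
size-controlled with it. Presentation keeps the top 20 terms per trait
and direction, merges duplicates at their best rank, and prunes a term
whose gene-set Jaccard overlap with a better-ranked kept term exceeds
0.5 (the external pruning procedure the source cites has no published
parameters, so ours is declared and configurable).

## cis-eQTL mapping

Expression is prepared by `latent_factor_adjust()`: inverse normal per
gene, residualization on known covariates, removal of the top-$K$
principal components of the residual matrix, and a final inverse normal
so every gene has standard-normal marginals. This is a deliberately
transparent stand-in for factor-analysis tools (PEER and kin, which are
external programs): the contract — remove broad unknown structure such
as batch and latent technical variation — is preserved and tested
(planted factors and batch drop below $R^2 = 0.01$ on the residuals).
$K$ is user-facing; large real cohorts commonly remove tens of factors
(the study this package models used 60), while the synthetic generator
plants only 3 latent factors plus batch, so the bundled pipeline and
experiments use $K$ of 10–15. The final inverse normal also makes the
per-pair t-test essentially exact under the null: the gene's values are
a random permutation of fixed normal scores, independent of dosage.

Mapping is per-pair simple regression $Y = \alpha + \beta G$ over all
variants within 1 Mb of the gene's most upstream TSS. "Most upstream" is
strand-aware (smallest coordinate on +, largest on −); the source text
says "most upstream" in one place and "most distal" in another, so the
anchor rule is a config override. Window bounds are inclusive on both
sides — unspecified, one choice had to be made. Variants with minor
allele count ≤ 5 or zero variance are skipped with a reason. LD pruning
is greedy per gene (keep lowest p, drop r² ≥ 0.2 with anything kept);
best-per-gene breaks p ties by genomic position.

Conditional analysis of a GWAS variant holds its dosage in the model
and forward-selects other cis variants while the best addition p-value
is below 0.0019 (a dataset-derived constant in the source, treated here
as a config default, not recomputed). The reported conditional p is the
Wald p of the GWAS variant in the final model; whether the source means
this or a drop-one comparison is ambiguous, and this reading is
documented as the implemented one. A selected variant in near-perfect
LD with the GWAS variant (r² > 0.99) flags the result non-identifiable.

## Allele-specific expression

Rows failing the mappability mask are removed before any statistics:
simulated read coverage outside [193, 202] (the band is tied to a
101-bp paired-end design and is a config value), ENCODE-style blacklist,
indel proximity, or fracRef outside (0.01, 0.99). A variant missing from
the mask is a hard error — silent pass-through would defeat the filter.
The read-mapping simulation that produces the simulated-coverage values
is consumed as input, not re-run; the synthetic generator assigns values
inside or outside the band directly.

Forward and reverse strand counts are merged per sample × variant before
estimation. The null fracRef is estimated per sample and ordered allele
pair (A→G and G→A differ, because reference-mapping bias does) as
$\sum \mathrm{ref} / \sum \mathrm{total}$ over the group's SNPs, after
down-sampling SNPs above the sample's 75th coverage percentile to 30
reads by a seeded hypergeometric draw — drawing reads without
replacement preserves the expectation while bounding any single
high-coverage SNP's leverage. The mechanism of the down-sampling is not
specified by the source; the hypergeometric draw is the natural
read-subsampling model. The thinned counts feed only the expectation,
never the per-SNP test.

The per-SNP test is the exact two-sided binomial test in its
minimum-likelihood form (sum of all point probabilities not exceeding
the observed one, with a $1+10^{-7}$ relative tolerance against
floating-point ties); the source says only "two-sided", so a central
(2 × min tail) alternative sits behind a flag. Variants tested in ≥ 10
samples (post-filter; pre- vs post-filter counting is unstated) get a
Fisher combination, $-2\sum\ln p \sim \chi^2_{2k}$. Storey q-values use
the λ grid 0.05–0.95 with cubic-spline smoothing and fall back to BH
below 100 p-values, where the $\pi_0$ estimate is too unstable.

## Enhancer classification and matched-null enrichment

Segmentations are BED 0-based half-open with an 11-state vocabulary;
contiguous enhancer-state bins merge into maximal runs; runs ≥ 3 kb are
stretch enhancers, ≤ 800 bp typical (both inclusive, as the definitions
are written), the remainder intermediate and excluded from both classes
by default (their treatment in the source's comparisons is unstated).
An interval is tissue-specific when at most 10% of its bases overlap
active chromatin in every other tissue supplied; the criterion is a
declared parameter because the source defers to an earlier definition
without parameterizing it.

Enrichment compares the number of test SNPs inside a feature set with
null SNP sets drawn from a universe annotated with MAF, distance to the
nearest TSS, and LD-neighbour count (r² ≥ 0.8 within 1 Mb). Each null
SNP must share its test SNP's three bins — MAF width 0.02, log₁₀ TSS
distance width 0.5, LD counts binned {0, 1–4, 5–19, 20–99, ≥ 100}; the
external matching tool the source used does not publish its binning, so
ours is declared and configurable. Pools below the minimum size widen
stepwise (doubled widths, then the LD bin dropped, then unbinned) and
error if still unmet. Null sets are drawn without replacement within a
set; fold is observed / mean-null and the empirical p is
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$, which is
super-uniform under the null by construction. A count-based fold with
an empirical p was chosen over reproducing the external tool's
parametric approximation: it is transparent and exactly testable.

## The synthetic-data generator

The generator's defaults are the study conditions the package is built
around: 267 samples (the genotyped subset of a 271-sample muscle
cohort), a 16-tissue reference panel, common variants (MAF 0.05–0.5) in
50-variant LD blocks, ~50× overdispersed allelic coverage, planted
standardized cis effects {0, 0.25, 0.5, 1}, planted ASE at fracRef 0.7,
and cis effects at 90% of genes (well-powered muscle studies detect
cis-eQTLs for over nine-tenths of expressed genes).

Genotypes come from a haplotype-copying model: within a block each
haplotype's latent uniform is copied from the previous variant with
probability `ld_decay` or redrawn, giving adjacent-variant correlation
equal to `ld_decay`, geometric decay with distance, and independence
across blocks. This is a caricature of real LD (no recombination
hotspots, no allele-frequency-dependent LD) but gives exactly the
controllable r² structure the pruning, neighbour-count and conditional
machinery need. Expression is generated directly on the transformed
scale with per-gene noise variance $1 - \beta^2\mathrm{var}(G)$, so a
planted $\beta$ is the standardized effect the mapper should recover
after adjustment; covariate, batch and latent-factor structure are
added on top and removed by the pipeline. Trait effects are planted by
`simulate_phenotypes()`, which draws phenotypes first and then shifts
the chosen genes' expression along the standardized trait (the
disease/trait labels do not exist earlier in the dependency order, so
the DE truth table is emitted here rather than by the expression
simulator).

Chromatin segmentations plant stretch enhancers over eQTL variants with
a per-decile placement rate that ramps linearly so the decile-10 fold
equals `target_fold` (default 3) and decile 1 sits at 1. The rates are
solved by fixed-point iteration against the *realized* universe-wide
stretch fraction — background plus planted mass — because the planted
intervals themselves raise the matched-null baseline; without this
correction a nominal 3× plants as ~2.7×. Typical enhancers are placed
uniformly and independently of eQTL status. One consequence worth
knowing: because stretch and typical intervals cannot overlap, variants
under planted stretch enhancers are unavailable to typical enhancers,
which induces a mild *negative* typical-enhancer trend across deciles.
The tests therefore assert the scientific claim — no increasing typical
trend — rather than |ρ| being small: for 10 noisy decile folds the null
probability of |Spearman ρ| < 0.5 is only ≈ 0.85 even for pure noise.

What the generator does not emulate: realistic human LD maps, read-level
sequences, isoform structure, population stratification, relatedness, or
cell-type heterogeneity. Passing tests therefore demonstrate that the
statistical machinery recovers planted truth under its own model
assumptions — they do not certify behaviour under real-data pathologies
(fine-scale LD, expression outliers, annotation errors).

## Numerical choices and degenerate inputs

Entropy uses $0\log 0 = 0$ and checks the simplex constraint to a
tolerance; the exact binomial test compares point probabilities with a
$1+10^{-7}$ relative tolerance; Fisher combination refuses p = 0 (cap
upstream at the smallest representable p); regression scans residualize
via QR and match `lm()` to 10⁻¹⁰ in the tests; zero-variance dosages,
all-zero panel rows, empty allele-pair groups and all-infinite Q vectors
all take defined non-exception paths (skip reasons, unscorable flags)
except where silence would be dangerous (unmasked ASE variants,
overlapping segmentation intervals: hard errors). All randomness —
tie-breaking, down-sampling, null-set draws, every simulator stage —
flows from explicit seeds, and stage seeds are derived from the master
seed through decoupled streams, so identical configurations are
byte-identical end to end.

## Problem sizes used by the bundled checks

The test suite and acceptance script size their experiments to the
study scale where the quantity demands it (267 samples, 2,000 genes,
20,000 variants for eQTL beta recovery; 2,000-pair power experiments;
200-replicate conditional scenarios) and to smaller grids where the
check is scale-free (determinism, format round-trips, oracle
comparisons). The enrichment recovery experiment uses 2,400 genes so
each decile carries ~200 test SNPs, keeping the per-decile fold's
sampling noise near 10%; KS uniformity of null eQTL p-values is
evaluated on one tested pair per null gene (≥ 1,000 genes), because the
marginal distribution is uniform but LD makes the full pair set far
from independent, which a naive KS test misreads.

## Known limitations

- The latent-factor adjustment is PCA-based; variance components that
  correlate strongly with the planted signal would be partially absorbed
  (mitigated by choosing $K$ modestly).
- The inverse normal transform shrinks large standardized effects
  slightly (a gene with $\beta = 1$ and common variant recovers ~0.95);
  the beta-recovery slope criterion brackets this.
- Matched-null enrichment requires an annotated universe large enough to
  fill the matching bins; small universes need `min_pool` lowered and
  rely on bin widening, which weakens the matching.
- The conditional analysis assumes the candidate set is the gene's cis
  window; signals outside the window (or trans) are invisible to it.
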