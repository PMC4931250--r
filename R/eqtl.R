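#' Latent-factor adjustment of an expression matrix
#'
#' Removes known covariates and broad unknown structure from expression
#' before eQTL mapping. Pipeline: per-gene inverse normal transform;
#' residualize on the covariate design; extract the top-K principal
#' components of the residual matrix (sample scores) and residualize on
#' covariates plus those components; per-gene inverse normal of the final
#' residuals, so every gene has standard-normal marginals. With K = 0 the
#' principal-component step vanishes and the result is plain
#' covariate-residualized (then renormalised) expression.
#'
#' The principal-component step is a transparent stand-in for richer
#' factor-analysis models: the contract here is only to remove broad
#' variance components (batch, unmodelled biology) that otherwise cost
#' eQTL power.
#'
#' @param expression sample x gene numeric matrix (FPKM-like or already
#'   transformed; only ranks matter for the first step).
#' @param covariates data.frame (age, sex, batch, genotype PCs, ...) or NULL.
#' @param K number of latent factors to remove; must be < n_samples.
#' @param seed tie-breaking seed for the inverse normal steps.
#' @param final_int apply the final inverse normal (default TRUE).
#' @return adjusted sample x gene matrix.
#' @export
latent_factor_adjust <- function(expression, covariates = NULL, K = 0L,
                                 seed = 1L, final_int = TRUE) {
  Y <- as.matrix(expression)
  n <- nrow(Y)
  check_that(K < n, "K (%d) must be smaller than the sample count (%d)", K, n)
  int_cols <- function(m, base_seed) {
    out <- vapply(seq_len(ncol(m)), function(j) {
      inverse_normal(m[, j], seed = derive_seed(base_seed, j))
    }, numeric(n))
    dimnames(out) <- dimnames(m)
    out
  }
  Y1 <- int_cols(Y, seed)
  R <- residualize(Y1, covariates)
  if (K > 0) {
    pcs <- prcomp(R, center = TRUE, scale. = FALSE, rank. = K)$x
    design <- if (is.null(covariates)) {
      as.data.frame(pcs)
    } else {
      cbind(as.data.frame(covariates), as.data.frame(pcs))
    }
    R <- residualize(Y1, design)
  }
  if (final_int) int_cols(as.matrix(R), seed + 7L) else {
    R <- as.matrix(R); dimnames(R) <- dimnames(Y); R
  }
}

#' Enumerate cis gene-variant pairs
#'
#' A variant is paired with a gene when it lies on the same chromosome
#' within `window_bp` of the gene's window anchor (the most upstream TSS:
#' smallest TSS coordinate on the + strand, largest on -). The window is
#' inclusive at both boundaries.
#'
#' @param genes data.frame: gene_id, chrom, strand ("+"/"-"), tss
#'   (comma-separated string or numeric for a single TSS).
#' @param variants data.frame: variant_id, chrom, pos (1-based).
#' @param window_bp window half-width in bp (default 1e6).
#' @param anchor "upstream" (default) or "downstream" most-distal override.
#' @return data.frame: gene_id, variant_id, tss_dist.
#' @export
cis_pairs <- function(genes, variants, window_bp = 1e6, anchor = "upstream") {
  anchor_pos <- vapply(seq_len(nrow(genes)), function(i) {
    tss <- genes$tss[i]
    tss <- if (is.character(tss)) as.numeric(strsplit(tss, ",")[[1]]) else as.numeric(tss)
    check_that(length(tss) >= 1 && !any(is.na(tss)), "gene %s has no TSS", genes$gene_id[i])
    plus <- genes$strand[i] == "+"
    if ((anchor == "upstream") == plus) min(tss) else max(tss)
  }, numeric(1))
  g <- data.table::data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                              anchor = anchor_pos)
  v <- data.table::data.table(variant_id = variants$variant_id,
                              chrom = variants$chrom, pos = variants$pos)
  merged <- merge(g, v, by = "chrom", allow.cartesian = TRUE)
  merged <- merged[abs(merged$pos - merged$anchor) <= window_bp]
  out <- data.frame(gene_id = merged$gene_id, variant_id = merged$variant_id,
                    tss_dist = merged$pos - merged$anchor,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$tss_dist), , drop = FALSE]
}

#' Map cis-eQTLs by per-pair simple regression
#'
#' For every (gene, variant) pair fits \eqn{Y_{ij} = \alpha + \beta_{js}
#' G_{is} + \epsilon} where G is the allele dosage in \[0,2\], with a
#' two-sided t-test on beta and FDR across all tested pairs. Variants
#' with minor allele count <= `mac_min` or zero dosage variance are
#' skipped (reported in the `skipped` attribute).
#'
#' @param Y sample x gene adjusted expression matrix (see
#'   [latent_factor_adjust()]).
#' @param G sample x variant dosage matrix.
#' @param pairs data.frame gene_id, variant_id from [cis_pairs()].
#' @param mac_min minimum minor allele count (pairs at or below are
#'   dropped; default 5).
#' @param fdr_method "BH" or "storey".
#' @return data.frame: gene_id, variant_id, beta, se, t, p, q, n.
#' @export
map_cis_eqtl <- function(Y, G, pairs, mac_min = 5, fdr_method = "BH") {
  Y <- as.matrix(Y); G <- as.matrix(G)
  n <- nrow(Y)
  check_that(nrow(G) == n, "Y and G disagree on samples")
  mac <- pmin(colSums(G), 2 * n - colSums(G))
  vvar <- apply(G, 2, var)
  usable <- mac > mac_min & vvar > 0
  keep <- pairs$variant_id %in% colnames(G)[usable] &
    pairs$gene_id %in% colnames(Y)
  skipped <- pairs[!keep, , drop = FALSE]
  pr <- pairs[keep, , drop = FALSE]
  check_that(nrow(pr) > 0, "no testable pairs after MAC/variance filters")
  # vectorise per gene: all cis variants of one gene against its expression
  res_list <- lapply(split(seq_len(nrow(pr)), pr$gene_id), function(idx) {
    gid <- pr$gene_id[idx[1]]
    vids <- pr$variant_id[idx]
    y <- Y[, gid]
    Gs <- G[, vids, drop = FALSE]
    yc <- y - mean(y)
    Gc <- sweep(Gs, 2, colMeans(Gs))
    sxx <- colSums(Gc^2)
    beta <- drop(crossprod(Gc, yc)) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    rss <- pmax(rss, 0)
    df <- n - 2L
    se <- sqrt(rss / df / sxx)
    tt <- beta / se
    data.frame(gene_id = gid, variant_id = vids, beta = beta, se = se,
               t = tt, p = 2 * pt(abs(tt), df, lower.tail = FALSE), n = n,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res_list)
  rownames(out) <- NULL
  out$q <- fdr_adjust(out$p, fdr_method)
  out <- out[, c("gene_id", "variant_id", "beta", "se", "t", "p", "q", "n")]
  attr(out, "skipped") <- skipped
  out
}

#' Squared LD between two dosage vectors
#'
#' Squared Pearson correlation of dosages; invariant to allele-coding
#' flips (2 - g). Returns NA when either vector has zero variance.
#'
#' @param g1,g2 dosage vectors over the same samples.
#' @return r-squared in \[0,1\], or NA.
#' @export
ld_r2 <- function(g1, g2) {
  if (var(g1) == 0 || var(g2) == 0) return(NA_real_)
  cor(g1, g2)^2
}

#' Greedy per-gene LD pruning of eQTL records
#'
#' Within each gene, repeatedly keep the record with the smallest p-value
#' and drop every remaining record whose variant has r2 >= `threshold`
#' with any kept variant. No kept pair within a gene exceeds the
#' threshold.
#'
#' @param records eQTL data.frame (gene_id, variant_id, p, ...).
#' @param G sample x variant dosage matrix covering all record variants.
#' @param threshold r2 threshold (default 0.2, i.e. prune at r2 >= 0.2).
#' @return pruned records (row subset of `records`).
#' @export
ld_prune_per_gene <- function(records, G, threshold = 0.2) {
  keep_rows <- unlist(lapply(split(seq_len(nrow(records)), records$gene_id),
                             function(idx) {
    sub <- records[idx, , drop = FALSE]
    ord <- order(sub$p, sub$variant_id)
    kept <- integer(0)
    for (i in ord) {
      gi <- G[, sub$variant_id[i]]
      clash <- any(vapply(kept, function(j) {
        r2 <- ld_r2(gi, G[, sub$variant_id[j]])
        !is.na(r2) && r2 >= threshold
      }, logical(1)))
      if (!clash) kept <- c(kept, i)
    }
    idx[kept]
  }))
  out <- records[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best (lowest-p) eQTL per gene
#'
#' Ties on p are broken by the smaller genomic position (requires a
#' `pos` column or a variant position lookup), then variant id.
#'
#' @param records eQTL data.frame with gene_id, variant_id, p.
#' @param variant_pos optional named vector of positions for tie-breaks.
#' @return one record per gene.
#' @export
best_per_gene <- function(records, variant_pos = NULL) {
  pos <- if (is.null(variant_pos)) rep(0, nrow(records)) else
    variant_pos[records$variant_id]
  ord <- order(records$gene_id, records$p, pos, records$variant_id)
  r <- records[ord, , drop = FALSE]
  out <- r[!duplicated(r$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative conditional analysis of a GWAS variant cis-eQTL
#'
#' Starts from a model of adjusted expression on the GWAS variant's
#' dosage, then forward-selects other cis variants: at each step the
#' candidate with the smallest addition p-value (t-test of the candidate
#' in the current model) joins the model if that p-value is below
#' `stop_p`; ties are broken by genomic position. The GWAS variant is
#' held in the model throughout and its Wald p in the final model is
#' reported as the conditional p-value. A selected variant in near-perfect
#' LD with the GWAS variant (r2 > 0.99) makes the conditional test
#' non-identifiable and is flagged.
#'
#' @param gwas_variant_id focal variant id (column of G).
#' @param gene_id gene id (column of Y).
#' @param Y sample x gene adjusted expression.
#' @param G sample x variant dosages; columns = the gene's cis variants
#'   (the focal variant must be among them).
#' @param variant_pos named position vector for tie-breaks.
#' @param stop_p forward-selection stopping threshold (default 0.0019).
#' @param max_steps safety cap on selected variants (default 20).
#' @return list: gwas_variant_id, gene_id, marginal_p, conditional_p,
#'   selected_covariate_variants, stopped_reason, non_identifiable.
#' @export
conditional_gwas_eqtl <- function(gwas_variant_id, gene_id, Y, G,
                                  variant_pos = NULL, stop_p = 0.0019,
                                  max_steps = 20L) {
  check_that(gwas_variant_id %in% colnames(G), "focal variant not in G")
  y <- Y[, gene_id]
  n <- length(y)
  g0 <- G[, gwas_variant_id]
  candidates <- setdiff(colnames(G), gwas_variant_id)
  pos <- if (is.null(variant_pos)) setNames(seq_along(candidates), candidates) else
    variant_pos
  wald_p <- function(design, col) {
    fit <- qr(design)
    df <- n - fit$rank
    cf <- qr.coef(fit, y)
    res <- qr.resid(fit, y)
    s2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(fit))
    se <- sqrt(s2 * diag(XtXinv))
    tt <- cf / se
    unname(2 * pt(abs(tt[col]), df, lower.tail = FALSE))
  }
  selected <- character(0)
  marginal_p <- NA_real_
  stopped_reason <- "no_candidate_below_stop_p"
  for (step in 0:max_steps) {
    design <- cbind(`(Intercept)` = 1, g0,
                    if (length(selected)) G[, selected, drop = FALSE])
    qrd <- qr(design)
    if (step == 0) marginal_p <- wald_p(design, 2L)
    if (step == max_steps) { stopped_reason <- "max_steps"; break }
    cand <- setdiff(candidates, selected)
    if (!length(cand)) { stopped_reason <- "candidates_exhausted"; break }
    # addition p-value for each candidate given the current model
    yr <- qr.resid(qrd, y)
    Cr <- qr.resid(qrd, G[, cand, drop = FALSE])
    sxx <- colSums(Cr^2)
    ok <- sxx > 1e-10
    if (!any(ok)) { stopped_reason <- "candidates_collinear"; break }
    beta <- drop(crossprod(Cr, yr)) / ifelse(ok, sxx, NA)
    df <- n - qrd$rank - 1L
    rss <- pmax(sum(yr^2) - beta^2 * sxx, 0)
    tt <- beta / sqrt(rss / df / sxx)
    pv <- 2 * pt(abs(tt), df, lower.tail = FALSE)
    pv[!ok] <- NA
    best <- order(pv, pos[cand], cand)[1]
    if (is.na(pv[best]) || pv[best] >= stop_p) break
    selected <- c(selected, cand[best])
  }
  design <- cbind(`(Intercept)` = 1, g0,
                  if (length(selected)) G[, selected, drop = FALSE])
  conditional_p <- wald_p(design, 2L)
  non_id <- length(selected) > 0 && any(vapply(selected, function(v) {
    r2 <- ld_r2(g0, G[, v]); !is.na(r2) && r2 > 0.99
  }, logical(1)))
  list(gwas_variant_id = gwas_variant_id, gene_id = gene_id,
       marginal_p = marginal_p, conditional_p = conditional_p,
       selected_covariate_variants = selected,
       stopped_reason = stopped_reason, non_identifiable = non_id)
}

#' Conditional analysis across many GWAS variant - gene pairs
#'
#' Runs [conditional_gwas_eqtl()] for each pair and computes marginal and
#' conditional q-values across the tested set.
#'
#' @param pairs data.frame: gwas_variant_id, gene_id.
#' @param Y,G as in [conditional_gwas_eqtl()]; G must hold every cis
#'   variant involved.
#' @param cis data.frame gene_id, variant_id limiting each gene's
#'   candidate set.
#' @param variant_pos named positions.
#' @param stop_p stopping threshold.
#' @return data.frame with marginal/conditional p and q per pair.
#' @export
conditional_scan <- function(pairs, Y, G, cis, variant_pos = NULL,
                             stop_p = 0.0019) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    gid <- pairs$gene_id[i]
    vset <- cis$variant_id[cis$gene_id == gid]
    vset <- union(vset, pairs$gwas_variant_id[i])
    r <- conditional_gwas_eqtl(pairs$gwas_variant_id[i], gid, Y,
                               G[, vset, drop = FALSE], variant_pos, stop_p)
    data.frame(gwas_variant_id = r$gwas_variant_id, gene_id = r$gene_id,
               marginal_p = r$marginal_p, conditional_p = r$conditional_p,
               n_selected = length(r$selected_covariate_variants),
               selected = paste(r$selected_covariate_variants, collapse = ","),
               stopped_reason = r$stopped_reason,
               non_identifiable = r$non_identifiable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$marginal_q <- p.adjust(out$marginal_p, "BH")
  out$conditional_q <- p.adjust(out$conditional_p, "BH")
  out
}
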