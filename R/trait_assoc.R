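#' Rank-based inverse normal transform
#'
#' Maps values to normal scores \eqn{\Phi^{-1}((r - c)/n)} where r is the
#' rank and c the offset (default 0.5). Ties are broken uniformly at random
#' under the supplied seed so repeated calls are reproducible; the transform
#' is strictly monotone over untied values and invariant to monotone
#' transformations of the input.
#'
#' @param values numeric vector, at least 2 finite values.
#' @param seed integer seed for random tie breaking.
#' @param offset rank offset c in (0, 1).
#' @return numeric vector of normal scores.
#' @export
inverse_normal <- function(values, seed = 1L, offset = 0.5) {
  ok <- is.finite(values)
  check_that(sum(ok) >= 2, "need at least 2 finite values")
  if (length(unique(values[ok])) == 1L) {
    warning("all values tied; inverse normal applies a random ordering")
  }
  out <- rep(NA_real_, length(values))
  r <- with_seed(seed, rank(values[ok], ties.method = "random"))
  out[ok] <- qnorm((r - offset) / sum(ok))
  out
}

# Build a full-rank model matrix from a covariate data.frame (factors are
# expanded with treatment contrasts). Errors name the collinear columns.
covariate_design <- function(covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(NULL)
  }
  covariates <- as.data.frame(covariates)
  mm <- stats::model.matrix(~., data = covariates)
  qrd <- qr(mm)
  if (qrd$rank < ncol(mm)) {
    drop <- colnames(mm)[qrd$pivot[(qrd$rank + 1):ncol(mm)]]
    stopf("rank-deficient covariate design; collinear columns: %s",
          paste(drop, collapse = ", "))
  }
  mm
}

#' Residualize values on covariates
#'
#' Ordinary least-squares residuals of `values` on an intercept plus the
#' covariate columns (factors expanded). Residuals are orthogonal to every
#' design column.
#'
#' @param values numeric vector or matrix (rows = samples).
#' @param covariates data.frame of covariates, or NULL (then values are
#'   centred only).
#' @return residuals, same shape as `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  mm <- covariate_design(covariates)
  if (is.null(mm)) {
    res <- sweep(v, 2, colMeans(v))
  } else {
    check_that(nrow(mm) == nrow(v), "covariates and values disagree on samples")
    res <- qr.resid(qr(mm), v)
  }
  if (is.null(dim(values))) drop(res) else res
}

# Per-gene OLS of y on a focal predictor plus covariates, vectorised over
# genes via the Frisch-Waugh theorem: residualize both sides on the
# covariate design, then simple regression with dof = n - p_cov - 1.
ols_scan <- function(Y, x, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  mm <- covariate_design(covariates)
  p_cov <- if (is.null(mm)) 1L else ncol(mm)   # intercept included
  if (is.null(mm)) mm <- matrix(1, n, 1)
  qrd <- qr(mm)
  xr <- qr.resid(qrd, x)
  Yr <- qr.resid(qrd, Y)
  sxx <- sum(xr^2)
  check_that(sxx > 0, "focal predictor has zero residual variance")
  beta <- drop(crossprod(Yr, xr)) / sxx
  df <- n - p_cov - 1L
  rss <- colSums(Yr^2) - beta^2 * sxx
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(beta = beta, se = se, t = tstat, p = p, df = df,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binary-trait (T2D) gene expression association
#'
#' For each gene j fits \eqn{Y_{ij} = \alpha_j + \beta_j T_i + \gamma_j' Z_i
#' + \epsilon_{ij}} by OLS, where Y is inverse-normalised expression, T is
#' disease status (0/1) and Z the covariates (age, sex, batch by default).
#' Two-sided t-test p-values; q-values across genes.
#'
#' @param Y sample x gene matrix of transformed expression.
#' @param trait 0/1 vector.
#' @param covariates data.frame of covariates or NULL.
#' @param fdr_method "BH" (default) or "storey".
#' @return data.frame: gene_id, beta, se, t, p, q.
#' @export
t2d_association <- function(Y, trait, covariates = NULL, fdr_method = "BH") {
  check_that(all(trait %in% c(0, 1)), "trait must be coded 0/1")
  check_that(length(unique(trait)) == 2, "both trait classes must be present")
  res <- ols_scan(Y, as.numeric(trait), covariates)
  res$gene_id <- colnames(Y) %||% paste0("gene", seq_len(ncol(Y)))
  res$q <- fdr_adjust(res$p, method = fdr_method)
  res[, c("gene_id", "beta", "se", "t", "p", "q")]
}

#' Quantitative trait - gene expression association
#'
#' Simple regression of doubly-transformed expression on a
#' doubly-transformed quantitative trait (both sides already put through
#' inverse normal -> covariate residualization -> inverse normal; see
#' [transform_quantitative()]).
#'
#' @param Y sample x gene matrix of transformed expression.
#' @param x transformed trait vector.
#' @param fdr_method "BH" or "storey".
#' @return data.frame: gene_id, beta, se, t, p, q.
#' @export
quant_trait_association <- function(Y, x, fdr_method = "BH") {
  check_that(length(x) >= 10, "need at least 10 samples (got %d)", length(x))
  res <- ols_scan(Y, as.numeric(x), covariates = NULL)
  res$gene_id <- colnames(Y) %||% paste0("gene", seq_len(ncol(Y)))
  res$q <- fdr_adjust(res$p, method = fdr_method)
  res[, c("gene_id", "beta", "se", "t", "p", "q")]
}

#' The double transform used for quantitative traits and expression
#'
#' inverse normal -> residualize on covariates -> inverse normal.
#'
#' @param values numeric vector or sample x feature matrix.
#' @param covariates data.frame (e.g. age, sex, batch) or NULL.
#' @param seed tie-breaking seed.
#' @return transformed values, same shape.
#' @export
transform_quantitative <- function(values, covariates = NULL, seed = 1L) {
  v <- as.matrix(values)
  apply_int <- function(m, base_seed) {
    vapply(seq_len(ncol(m)), function(j) {
      inverse_normal(m[, j], seed = derive_seed(base_seed, j))
    }, numeric(nrow(m)))
  }
  t1 <- apply_int(v, seed)
  t2 <- residualize(t1, covariates)
  t3 <- apply_int(as.matrix(t2), seed + 1L)
  dimnames(t3) <- dimnames(v)
  if (is.null(dim(values))) drop(t3) else t3
}

fdr_adjust <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (method == "BH") p.adjust(p, "BH") else storey_qvalue(p)
}

#' Signed-log-p GO term enrichment (logistic model)
#'
#' For each gene set (GO term) fits the logistic regression
#' \eqn{logit(\pi_j) = \alpha + \beta P_j + \gamma L_j} where \eqn{\pi_j}
#' is the probability of term membership for gene j, \eqn{P_j} the signed
#' -log10 association p-value (positive when higher expression goes with
#' the trait) and \eqn{L_j} the log10 gene length. The length covariate
#' absorbs the confounding of power with gene length; it can be disabled
#' for comparison.
#'
#' @param signed_logp named numeric vector per gene.
#' @param log10_length named numeric vector per gene (same genes).
#' @param memberships data.frame with columns term_id, gene_id.
#' @param min_genes minimum term size tested (default 5).
#' @param length_adjust include the gene-length covariate (default TRUE).
#' @return data.frame: term_id, beta_enrich, gamma_length, intercept, p, q,
#'   n_genes, direction.
#' @export
go_enrichment <- function(signed_logp, log10_length, memberships,
                          min_genes = 5L, length_adjust = TRUE) {
  genes <- names(signed_logp)
  check_that(!is.null(genes), "signed_logp must be named by gene id")
  check_that(identical(sort(genes), sort(names(log10_length))),
             "signed_logp and log10_length must cover the same genes")
  L <- log10_length[genes]
  terms <- split(memberships$gene_id, memberships$term_id)
  rows <- lapply(names(terms), function(tid) {
    memb <- as.integer(genes %in% terms[[tid]])
    ng <- sum(memb)
    if (ng < min_genes || ng == length(genes)) {
      return(NULL)   # degenerate term: all genes or below minimum
    }
    fit <- if (length_adjust) {
      suppressWarnings(glm(memb ~ signed_logp + L, family = binomial()))
    } else {
      suppressWarnings(glm(memb ~ signed_logp, family = binomial()))
    }
    cf <- summary(fit)$coefficients
    data.frame(
      term_id = tid,
      beta_enrich = cf["signed_logp", "Estimate"],
      gamma_length = if (length_adjust) cf["L", "Estimate"] else NA_real_,
      intercept = cf["(Intercept)", "Estimate"],
      p = cf["signed_logp", "Pr(>|z|)"],
      n_genes = ng,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  check_that(!is.null(out), "no testable terms (all below min_genes?)")
  out$q <- p.adjust(out$p, "BH")
  out$direction <- ifelse(out$beta_enrich >= 0, "+", "-")
  out[, c("term_id", "beta_enrich", "gamma_length", "intercept", "p", "q",
          "n_genes", "direction")]
}

#' Rank, merge and prune GO term results for presentation
#'
#' Per trait and direction of enrichment, keeps the top-k terms by p-value
#' and ranks them 1..k; lists are then combined, a term appearing more than
#' once keeping its lowest (best) rank. Finally redundant terms are pruned:
#' a term whose gene-set Jaccard overlap with a better-ranked kept term
#' exceeds `jaccard_max` is dropped.
#'
#' @param results named list of GoTermResult data.frames, one per trait.
#' @param memberships data.frame term_id, gene_id (for overlap computation).
#' @param k top terms kept per trait x direction (default 20).
#' @param jaccard_max redundancy threshold (default 0.5).
#' @return data.frame: term_id, rank, traits (comma-joined), direction.
#' @export
present_go_terms <- function(results, memberships, k = 20L, jaccard_max = 0.5) {
  term_genes <- split(memberships$gene_id, memberships$term_id)
  picked <- list()
  for (trait in names(results)) {
    res <- results[[trait]]
    for (dir in c("+", "-")) {
      sub <- res[res$direction == dir, , drop = FALSE]
      sub <- sub[order(sub$p), , drop = FALSE]
      sub <- head(sub, k)
      if (nrow(sub) == 0) next
      picked[[length(picked) + 1L]] <- data.frame(
        term_id = sub$term_id, rank = seq_len(nrow(sub)),
        trait = trait, direction = dir, stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, picked)
  if (is.null(all)) {
    return(data.frame(term_id = character(), rank = integer(),
                      traits = character(), direction = character()))
  }
  agg <- stats::aggregate(rank ~ term_id, data = all, FUN = min)
  agg$traits <- vapply(agg$term_id, function(t) {
    paste(sort(unique(all$trait[all$term_id == t])), collapse = ",")
  }, character(1))
  agg$direction <- vapply(agg$term_id, function(t) {
    all$direction[all$term_id == t][which.min(all$rank[all$term_id == t])]
  }, character(1))
  agg <- agg[order(agg$rank, agg$term_id), , drop = FALSE]
  kept <- character(0)
  keep_row <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    gi <- term_genes[[agg$term_id[i]]]
    redundant <- any(vapply(kept, function(kt) {
      gk <- term_genes[[kt]]
      length(intersect(gi, gk)) / length(union(gi, gk)) > jaccard_max
    }, logical(1)))
    keep_row[i] <- !redundant
    if (!redundant) kept <- c(kept, agg$term_id[i])
  }
  out <- agg[keep_row, c("term_id", "rank", "traits", "direction")]
  rownames(out) <- NULL
  out
}
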