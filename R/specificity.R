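#' Relative expression across a tissue panel
#'
#' Converts a gene x tissue expression matrix (FPKM-like, non-negative) into
#' per-gene tissue proportions \eqn{p_{g,t} = x_{g,t} / \sum_t x_{g,t}}.
#' Genes whose whole row is zero cannot be normalised and are flagged
#' unscorable rather than raising an error.
#'
#' @param x numeric matrix, genes in rows, tissues in columns; row and column
#'   names required. All values must be >= 0.
#' @return list with `p` (proportions matrix, rows summing to 1 for scorable
#'   genes, `NA` rows otherwise) and `scorable` (named logical).
#' @export
relative_expression <- function(x) {
  check_that(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  check_that(!is.null(rownames(x)) && !is.null(colnames(x)),
             "x must have gene rownames and tissue colnames")
  check_that(all(x >= 0, na.rm = TRUE), "expression values must be non-negative")
  tot <- rowSums(x)
  scorable <- tot > 0
  p <- x / tot
  p[!scorable, ] <- NA_real_
  list(p = p, scorable = setNames(scorable, rownames(x)))
}

#' Shannon entropy of an expression profile, in bits
#'
#' \eqn{H = -\sum_t p_t \log_2 p_t} with the convention
#' \eqn{0 \cdot \log_2 0 = 0}. For a gene expressed uniformly across
#' \eqn{T} tissues, \eqn{H = \log_2 T}; for a point mass, \eqn{H = 0}.
#'
#' @param p_row numeric vector of proportions summing to 1.
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in bits.
#' @export
entropy_bits <- function(p_row, tol = 1e-8) {
  check_that(all(p_row >= 0), "proportions must be non-negative")
  check_that(abs(sum(p_row) - 1) <= tol,
             "proportions must sum to 1 (got %.12f)", sum(p_row))
  nz <- p_row[p_row > 0]
  -sum(nz * log2(nz))
}

#' Target-tissue expression specificity Q
#'
#' \eqn{Q = H - \log_2 p_{target}}, in bits. Q is 0 exactly when all
#' expression falls in the target tissue (H = 0, p = 1) and grows as
#' expression becomes less abundant in, or less specific to, the target.
#' A gene with zero target-tissue expression gets `Inf` (it is maximally
#' non-specific; downstream it maps to a specificity index of 0).
#'
#' @param H entropy in bits.
#' @param p_target target-tissue proportion in \[0, 1\].
#' @return Q in bits (possibly `Inf`).
#' @export
specificity_q <- function(H, p_target) {
  check_that(all(p_target >= 0 & p_target <= 1), "p_target must lie in [0,1]")
  ifelse(p_target == 0, Inf, H - log2(p_target))
}

#' Expression specificity index from Q values
#'
#' Rescales Q to \eqn{1 - Q / \max Q} over finite Q, so the most
#' target-specific gene(s) (minimal Q) score near 1 and ubiquitous or
#' silent genes score near 0. Infinite-Q genes (no target expression)
#' are assigned 0.
#'
#' @param q_values numeric vector of per-gene Q (bits), `Inf` allowed.
#' @return numeric vector in \[0, 1\].
#' @export
mesi <- function(q_values) {
  finite <- is.finite(q_values)
  check_that(any(finite), "all Q values are infinite; nothing to score")
  qmax <- max(q_values[finite])
  out <- ifelse(finite, 1 - q_values / qmax, 0)
  pmin(pmax(out, 0), 1)
}

#' Equal-count decile assignment
#'
#' Rank-based binning of specificity scores into deciles 1..10; decile 10
#' holds the highest scores. Bin sizes differ by at most one. Ties are
#' broken by a stable sort on gene id so assignment is reproducible.
#'
#' @param mesi_values named numeric vector (names = gene ids).
#' @return named integer vector of deciles.
#' @export
assign_deciles <- function(mesi_values) {
  n <- length(mesi_values)
  check_that(n >= 10, "need at least 10 scorable genes for deciles (got %d)", n)
  check_that(!is.null(names(mesi_values)), "mesi_values must be named by gene id")
  ord <- order(mesi_values, names(mesi_values))
  # bins sized floor/ceil(n/10), lowest scores -> decile 1
  sizes <- rep(n %/% 10, 10) + c(rep(0, 10 - n %% 10), rep(1, n %% 10))
  dec <- rep(seq_len(10), times = sizes)
  out <- integer(n)
  out[ord] <- dec
  setNames(out, names(mesi_values))
}

#' Score target-tissue expression specificity for a whole panel
#'
#' Runs the full specificity pipeline: tissue proportions, entropy (bits),
#' Q, the specificity index in \[0,1\], and decile assignment. Genes with
#' all-zero rows are kept with `scorable = FALSE` and NA scores.
#'
#' @param panel gene x tissue numeric matrix (FPKM-like), named dims.
#' @param target_tissue column name of the target tissue.
#' @return data.frame: gene_id, p_target, H_bits, Q_bits, mesi, decile,
#'   scorable.
#' @export
mesi_scores <- function(panel, target_tissue) {
  check_that(target_tissue %in% colnames(panel),
             "target tissue '%s' not in panel", target_tissue)
  rel <- relative_expression(panel)
  p <- rel$p
  scorable <- rel$scorable
  H <- rep(NA_real_, nrow(panel))
  H[scorable] <- apply(p[scorable, , drop = FALSE], 1, entropy_bits)
  p_t <- p[, target_tissue]
  Q <- rep(NA_real_, nrow(panel))
  Q[scorable] <- specificity_q(H[scorable], p_t[scorable])
  m <- rep(NA_real_, nrow(panel))
  m[scorable] <- mesi(Q[scorable])
  dec <- rep(NA_integer_, nrow(panel))
  if (sum(scorable) >= 10) {
    dec[scorable] <- assign_deciles(setNames(m[scorable], rownames(panel)[scorable]))
  }
  data.frame(
    gene_id = rownames(panel),
    p_target = unname(p_t),
    H_bits = H,
    Q_bits = Q,
    mesi = m,
    decile = dec,
    scorable = unname(scorable),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
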