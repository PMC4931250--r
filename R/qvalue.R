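#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 with
#' cubic smoothing-spline extrapolation at lambda = max(grid), then
#' computes step-down q-values q(i) = min_{j >= i} pi0 * m * p(j) / j.
#' With fewer than `min_m` p-values the pi0 estimate is too unstable and
#' Benjamini-Hochberg is used instead (pi0 = 1).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param lambda grid for pi0 estimation.
#' @param min_m below this count fall back to BH.
#' @return q-values, same length/order as `p`; the estimated pi0 is
#'   attached as attribute `pi0` (1 under the BH fallback).
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05), min_m = 100L) {
  check_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  ok <- !is.na(p)
  m <- sum(ok)
  check_that(m >= 1, "need at least one p-value")
  if (m < min_m) {
    out <- rep(NA_real_, length(p))
    out[ok] <- p.adjust(p[ok], "BH")
    attr(out, "pi0") <- 1
    return(out)
  }
  pv <- p[ok]
  pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
  # smooth and take the estimate at the largest lambda (Storey 2003)
  sp <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(sp, x = max(lambda))$y
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pv[o] / (m - seq_len(m) + 1)))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}
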