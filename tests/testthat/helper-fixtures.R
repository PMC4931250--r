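# Small fixtures shared across test files. Everything is generated in
# code; sizes are kept small so the whole suite stays fast.

small_config <- function(seed = 1L, ...) {
  args <- list(n_samples = 80L, n_genes = 120L, n_variants = 600L,
               n_ase_variants = 100L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# independent high-precision entropy oracle (log-space, base 2)
oracle_entropy <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * (log(x) / log(2))
  s
}

# brute-force exact two-sided binomial p via log-pmf enumeration,
# written independently of the package implementation
oracle_binom_two_sided <- function(k, n, p0) {
  lp <- lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log1p(-p0)
  sum(exp(lp[lp <= lp[k + 1] + 1e-9]))
}

# random simplex vector
rsimplex <- function(k) {
  x <- rexp(k)
  x / sum(x)
}
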