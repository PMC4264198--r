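# shared fixtures and independent oracles, built in code at test time

small_sim <- function(seed = 11, ...) {
  simulate_all(sim_config(n_genes = 40, frac_ase = 0.2,
                          frac_imprinted_maternal = 0.1,
                          mean_snp_depth = 150, seed = seed, ...))
}

# bias table for classify_snps() straight from an allelic-count table
bias_table <- function(counts, cross) {
  cr <- hybridASE:::reciprocal_pair(cross)
  do.call(rbind, lapply(cr$hybrid_id, function(h) {
    x <- counts[counts$sample_id == h, , drop = FALSE]
    cbind(snp_id = x$snp_id, hybrid_id = h,
          allelic_bias_test(x$n_allele1, x$n_allele2))
  }))
}

# --- independent oracles ------------------------------------------------

# NB exact test by direct enumeration on the probability scale (no
# log-space tricks, no shared code path beyond dnbinom itself)
oracle_nb_exact <- function(kA, kB, sfA, sfB, model) {
  kS <- kA + kB
  if (kS == 0) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  q0 <- kS / (sA + sB)
  v <- model$raw_variance(q0)
  pmf <- function(k, mu, var) {
    if (var > mu) dnbinom(k, mu = mu, size = mu^2 / (var - mu))
    else dpois(k, mu)
  }
  pa <- vapply(0:kS, function(a)
    pmf(a, q0 * sA, q0 * sA + v * sum(sfA^2)) *
      pmf(kS - a, q0 * sB, q0 * sB + v * sum(sfB^2)), 0)
  pobs <- pa[kA + 1]
  min(1, sum(pa[pa <= pobs]) / sum(pa))
}

# hypergeometric upper tail by choose() enumeration
oracle_hyper_over <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
}
oracle_hyper_under <- function(k, K, N, n) {
  sum(vapply(0:k, function(i)
    choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
}

# median-of-ratios, brute force
oracle_size_factors <- function(m) {
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- gm > 0 & is.finite(gm)
  apply(m, 2, function(col) median(col[ok] / gm[ok]))
}
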