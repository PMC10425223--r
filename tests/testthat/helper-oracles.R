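# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_wilcoxon_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating the hypergeometric
# support and summing probabilities <= that of the observed table.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# One-sided hypergeometric over-representation p by direct summation.
oracle_hyper_p <- function(k, category, draw, universe) {
  kk <- k:min(category, draw)
  sum(choose(category, kk) * choose(universe - category, draw - kk)) /
    choose(universe, draw)
}

# Direct-formula log2 ratio of geometric means (independent of
# dysbiosis_score internals).
oracle_di <- function(table, enriched, depleted, pc) {
  apply(table, 1, function(r) {
    ge <- prod(r[enriched] + pc)^(1 / length(enriched))
    gd <- prod(r[depleted] + pc)^(1 / length(depleted))
    log2(ge / gd)
  })
}

# Adjusted Rand index between two label vectors.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Small relative-abundance fixture with lineage labels.
toy_table <- function(n = 6, m = 5, seed = 42) {
  set.seed(seed)
  x <- matrix(stats::rexp(n * m), n, m,
              dimnames = list(paste0("s", seq_len(n)),
                              sprintf("g__Genus%d|s__Genus%d_sp", seq_len(m),
                                      seq_len(m))))
  x / rowSums(x)
}

small_sim <- function(seed = 1, ...) {
  defaults <- list(n_cases = 40, n_controls = 50, n_features = 60,
                   n_enriched = 8, n_depleted = 4, n_gene_families = 300,
                   n_diff_gene_families = 120, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
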