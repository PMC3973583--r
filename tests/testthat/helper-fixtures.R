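# Shared fixtures built in code.

# small study-shaped config (fast); the full-size default config is only
# used by the acceptance checks
small_config <- function(seed = 1, n_genes = 600, n_de = 30,
                         noise_cv = 0.2, n_cluster = 10) {
  simulation_config(seed = seed, n_genes = n_genes, n_de_genes = n_de,
                    noise_cv = noise_cv,
                    cluster_spec = list(arm = "3L", start = 8.5e6,
                                        width = 5e5, n_genes = n_cluster))
}

# tiny expression matrix with hand-chosen values; groups a (2) and b (2)
tiny_expr <- function() {
  m <- rbind(g1 = c(10, 10, 40, 40),
             g2 = c(40, 40, 10, 10),
             g3 = c(10, 10, 10, 10))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  m
}
tiny_groups <- c("a", "a", "b", "b")

# brute-force binomial upper tail by direct summation of the pmf
brute_binomial_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# brute-force hypergeometric upper tail by enumerating all C(N, n) draws
enum_hypergeom_tail <- function(k, n, M, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= k)  # items 1..M are the annotated ones
}

# hypergeometric upper tail by direct summation of the pmf via lchoose
sum_hypergeom_tail <- function(k, n, M, N) {
  hi <- min(n, M)
  if (k > hi) return(0)
  j <- k:hi
  sum(exp(lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)))
}

# explicit min-over-suffix BH construction
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    pi <- p[i]
    cand <- vapply(seq_len(m), function(j) {
      pj <- p[ord[j]]
      if (pj >= pi) pj * m / j else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}
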