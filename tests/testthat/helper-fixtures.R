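# Shared fixtures and independent oracles used across the suite.

# small but non-trivial count matrix with named genes/samples
tiny_counts <- function(seed = 42, n_genes = 60, n_samples = 8) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 200, size = 10),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m, rep(c("tumour", "normal"), length.out = n_samples))
}

# independent TMM oracle: straightforward trimmed weighted mean of
# M-values against a given reference column, no library-size bookkeeping
# beyond the definition itself
oracle_tmm_factor <- function(m, j, ref, logratio_trim = 0.3,
                              sum_trim = 0.05) {
  lib <- colSums(m)
  p_j <- m[, j] / lib[j]
  p_r <- m[, ref] / lib[ref]
  keep <- m[, j] > 0 & m[, ref] > 0
  M <- log2(p_j[keep] / p_r[keep])
  A <- (log2(p_j[keep]) + log2(p_r[keep])) / 2
  w <- (lib[j] - m[keep, j]) / (lib[j] * m[keep, j]) +
    (lib[ref] - m[keep, ref]) / (lib[ref] * m[keep, ref])
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# independent hypergeometric upper-tail oracle by full enumeration with
# binomial coefficients (no distribution function calls)
oracle_hyper_upper <- function(k, K, n, N) {
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= k])
}

# hand product-limit estimator
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_i <- sum(times >= ut[i])
    d_i <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}
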