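# Independent oracles, deliberately implemented by direct enumeration from
# first principles (lchoose / PMF sums), never via the code paths they check.

# P(X >= n_alt) for the 2x2 table [[n_alt, N-n_alt], [E, N-E]] under the
# hypergeometric null of its margins: X counts first-column successes in the
# first row. Enumerates the (at most E+1) upper-tail PMF terms directly.
oracle_fisher_tail <- function(n_alt, N, E) {
  K <- n_alt + E            # first-column margin
  total <- 2L * N
  ks <- seq.int(n_alt, min(N, K))
  sum(exp(lchoose(K, ks) + lchoose(total - K, N - ks) - lchoose(total, N)))
}

# two-sided exact binomial p by PMF enumeration (sum of outcomes no more
# likely than the observed one)
oracle_binom_two_sided <- function(x, n, p) {
  pmf <- exp(lchoose(n, 0:n) + (0:n) * log(p) + (n - (0:n)) * log(1 - p))
  obs <- pmf[x + 1]
  sum(pmf[pmf <= obs * (1 + 1e-9)])
}

# two-sided Fisher's exact p for [[a, b], [c, d]] by hypergeometric PMF
# enumeration with the same no-more-likely rule
oracle_fisher_two_sided <- function(a, b, c, d) {
  K <- a + c; total <- a + b + c + d; n1 <- a + b
  ks <- max(0, K - (total - n1)):min(n1, K)
  pmf <- exp(lchoose(K, ks) + lchoose(total - K, n1 - ks) - lchoose(total, n1))
  obs <- pmf[ks == a]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# exhaustive phasing oracle: minimal summed min-distance over all per-site
# allele assignments, computed with plain loops over reads and sites
oracle_phase_objective <- function(mat, ref, alt) {
  k <- ncol(mat)
  best <- Inf
  for (code in 0:(2^k - 1)) {
    a <- as.integer(intToBits(code)[1:k])
    h0 <- ifelse(a == 0, ref, alt)
    h1 <- ifelse(a == 0, alt, ref)
    tot <- 0
    for (r in seq_len(nrow(mat))) {
      d0 <- 0; d1 <- 0
      for (s in seq_len(k)) {
        b <- mat[r, s]
        if (is.na(b)) next
        if (b != h0[s]) d0 <- d0 + 1
        if (b != h1[s]) d1 <- d1 + 1
      }
      tot <- tot + min(d0, d1)
    }
    if (tot < best) best <- tot
  }
  best
}

# step-by-step Fleiss kappa evaluation, written out longhand
oracle_fleiss <- function(t) {
  t <- as.matrix(t)
  n <- nrow(t); r <- ncol(t)
  cats <- unique(as.vector(t))
  nij <- matrix(0, n, length(cats))
  for (i in seq_len(n)) for (j in seq_len(r))
    nij[i, match(t[i, j], cats)] <- nij[i, match(t[i, j], cats)] + 1
  Pi <- numeric(n)
  for (i in seq_len(n)) Pi[i] <- (sum(nij[i, ]^2) - r) / (r * (r - 1))
  Pbar <- sum(Pi) / n
  pj <- colSums(nij) / (n * r)
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}
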