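# Independent brute-force oracles used to pin down the estimators.
# Each oracle is written against the defining formula directly, with no
# shared code with the implementation under test.

# histogram plug-in TE by explicit triple loop over all Q^3 cells
oracle_fixed_bin <- function(target, target_past, source_past, n, Q) {
  edges <- seq(1, n, length.out = Q + 1)
  binof <- function(v) {
    b <- rep(NA_integer_, length(v))
    for (i in seq_along(v)) {
      for (q in seq_len(Q)) {
        hi_ok <- if (q == Q) v[i] <= edges[q + 1] else v[i] < edges[q + 1]
        if (v[i] >= edges[q] && hi_ok) { b[i] <- q; break }
      }
    }
    b
  }
  a <- binof(target); b <- binof(target_past); cc <- binof(source_past)
  P <- length(a)
  te <- 0
  for (qa in 1:Q) for (qb in 1:Q) for (qc in 1:Q) {
    m_abc <- sum(a == qa & b == qb & cc == qc)
    if (m_abc == 0) next
    m_b <- sum(b == qb)
    m_ab <- sum(a == qa & b == qb)
    m_bc <- sum(b == qb & cc == qc)
    te <- te + m_abc / P * log2(m_abc * m_b / (m_bc * m_ab))
  }
  te
}

# same histogram, but via the conditional-entropy decomposition
# H(target | target_past) - H(target | target_past, source_past)
oracle_entropy_difference <- function(target, target_past, source_past, n, Q) {
  edges <- seq(1, n, length.out = Q + 1)
  binof <- function(v) pmin(pmax(findInterval(v, edges,
                                              rightmost.closed = TRUE), 1), Q)
  a <- binof(target); b <- binof(target_past); cc <- binof(source_past)
  P <- length(a)
  H <- function(labels) {
    p <- table(labels) / P
    -sum(p * log2(p))
  }
  H_ab <- H(paste(a, b))
  H_b <- H(b)
  H_abc <- H(paste(a, b, cc))
  H_bc <- H(paste(b, cc))
  (H_ab - H_b) - (H_abc - H_bc)
}

# resubstitution KDE TE by explicit double loops over points and kernels
oracle_kde <- function(target, target_past, source_past, alpha) {
  P <- length(target)
  gauss <- function(u) exp(-0.5 * u^2) / sqrt(2 * pi)
  h <- function(v) 1.06 * alpha * sd(v) * P^(-1 / 5)
  ht <- h(target); hp <- h(target_past); hs <- h(source_past)
  te <- 0
  for (i in seq_len(P)) {
    p3 <- p1 <- p2a <- p2b <- 0
    for (j in seq_len(P)) {
      kt <- gauss((target[i] - target[j]) / ht) / ht
      kp <- gauss((target_past[i] - target_past[j]) / hp) / hp
      ks <- gauss((source_past[i] - source_past[j]) / hs) / hs
      p3 <- p3 + kt * kp * ks
      p1 <- p1 + kp
      p2a <- p2a + kp * ks
      p2b <- p2b + kt * kp
    }
    te <- te + log2((p3 / P) * (p1 / P) / ((p2a / P) * (p2b / P)))
  }
  te / P
}

# TE from a list of boxes by direct counting over the point cloud
oracle_dv_te <- function(boxes, target, target_past, source_past) {
  P <- length(target)
  te <- 0
  for (bx in boxes) {
    n_k <- sum(target >= bx$target[1] & target < bx$target[2] &
                 target_past >= bx$tpast[1] & target_past < bx$tpast[2] &
                 source_past >= bx$source[1] & source_past < bx$source[2])
    if (n_k == 0) next
    n_tp <- sum(target_past >= bx$tpast[1] & target_past < bx$tpast[2])
    n_tp_s <- sum(target_past >= bx$tpast[1] & target_past < bx$tpast[2] &
                    source_past >= bx$source[1] & source_past < bx$source[2])
    n_t_tp <- sum(target >= bx$target[1] & target < bx$target[2] &
                    target_past >= bx$tpast[1] & target_past < bx$tpast[2])
    te <- te + n_k / P * log2(n_k * n_tp / (n_tp_s * n_t_tp))
  }
  te
}

# exact one-sided rank-sum p-value by enumerating all group assignments
oracle_ranksum_exact <- function(low, high) {
  pooled <- c(low, high)
  n <- length(pooled)
  idx <- utils::combn(n, length(high))
  obs <- sum(rank(pooled)[seq_along(high) + length(low)])
  stat <- apply(idx, 2, function(k) sum(rank(pooled)[k]))
  mean(stat >= obs)
}

# exact one-sided signed-rank p-value by enumerating all 2^n sign flips
oracle_signedrank_exact <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  stat <- as.matrix(signs) %*% r
  mean(stat >= obs)
}

# deterministic coupled pair for tests that need clear directed coupling
coupled_pair <- function(n, lag = 2, noise = 0.1, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- c(rnorm(lag, sd = noise), head(x, n - lag)^2 + rnorm(n - lag, sd = noise))
    list(x = x, y = y)
  })
}
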