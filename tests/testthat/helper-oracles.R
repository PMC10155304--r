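# Joint-state enumeration oracle: expectations of v_m h_j under the model
# and under the data-clamped conditional, computed from unnormalized joint
# probabilities exp(b.v + c.h + h'Wv) without the sigmoid factorization.
enum_gradient <- function(W, b, cc, X) {
  K <- nrow(W); M <- ncol(W)
  vs <- as.matrix(expand.grid(rep(list(0:1), M)))
  hs <- as.matrix(expand.grid(rep(list(0:1), K)))
  joint <- matrix(0, nrow(vs), nrow(hs))
  for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(hs))) {
    v <- vs[i, ]; h <- hs[j, ]
    joint[i, j] <- exp(sum(b * v) + sum(cc * h) + as.numeric(t(h) %*% W %*% v))
  }
  pj <- joint / sum(joint)
  neg_W <- matrix(0, K, M); neg_b <- numeric(M); neg_c <- numeric(K)
  for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(hs))) {
    neg_W <- neg_W + pj[i, j] * outer(hs[j, ], vs[i, ])
    neg_b <- neg_b + pj[i, j] * vs[i, ]
    neg_c <- neg_c + pj[i, j] * hs[j, ]
  }
  pos_W <- matrix(0, K, M); pos_c <- numeric(K)
  for (r in seq_len(nrow(X))) {
    v <- X[r, ]
    w_h <- vapply(seq_len(nrow(hs)), function(j) {
      exp(sum(cc * hs[j, ]) + as.numeric(t(hs[j, ]) %*% W %*% v))
    }, numeric(1))
    w_h <- w_h / sum(w_h)
    eh <- as.numeric(t(hs) %*% w_h)
    pos_W <- pos_W + outer(eh, v)
    pos_c <- pos_c + eh
  }
  list(dW = pos_W / nrow(X) - neg_W,
       db = colMeans(X) - neg_b,
       dc = pos_c / nrow(X) - neg_c)
}


# Independent enumeration oracle for the two-sided rank-sum p-value:
# enumerate all C(n_x + n_y, n_x) group splits of the pooled sample.
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (n - nx) / 2
  splits <- utils::combn(n, nx)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Oracle: full hypergeometric enumeration over tables with fixed margins.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook step-down oracle.
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m); out[o] <- adj
  out
}
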