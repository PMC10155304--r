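# Shared fixtures, built in code at test time.

# The standard synthetic cohort configuration used by the recovery checks:
# 500 patients, 100 medications in 5 planted groups, 5 archetypes with
# diagonal-dominant mixing 0.8, 5% order noise.
standard_spec <- function(seed = 7, ...) {
  synthetic_spec(n_patients = 500, n_medications = 100, n_groups = 5,
                 n_archetypes = 5, noise_rate = 0.05, seed = seed, ...)
}

# A small cohort for cheap end-to-end plumbing tests.
small_spec <- function(seed = 3) {
  synthetic_spec(n_patients = 40, n_medications = 20, n_groups = 4,
                 n_archetypes = 3, orders_per_patient_mean = 8,
                 noise_rate = 0.05, seed = seed)
}

# Hand-built RBM with chosen parameters (bypasses training).
toy_rbm <- function(W, b = NULL, c = NULL) {
  K <- nrow(W); M <- ncol(W)
  structure(
    list(W = W, b = b %||% numeric(M), c = c %||% numeric(K),
         K = K, M = M, order_keys = NULL,
         epochs = 0L, learning_rate = 0, cd_steps = 1L, batch_size = 1L,
         seed = 0L, training_trace = tibble::tibble(epoch = integer(0),
                                                    pll = numeric(0))),
    class = "rbm_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index between two label vectors (via mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Build a phenotype_assignment by hand from a membership table.
make_assignment <- function(df, K, tau = 0.5) {
  df <- tibble::as_tibble(df)
  if (!"activation" %in% names(df)) df$activation <- 0.9
  attr(df, "K") <- as.integer(K)
  attr(df, "tau") <- tau
  class(df) <- c("phenotype_assignment", class(df))
  df
}

# Naive O(n^3) agglomerative clustering oracle: recomputes every cluster
# distance from scratch at every step (no Lance-Williams recurrence).
naive_hac_heights <- function(X, linkage) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  cluster_dist <- function(a, b) {
    if (linkage == "single") min(D[a, b])
    else if (linkage == "complete") max(D[a, b])
    else if (linkage == "average") mean(D[a, b])
    else { # ward on euclidean distances (ward.D2 convention)
      ma <- colMeans(X[a, , drop = FALSE]); mb <- colMeans(X[b, , drop = FALSE])
      sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
        sqrt(sum((ma - mb)^2))
    }
  }
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- cluster_dist(clusters[[i]], clusters[[j]])
      if (d < best[1] - 1e-12) best <- c(d, i, j)
    }
    heights[step] <- best[1]
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
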