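#' Train a Bernoulli restricted Boltzmann machine
#'
#' Fits a two-layer energy-based model to the binary exposure matrix by
#' contrastive divergence (CD-k). The positive phase clamps the visible layer
#' to a data minibatch and uses the analytic hidden probabilities
#' `sigma(c + W v)`; the negative phase runs `cd_steps` alternating Gibbs
#' steps (hidden samples, visible samples, final hidden probabilities) and
#' the update follows the gradient estimate
#' `<v h'>_data - <v h'>_model`. Weights start at Normal(0, 0.01), biases at
#' zero. Training is fully reproducible from `seed`; a pseudo-log-likelihood
#' trace is recorded every `eval_every` epochs as a convergence monitor.
#'
#' @param X Binary matrix (rows = patients, columns = medications /
#'   order keys) or a `cohort_matrix`.
#' @param K Number of hidden units (pharmacophenotypes before the unassigned
#'   bucket); default 5.
#' @param epochs Training epochs; default 5000.
#' @param learning_rate Step size; default 0.05.
#' @param cd_steps Gibbs steps in the negative phase; default 1 (CD-1).
#' @param batch_size Minibatch size; default 32.
#' @param seed Integer seed for initialization and Gibbs sampling.
#' @param eval_every Epoch interval for the pseudo-log-likelihood trace;
#'   default `max(1, epochs %/% 100)`.
#' @return An object of class `rbm_model`: weight matrix `W` (K x M), visible
#'   bias `b`, hidden bias `c`, the hyperparameters, and `training_trace`
#'   (tibble `epoch`, `pll`).
#' @export
train_rbm <- function(X, K = 5, epochs = 5000, learning_rate = 0.05,
                      cd_steps = 1, batch_size = 32, seed = 1,
                      eval_every = NULL) {
  keys <- NULL
  if (inherits(X, "cohort_matrix")) {
    keys <- X$order_keys
    X <- X$X
  }
  assert_binary_matrix(X)
  assert_scalar_number(K, "K", lower = 1)
  assert_scalar_number(epochs, "epochs", lower = 0)
  assert_scalar_number(learning_rate, "learning_rate", lower = 0)
  assert_scalar_number(cd_steps, "cd_steps", lower = 1)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  P <- nrow(X); M <- ncol(X)
  K <- as.integer(K); epochs <- as.integer(epochs)
  eval_every <- as.integer(eval_every %||% max(1L, epochs %/% 100L))

  with_seed(seed, {
    W <- matrix(rnorm(K * M, sd = 0.01), nrow = K, ncol = M)
    b <- numeric(M)
    cc <- numeric(K)
    trace_epoch <- integer(0)
    trace_pll <- numeric(0)

    for (epoch in seq_len(epochs)) {
      idx <- sample.int(P)
      starts <- seq(1L, P, by = batch_size)
      for (s in starts) {
        rows <- idx[s:min(s + batch_size - 1L, P)]
        v0 <- X[rows, , drop = FALSE]
        n <- nrow(v0)
        ph0 <- sigmoid(v0 %*% t(W) + matrix(cc, n, K, byrow = TRUE))
        h <- (matrix(runif(n * K), n, K) < ph0) * 1
        vk <- v0
        phk <- ph0
        for (step in seq_len(cd_steps)) {
          pv <- sigmoid(h %*% W + matrix(b, n, M, byrow = TRUE))
          vk <- (matrix(runif(n * M), n, M) < pv) * 1
          phk <- sigmoid(vk %*% t(W) + matrix(cc, n, K, byrow = TRUE))
          if (step < cd_steps) h <- (matrix(runif(n * K), n, K) < phk) * 1
        }
        lr <- learning_rate / n
        W <- W + lr * (t(ph0) %*% v0 - t(phk) %*% vk)
        b <- b + lr * colSums(v0 - vk)
        cc <- cc + lr * colSums(ph0 - phk)
      }
      if (!all(is.finite(W)) || !all(is.finite(b)) || !all(is.finite(cc))) {
        abort(sprintf("training diverged: non-finite parameters at epoch %d.", epoch))
      }
      if (epoch %% eval_every == 0L || epoch == epochs) {
        trace_epoch <- c(trace_epoch, epoch)
        trace_pll <- c(trace_pll, pll_value(W, b, cc, X))
      }
    }

    dimnames(W) <- NULL
    b <- unname(b)
    cc <- unname(cc)
    structure(
      list(W = W, b = b, c = cc, K = K, M = M,
           order_keys = keys,
           epochs = epochs, learning_rate = learning_rate,
           cd_steps = as.integer(cd_steps),
           batch_size = as.integer(batch_size), seed = as.integer(seed),
           training_trace = tibble(epoch = trace_epoch, pll = trace_pll)),
      class = "rbm_model"
    )
  })
}

#' @export
print.rbm_model <- function(x, ...) {
  cat(sprintf("<rbm_model> %d hidden x %d visible units; %d epochs (CD-%d), final PLL %.3f\n",
              x$K, x$M, x$epochs, x$cd_steps,
              if (nrow(x$training_trace)) tail(x$training_trace$pll, 1) else NA_real_))
  invisible(x)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Free energy F(v) = -b.v - sum_j softplus(c_j + (W v)_j), rowwise for a matrix.
free_energy <- function(W, b, cc, V) {
  A <- V %*% t(W) + matrix(cc, nrow(V), length(cc), byrow = TRUE)
  -as.numeric(V %*% b) - rowSums(softplus(A))
}

# Full-coordinate pseudo-log-likelihood, averaged over rows:
# sum_m log sigma(F(v with bit m flipped) - F(v)).
pll_value <- function(W, b, cc, X) {
  P <- nrow(X); M <- ncol(X); K <- nrow(W)
  A <- X %*% t(W) + matrix(cc, P, K, byrow = TRUE)
  Xb <- as.numeric(X %*% b)
  F0 <- -Xb - rowSums(softplus(A))
  total <- 0
  for (m in seq_len(M)) {
    delta <- 1 - 2 * X[, m]
    Am <- A + outer(delta, W[, m])
    Fm <- -(Xb + delta * b[m]) - rowSums(softplus(Am))
    total <- total + sum(-softplus(-(Fm - F0)))   # log sigma(Fm - F0)
  }
  total / P
}

#' Pseudo-log-likelihood of binary data under an RBM
#'
#' Deterministic full-coordinate pseudo-likelihood proxy for the intractable
#' log-likelihood: for every row and every visible coordinate it scores the
#' model's conditional probability of the observed bit given the rest,
#' `log sigma(F(v_flip) - F(v))`, summed over coordinates and averaged over
#' rows. Used as the training monitor.
#'
#' @param model An `rbm_model`.
#' @param X Binary matrix with `model$M` columns.
#' @return A single number (<= 0; closer to 0 is better).
#' @export
pseudo_log_likelihood <- function(model, X) {
  stopifnot(inherits(model, "rbm_model"))
  if (inherits(X, "cohort_matrix")) X <- X$X
  assert_binary_matrix(X)
  if (ncol(X) != model$M) abort("column count does not match the model.")
  pll_value(model$W, model$b, model$c, X)
}

#' Hidden-unit activation probabilities
#'
#' `p_j = sigma(c_j + sum_m W[j, m] v_m)` for each hidden unit `j`.
#'
#' @param model An `rbm_model`.
#' @param v Binary vector of length `M`, or a matrix with `M` columns
#'   (one row per configuration).
#' @return A length-`K` probability vector (or rows x K matrix).
#' @export
hidden_activation <- function(model, v) {
  stopifnot(inherits(model, "rbm_model"))
  vec <- is.null(dim(v))
  V <- if (vec) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(V) != model$M) {
    abort(sprintf("`v` must have length/width %d, got %d.", model$M, ncol(V)))
  }
  p <- sigmoid(V %*% t(model$W) + matrix(model$c, nrow(V), model$K, byrow = TRUE))
  if (vec) as.numeric(p) else p
}

#' Assign medications to pharmacophenotypes
#'
#' Reads each medication's learned activation pattern off the trained RBM and
#' converts it into phenotype memberships: medication `m` joins every hidden
#' unit (pharmacophenotype) `j` whose activation probability exceeds `tau`.
#' Multi-membership is allowed — the membership sets describe the overlap
#' between phenotypes — and medications activating no hidden unit fall into
#' the explicit unassigned bucket, phenotype `K + 1`.
#'
#' Two probing rules are available. The default, `probe = "data"`, defines
#' medication `m`'s activation of unit `j` as the mean of `p(h_j = 1 | v)`
#' over the training patients exposed to `m` — the activation pattern the
#' unit actually exhibits for that medication in the cohort. With
#' `probe = "onehot"` the activation is `sigma(c_j + W[j, m])`, the response
#' to the medication's one-hot visible vector in isolation. The data rule is
#' the default because hidden units learn codes for co-occurring medication
#' blocks that are only fully expressed on realistic visible configurations;
#' one-hot probing under-drives the hidden layer and can split a coherent
#' medication block across phenotypes.
#'
#' @param model An `rbm_model`.
#' @param X Binary training matrix (or `cohort_matrix`) used by the
#'   `"data"` probe; unused for `"onehot"`.
#' @param tau Activation threshold in (0, 1); default 0.5, the natural
#'   decision boundary of the logistic function.
#' @param exclusive If `TRUE`, assign each medication only to its
#'   highest-activation phenotype (still `K + 1` when none exceeds `tau`).
#' @param probe `"data"` (cohort-conditional activation, default) or
#'   `"onehot"`.
#' @return A tibble of class `phenotype_assignment` with one row per
#'   membership: `order_key`, `phenotype` (integer in `1..K+1`) and
#'   `activation` (the probing probability; for unassigned keys, the maximum
#'   over hidden units). Attributes `K` and `tau` record the configuration.
#' @export
assign_medications <- function(model, X = NULL, tau = 0.5, exclusive = FALSE,
                               probe = c("data", "onehot")) {
  stopifnot(inherits(model, "rbm_model"))
  probe <- match.arg(probe)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    abort("`tau` must lie strictly between 0 and 1.")
  }
  keys <- model$order_keys %||% paste0("v", seq_len(model$M))
  if (probe == "data") {
    if (is.null(X)) abort("the 'data' probe needs the training matrix `X`.")
    if (inherits(X, "cohort_matrix")) X <- X$X
    assert_binary_matrix(X)
    if (ncol(X) != model$M) abort("column count does not match the model.")
    H <- hidden_activation(model, X)        # patients x K
    exposure <- colSums(X)
    # P[j, m] = mean activation of unit j over patients exposed to med m;
    # a medication no patient received has no pattern -> unassigned
    P <- t(crossprod(X, H) / ifelse(exposure > 0, exposure, 1))
    P[, exposure == 0] <- 0
  } else {
    # one-hot probe of every medication at once: P[j, m] = sigma(c_j + W[j, m])
    P <- sigmoid(model$W + matrix(model$c, model$K, model$M))
  }
  rows <- purrr::map(seq_len(model$M), function(m) {
    p <- P[, m]
    hit <- which(p > tau)
    if (exclusive && length(hit) > 1) hit <- hit[which.max(p[hit])]
    if (length(hit) == 0) {
      tibble(order_key = keys[m], phenotype = model$K + 1L,
             activation = max(p))
    } else {
      tibble(order_key = keys[m], phenotype = as.integer(hit),
             activation = p[hit])
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "K") <- model$K
  attr(out, "tau") <- tau
  class(out) <- c("phenotype_assignment", class(out))
  out
}

#' Primary phenotype label per medication
#'
#' Reduces a (possibly multi-membership) assignment to one label per order
#' key: the member phenotype with the highest activation, or `K + 1` for
#' unassigned keys. Used when comparing assignments to a reference partition.
#'
#' @param assignment A [assign_medications()] result.
#' @return Tibble `order_key`, `phenotype`.
#' @export
primary_phenotype <- function(assignment) {
  stopifnot(inherits(assignment, "phenotype_assignment"))
  assignment |>
    as_tibble() |>
    dplyr::group_by(.data$order_key) |>
    dplyr::slice_max(.data$activation, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("order_key", "phenotype")
}

#' Membership-pattern labels per medication
#'
#' Collapses a (possibly multi-membership) assignment into one label per
#' order key: the sorted set of phenotypes the key belongs to, as a string
#' such as `"1+3"` (or `"6"` for the unassigned bucket). Medications with
#' identical labels are assigned identically — this is the partition the
#' assignment induces, used when comparing against a reference grouping.
#'
#' @param assignment A [assign_medications()] result.
#' @return Tibble `order_key`, `pattern`.
#' @export
assignment_patterns <- function(assignment) {
  stopifnot(inherits(assignment, "phenotype_assignment"))
  assignment |>
    as_tibble() |>
    dplyr::group_by(.data$order_key) |>
    dplyr::summarise(pattern = paste(sort(unique(.data$phenotype)),
                                     collapse = "+"),
                     .groups = "drop")
}

#' Exact log-likelihood gradient of a small RBM
#'
#' Computes the exact gradient `<v h'>_data - <v h'>_model` (and the bias
#' gradients) that contrastive divergence approximates, with the model
#' expectation taken by enumerating all `2^M` visible states. Only feasible
#' for small models (`M <= 20`); used to validate the CD training direction.
#'
#' @param model An `rbm_model`.
#' @param X Binary data matrix (rows are the clamped visible configurations).
#' @return List with `dW` (K x M), `db` (length M), `dc` (length K).
#' @export
rbm_exact_gradient <- function(model, X) {
  stopifnot(inherits(model, "rbm_model"))
  if (inherits(X, "cohort_matrix")) X <- X$X
  assert_binary_matrix(X)
  M <- model$M; K <- model$K
  if (M > 20) abort("exact gradient enumerates 2^M states; M must be <= 20.")

  ph_data <- hidden_activation(model, X)
  pos_W <- t(ph_data) %*% X / nrow(X)
  pos_b <- colMeans(X)
  pos_c <- colMeans(ph_data)

  V <- as.matrix(expand.grid(rep(list(c(0, 1)), M)))[, seq_len(M), drop = FALSE]
  colnames(V) <- NULL
  fe <- free_energy(model$W, model$b, model$c, V)
  p <- exp(fe * -1 - max(-fe))
  p <- p / sum(p)
  ph_model <- hidden_activation(model, V)
  neg_W <- t(ph_model * p) %*% V
  neg_b <- as.numeric(t(V) %*% p)
  neg_c <- as.numeric(t(ph_model) %*% p)

  list(dW = pos_W - neg_W, db = pos_b - neg_b, dc = pos_c - neg_c)
}

#' @method tidy rbm_model
#' @export
tidy.rbm_model <- function(x, ...) {
  keys <- x$order_keys %||% paste0("v", seq_len(x$M))
  tibble(
    phenotype = rep(seq_len(x$K), times = x$M),
    order_key = rep(keys, each = x$K),
    weight = as.numeric(x$W)
  )
}

#' @method glance rbm_model
#' @export
glance.rbm_model <- function(x, ...) {
  tibble(K = x$K, M = x$M, epochs = x$epochs,
         learning_rate = x$learning_rate, cd_steps = x$cd_steps,
         batch_size = x$batch_size, seed = x$seed,
         final_pll = if (nrow(x$training_trace)) tail(x$training_trace$pll, 1) else NA_real_)
}

#' @describeIn train_rbm Plot the pseudo-log-likelihood training trace.
#' @param object An `rbm_model`.
#' @param ... Unused.
#' @method autoplot rbm_model
#' @export
autoplot.rbm_model <- function(object, ...) {
  ggplot2::ggplot(object$training_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$pll)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "pseudo-log-likelihood",
                  title = "RBM training trace") +
    ggplot2::theme_minimal()
}
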