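test_that("exact RBM gradient matches the exhaustive joint-state oracle", {
  set.seed(99)
  for (rep in 1:3) {
    W <- matrix(rnorm(2 * 3, sd = 0.8), 2, 3)
    b <- rnorm(3, sd = 0.5); cc <- rnorm(2, sd = 0.5)
    model <- toy_rbm(W, b, cc)
    X <- matrix(rbinom(15, 1, 0.5), 5, 3)
    got <- rbm_exact_gradient(model, X)
    want <- enum_gradient(W, b, cc, X)
    expect_lt(max(abs(got$dW - want$dW)), 1e-10)
    expect_lt(max(abs(got$db - want$db)), 1e-10)
    expect_lt(max(abs(got$dc - want$dc)), 1e-10)
  }
})

test_that("hidden activations follow the logistic closed form", {
  zero <- toy_rbm(matrix(0, 4, 6))
  expect_equal(hidden_activation(zero, rep(1, 6)), rep(0.5, 4))

  W <- matrix(0, 2, 3); W[1, 2] <- 2
  m <- toy_rbm(W, c = c(-1, 0))
  v <- c(0, 1, 0)
  expect_equal(hidden_activation(m, v)[1], 1 / (1 + exp(-1)), tolerance = 1e-12)

  set.seed(12)
  W <- matrix(rnorm(12), 3, 4); b <- rnorm(4); cc <- rnorm(3)
  mod <- toy_rbm(W, b, cc)
  v <- rbinom(4, 1, 0.5)
  expect_equal(hidden_activation(mod, v),
               as.numeric(1 / (1 + exp(-(cc + W %*% v)))), tolerance = 1e-12)
  expect_error(hidden_activation(mod, c(1, 0)), "length")
})

test_that("training is reproducible and a zero learning rate freezes parameters", {
  set.seed(6)
  X <- matrix(rbinom(80, 1, 0.4), 20, 4)
  m1 <- train_rbm(X, K = 2, epochs = 30, seed = 42, eval_every = 10)
  m2 <- train_rbm(X, K = 2, epochs = 30, seed = 42, eval_every = 10)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  expect_identical(m1$c, m2$c)
  expect_identical(m1$training_trace, m2$training_trace)

  frozen <- train_rbm(X, K = 2, epochs = 15, learning_rate = 0, seed = 42)
  init <- train_rbm(X, K = 2, epochs = 0, learning_rate = 0.05, seed = 42)
  expect_equal(frozen$W, init$W)
  expect_equal(frozen$b, init$b)
  expect_equal(frozen$c, init$c)

  expect_error(train_rbm(matrix(c(0, 2), 1, 2), K = 1), "binary")
})

test_that("one-hot probing assigns phenotypes by thresholded activation", {
  # all-zero model: every activation is exactly 0.5, boundary excluded
  zero <- toy_rbm(matrix(0, 3, 4))
  asg <- assign_medications(zero, tau = 0.5, probe = "onehot")
  expect_true(all(asg$phenotype == 4L))
  expect_equal(nrow(asg), 4)

  # strong single connection: medication joins exactly that phenotype
  W <- matrix(-6, 3, 4); W[2, 1] <- 3
  mod <- toy_rbm(W, c = c(-8, 0, -8))
  asg2 <- assign_medications(mod, tau = 0.5, probe = "onehot")
  expect_equal(asg2$phenotype[asg2$order_key == "v1"], 2L)
  expect_true(all(asg2$phenotype[asg2$order_key != "v1"] == 4L))

  expect_error(assign_medications(mod, tau = 0, probe = "onehot"), "tau")
  expect_error(assign_medications(mod, tau = 1, probe = "onehot"), "tau")
})

test_that("raising tau never grows memberships; tau near 1 unassigns all", {
  set.seed(23)
  W <- matrix(rnorm(5 * 8, sd = 1), 5, 8)
  W[W > 2] <- 2; W[W < -2] <- -2
  mod <- toy_rbm(W, c = rnorm(5, sd = 0.5))
  taus <- c(0.3, 0.5, 0.7, 0.9)
  sets <- lapply(taus, function(t) {
    a <- assign_medications(mod, tau = t, probe = "onehot")
    split(a$phenotype[a$phenotype <= 5], a$order_key[a$phenotype <= 5])
  })
  for (i in seq_len(length(taus) - 1)) {
    for (k in names(sets[[i + 1]])) {
      expect_true(all(sets[[i + 1]][[k]] %in% (sets[[i]][[k]] %||% integer(0))))
    }
  }
  near1 <- assign_medications(mod, tau = 0.999, probe = "onehot")
  expect_true(all(near1$phenotype == 6L))

  # exclusive mode keeps only the top activation
  excl <- assign_medications(mod, tau = 0.3, exclusive = TRUE, probe = "onehot")
  expect_equal(nrow(excl), 8)
  expect_equal(nrow(primary_phenotype(assign_medications(mod, tau = 0.3, probe = "onehot"))), 8)
})

test_that("pseudo-log-likelihood has its closed-form value for the zero model", {
  set.seed(4)
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  zero <- toy_rbm(matrix(0, 3, 4))
  expect_equal(pseudo_log_likelihood(zero, X), 4 * log(0.5), tolerance = 1e-12)
})

test_that("pseudo-log-likelihood ranks candidate models like the exact likelihood", {
  # 2 visible / 1 hidden: the partition function is enumerable
  exact_ll <- function(W, b, cc, X) {
    vs <- as.matrix(expand.grid(0:1, 0:1))
    hs <- matrix(0:1, ncol = 1)
    z <- 0
    for (i in 1:4) for (j in 1:2) {
      z <- z + exp(sum(b * vs[i, ]) + cc * hs[j, ] +
                   hs[j, ] * sum(W * vs[i, ]))
    }
    ll <- 0
    for (r in seq_len(nrow(X))) {
      pv <- 0
      for (j in 1:2) {
        pv <- pv + exp(sum(b * X[r, ]) + cc * hs[j, ] +
                       hs[j, ] * sum(W * X[r, ]))
      }
      ll <- ll + log(pv / z)
    }
    ll / nrow(X)
  }
  X <- rbind(c(1, 1), c(1, 1), c(1, 1), c(0, 0))
  cands <- list(
    aligned = list(W = matrix(c(2, 2), 1), b = c(-1, -1), cc = 0),
    zero    = list(W = matrix(c(0, 0), 1), b = c(0, 0), cc = 0),
    anti    = list(W = matrix(c(-2, 2), 1), b = c(0, 0), cc = 0)
  )
  ll <- vapply(cands, function(p) exact_ll(p$W, p$b, p$cc, X), numeric(1))
  pll <- vapply(cands, function(p) {
    pseudo_log_likelihood(toy_rbm(p$W, p$b, p$cc), X)
  }, numeric(1))
  expect_identical(order(ll), order(pll))
})

test_that("model JSON archive round-trips activations exactly", {
  dir <- withr::local_tempdir()
  set.seed(50)
  X <- matrix(rbinom(60, 1, 0.4), 15, 4)
  mod <- train_rbm(X, K = 2, epochs = 20, seed = 9, eval_every = 5)
  path <- file.path(dir, "rbm.json")
  write_rbm_json(mod, path)
  back <- read_rbm_json(path)
  expect_equal(back$W, mod$W, tolerance = 1e-12)
  v <- rbinom(4, 1, 0.5)
  expect_equal(hidden_activation(back, v), hidden_activation(mod, v))
  expect_equal(as.data.frame(back$training_trace),
               as.data.frame(mod$training_trace))
})
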