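
test_that("rank-sum exact path equals full enumeration for tie-free samples", {
  # worked example: complete separation of 3 vs 3 gives p = 2 / C(6,3) = 0.1
  t0 <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 0.1)
  expect_equal(t0$method, "exact")

  set.seed(31)
  for (rep in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(1000, nx + ny)  # distinct values, no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(rank_sum_test(x, y)$p_value, enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum large-sample path matches the tie-corrected normal formula", {
  set.seed(17)
  for (rep in 1:10) {
    x <- sample(1:8, 15, replace = TRUE)  # heavy ties
    y <- sample(3:10, 15, replace = TRUE)
    got <- rank_sum_test(x, y)
    expect_equal(got$method, "normal")
    # independent normal-approximation oracle with tie correction and
    # continuity correction
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - n1 * n2 / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    expect_equal(got$p_value, 2 * stats::pnorm(-abs(z)), tolerance = 1e-6)
  }

  # identical distributions: p = 1
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-missing")
})


test_that("fisher_exact_2x2 equals hypergeometric enumeration", {
  # worked values
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 5, 0, 5)$p_value, 1)

  set.seed(13)
  for (rep in 1:40) {
    cells <- as.vector(stats::rmultinom(1, sample(8:30, 1), prob = runif(4)))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 enum_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }

  expect_equal(fisher_exact_2x2(2, 1, 1, 2)$odds_ratio, 4)
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(-1, 0, 0, 2), "nonnegative")
})


test_that("holm_adjust equals the textbook step-down on random vectors", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)

  set.seed(5)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_identical(adj, brute_holm(p))
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(holm_adjust(c(0.5, 0)), "0, 1")
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise_compare covers all pairs per outcome with within-family Holm", {
  set.seed(77)
  n_per <- 40
  labels <- tibble::tibble(patient_id = sprintf("p%03d", 1:(5 * n_per)),
                           cluster = rep(1:5, each = n_per))
  outcomes <- tibble::tibble(
    patient_id = labels$patient_id,
    los = rnorm(5 * n_per, mean = rep(c(5, 5, 5, 5, 12), each = n_per)),
    death = rbinom(5 * n_per, 1, 0.2)
  )
  res <- pairwise_compare(labels, outcomes,
                          c(los = "continuous", death = "categorical"))
  expect_equal(nrow(res), 2 * choose(5, 2))
  expect_equal(sum(res$outcome == "los"), 10)
  expect_true(all(res$test[res$outcome == "death"] == "fisher_exact"))
  # Holm within the outcome family
  for (nm in c("los", "death")) {
    sub <- res[res$outcome == nm, ]
    expect_equal(sub$p_holm, holm_adjust(sub$p_raw))
  }
  # the planted shift in cluster 5 dominates the smallest adjusted p
  best <- res[which.min(res$p_holm), ]
  expect_equal(best$outcome, "los")
  expect_true(5 %in% c(best$cluster_a, best$cluster_b))

  # identical outcome distributions: all Holm-adjusted p equal 1
  outcomes_null <- tibble::tibble(patient_id = labels$patient_id,
                                  flat = rep(c(1, 2, 3, 4), length.out = 5 * n_per))
  res_null <- pairwise_compare(labels, outcomes_null, c(flat = "continuous"))
  expect_true(all(res_null$p_holm > 0.999))
})

test_that("missing outcome values are excluded with per-pair denominators", {
  labels <- tibble::tibble(patient_id = paste0("p", 1:60),
                           cluster = rep(1:3, each = 20))
  set.seed(8)
  outcomes <- tibble::tibble(patient_id = labels$patient_id,
                             aki = c(rbinom(40, 1, 0.3), rep(NA, 20)))
  expect_message(
    res <- pairwise_compare(labels, outcomes, c(aki = "categorical")),
    "skipped"
  )
  done <- res[!is.na(res$p_raw), ]
  expect_equal(nrow(done), 1)          # only pair 1-2 is computable
  expect_equal(done$n_a + done$n_b, 40)
  expect_true(all(is.na(res$p_raw[res$cluster_b == 3])))
})

test_that("pooled_summary reproduces size-weighted means and pooled counts", {
  per <- tibble::tibble(
    cluster = rep(1:3, 2),
    n = rep(c(10L, 20L, 30L), 2),
    outcome = rep(c("score", "event"), each = 3),
    type = rep(c("continuous", "categorical"), each = 3),
    mean = c(1, 2, 3, NA, NA, NA),
    count = c(NA, NA, NA, 1L, 2L, 3L),
    denom = c(NA, NA, NA, 10L, 20L, 30L)
  )
  pooled <- pooled_summary(per)
  expect_equal(pooled$n_total, rep(60L, 2))
  expect_equal(pooled$mean[pooled$outcome == "score"],
               round((10 * 1 + 20 * 2 + 30 * 3) / 60, 1))
  expect_equal(pooled$count[pooled$outcome == "event"], 6L)
  expect_equal(pooled$pct[pooled$outcome == "event"], 10)

  # one cluster pools to itself
  one <- pooled_summary(per[per$cluster == 1, ])
  expect_equal(one$n_total, rep(10L, 2))
  expect_equal(one$mean[1], 1)
})

test_that("phenotype_profile matches brute-force group-by counting", {
  set.seed(14)
  membership <- tibble::tibble(
    order_key = paste0("k", 1:12),
    phenotype = sample(1:4, 12, replace = TRUE)
  )
  asg <- make_assignment(membership, K = 3)
  ann <- tibble::tibble(order_key = paste0("k", c(1, 2, 3, 7)),
                        category = c("antibiotic", "antibiotic", "sedative",
                                     "antibiotic"))
  prof <- phenotype_profile(asg, ann)
  for (i in seq_len(nrow(prof))) {
    keys_in <- membership$order_key[membership$phenotype == prof$phenotype[i]]
    expected_n <- if (prof$category[i] == "unannotated") {
      sum(!keys_in %in% ann$order_key)
    } else {
      sum(keys_in %in% ann$order_key[ann$category == prof$category[i]])
    }
    expect_equal(prof$n[i], expected_n)
    expect_equal(prof$pct[i], round(100 * expected_n / length(keys_in), 1))
  }

  # empty annotations: everything unannotated at 100%
  prof0 <- phenotype_profile(asg, NULL)
  expect_true(all(prof0$category == "unannotated"))
  expect_true(all(prof0$pct == 100))

  # toy: one of two member keys annotated -> 1 (50.0)
  asg2 <- make_assignment(tibble::tibble(order_key = c("k1", "k2"),
                                         phenotype = c(1L, 1L)), K = 2)
  prof2 <- phenotype_profile(asg2, tibble::tibble(order_key = "k1",
                                                  category = "antibiotic"))
  row <- prof2[prof2$category == "antibiotic", ]
  expect_equal(row$n, 1L)
  expect_equal(row$pct, 50)
})

test_that("signed_rank_test handles paired data", {
  set.seed(2)
  x <- rnorm(20); y <- x + 0.1 * rnorm(20)
  out <- signed_rank_test(x, y)
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_error(signed_rank_test(1:3, 1:4), "paired")
})
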