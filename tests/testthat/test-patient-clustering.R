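test_that("phenotype distributions match direct counting in both modes", {
  # worked example: keys a,b -> {1}; c -> {2}; d -> unassigned (K+1)
  K <- 5
  asg <- make_assignment(
    data.frame(order_key = paste0(c("a", "b", "c", "d"), "||||"),
               phenotype = c(1L, 1L, 2L, 6L)), K = K)
  mar <- tibble::tibble(patient_id = "p1", drug = c("a", "b", "c", "d"),
                        dose = "", strength = "", formulation = "", route = "")
  m <- encode_matrix(mar)
  d <- phenotype_distribution(m, asg, mode = "fractional")
  expect_equal(unlist(d[1, paste0("phenotype_", 1:6)], use.names = FALSE),
               c(0.5, 0.25, 0, 0, 0, 0.25))
  expect_equal(d$total_orders, 4L)

  # single-membership assignment: fractional and full coincide
  d_full <- phenotype_distribution(m, asg, mode = "full")
  expect_equal(as.data.frame(d), as.data.frame(d_full))
})

test_that("multi-membership distributions match a brute-force counting oracle", {
  set.seed(21)
  K <- 3
  keys <- paste0(letters[1:8], "||||")
  membership <- purrr::map_dfr(keys, function(k) {
    n_mem <- sample(0:2, 1)
    ph <- if (n_mem == 0) K + 1L else sort(sample.int(K, n_mem))
    tibble::tibble(order_key = k, phenotype = as.integer(ph))
  })
  asg <- make_assignment(membership, K = K)
  mar <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(patient_id = paste0("p", i),
                   drug = sub("\\|+$", "", sample(keys, sample(2:6, 1))),
                   dose = "", strength = "", formulation = "", route = "")
  })
  m <- encode_matrix(mar)

  for (mode in c("fractional", "full")) {
    got <- phenotype_distribution(m, asg, mode = mode)
    for (i in seq_along(m$patients)) {
      exposed <- m$order_keys[m$X[i, ] == 1]
      counts <- numeric(K + 1)
      for (k in exposed) {
        mem <- membership$phenotype[membership$order_key == k]
        w <- if (mode == "fractional") 1 / length(mem) else 1
        counts[mem] <- counts[mem] + w
      }
      expect_equal(
        unlist(got[got$patient_id == m$patients[i],
                   paste0("phenotype_", 1:(K + 1))], use.names = FALSE),
        counts / length(exposed),
        tolerance = 1e-12
      )
    }
    if (mode == "fractional") {
      sums <- rowSums(got[, paste0("phenotype_", 1:(K + 1))])
      expect_equal(sums, rep(1, nrow(got)), tolerance = 1e-9)
    }
  }

  # a key missing from the assignment is a named error
  asg_partial <- make_assignment(membership[membership$order_key != "a||||", ], K = K)
  expect_error(phenotype_distribution(m, asg_partial), "absent")
})

test_that("hac merge heights equal the naive all-pairs oracle for every linkage", {
  set.seed(11)
  for (rep in 1:3) {
    X <- matrix(rnorm(24), 8, 3)
    for (lk in c("ward", "average", "complete", "single")) {
      tree <- hac(X, linkage = lk)
      expect_equal(sort(tree$hclust$height),
                   sort(naive_hac_heights(X, lk)),
                   tolerance = 1e-8,
                   label = paste("linkage", lk, "rep", rep))
    }
  }
})

test_that("forced geometries merge as expected", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  tree <- hac(X, linkage = "single")
  expect_equal(min(tree$hclust$height), 1)
  labs <- cut_tree(tree, 2)
  expect_equal(labs$cluster, c(1, 1, 2))  # {0,1} bigger cluster first

  # duplicated rows merge at height zero
  tree0 <- hac(matrix(c(0, 0, 5), ncol = 1), linkage = "average")
  expect_equal(min(tree0$hclust$height), 0)

  expect_error(hac(matrix(c(0, NA), ncol = 1)), "finite")
  expect_error(hac(matrix(1, 1, 1)), "2 rows")
})

test_that("cut_tree boundary cuts and renumbering by size", {
  set.seed(4)
  X <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(20, 8), 10))
  tree <- hac(X)
  all1 <- cut_tree(tree, 1)
  expect_true(all(all1$cluster == 1))
  singletons <- cut_tree(tree, nrow(X))
  expect_equal(sort(singletons$cluster), 1:nrow(X))
  two <- cut_tree(tree, 2)
  # label 1 is the larger (10-member) cluster
  expect_equal(sum(two$cluster == 1), 10)
  expect_error(cut_tree(tree, 0), "n_clusters")
  expect_error(cut_tree(tree, nrow(X) + 1), "n_clusters")
})

test_that("suggest_k finds well-separated structure and flags flat trees", {
  set.seed(9)
  blobs <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 10, 0.3), 20))
  s <- suggest_k(hac(blobs))
  expect_equal(s$k, 2L)
  expect_true(all(c("k", "h_below", "h_above", "gap") %in% names(s$gaps)))

  # equally spaced 1-D points under single linkage: all merge heights equal
  flat <- matrix(c(0, 1, 2, 3), ncol = 1)
  expect_warning(sf <- suggest_k(hac(flat, linkage = "single")), "flat")
  expect_equal(sf$k, 2L)
})
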