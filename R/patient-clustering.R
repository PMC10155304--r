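#' Per-patient normalized pharmacophenotype distributions
#'
#' Converts the binary exposure matrix plus a medication-to-phenotype
#' assignment into each patient's normalized phenotype frequency vector —
#' the derived feature used to cluster patients. For every patient, each of
#' their distinct order keys contributes to the phenotypes it belongs to and
#' the counts are divided by the patient's total number of distinct orders.
#' In `"fractional"` mode (default) a key belonging to several phenotypes
#' splits its unit mass equally among them, so each row is a probability
#' vector over phenotypes `1..K+1`; `"full"` mode credits each member
#' phenotype with the whole unit (rows may then sum to more than 1).
#'
#' @param matrix A `cohort_matrix` from [encode_matrix()].
#' @param assignment A [assign_medications()] result covering every order key
#'   in `matrix`.
#' @param mode `"fractional"` or `"full"`.
#' @return A tibble with `patient_id`, columns `phenotype_1` ..
#'   `phenotype_{K+1}`, and `total_orders`.
#' @export
phenotype_distribution <- function(matrix, assignment,
                                   mode = c("fractional", "full")) {
  stopifnot(inherits(matrix, "cohort_matrix"),
            inherits(assignment, "phenotype_assignment"))
  mode <- match.arg(mode)
  K <- attr(assignment, "K")
  missing_keys <- setdiff(matrix$order_keys, assignment$order_key)
  if (length(missing_keys) > 0) {
    abort(sprintf("order key(s) absent from assignment: %s",
                  paste(head(missing_keys, 5), collapse = ", ")))
  }

  # key x phenotype membership weights
  a <- as_tibble(assignment)
  a <- a[a$order_key %in% matrix$order_keys, ]
  Wm <- membership_weights(a, matrix$order_keys, K, mode)

  counts <- matrix$X %*% Wm
  totals <- rowSums(matrix$X)
  f <- counts / ifelse(totals > 0, totals, 1)
  out <- as_tibble(f, .name_repair = "minimal")
  names(out) <- phenotype_cols(K)
  dplyr::bind_cols(tibble(patient_id = matrix$patients), out,
                   tibble(total_orders = as.integer(totals)))
}

membership_weights <- function(a, keys, K, mode) {
  Wm <- matrix(0, nrow = length(keys), ncol = K + 1L,
               dimnames = list(keys, NULL))
  sizes <- table(a$order_key)
  w <- if (mode == "fractional") 1 / as.numeric(sizes[a$order_key]) else 1
  Wm[cbind(match(a$order_key, keys), a$phenotype)] <- w
  Wm
}

#' Hierarchical agglomerative clustering of patients
#'
#' Bottom-up clustering: every observation starts as its own cluster and the
#' two most similar clusters merge repeatedly until one remains. Cluster
#' distances follow the chosen linkage (Ward by default, on Euclidean
#' distances); merges and heights come from the Lance-Williams recurrence as
#' implemented by [stats::hclust()].
#'
#' @param features A data frame whose numeric columns are the clustering
#'   features (an id column, by default `patient_id`, is carried along), or a
#'   numeric matrix with row names as ids.
#' @param linkage `"ward"`, `"average"`, `"complete"` or `"single"`.
#' @param metric Distance metric passed to [stats::dist()]; default
#'   `"euclidean"`.
#' @param id_col Name of the id column when `features` is a data frame.
#' @return An object of class `linkage_tree` wrapping the merge history.
#' @export
hac <- function(features, linkage = c("ward", "average", "complete", "single"),
                metric = "euclidean", id_col = "patient_id") {
  linkage <- match.arg(linkage)
  if (is.data.frame(features)) {
    ids <- if (id_col %in% names(features)) as.character(features[[id_col]])
           else as.character(seq_len(nrow(features)))
    num <- features[, setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                              id_col), drop = FALSE]
    fm <- as.matrix(num)
  } else {
    fm <- as.matrix(features)
    ids <- rownames(fm) %||% as.character(seq_len(nrow(fm)))
  }
  if (nrow(fm) < 2) abort("clustering needs at least 2 rows.")
  if (!all(is.finite(fm))) abort("features must be finite (no NA/NaN/Inf).")

  method <- switch(linkage, ward = "ward.D2", linkage)
  hc <- stats::hclust(stats::dist(fm, method = metric), method = method)
  structure(list(hclust = hc, ids = ids, linkage = linkage, metric = metric,
                 n = nrow(fm)),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %s linkage (%s), max height %.4f\n",
              x$n, x$linkage, x$metric, max(x$hclust$height)))
  invisible(x)
}

#' @export
plot.linkage_tree <- function(x, ...) {
  plot(x$hclust, labels = FALSE, main = "patient dendrogram",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' @method tidy linkage_tree
#' @export
tidy.linkage_tree <- function(x, ...) {
  tibble(step = seq_along(x$hclust$height),
         cluster_a = x$hclust$merge[, 1],
         cluster_b = x$hclust$merge[, 2],
         height = x$hclust$height)
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' Labels are renumbered `1..n_clusters` by descending cluster size (ties
#' broken by the lowest member index) so labels are comparable across runs.
#'
#' @param tree A [hac()] result.
#' @param n_clusters Number of clusters, between 1 and the number of leaves.
#' @return A tibble `patient_id`, `cluster`.
#' @export
cut_tree <- function(tree, n_clusters) {
  stopifnot(inherits(tree, "linkage_tree"))
  assert_scalar_number(n_clusters, "n_clusters", lower = 1, upper = tree$n)
  raw <- stats::cutree(tree$hclust, k = as.integer(n_clusters))
  sizes <- tabulate(raw)
  first_member <- vapply(seq_along(sizes), function(g) match(g, raw), integer(1))
  ord <- order(-sizes, first_member)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  tibble(patient_id = tree$ids, cluster = relabel[raw])
}

#' Suggest a cluster count from dendrogram merge heights
#'
#' Programmatic surrogate for visual dendrogram inspection: for each
#' candidate `k`, the relative gap between the merge height just above and
#' just below the k-cluster cut, `(h_above - h_below) / h_below`, measures
#' how well separated a k-cluster solution is; the `k` with the largest gap
#' is suggested. The full gap table is returned so the choice can be
#' overridden by eye.
#'
#' @param tree A [hac()] result.
#' @param k_max Largest cluster count considered (default 10, capped at
#'   `n - 1`).
#' @return An object of class `k_suggestion`: list with `k` and the tibble
#'   `gaps` (`k`, `h_below`, `h_above`, `gap`).
#' @export
suggest_k <- function(tree, k_max = 10) {
  stopifnot(inherits(tree, "linkage_tree"))
  assert_scalar_number(k_max, "k_max", lower = 2)
  h <- tree$hclust$height
  n <- tree$n
  ks <- 2:min(k_max, n - 1)
  gaps <- purrr::map_dfr(ks, function(k) {
    h_below <- h[n - k]
    h_above <- h[n - k + 1]
    gap <- if (h_below > 1e-12) (h_above - h_below) / h_below
           else if (h_above > 1e-12) Inf else 0
    tibble(k = k, h_below = h_below, h_above = h_above, gap = gap)
  })
  if (all(gaps$gap <= 1e-12)) {
    warn("flat dendrogram: all merge heights are equal; defaulting to k = 2.")
    k_best <- 2L
  } else {
    k_best <- gaps$k[which.max(gaps$gap)]
  }
  structure(list(k = as.integer(k_best), gaps = gaps), class = "k_suggestion")
}

#' @export
print.k_suggestion <- function(x, ...) {
  cat(sprintf("<k_suggestion> k = %d\n", x$k))
  print(x$gaps)
  invisible(x)
}
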