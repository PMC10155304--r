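#' PCA with explained-variance component selection
#'
#' Fits principal components to the centered (not scaled: the exposure
#' indicators share a 0/1 scale) cohort matrix via singular value
#' decomposition, and keeps the smallest number of components whose
#' cumulative explained-variance ratio exceeds `variance_target`, optionally
#' capped. The sign of each component is fixed so its largest-magnitude
#' loading is positive, making outputs stable across runs and platforms.
#'
#' @param X Numeric matrix (patients x features) or a `cohort_matrix`.
#' @param variance_target Fraction of total variance the kept components must
#'   exceed; default 0.70.
#' @param max_components Optional cap on the number of kept components (the
#'   study-scale configuration caps at 150 to reduce dimensionality while
#'   holding more than 70% of the variance).
#' @return An object of class `pca_model` with `mean_vector`, `components`
#'   (n_components x M, orthonormal rows), `explained_variance_ratio` (all
#'   ranks), `n_components` and `variance_target`.
#' @export
fit_pca <- function(X, variance_target = 0.70, max_components = NULL) {
  if (inherits(X, "cohort_matrix")) X <- X$X
  stopifnot(is.matrix(X), is.numeric(X))
  if (nrow(X) < 2) abort("PCA needs at least 2 rows.")
  assert_scalar_number(variance_target, "variance_target",
                       lower = .Machine$double.eps, upper = 1)

  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  var_all <- fit$sdev^2
  total <- sum(var_all)
  if (total < 1e-12) abort("degenerate input: the matrix is constant (rank 0).")
  ratio <- var_all / total
  # numerical rank: drop components explaining ~0 variance
  rank <- sum(var_all > max(var_all) * 1e-12)

  cum <- cumsum(ratio)
  n_c <- which(cum > variance_target - 1e-12)[1]
  if (is.na(n_c)) n_c <- rank
  n_c <- min(n_c, rank, max_components %||% Inf)
  n_c <- as.integer(n_c)

  rot <- t(fit$rotation[, seq_len(n_c), drop = FALSE])
  # deterministic sign convention
  for (j in seq_len(n_c)) {
    m <- which.max(abs(rot[j, ]))
    if (rot[j, m] < 0) rot[j, ] <- -rot[j, ]
  }

  structure(
    list(mean_vector = fit$center,
         components = rot,
         explained_variance_ratio = ratio[seq_len(rank)],
         n_components = n_c,
         variance_target = variance_target),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components (target %.0f%% variance, achieved %.1f%%)\n",
              x$n_components, 100 * x$variance_target,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  invisible(x)
}

#' Project data onto fitted principal components
#'
#' @param object A `pca_model`.
#' @param newdata Matrix (or `cohort_matrix`) with the same columns the model
#'   was fitted on.
#' @param ... Unused.
#' @return Score matrix, rows x `n_components`.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "cohort_matrix")) newdata <- newdata$X
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != length(object$mean_vector)) {
    abort(sprintf("column mismatch: model has %d features, data has %d.",
                  length(object$mean_vector), ncol(newdata)))
  }
  scores <- sweep(newdata, 2, object$mean_vector) %*% t(object$components)
  colnames(scores) <- paste0("pc_", seq_len(object$n_components))
  scores
}

#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance_ratio),
         explained_variance_ratio = x$explained_variance_ratio,
         cumulative = cumsum(x$explained_variance_ratio),
         kept = seq_along(x$explained_variance_ratio) <= x$n_components)
}

#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_components = x$n_components,
         variance_target = x$variance_target,
         variance_kept = sum(x$explained_variance_ratio[seq_len(x$n_components)]))
}
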