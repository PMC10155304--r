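#' Canonical composite order keys
#'
#' Collapses a medication order's identifying fields (drug, dose, strength,
#' formulation, route) into one canonical key, so that the same order written
#' with different casing or spacing maps to the same exposure column while
#' genuinely different orders (e.g. two dose levels of the same drug) stay
#' distinct. Fields are case-folded, internal whitespace is collapsed to a
#' single space, and the fields are joined with `|`.
#'
#' @param orders A data frame with character columns `drug`, `dose`,
#'   `strength`, `formulation`, `route` (missing columns are treated as
#'   empty), or a single named list with those fields.
#' @return A character vector of canonical keys, one per order row.
#' @export
#' @examples
#' build_order_key(data.frame(drug = "Cefepime", dose = "2 G", strength = "",
#'                            formulation = "IVPB", route = "IV"))
build_order_key <- function(orders) {
  if (!is.data.frame(orders)) orders <- as_tibble(as.list(orders))
  fields <- c("drug", "dose", "strength", "formulation", "route")
  canon <- lapply(fields, function(f) {
    x <- if (f %in% names(orders)) as.character(orders[[f]]) else rep("", nrow(orders))
    x[is.na(x)] <- ""
    x <- stringr::str_squish(stringr::str_to_lower(x))
    x
  })
  if (any(canon[[1]] == "")) {
    abort("`drug` must be nonempty for every order.")
  }
  do.call(paste, c(canon, sep = "|"))
}

#' Encode a binary patient-by-order exposure matrix
#'
#' Converts long medication administration records into the binary cohort
#' matrix the phenotyping workflow consumes: entry `(i, m)` is 1 when patient
#' `i` received at least one order with canonical key `m` in the observation
#' window, 0 otherwise. Duplicate administrations of the same order collapse
#' to a single exposure; unknown or missing fields canonicalize to empty and
#' therefore count as absences of any more specific order. Columns are sorted
#' lexicographically by key and rows by patient id, so the matrix is stable
#' across row orderings of the input.
#'
#' @param mar Long-format order table with a `patient_id` column and the
#'   order fields of [build_order_key()].
#' @return An object of class `cohort_matrix`: list with `patients`,
#'   `order_keys` and the binary matrix `X` (patients x keys, dimnames set).
#' @export
encode_matrix <- function(mar) {
  stopifnot(is.data.frame(mar))
  if (nrow(mar) == 0) {
    return(new_cohort_matrix(matrix(0, 0, 0)))
  }
  if (!"patient_id" %in% names(mar)) abort("`mar` needs a `patient_id` column.")
  if ("admin_time_h" %in% names(mar)) {
    t <- mar$admin_time_h
    if (any(!is.na(t) & (t < 0 | t > 24))) {
      abort("`admin_time_h` must lie in [0, 24] when present.")
    }
  }
  keys <- build_order_key(mar)
  pid <- as.character(mar$patient_id)
  patients <- sort(unique(pid))
  order_keys <- sort(unique(keys))
  X <- matrix(0, nrow = length(patients), ncol = length(order_keys),
              dimnames = list(patients, order_keys))
  X[cbind(match(pid, patients), match(keys, order_keys))] <- 1
  new_cohort_matrix(X)
}

new_cohort_matrix <- function(X) {
  structure(
    list(patients = rownames(X) %||% character(0),
         order_keys = colnames(X) %||% character(0),
         X = X),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d patients x %d order keys, density %.3f\n",
              nrow(x$X), ncol(x$X),
              if (length(x$X)) mean(x$X) else 0))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$X)

#' Weighted medication-regimen complexity score
#'
#' Computes a per-patient weighted sum over the exposure matrix,
#' `score_i = sum_m X[i, m] * w(m)`, the generic form of published
#' regimen-complexity scores such as MRC-ICU. The weight table is
#' user-supplied; order keys without a weight contribute 0 (their count is
#' reported via a message).
#'
#' @param matrix A [encode_matrix()] result.
#' @param weights Named numeric vector or two-column data frame
#'   (`order_key`, `weight`) of nonnegative weights.
#' @return A tibble with `patient_id` and `complexity`.
#' @export
regimen_complexity <- function(matrix, weights) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (is.data.frame(weights)) {
    weights <- setNames(weights$weight, weights$order_key)
  }
  if (any(weights < 0)) abort("weights must be nonnegative.")
  w <- weights[matrix$order_keys]
  n_missing <- sum(is.na(w))
  if (n_missing > 0) {
    inform(sprintf("%d order keys without a weight contribute 0.", n_missing))
    w[is.na(w)] <- 0
  }
  tibble(patient_id = matrix$patients,
         complexity = as.numeric(matrix$X %*% w))
}

#' Write or read a cohort matrix as TSV
#'
#' The wide layout has one row per patient (first column `patient_id`, then
#' one 0/1 column per canonical order key).
#'
#' @param matrix A `cohort_matrix`.
#' @param path Output/input TSV path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  df <- as_tibble(matrix$X, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(patient_id = matrix$patients), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$patient_id
  new_cohort_matrix(X)
}
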