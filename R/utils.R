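# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a master seed and a stream label.
# Keeps per-patient / per-stage draws reproducible independently of call order.
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }, numeric(1))
  x <- (as.numeric(seed) %% 2147483647)
  for (p in parts) {
    x <- (x * 69069 + p * 104729 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_binary_matrix <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (anyNA(X) || !all(X %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (entries 0/1, no missing values).", name))
  }
  invisible(X)
}

phenotype_cols <- function(k) paste0("phenotype_", seq_len(k + 1L))
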