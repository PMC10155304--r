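#' Two-sample rank-sum test (Mann-Whitney U)
#'
#' Compares a continuous outcome between two independent patient groups.
#' Ties get midranks; the p-value is exact (full enumeration) when the
#' pooled sample size is at most 12 and there are no ties, and otherwise
#' uses the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `n_x`, `n_y`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups need at least one non-missing value.")
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  n_x = length(x), n_y = length(y), method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && length(pooled) <= 12
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_x = length(x), n_y = length(y),
         method = if (use_exact) "exact" else "normal")
}

#' Wilcoxon signed-rank test (paired utility)
#'
#' Paired-sample companion to [rank_sum_test()]. Patient-cluster comparisons
#' are between independent groups, so the pipeline itself uses the rank-sum
#' test; the signed-rank test is exposed for paired analyses of the same
#' patients.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return One-row tibble: `statistic`, `p_value`, `n`.
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  keep <- !is.na(x) & !is.na(y)
  wt <- suppressWarnings(stats::wilcox.test(x[keep], y[keep], paired = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value, n = sum(keep))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration over the fixed margins
#' using the point-probability rule (every table whose probability does not
#' exceed the observed table's, within a `1 + 1e-7` slack, contributes).
#' The reported odds ratio is the sample odds ratio `ad/bc` (infinite when
#' `bc = 0` and `ad > 0`).
#'
#' @param a,b,c,d Nonnegative integer cell counts, laid out as
#'   rows = groups, columns = event / non-event.
#' @return One-row tibble: `odds_ratio`, `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts))) {
    abort("cell counts must be nonnegative integers.")
  }
  if (sum(counts) == 0) abort("at least one margin must be positive.")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NaN
  tibble(odds_ratio = or, p_value = min(p, 1))
}

#' Holm step-down familywise adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by cumulative maximum, caps at 1, and
#' returns the adjusted values in the original order.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  stats::p.adjust(p, method = "holm")
}

#' Pairwise patient-cluster outcome comparisons
#'
#' Runs every unordered pair of patient clusters against every outcome:
#' rank-sum tests for continuous outcomes, Fisher's exact tests for
#' categorical (0/1) outcomes, with missing values excluded per outcome.
#' Holm adjustment is applied within each outcome family across its cluster
#' pairs, controlling the familywise error rate per outcome. Both raw and
#' adjusted p-values are reported.
#'
#' @param labels Tibble `patient_id`, `cluster` (from [cut_tree()]).
#' @param outcomes Tibble with `patient_id` and one column per outcome.
#' @param outcome_spec Named character vector mapping outcome column names to
#'   `"continuous"` or `"categorical"` (or a tibble with columns `outcome`,
#'   `type`).
#' @param alpha Significance level recorded on the result; default 0.05.
#' @return A tibble of class `comparison_table`: `outcome`, `test`,
#'   `cluster_a`, `cluster_b`, `n_a`, `n_b`, `statistic`, `p_raw`, `p_holm`.
#'   Pairs where one cluster has no non-missing values get `NA` p-values.
#' @export
pairwise_compare <- function(labels, outcomes, outcome_spec, alpha = 0.05) {
  stopifnot(is.data.frame(labels), is.data.frame(outcomes))
  if (is.data.frame(outcome_spec)) {
    outcome_spec <- setNames(outcome_spec$type, outcome_spec$outcome)
  }
  if (!all(outcome_spec %in% c("continuous", "categorical"))) {
    abort("outcome types must be 'continuous' or 'categorical'.")
  }
  missing_cols <- setdiff(names(outcome_spec), names(outcomes))
  if (length(missing_cols) > 0) {
    abort(sprintf("outcome column(s) not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- dplyr::inner_join(labels, outcomes, by = "patient_id")
  clusters <- sort(unique(df$cluster))
  if (length(clusters) < 2) abort("need at least two clusters to compare.")
  pairs <- utils::combn(clusters, 2, simplify = FALSE)

  res <- purrr::map_dfr(names(outcome_spec), function(nm) {
    type <- outcome_spec[[nm]]
    purrr::map_dfr(pairs, function(pr) {
      va <- df[[nm]][df$cluster == pr[1]]
      vb <- df[[nm]][df$cluster == pr[2]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) == 0 || length(vb) == 0) {
        inform(sprintf("outcome '%s', pair %d-%d: no data in one cluster; skipped.",
                       nm, pr[1], pr[2]))
        return(tibble(outcome = nm,
                      test = if (type == "continuous") "rank_sum" else "fisher_exact",
                      cluster_a = pr[1], cluster_b = pr[2],
                      n_a = length(va), n_b = length(vb),
                      statistic = NA_real_, p_raw = NA_real_))
      }
      if (type == "continuous") {
        t <- rank_sum_test(va, vb)
        tibble(outcome = nm, test = "rank_sum",
               cluster_a = pr[1], cluster_b = pr[2],
               n_a = t$n_x, n_b = t$n_y,
               statistic = t$statistic, p_raw = t$p_value)
      } else {
        t <- fisher_exact_2x2(sum(va == 1), sum(va == 0),
                              sum(vb == 1), sum(vb == 0))
        tibble(outcome = nm, test = "fisher_exact",
               cluster_a = pr[1], cluster_b = pr[2],
               n_a = length(va), n_b = length(vb),
               statistic = t$odds_ratio, p_raw = t$p_value)
      }
    })
  })

  res <- res |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(p_holm = {
      ok <- !is.na(.data$p_raw)
      out <- rep(NA_real_, dplyr::n())
      if (any(ok)) out[ok] <- holm_adjust(.data$p_raw[ok])
      out
    }) |>
    dplyr::ungroup()
  attr(res, "alpha") <- alpha
  class(res) <- c("comparison_table", class(res))
  res
}

#' @describeIn pairwise_compare Heatmap of Holm-adjusted p-values by cluster
#'   pair and outcome.
#' @param object A `comparison_table`.
#' @param ... Unused.
#' @method autoplot comparison_table
#' @export
autoplot.comparison_table <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(pair = paste0(.data$cluster_a, "-", .data$cluster_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$outcome,
                                   fill = .data$p_holm)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "white",
                                 limits = c(0, 1), name = "Holm p") +
    ggplot2::labs(x = "cluster pair", y = NULL,
                  title = "Pairwise cluster-outcome comparisons") +
    ggplot2::theme_minimal()
}

#' Pool per-cluster summary rows into a cohort total
#'
#' Combines per-cluster descriptive cells (mean for continuous outcomes,
#' event count with its denominator for categorical outcomes) into the
#' pooled-cohort column: the pooled `n` is the sum of cluster sizes, the
#' pooled mean is the size-weighted mean of cluster means, and pooled
#' percentages use summed counts over summed denominators. Means and
#' percentages are rounded to one decimal for reporting.
#'
#' @param per_cluster Long tibble with one row per cluster and outcome:
#'   columns `cluster`, `n` (cluster size), `outcome`, `type` (`"continuous"`
#'   or `"categorical"`), `mean` (continuous), `count` and `denom`
#'   (categorical; `denom` defaults to `n` when `NA`).
#' @return A tibble with one row per outcome: `outcome`, `type`, `n_total`,
#'   `mean` (pooled, 1 decimal), `count`, `denom`, `pct` (1 decimal).
#' @export
pooled_summary <- function(per_cluster) {
  need <- c("cluster", "n", "outcome", "type")
  if (!is.data.frame(per_cluster) || !all(need %in% names(per_cluster))) {
    abort("`per_cluster` needs columns cluster, n, outcome, type.")
  }
  if (any(per_cluster$n <= 0)) abort("cluster sizes must be positive.")
  sizes <- dplyr::distinct(per_cluster, .data$cluster, .data$n)
  n_total <- sum(sizes$n)

  purrr::map_dfr(unique(per_cluster$outcome), function(nm) {
    rows <- per_cluster[per_cluster$outcome == nm, ]
    type <- rows$type[1]
    if (type == "continuous") {
      tibble(outcome = nm, type = type, n_total = n_total,
             mean = round(sum(rows$n * rows$mean) / sum(rows$n), 1),
             count = NA_integer_, denom = NA_integer_, pct = NA_real_)
    } else {
      denom <- if ("denom" %in% names(rows)) {
        ifelse(is.na(rows$denom), rows$n, rows$denom)
      } else rows$n
      if (any(is.na(denom))) {
        abort(sprintf("missing denominators for outcome '%s'.", nm))
      }
      tibble(outcome = nm, type = type, n_total = n_total,
             mean = NA_real_,
             count = as.integer(sum(rows$count)),
             denom = as.integer(sum(denom)),
             pct = round(100 * sum(rows$count) / sum(denom), 1))
    }
  })
}

#' Describe pharmacophenotypes by medication annotation
#'
#' Cross-tabulates phenotype membership against medication-level annotations
#' (e.g. drug class or route flags): for each phenotype, the number and
#' percentage of member order keys carrying each category. Keys without any
#' annotation are counted under `"unannotated"`.
#'
#' @param assignment A [assign_medications()] result.
#' @param annotations Tibble `order_key`, `category` (one row per key and
#'   category; may cover only some keys), or `NULL`.
#' @return Tibble `phenotype`, `category`, `n`, `pct`, `phenotype_size`
#'   (percentages over the phenotype's member-key count).
#' @export
phenotype_profile <- function(assignment, annotations = NULL) {
  stopifnot(inherits(assignment, "phenotype_assignment"))
  members <- as_tibble(assignment)[, c("order_key", "phenotype")]
  sizes <- members |>
    dplyr::count(.data$phenotype, name = "phenotype_size")
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- tibble(order_key = character(0), category = character(0))
  }
  annotated_keys <- unique(annotations$order_key)
  ann <- dplyr::bind_rows(
    annotations[, c("order_key", "category")],
    tibble(order_key = setdiff(unique(members$order_key), annotated_keys),
           category = "unannotated")
  )
  members |>
    dplyr::inner_join(ann, by = "order_key",
                      relationship = "many-to-many") |>
    dplyr::count(.data$phenotype, .data$category, name = "n") |>
    dplyr::left_join(sizes, by = "phenotype") |>
    dplyr::mutate(pct = round(100 * .data$n / .data$phenotype_size, 1)) |>
    dplyr::arrange(.data$phenotype, dplyr::desc(.data$n))
}
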