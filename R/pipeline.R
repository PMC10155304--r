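#' Configure the pharmacophenotyping pipeline
#'
#' Collects every stage parameter of the end-to-end workflow
#' (simulate/load -> encode -> PCA -> RBM -> assign -> distribute -> cluster
#' -> compare -> report) with defaults mirroring the reference analysis:
#' 5 hidden units trained for 5000 epochs, activation threshold 0.5, a 70%
#' explained-variance PCA target capped at 150 components, Ward linkage, and
#' 5 patient clusters with Holm-adjusted pairwise tests at alpha 0.05.
#'
#' @param input_dir Directory containing `mar.csv` and `outcomes.csv`; when
#'   `NULL`, a synthetic cohort is generated from `spec`.
#' @param spec A [synthetic_spec()] used when simulating (default: the
#'   standard synthetic cohort with `seed` as its master seed).
#' @param K,epochs,learning_rate,cd_steps,batch_size,tau RBM stage
#'   parameters (see [train_rbm()] and [assign_medications()]).
#' @param exclusive Assign each medication only to its top phenotype.
#' @param variance_target,max_components PCA stage parameters.
#' @param linkage Linkage for [hac()].
#' @param n_clusters Number of patient clusters, or `"auto"` to use
#'   [suggest_k()].
#' @param alpha Significance level for the comparison stage.
#' @param distribution_mode `"fractional"` or `"full"` (see
#'   [phenotype_distribution()]).
#' @param cluster_features `"distributions"` (default: cluster the normalized
#'   phenotype distributions) or `"pca"` (cluster PCA scores of the exposure
#'   matrix).
#' @param outcome_spec Named character vector of outcome types; `NULL` infers
#'   it from the data (0/1 columns are categorical, the rest continuous).
#' @param seed Master seed; per-stage seeds are derived from it so stages are
#'   individually reproducible.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            spec = NULL,
                            K = 5, epochs = 5000, learning_rate = 0.05,
                            cd_steps = 1, batch_size = 32, tau = 0.5,
                            exclusive = FALSE,
                            variance_target = 0.70, max_components = 150,
                            linkage = "ward",
                            n_clusters = 5,
                            alpha = 0.05,
                            distribution_mode = "fractional",
                            cluster_features = c("distributions", "pca"),
                            outcome_spec = NULL,
                            seed = 1) {
  cluster_features <- match.arg(cluster_features)
  if (is.null(input_dir) && is.null(spec)) {
    spec <- synthetic_spec(seed = derive_seed(seed, "cohort"))
  }
  structure(
    list(input_dir = input_dir, spec = spec,
         K = as.integer(K), epochs = as.integer(epochs),
         learning_rate = learning_rate, cd_steps = as.integer(cd_steps),
         batch_size = as.integer(batch_size), tau = tau,
         exclusive = isTRUE(exclusive),
         variance_target = variance_target,
         max_components = max_components,
         linkage = linkage, n_clusters = n_clusters, alpha = alpha,
         distribution_mode = distribution_mode,
         cluster_features = cluster_features,
         outcome_spec = outcome_spec,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

infer_outcome_spec <- function(outcomes) {
  cols <- setdiff(names(outcomes), "patient_id")
  types <- vapply(cols, function(nm) {
    v <- outcomes[[nm]]
    v <- v[!is.na(v)]
    if (length(v) > 0 && all(v %in% c(0, 1))) "categorical" else "continuous"
  }, character(1))
  setNames(types, cols)
}

#' Run the full pharmacophenotyping pipeline
#'
#' Executes every stage in order and writes each stage's interface files to
#' `output_dir`: the cohort CSVs (when simulated), the binary exposure matrix
#' (`matrix.tsv`), PCA scores (`pca_scores.tsv`), the trained RBM
#' (`rbm_model.json`) and its training trace (`rbm_trace.tsv`), phenotype
#' assignments (`assignment.csv`), per-patient phenotype distributions
#' (`distributions.tsv`), the linkage matrix (`linkage.tsv`), cluster labels
#' (`labels.csv`), pairwise comparisons (`comparisons.tsv`), the per-cluster
#' plus pooled summary (`summary.tsv`), per-cluster mean phenotype
#' distributions (`radar.csv`) and the effective configuration
#' (`config.json`). Identical configuration and seed reproduce identical
#' outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Run directory (created if needed).
#' @return Invisibly, a `pipeline_result` list with the in-memory stage
#'   objects (`matrix`, `pca`, `rbm`, `assignment`, `distributions`, `tree`,
#'   `labels`, `comparisons`, `summary`, `radar`, `k_suggestion`) and the
#'   output `paths`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)

  # -- cohort ----------------------------------------------------------------
  if (is.null(config$input_dir)) {
    cohort <- generate_cohort(config$spec)
    write_cohort(cohort, output_dir)
    mar <- cohort$mar
    outcomes <- cohort$outcomes
  } else {
    mar <- read_mar(file.path(config$input_dir, "mar.csv"))
    outcomes <- read_outcomes(file.path(config$input_dir, "outcomes.csv"))
  }

  # -- encode ----------------------------------------------------------------
  matrix <- encode_matrix(mar)
  write_matrix_tsv(matrix, p("matrix.tsv"))

  # -- dimensionality reduction ---------------------------------------------
  pca <- fit_pca(matrix, variance_target = config$variance_target,
                 max_components = config$max_components)
  scores <- predict(pca, matrix)
  readr::write_tsv(
    dplyr::bind_cols(tibble(patient_id = matrix$patients),
                     as_tibble(scores)),
    p("pca_scores.tsv")
  )

  # -- RBM phenotyping -------------------------------------------------------
  rbm <- train_rbm(matrix, K = config$K, epochs = config$epochs,
                   learning_rate = config$learning_rate,
                   cd_steps = config$cd_steps,
                   batch_size = config$batch_size,
                   seed = derive_seed(config$seed, "rbm"))
  write_rbm_json(rbm, p("rbm_model.json"))
  readr::write_tsv(rbm$training_trace, p("rbm_trace.tsv"))

  assignment <- assign_medications(rbm, matrix, tau = config$tau,
                                   exclusive = config$exclusive)
  readr::write_csv(as_tibble(assignment), p("assignment.csv"))

  # -- phenotype distributions ----------------------------------------------
  distributions <- phenotype_distribution(matrix, assignment,
                                          mode = config$distribution_mode)
  readr::write_tsv(distributions, p("distributions.tsv"))

  # -- patient clustering ----------------------------------------------------
  features <- if (config$cluster_features == "pca") {
    dplyr::bind_cols(tibble(patient_id = matrix$patients), as_tibble(scores))
  } else {
    dplyr::select(distributions, -"total_orders")
  }
  tree <- hac(features, linkage = config$linkage)
  readr::write_tsv(tidy(tree), p("linkage.tsv"))

  suggestion <- suggest_k(tree, k_max = max(10, if (is.numeric(config$n_clusters)) config$n_clusters else 0))
  if (identical(config$n_clusters, "auto")) {
    n_clusters <- suggestion$k
    readr::write_tsv(suggestion$gaps, p("k_gaps.tsv"))
  } else {
    n_clusters <- as.integer(config$n_clusters)
  }
  labels <- cut_tree(tree, n_clusters)
  readr::write_csv(labels, p("labels.csv"))

  # -- outcome comparisons ---------------------------------------------------
  outcome_spec <- config$outcome_spec %||% infer_outcome_spec(outcomes)
  comparisons <- pairwise_compare(labels, outcomes, outcome_spec,
                                  alpha = config$alpha)
  readr::write_tsv(as_tibble(comparisons), p("comparisons.tsv"))

  summary <- cluster_summary(labels, outcomes, outcome_spec)
  readr::write_tsv(summary, p("summary.tsv"))

  # -- report ----------------------------------------------------------------
  radar <- radar_table(labels, distributions)
  readr::write_csv(radar, p("radar.csv"))
  write_config_json(config, p("config.json"))

  invisible(structure(
    list(matrix = matrix, pca = pca, rbm = rbm, assignment = assignment,
         distributions = distributions, tree = tree, labels = labels,
         comparisons = comparisons, summary = summary, radar = radar,
         k_suggestion = suggestion, output_dir = output_dir),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d patients x %d order keys -> %d phenotypes, %d clusters\n",
              nrow(x$matrix$X), ncol(x$matrix$X),
              attr(x$assignment, "K") + 1L,
              dplyr::n_distinct(x$labels$cluster)))
  cat("outputs in ", x$output_dir, "\n", sep = "")
  invisible(x)
}

#' Per-cluster and pooled outcome summary
#'
#' Builds the per-cluster descriptive table (mean and SD for continuous
#' outcomes; event count, denominator and percentage for categorical
#' outcomes, with missing values excluded per outcome) and appends the
#' pooled-cohort column computed by [pooled_summary()] as `cluster = 0`.
#'
#' @inheritParams pairwise_compare
#' @return Long tibble: `cluster` (0 = pooled), `n`, `outcome`, `type`,
#'   `mean`, `sd`, `count`, `denom`, `pct`.
#' @export
cluster_summary <- function(labels, outcomes, outcome_spec) {
  if (is.data.frame(outcome_spec)) {
    outcome_spec <- setNames(outcome_spec$type, outcome_spec$outcome)
  }
  df <- dplyr::inner_join(labels, outcomes, by = "patient_id")
  sizes <- dplyr::count(df, .data$cluster, name = "n")

  per_cluster <- purrr::map_dfr(names(outcome_spec), function(nm) {
    type <- outcome_spec[[nm]]
    purrr::map_dfr(sizes$cluster, function(cl) {
      v <- df[[nm]][df$cluster == cl]
      n_cl <- sizes$n[sizes$cluster == cl]
      ok <- !is.na(v)
      if (type == "continuous") {
        tibble(cluster = cl, n = n_cl, outcome = nm, type = type,
               mean = round(mean(v[ok]), 1), sd = round(sd(v[ok]), 1),
               count = NA_integer_, denom = NA_integer_, pct = NA_real_)
      } else {
        tibble(cluster = cl, n = n_cl, outcome = nm, type = type,
               mean = NA_real_, sd = NA_real_,
               count = as.integer(sum(v[ok] == 1)),
               denom = as.integer(sum(ok)),
               pct = round(100 * sum(v[ok] == 1) / max(sum(ok), 1), 1))
      }
    })
  })

  pooled <- pooled_summary(per_cluster) |>
    dplyr::transmute(cluster = 0L, n = .data$n_total, outcome = .data$outcome,
                     type = .data$type, mean = .data$mean, sd = NA_real_,
                     count = .data$count, denom = .data$denom, pct = .data$pct)
  dplyr::bind_rows(per_cluster, pooled) |>
    dplyr::arrange(.data$outcome, .data$cluster)
}

#' Mean phenotype distribution per patient cluster
#'
#' The table behind the phenotype radar chart: one row per patient cluster,
#' one column per pharmacophenotype, each value the mean of the member
#' patients' normalized phenotype frequencies. Under fractional-membership
#' distributions every row is itself a probability vector.
#'
#' @param labels Tibble `patient_id`, `cluster`.
#' @param distributions A [phenotype_distribution()] table covering the same
#'   patients.
#' @return Tibble of class `radar_table`: `cluster`, `n`, then one column per
#'   phenotype. Clusters without member distributions yield `NaN` rows with a
#'   warning.
#' @export
radar_table <- function(labels, distributions) {
  pcols <- grep("^phenotype_", names(distributions), value = TRUE)
  joined <- dplyr::left_join(labels, distributions, by = "patient_id")
  if (anyNA(joined[[pcols[1]]])) {
    warn("some clusters have patients without phenotype distributions.")
  }
  out <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(pcols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::arrange(.data$cluster)
  class(out) <- c("radar_table", class(out))
  out
}

#' @describeIn radar_table Line/point profile plot of the per-cluster mean
#'   phenotype distributions (flat analog of the radar chart).
#' @param object A `radar_table`.
#' @param ... Unused.
#' @method autoplot radar_table
#' @export
autoplot.radar_table <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::starts_with("phenotype_"),
                        names_to = "phenotype", values_to = "mean_share") |>
    dplyr::mutate(phenotype = as.integer(sub("phenotype_", "", .data$phenotype)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$mean_share,
                                   color = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$phenotype)) +
    ggplot2::labs(x = "pharmacophenotype", y = "mean normalized share",
                  color = "patient cluster",
                  title = "Mean phenotype distribution per patient cluster") +
    ggplot2::theme_minimal()
}

#' Serialize an RBM model to JSON
#'
#' Plain-text archive of the trained parameters, hyperparameters and
#' training trace; `read_rbm_json()` restores a model that reproduces
#' activations exactly (parameters are stored at full double precision).
#'
#' @param model An `rbm_model`.
#' @param path JSON file path.
#' @export
write_rbm_json <- function(model, path) {
  stopifnot(inherits(model, "rbm_model"))
  payload <- list(
    W = model$W, b = model$b, c = model$c, K = model$K, M = model$M,
    order_keys = model$order_keys,
    epochs = model$epochs, learning_rate = model$learning_rate,
    cd_steps = model$cd_steps, batch_size = model$batch_size,
    seed = model$seed,
    training_trace = model$training_trace
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_rbm_json
#' @export
read_rbm_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(W = matrix(as.numeric(raw$W), nrow = raw$K, byrow = FALSE),
         b = as.numeric(raw$b), c = as.numeric(raw$c),
         K = as.integer(raw$K), M = as.integer(raw$M),
         order_keys = if (is.null(raw$order_keys)) NULL else as.character(raw$order_keys),
         epochs = as.integer(raw$epochs),
         learning_rate = raw$learning_rate,
         cd_steps = as.integer(raw$cd_steps),
         batch_size = as.integer(raw$batch_size),
         seed = as.integer(raw$seed),
         training_trace = as_tibble(raw$training_trace)),
    class = "rbm_model"
  )
}

write_config_json <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$spec)) {
    sp <- unclass(cfg$spec)
    sp$mixing <- apply(sp$mixing, 1, as.numeric, simplify = FALSE)
    sp$outcome_effects <- as.data.frame(sp$outcome_effects)
    cfg$spec <- sp
  }
  jsonlite::write_json(cfg, path, digits = NA, auto_unbox = TRUE,
                       null = "null", dataframe = "columns")
  invisible(path)
}
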