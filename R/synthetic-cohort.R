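#' Specify a synthetic ICU medication cohort
#'
#' Defines the generative model for a synthetic cohort with planted structure:
#' medications are partitioned into latent groups, each patient belongs to one
#' of several archetypes, and an archetype is characterized by a mixing
#' distribution over medication groups. Orders are drawn group-first, then a
#' medication uniformly within the group; a small noise rate replaces a drawn
#' medication with a uniformly random one. Outcomes are archetype-conditional
#' (Normal for continuous, Bernoulli for categorical), so downstream medication
#' clustering, patient clustering and outcome comparisons all have a known
#' ground truth to recover.
#'
#' @param n_patients Number of patients.
#' @param n_medications Number of distinct medication order keys in the
#'   formulary.
#' @param n_groups Number of planted medication groups (the analog of the
#'   hidden-unit count `K` used for phenotyping).
#' @param n_archetypes Number of planted patient archetypes (the analog of the
#'   patient clusters).
#' @param mixing `n_archetypes` x `n_groups` matrix of nonnegative weights;
#'   each row is normalized to a probability vector over medication groups.
#'   Default: 0.8 on the (wrapped) diagonal, the remaining 0.2 spread evenly.
#' @param orders_per_patient_mean Mean of the per-patient order count,
#'   `n_i ~ max(1, Poisson(mean))`. The default 20 mirrors a realistic ICU
#'   first-24-h order volume relative to a 100-medication formulary (roughly
#'   the orders-to-formulary ratio seen in real MAR extracts).
#' @param noise_rate Probability that a drawn medication is replaced by one
#'   sampled uniformly from the whole formulary.
#' @param outcome_effects Long tibble with columns `outcome`, `type`
#'   (`"continuous"` or `"categorical"`), `archetype`, `mean` (for categorical
#'   outcomes the event probability) and `sd` (`NA` for categorical). Defaults
#'   to [default_outcome_effects()].
#' @param seed Integer master seed; every random draw derives from it.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [generate_formulary()], [write_cohort()]
#' @export
#' @examples
#' spec <- synthetic_spec(n_patients = 50, n_medications = 20, seed = 1)
#' cohort <- generate_cohort(spec)
#' dplyr::count(cohort$truth_archetypes, archetype)
synthetic_spec <- function(n_patients = 500,
                           n_medications = 100,
                           n_groups = 5,
                           n_archetypes = 5,
                           mixing = NULL,
                           orders_per_patient_mean = 20,
                           noise_rate = 0.05,
                           outcome_effects = NULL,
                           seed = 1) {
  assert_scalar_number(n_patients, "n_patients", lower = 1)
  assert_scalar_number(n_medications, "n_medications", lower = 1)
  assert_scalar_number(n_groups, "n_groups", lower = 1)
  assert_scalar_number(n_archetypes, "n_archetypes", lower = 1)
  assert_scalar_number(orders_per_patient_mean, "orders_per_patient_mean",
                       lower = .Machine$double.eps)
  assert_scalar_number(noise_rate, "noise_rate", lower = 0, upper = 1)
  assert_scalar_number(seed, "seed")
  if (n_groups > n_medications) {
    abort("`n_groups` must not exceed `n_medications`.")
  }

  if (is.null(mixing)) {
    mixing <- diag_dominant_mixing(n_archetypes, n_groups, weight = 0.8)
  }
  mixing <- as.matrix(mixing)
  if (!identical(dim(mixing), c(as.integer(n_archetypes), as.integer(n_groups)))) {
    abort("`mixing` must be an n_archetypes x n_groups matrix.")
  }
  if (anyNA(mixing) || any(mixing < 0)) {
    abort("`mixing` entries must be nonnegative and non-missing.")
  }
  if (any(rowSums(mixing) <= 0)) {
    abort("every `mixing` row needs at least one positive entry.")
  }
  mixing <- mixing / rowSums(mixing)

  if (is.null(outcome_effects)) {
    outcome_effects <- default_outcome_effects(n_archetypes)
  }
  validate_outcome_effects(outcome_effects, n_archetypes)

  structure(
    list(
      n_patients = as.integer(n_patients),
      n_medications = as.integer(n_medications),
      n_groups = as.integer(n_groups),
      n_archetypes = as.integer(n_archetypes),
      mixing = mixing,
      orders_per_patient_mean = orders_per_patient_mean,
      noise_rate = noise_rate,
      outcome_effects = outcome_effects,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Row-stochastic mixing with `weight` on the wrapped diagonal.
diag_dominant_mixing <- function(n_archetypes, n_groups, weight = 0.8) {
  off <- if (n_groups > 1) (1 - weight) / (n_groups - 1) else 0
  m <- matrix(off, nrow = n_archetypes, ncol = n_groups)
  for (a in seq_len(n_archetypes)) {
    m[a, ((a - 1L) %% n_groups) + 1L] <- if (n_groups > 1) weight else 1
  }
  m
}

#' Archetype-conditional outcome effects
#'
#' `default_outcome_effects()` plants archetype differences typical of an ICU
#' cohort: severity scores (APACHE II, MRC-ICU), ICU length of stay and
#' vasopressor duration as continuous outcomes, and mortality, acute kidney
#' injury and mechanical-ventilation presence as categorical outcomes.
#' `null_outcome_effects()` gives every archetype the pooled value, so no
#' outcome differs between archetypes — the null configuration used to check
#' familywise type-I error control.
#'
#' @param n_archetypes Number of archetypes; base profiles are recycled when
#'   it is not 5.
#' @return A tibble with columns `outcome`, `type`, `archetype`, `mean`, `sd`.
#' @export
default_outcome_effects <- function(n_archetypes = 5) {
  cont <- list(
    apache_ii        = list(mean = c(13.5, 15.7, 14.6, 13.3, 14.7), sd = 6.4),
    mrc_icu          = list(mean = c(9.4, 11.6, 10.0, 10.1, 11.2), sd = 7.7),
    icu_los_days     = list(mean = c(6.2, 5.6, 4.7, 4.3, 3.6), sd = 4.0),
    vasopressor_days = list(mean = c(2.1, 1.4, 1.5, 2.1, 1.2), sd = 1.4)
  )
  cat <- list(
    mortality        = c(0.099, 0.058, 0.118, 0.132, 0.081),
    aki              = c(0.172, 0.115, 0.175, 0.181, 0.115),
    mech_ventilation = c(0.299, 0.435, 0.262, 0.257, 0.333)
  )
  rows_c <- purrr::imap(cont, function(x, nm) {
    tibble(outcome = nm, type = "continuous",
           archetype = seq_len(n_archetypes),
           mean = rep_len(x$mean, n_archetypes), sd = x$sd)
  })
  rows_k <- purrr::imap(cat, function(p, nm) {
    tibble(outcome = nm, type = "categorical",
           archetype = seq_len(n_archetypes),
           mean = rep_len(p, n_archetypes), sd = NA_real_)
  })
  dplyr::bind_rows(unname(rows_c), unname(rows_k))
}

#' @rdname default_outcome_effects
#' @export
null_outcome_effects <- function(n_archetypes = 5) {
  default_outcome_effects(n_archetypes) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(mean = mean(.data$mean)) |>
    dplyr::ungroup()
}

validate_outcome_effects <- function(x, n_archetypes) {
  need <- c("outcome", "type", "archetype", "mean", "sd")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort("`outcome_effects` needs columns outcome, type, archetype, mean, sd.")
  }
  if (!all(x$type %in% c("continuous", "categorical"))) {
    abort("`outcome_effects$type` must be 'continuous' or 'categorical'.")
  }
  counts <- dplyr::count(x, .data$outcome)
  if (!all(counts$n == n_archetypes)) {
    abort("each outcome needs exactly one `outcome_effects` row per archetype.")
  }
  bad_p <- x$type == "categorical" & (x$mean < 0 | x$mean > 1)
  if (any(bad_p)) abort("categorical outcome probabilities must lie in [0, 1].")
  invisible(x)
}

#' Generate the synthetic formulary with planted medication groups
#'
#' Builds `n_medications` distinct medication orders and assigns each to one
#' planted group round-robin, so group sizes differ by at most one.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with one row per medication: the order fields (`drug`,
#'   `dose`, `strength`, `formulation`, `route`), the canonical `order_key`,
#'   and the planted `group`.
#' @export
generate_formulary <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  i <- seq_len(spec$n_medications)
  meds <- tibble(
    drug = sprintf("med%04d", i),
    dose = paste0(((i - 1L) %% 10L + 1L) * 10L, " mg"),
    strength = "",
    formulation = "inj",
    route = "iv",
    group = ((i - 1L) %% spec$n_groups) + 1L
  )
  meds$order_key <- build_order_key(meds)
  meds[, c("drug", "dose", "strength", "formulation", "route", "order_key", "group")]
}

#' Generate a synthetic cohort
#'
#' Draws the full cohort defined by a [synthetic_spec()]: one archetype per
#' patient (uniform), a truncated-Poisson number of orders, group-then-drug
#' order sampling with uniform noise replacement, and archetype-conditional
#' outcomes. Per-patient draws use sub-seeds derived from the master seed, so
#' any patient's records are reproducible in isolation.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_cohort`: a list with tibbles `mar`
#'   (long medication administration records), `outcomes` (one row per
#'   patient), `truth_med_groups` (`order_key`, `group`) and
#'   `truth_archetypes` (`patient_id`, `archetype`), plus the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  formulary <- generate_formulary(spec)
  patient_id <- sprintf("p%04d", seq_len(spec$n_patients))

  archetype <- with_seed(
    derive_seed(spec$seed, "archetypes"),
    sample.int(spec$n_archetypes, spec$n_patients, replace = TRUE)
  )

  mar_rows <- purrr::map(seq_len(spec$n_patients), function(i) {
    with_seed(derive_seed(spec$seed, "patient", i), {
      n_i <- max(1L, rpois(1L, spec$orders_per_patient_mean))
      grp <- sample.int(spec$n_groups, n_i, replace = TRUE,
                        prob = spec$mixing[archetype[i], ])
      med_idx <- vapply(grp, function(g) {
        members <- which(formulary$group == g)
        members[sample.int(length(members), 1L)]
      }, integer(1))
      flip <- runif(n_i) < spec$noise_rate
      if (any(flip)) {
        med_idx[flip] <- sample.int(spec$n_medications, sum(flip), replace = TRUE)
      }
      out <- formulary[med_idx, c("drug", "dose", "strength", "formulation", "route")]
      out$patient_id <- patient_id[i]
      out$admin_time_h <- round(runif(n_i, 0, 24), 3)
      out
    })
  })
  mar <- dplyr::bind_rows(mar_rows)[, c("patient_id", "drug", "dose", "strength",
                                        "formulation", "route", "admin_time_h")]

  eff <- spec$outcome_effects
  outcomes <- tibble(patient_id = patient_id)
  for (nm in unique(eff$outcome)) {
    rows <- eff[eff$outcome == nm, ]
    rows <- rows[order(rows$archetype), ]
    vals <- with_seed(derive_seed(spec$seed, "outcome", nm), {
      if (rows$type[1] == "continuous") {
        round(rnorm(spec$n_patients,
                    mean = rows$mean[archetype],
                    sd = rows$sd[archetype]), 4)
      } else {
        rbinom(spec$n_patients, 1L, rows$mean[archetype])
      }
    })
    outcomes[[nm]] <- vals
  }

  structure(
    list(
      mar = mar,
      outcomes = outcomes,
      truth_med_groups = formulary[, c("order_key", "group")],
      truth_archetypes = tibble(patient_id = patient_id, archetype = archetype),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d orders, %d medications\n",
    nrow(x$outcomes), nrow(x$mar), nrow(x$truth_med_groups)
  ))
  invisible(x)
}

#' Write and read a synthetic cohort as CSV
#'
#' `write_cohort()` writes `mar.csv`, `outcomes.csv` and `truth.csv`
#' (UTF-8, comma-separated, header row; `truth.csv` holds both medication
#' group and patient archetype labels as `entity_type,key,label` rows).
#' `read_mar()`, `read_outcomes()` and `read_truth()` read the individual
#' files back; `read_cohort()` reassembles the full cohort from a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @return `write_cohort()` invisibly returns the named file paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(
    mar = file.path(directory, "mar.csv"),
    outcomes = file.path(directory, "outcomes.csv"),
    truth = file.path(directory, "truth.csv")
  )
  readr::write_csv(cohort$mar, paths[["mar"]])
  readr::write_csv(cohort$outcomes, paths[["outcomes"]])
  truth <- dplyr::bind_rows(
    tibble(entity_type = "medication",
           key = cohort$truth_med_groups$order_key,
           label = as.integer(cohort$truth_med_groups$group)),
    tibble(entity_type = "patient",
           key = cohort$truth_archetypes$patient_id,
           label = as.integer(cohort$truth_archetypes$archetype))
  )
  readr::write_csv(truth, paths[["truth"]])
  invisible(paths)
}

#' @rdname write_cohort
#' @param path Path to a single CSV file.
#' @export
read_mar <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      drug = readr::col_character(),
      dose = readr::col_character(),
      strength = readr::col_character(),
      formulation = readr::col_character(),
      route = readr::col_character(),
      admin_time_h = readr::col_double()
    ),
    na = character(),
    progress = FALSE
  )
}

#' @rdname write_cohort
#' @export
read_outcomes <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(patient_id = readr::col_character(),
                            .default = readr::col_double()),
    progress = FALSE
  )
}

#' @rdname write_cohort
#' @export
read_truth <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(entity_type = readr::col_character(),
                            key = readr::col_character(),
                            label = readr::col_integer()),
    progress = FALSE
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  truth <- read_truth(file.path(directory, "truth.csv"))
  structure(
    list(
      mar = read_mar(file.path(directory, "mar.csv")),
      outcomes = read_outcomes(file.path(directory, "outcomes.csv")),
      truth_med_groups = truth |>
        dplyr::filter(.data$entity_type == "medication") |>
        dplyr::transmute(order_key = .data$key, group = .data$label),
      truth_archetypes = truth |>
        dplyr::filter(.data$entity_type == "patient") |>
        dplyr::transmute(patient_id = .data$key, archetype = .data$label),
      spec = NULL
    ),
    class = "synthetic_cohort"
  )
}
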