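#' Per-cluster summary cells of the reference ICU cohort
#'
#' Transcribed per-cluster demographic and outcome cells from the published
#' 991-patient ICU cohort report whose analysis this package reimplements:
#' cluster sizes, means for the continuous characteristics (age, APACHE II,
#' MRC-ICU, vasopressor duration) and event counts with their denominators
#' for the categorical ones (mortality, sex, medical ICU admission,
#' mechanical ventilation presence, acute kidney injury). Feeding this table
#' to [pooled_summary()] reproduces the report's pooled-cohort column by
#' arithmetic alone.
#'
#' @return Long tibble in the [pooled_summary()] input layout: `cluster`,
#'   `n`, `outcome`, `type`, `mean`, `count`, `denom`.
#' @export
#' @examples
#' pooled_summary(reference_cohort_summary())
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_summary.csv",
                      package = "pharmphen", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    cluster = readr::col_integer(),
    n = readr::col_integer(),
    outcome = readr::col_character(),
    type = readr::col_character(),
    mean = readr::col_double(),
    count = readr::col_integer(),
    denom = readr::col_integer()
  ), progress = FALSE)
}
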