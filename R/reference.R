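#' Published reference averages for the 25 highest-effort diagnoses
#'
#' The per-diagnosis factor averages and effort-risk totals reported from a
#' 12-month, roughly 60-million-claim extract at a large US payer, for the
#' 25 diagnoses that ranked highest under the expert-panel weights. The
#' table ships as plain text
#' (`system.file("extdata", "top25_reference.csv", package = "effortrisk")`)
#' and serves as a regression input: feeding each row's six averages into
#' [effort_risk_score()] with [default_weights()] reproduces the reported
#' total for 23 of the 25 rows exactly after two-decimal half-up rounding;
#' the remaining two rows ("Heart failure", "Sprain of the knee and leg")
#' differ by 0.01, attributable to the source totals having been computed
#' from unrounded averages while the table prints averages at two decimals.
#'
#' @return A tibble with columns `code` (diagnosis short description), the
#'   six `mean_*` factor averages, and `reported_total` (the published
#'   two-decimal total effort-risk score).
#' @examples
#' ref <- reference_averages()
#' s <- effort_risk_score(ref[ref$code == "Dislocation of the knee", ],
#'                        default_weights())
#' round_half_up(s$total)  # 2.80
#' @export
reference_averages <- function() {
  path <- system.file("extdata", "top25_reference.csv", package = "effortrisk")
  readr::read_csv(path, col_types = readr::cols(
    code = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}
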