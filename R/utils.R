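#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Canonical factor order used throughout: the order in which the six effort
# factors appear in per-diagnosis reports (household size first, then the
# "paying for care" factors, then the inquiry channels).
effort_factors <- function() {
  c("household", "out_of_network", "adjustments", "denials", "calls", "web_mobile")
}

# Column names of the per-household factor-count table, in factor order.
household_count_cols <- function() {
  c("n_members_with_claims", "n_out_of_network", "n_adjustments",
    "n_denials", "n_phone", "n_web_mobile")
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when rendering scores and
#' averages: 2.805 rounds to 2.81, not 2.80. Base `round()` rounds half to
#' even and is unsuitable for reproducing printed two-decimal tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.8008)  # 2.80
#' round_half_up(0.0399)  # 0.04
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small nudge absorbs binary representation error (e.g. 0.285 * 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Fixed two-decimal rendering used in report files.
format2 <- function(x) {
  formatC(round_half_up(x, 2), format = "f", digits = 2)
}

stop_schema <- function(msg) abort(msg, class = "effortrisk_schema_error")
stop_integrity <- function(msg) abort(msg, class = "effortrisk_integrity_error")
stop_validation <- function(msg) abort(msg, class = "effortrisk_validation_error")
stop_parameter <- function(msg) abort(msg, class = "effortrisk_parameter_error")
stop_config <- function(msg) abort(msg, class = "effortrisk_config_error")
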