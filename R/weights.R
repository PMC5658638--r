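#' Expert-elicited effort weights
#'
#' The six effort factors are combined into a single effort-risk score by a
#' weighted sum, where the weights are percentages elicited from a subject
#' matter expert panel and must total 100: total consumer effort is taken to
#' be 100%, and each weight states the share of that effort a factor
#' contributes.
#'
#' @param calls_pct Weight (%) of phone inquiries made by the household.
#' @param denials_pct Weight (%) of claim lines denied by the payer.
#' @param web_mobile_pct Weight (%) of web-portal plus mobile-app inquiries.
#' @param out_of_network_pct Weight (%) of claim lines from out-of-network
#'   providers.
#' @param adjustments_pct Weight (%) of claim lines requiring adjustment
#'   (reprocessing).
#' @param household_pct Weight (%) of the number of household members with
#'   claims.
#' @return An `effort_weights` object: a named numeric vector of the six
#'   percentages, in canonical factor order (household, out_of_network,
#'   adjustments, denials, calls, web_mobile).
#' @examples
#' effort_weights(calls_pct = 40, denials_pct = 25, web_mobile_pct = 15,
#'                out_of_network_pct = 8, adjustments_pct = 7,
#'                household_pct = 5)
#' @seealso [default_weights()], [read_weights()]
#' @export
effort_weights <- function(calls_pct, denials_pct, web_mobile_pct,
                           out_of_network_pct, adjustments_pct,
                           household_pct) {
  w <- c(household = household_pct, out_of_network = out_of_network_pct,
         adjustments = adjustments_pct, denials = denials_pct,
         calls = calls_pct, web_mobile = web_mobile_pct)
  if (!is.numeric(w) || anyNA(w)) {
    stop_validation("all six weights must be non-missing numbers")
  }
  if (any(w < 0)) {
    stop_validation(sprintf(
      "weights must be non-negative; offending factor(s): %s",
      paste(names(w)[w < 0], collapse = ", ")))
  }
  s <- sum(w)
  if (abs(s - 100) > 1e-9) {
    abort(sprintf("effort weights must sum to 100%%; got %.10g", s),
          class = "effortrisk_weight_sum_error")
  }
  structure(as.numeric(w), names = names(w), class = "effort_weights")
}

#' @export
print.effort_weights <- function(x, ...) {
  cat("Effort weights (% of total effort):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Default expert-panel weights
#'
#' The weighting elicited from a 12-member expert panel at a large US payer:
#' phone calls 40%, claim denials 25%, web/mobile inquiries 15%,
#' out-of-network visits 8%, claim adjustments 7%, household members with
#' claims 5%. These ship with the package as a plain-text config
#' (`system.file("extdata", "default_weights.yaml", package = "effortrisk")`).
#'
#' @return An [effort_weights()] object.
#' @examples
#' default_weights()
#' @export
default_weights <- function() {
  read_weights(system.file("extdata", "default_weights.yaml",
                           package = "effortrisk"))
}

weight_keys <- function() paste0(effort_factors(), "_pct")

#' Read an effort-weights config file
#'
#' Weights are inputs (expert-elicited), not code constants, so they are read
#' from a flat key-to-number config file in YAML or JSON. The six required
#' keys are `calls_pct`, `denials_pct`, `web_mobile_pct`,
#' `out_of_network_pct`, `adjustments_pct`, `household_pct`; their values
#' must sum to 100 (within 1e-9).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [effort_weights()] object.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("weights file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  missing <- setdiff(weight_keys(), names(cfg))
  if (length(missing) > 0) {
    stop_schema(sprintf("weights config is missing key(s): %s",
                        paste(missing, collapse = ", ")))
  }
  vals <- vapply(cfg[weight_keys()], as.numeric, numeric(1))
  effort_weights(calls_pct = vals[["calls_pct"]],
                 denials_pct = vals[["denials_pct"]],
                 web_mobile_pct = vals[["web_mobile_pct"]],
                 out_of_network_pct = vals[["out_of_network_pct"]],
                 adjustments_pct = vals[["adjustments_pct"]],
                 household_pct = vals[["household_pct"]])
}

#' Write an effort-weights config file
#'
#' @param weights An [effort_weights()] object.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "effort_weights"))
  cfg <- as.list(stats::setNames(as.numeric(weights),
                                 paste0(names(weights), "_pct")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
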