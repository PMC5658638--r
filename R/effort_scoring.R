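as_factor_means <- function(averages) {
  fac <- effort_factors()
  if (is.numeric(averages) && !is.null(names(averages))) {
    missing <- setdiff(fac, names(averages))
    if (length(missing) > 0) {
      stop_schema(sprintf("factor mean(s) missing: %s",
                          paste(missing, collapse = ", ")))
    }
    return(averages[fac])
  }
  if (is.data.frame(averages) && nrow(averages) == 1) {
    cols <- paste0("mean_", fac)
    missing <- setdiff(cols, names(averages))
    if (length(missing) > 0) {
      stop_schema(sprintf("averages column(s) missing: %s",
                          paste(missing, collapse = ", ")))
    }
    return(stats::setNames(as.numeric(averages[1, cols]), fac))
  }
  stop_validation("averages must be a named numeric vector of the six factor means or a one-row averages tibble")
}

#' Component effort scores for one diagnosis
#'
#' Each factor's contribution to the effort-risk score is its expert weight,
#' taken as a fraction of 100, multiplied by the per-diagnosis mean of the
#' factor: `component_f = (weight_f / 100) * mean_f`. Components are kept at
#' full precision; rounding is a display decision only.
#'
#' @param averages Named numeric vector of the six factor means (names
#'   `household`, `out_of_network`, `adjustments`, `denials`, `calls`,
#'   `web_mobile`), or a one-row tibble with the corresponding `mean_*`
#'   columns.
#' @param weights An [effort_weights()] object.
#' @return Named numeric vector of the six unrounded component scores, in
#'   canonical factor order.
#' @examples
#' component_scores(
#'   c(household = 2.14, out_of_network = 4.48, adjustments = 0.57,
#'     denials = 7.11, calls = 0.65, web_mobile = 1.72),
#'   default_weights())
#' @export
component_scores <- function(averages, weights) {
  stopifnot(inherits(weights, "effort_weights"))
  m <- as_factor_means(averages)
  if (anyNA(m)) stop_validation("factor means must not be missing")
  if (any(m < 0)) {
    stop_validation(sprintf("factor means must be non-negative; offending: %s",
                            paste(names(m)[m < 0], collapse = ", ")))
  }
  stats::setNames(as.numeric(weights)[match(names(m), names(weights))] / 100 * m,
                  names(m))
}

#' Effort-risk score for one diagnosis
#'
#' The total effort-risk score is the sum of the six unrounded component
#' scores (weight-fraction times factor mean). Totals are never computed
#' from rounded components; two-decimal rendering (half-up) is applied only
#' when printing or writing reports.
#'
#' @inheritParams component_scores
#' @param code Optional diagnosis code or label attached to the result.
#' @return An `effort_score` object: list with `code`, `means`,
#'   `components` (both named numeric), and `total`.
#' @examples
#' s <- effort_risk_score(
#'   c(household = 2.14, out_of_network = 4.48, adjustments = 0.57,
#'     denials = 7.11, calls = 0.65, web_mobile = 1.72),
#'   default_weights(), code = "dislocation of the knee")
#' s$total          # 2.8008
#' round_half_up(s$total)  # 2.80
#' @export
effort_risk_score <- function(averages, weights, code = NA_character_) {
  comp <- component_scores(averages, weights)
  if (is.data.frame(averages) && "code" %in% names(averages) && is.na(code)) {
    code <- averages$code[1]
  }
  structure(list(code = code, means = as_factor_means(averages),
                 components = comp, total = sum(comp)),
            class = "effort_score")
}

#' @export
print.effort_score <- function(x, ...) {
  if (!is.na(x$code)) cat("Effort-risk score for", x$code, "\n")
  df <- data.frame(factor = names(x$means),
                   average = format2(x$means),
                   score = format2(x$components))
  print(df, row.names = FALSE)
  cat("total effort risk:", format2(x$total), "\n")
  invisible(x)
}

#' Score every diagnosis in an averages table
#'
#' Vectorized form of [effort_risk_score()]: applies the weighted sum to
#' every row of a per-diagnosis averages table.
#'
#' @param averages Tibble from [per_diagnosis_averages()] (needs `code` and
#'   the six `mean_*` columns; other columns are carried through).
#' @param weights An [effort_weights()] object.
#' @return The input tibble with six `score_*` columns and a `total` column
#'   appended (all unrounded).
#' @export
score_diagnoses <- function(averages, weights) {
  stopifnot(inherits(weights, "effort_weights"))
  fac <- effort_factors()
  cols <- paste0("mean_", fac)
  missing <- setdiff(c("code", cols), names(averages))
  if (length(missing) > 0) {
    stop_schema(sprintf("averages column(s) missing: %s",
                        paste(missing, collapse = ", ")))
  }
  m <- as.matrix(averages[cols])
  if (anyNA(m) || any(m < 0)) {
    stop_validation("factor means must be present and non-negative")
  }
  w <- as.numeric(weights)[match(fac, names(weights))] / 100
  comp <- sweep(m, 2, w, `*`)
  out <- averages
  for (i in seq_along(fac)) out[[paste0("score_", fac[i])]] <- comp[, i]
  out$total <- as.numeric(comp %*% rep(1, length(fac)))
  out
}

#' Rank diagnoses by total effort-risk score
#'
#' Sorts by descending unrounded total, ties broken by ascending code, and
#' optionally truncates to the top `n`.
#'
#' @param scores Tibble from [score_diagnoses()].
#' @param top_n Optional positive integer; keep only the `top_n`
#'   highest-effort diagnoses.
#' @return The sorted (and possibly truncated) scores tibble.
#' @export
rank_diagnoses <- function(scores, top_n = NULL) {
  if (!all(c("code", "total") %in% names(scores))) {
    stop_schema("scores table needs 'code' and 'total' columns")
  }
  if (!is.null(top_n)) {
    if (!is.numeric(top_n) || length(top_n) != 1 || is.na(top_n) || top_n <= 0) {
      stop_parameter("top_n must be a positive integer")
    }
    top_n <- as.integer(top_n)
  }
  out <- scores[order(-scores$total, scores$code), ]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Correlations between household effort factors
#'
#' Pairwise correlations of the six factor counts across households, to see
#' how the effort of finding care and of paying for it relate. The
#' observation unit is the household, the only unit at which all six factors
#' are jointly observed. Pearson (linear) correlation is the default; rank
#' (Spearman) correlation is available. A factor with zero variance across
#' households yields undefined (NA) off-diagonal cells, flagged with a
#' warning; correlation of a constant is not defined.
#'
#' @param counts Per-household counts from [household_factor_counts()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A 6x6 symmetric correlation matrix with unit diagonal, rows and
#'   columns named by factor.
#' @export
factor_correlations <- function(counts, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  src <- household_count_cols()
  missing <- setdiff(src, names(counts))
  if (length(missing) > 0) {
    stop_schema(sprintf("counts column(s) missing: %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(counts) < 3) {
    abort("factor correlations need at least 3 households",
          class = "effortrisk_insufficient_data_error")
  }
  m <- as.matrix(counts[src])
  colnames(m) <- effort_factors()
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m, method = method))
  diag(cc) <- 1
  if (any(sds == 0)) {
    warn(sprintf("factor(s) with zero variance across households: %s; their correlations are undefined (NA)",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  cc
}
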