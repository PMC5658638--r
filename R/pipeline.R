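#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: either paths to real claims
#' and contacts tables, or a simulation config (exactly one of the two), a
#' weights source, the coverage threshold, and output settings.
#'
#' @param claims_path,contacts_path Paths to input CSV tables (both or
#'   neither).
#' @param sim A [sim_config()] object; mutually exclusive with the input
#'   paths.
#' @param weights An [effort_weights()] object or a path to a weights
#'   config file; defaults to the expert-panel weights shipped with the
#'   package.
#' @param coverage Cumulative occurrence share the scoped codes must reach
#'   (default 0.80).
#' @param top_n Number of top-ranked diagnoses in the report (default 25).
#' @param out_dir Directory the stage artifacts are written to.
#' @param log_level `"info"` (per-stage progress messages) or `"quiet"`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(claims_path = NULL, contacts_path = NULL,
                            sim = NULL, weights = default_weights(),
                            coverage = 0.80, top_n = 25, out_dir,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  have_paths <- !is.null(claims_path) || !is.null(contacts_path)
  if (have_paths && (is.null(claims_path) || is.null(contacts_path))) {
    stop_config("claims_path and contacts_path must be given together")
  }
  if (have_paths && !is.null(sim)) {
    stop_config("give either input paths or a simulation config, not both")
  }
  if (!have_paths && is.null(sim)) {
    stop_config("give input paths or a simulation config")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (is.character(weights)) weights <- read_weights(weights)
  stopifnot(inherits(weights, "effort_weights"))
  structure(list(claims_path = claims_path, contacts_path = contacts_path,
                 sim = sim, weights = weights, coverage = coverage,
                 top_n = top_n, out_dir = out_dir, log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, fmt, ...) {
  if (config$log_level == "info") message(sprintf(fmt, ...))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "effortrisk_stage_error", parent = e)
  })
}

#' Run the full effort-risk pipeline
#'
#' Executes simulate (or read) -> scope -> aggregate -> score -> report,
#' writing every stage artifact to `out_dir` so each boundary can be
#' inspected: `claims.csv`, `contacts.csv` and `truth.json` (when
#' simulating), `scoped_codes.txt`, `averages.tsv`, and `report.tsv`. The
#' run is deterministic given the inputs (and the simulation seed).
#'
#' @param config A [pipeline_config()] object.
#' @return An `effort_run_summary`: list with the table sizes per stage
#'   (claims, contacts, diagnosis occurrences, scoped codes, achieved
#'   coverage, scored diagnoses), the top-ranked diagnoses, and the paths
#'   of all artifacts.
#' @examples
#' out <- tempfile()
#' cfg <- pipeline_config(sim = sim_config(n_households = 60, seed = 3),
#'                        out_dir = out, log_level = "quiet")
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", simulate_claims(config$sim))
    claims <- sim$claims
    contacts <- sim$contacts
    paths$claims <- file.path(config$out_dir, "claims.csv")
    paths$contacts <- file.path(config$out_dir, "contacts.csv")
    paths$truth <- file.path(config$out_dir, "truth.json")
    run_stage("simulate", {
      write_claims(claims, paths$claims)
      write_contacts(contacts, paths$contacts)
      jsonlite::write_json(sim$truth, paths$truth, digits = NA)
    })
    pipe_log(config, "simulate: %d claims, %d contacts, %d households",
             nrow(claims), nrow(contacts), config$sim$n_households)
  } else {
    claims <- run_stage("read", read_claims(config$claims_path))
    contacts <- run_stage("read", read_contacts(config$contacts_path))
    pipe_log(config, "read: %d claims, %d contacts", nrow(claims), nrow(contacts))
  }

  freq <- run_stage("scope", count_diagnoses(claims))
  scoped <- run_stage("scope", select_top_coverage(freq, config$coverage))
  paths$scoped <- file.path(config$out_dir, "scoped_codes.txt")
  write_scoped_codes(scoped, paths$scoped)
  pipe_log(config, "scope: %d of %d codes cover %.4f of %d occurrences",
           length(scoped$codes), nrow(freq), scoped$coverage,
           sum(freq$occurrences))

  counts <- run_stage("aggregate", household_factor_counts(claims, contacts))
  index <- run_stage("aggregate", household_diagnosis_index(claims))
  averages <- run_stage("aggregate",
                        per_diagnosis_averages(counts, index, scoped))
  paths$averages <- file.path(config$out_dir, "averages.tsv")
  write_averages(averages, paths$averages)
  pipe_log(config, "aggregate: %d households, %d scoped diagnoses",
           nrow(counts), nrow(averages))

  scores <- run_stage("score", score_diagnoses(averages, config$weights))
  ranked <- run_stage("score", rank_diagnoses(scores, config$top_n))
  paths$report <- file.path(config$out_dir, "report.tsv")
  run_stage("report", write_report(ranked, paths$report))
  pipe_log(config, "score: %d diagnoses scored; top code %s (total %.4f)",
           nrow(scores), ranked$code[1], ranked$total[1])

  structure(list(
    n_claims = nrow(claims),
    n_contacts = nrow(contacts),
    n_diagnosis_occurrences = sum(freq$occurrences),
    n_codes_total = nrow(freq),
    n_codes_scoped = length(scoped$codes),
    achieved_coverage = scoped$coverage,
    n_scored = nrow(scores),
    top = ranked,
    paths = paths
  ), class = "effort_run_summary")
}

#' @export
print.effort_run_summary <- function(x, ...) {
  cat("Effort-risk pipeline run\n")
  cat(sprintf("  claims: %d   contacts: %d   diagnosis occurrences: %d\n",
              x$n_claims, x$n_contacts, x$n_diagnosis_occurrences))
  cat(sprintf("  scoped codes: %d of %d (coverage %.4f)\n",
              x$n_codes_scoped, x$n_codes_total, x$achieved_coverage))
  cat(sprintf("  diagnoses scored: %d\n", x$n_scored))
  cat("  top diagnoses by effort-risk score:\n")
  top <- utils::head(x$top, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-12s %s\n", top$code[i], format2(top$total[i])))
  }
  invisible(x)
}
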