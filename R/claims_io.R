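#' @title Claims and contact-event tables
#' @description
#' The pipeline consumes two tables. The *claims* table has one row per
#' adjudicated claim line: `claim_id`, `household_id`, `member_id`,
#' `service_date` (ISO-8601 date), `diagnosis_codes` (one or more
#' diagnosis-code strings; in files, ";"-separated within one field),
#' `out_of_network`, `denied`, `adjusted` (logicals). The *contacts* table
#' has one row per consumer inquiry: `household_id`, `channel` (one of
#' `"phone"`, `"web"`, `"mobile"`), `event_date`.
#'
#' A "consumer" is a household: all members covered under one plan. The
#' member/household columns let the pipeline count distinct members with
#' claims per household; `member_id` must therefore belong to exactly one
#' `household_id` across a table.
#' @name claims-tables
NULL

claims_cols <- function() {
  c("claim_id", "household_id", "member_id", "service_date",
    "diagnosis_codes", "out_of_network", "denied", "adjusted")
}

contact_channels <- function() c("phone", "web", "mobile")

# case-insensitive "true"/"false" parser; anything else is a row-level error
parse_bool <- function(x, col) {
  lx <- tolower(trimws(x))
  bad <- which(!lx %in% c("true", "false"))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "column '%s': value '%s' in row %d is not 'true'/'false'",
      col, x[bad[1]], bad[1]))
  }
  lx == "true"
}

#' Validate a claims table
#'
#' Checks the schema and the table invariants: all eight columns present and
#' correctly typed, `claim_id` unique, every claim line carrying at least one
#' non-empty diagnosis code, and every `member_id` belonging to exactly one
#' `household_id`.
#'
#' @param claims A tibble shaped like the claims table (`diagnosis_codes` may
#'   be a list of character vectors or a ";"-separated character column,
#'   which is converted).
#' @return The validated claims tibble (with `diagnosis_codes` as a
#'   list-column), invisibly usable downstream.
#' @export
validate_claims <- function(claims) {
  claims <- as_tibble(claims)
  missing <- setdiff(claims_cols(), names(claims))
  if (length(missing) > 0) {
    stop_schema(sprintf("claims table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  claims <- claims[claims_cols()]
  if (is.character(claims$diagnosis_codes)) {
    claims$diagnosis_codes <- strsplit(claims$diagnosis_codes, ";", fixed = TRUE)
  }
  if (!is.list(claims$diagnosis_codes)) {
    stop_schema("diagnosis_codes must be a list of code vectors or a ';'-separated character column")
  }
  if (anyDuplicated(claims$claim_id)) {
    dup <- unique(claims$claim_id[duplicated(claims$claim_id)])
    stop_integrity(sprintf("duplicate claim_id(s): %s",
                           paste(utils::head(dup, 5), collapse = ", ")))
  }
  n_codes <- lengths(claims$diagnosis_codes)
  flat <- unlist(claims$diagnosis_codes, use.names = FALSE)
  empty <- n_codes == 0L
  if (!all(!empty)) {
    stop_validation(sprintf("row %d has an empty diagnosis_codes field",
                            which(empty)[1]))
  }
  if (anyNA(flat) || !all(nzchar(flat))) {
    bad_row <- rep.int(seq_along(n_codes), n_codes)[is.na(flat) | !nzchar(flat)][1]
    stop_validation(sprintf("row %d has an empty diagnosis code", bad_row))
  }
  mh <- unique(tibble(member_id = claims$member_id,
                      household_id = claims$household_id))
  if (anyDuplicated(mh$member_id)) {
    off <- unique(mh$member_id[duplicated(mh$member_id)])
    stop_integrity(sprintf(
      "member_id(s) appearing under more than one household_id: %s",
      paste(utils::head(off, 5), collapse = ", ")))
  }
  claims
}

#' Read a claims table from CSV
#'
#' The file is UTF-8, comma-delimited, with a header row bearing exactly the
#' documented columns (see [claims-tables]). Multiple diagnosis codes on one
#' claim line are ";"-separated within the `diagnosis_codes` field; booleans
#' are serialized `"true"`/`"false"` (case-insensitive on read); dates are
#' ISO-8601. Row order is preserved.
#'
#' @param path Path to a claims CSV file.
#' @return A validated claims tibble with `diagnosis_codes` as a list-column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "claim_id,household_id,member_id,service_date,diagnosis_codes,out_of_network,denied,adjusted",
#'   "C1,H1,H1-M1,2014-03-02,D001;D002,false,true,false"), f)
#' read_claims(f)
#' @export
read_claims <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("claims file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(claims_cols(), names(raw))
  if (length(missing) > 0) {
    stop_schema(sprintf("claims file %s is missing column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), claims_cols())
  if (length(extra) > 0) {
    stop_schema(sprintf("claims file %s has unknown column(s): %s",
                        path, paste(extra, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(empty_claims())
  }
  dates <- readr::parse_date(raw$service_date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop_validation(sprintf("row %d has an invalid service_date '%s' (need YYYY-MM-DD)",
                            which(is.na(dates))[1],
                            raw$service_date[which(is.na(dates))[1]]))
  }
  if (anyNA(raw$diagnosis_codes)) {
    stop_validation(sprintf("row %d has an empty diagnosis_codes field",
                            which(is.na(raw$diagnosis_codes))[1]))
  }
  validate_claims(tibble(
    claim_id = raw$claim_id,
    household_id = raw$household_id,
    member_id = raw$member_id,
    service_date = dates,
    diagnosis_codes = raw$diagnosis_codes,
    out_of_network = parse_bool(raw$out_of_network, "out_of_network"),
    denied = parse_bool(raw$denied, "denied"),
    adjusted = parse_bool(raw$adjusted, "adjusted")
  ))
}

empty_claims <- function() {
  tibble(claim_id = character(), household_id = character(),
         member_id = character(), service_date = as.Date(character()),
         diagnosis_codes = list(), out_of_network = logical(),
         denied = logical(), adjusted = logical())
}

#' Write a claims table to CSV
#'
#' Inverse of [read_claims()]: diagnosis codes are ";"-joined, booleans
#' written `"true"`/`"false"`, dates ISO-8601, so a write-then-read
#' round-trip reproduces the table exactly.
#'
#' @param claims A validated claims tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  claims <- validate_claims(claims)
  out <- tibble(
    claim_id = claims$claim_id,
    household_id = claims$household_id,
    member_id = claims$member_id,
    service_date = format(claims$service_date, "%Y-%m-%d"),
    diagnosis_codes = vapply(claims$diagnosis_codes, paste, character(1),
                             collapse = ";"),
    out_of_network = ifelse(claims$out_of_network, "true", "false"),
    denied = ifelse(claims$denied, "true", "false"),
    adjusted = ifelse(claims$adjusted, "true", "false")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a contacts table
#'
#' @param contacts A tibble with columns `household_id`, `channel`,
#'   `event_date`.
#' @return The validated contacts tibble.
#' @export
validate_contacts <- function(contacts) {
  contacts <- as_tibble(contacts)
  missing <- setdiff(c("household_id", "channel", "event_date"), names(contacts))
  if (length(missing) > 0) {
    stop_schema(sprintf("contacts table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  bad <- which(!contacts$channel %in% contact_channels())
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "row %d has channel '%s'; must be one of %s",
      bad[1], contacts$channel[bad[1]],
      paste(contact_channels(), collapse = ", ")))
  }
  contacts[c("household_id", "channel", "event_date")]
}

#' Read a contact-events table from CSV
#'
#' One row per consumer inquiry to the payer's contact center, with columns
#' `household_id`, `channel` (`"phone"`, `"web"`, or `"mobile"`), and
#' `event_date` (ISO-8601). Contacts carry no diagnosis or member
#' information: the real contact center cannot attribute an inquiry to a
#' diagnosis, so inquiries are counted at household level.
#'
#' @param path Path to a contacts CSV file.
#' @return A validated contacts tibble.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("contacts file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(c("household_id", "channel", "event_date"), names(raw))
  if (length(missing) > 0) {
    stop_schema(sprintf("contacts file %s is missing column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(household_id = character(), channel = character(),
                  event_date = as.Date(character())))
  }
  dates <- readr::parse_date(raw$event_date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop_validation(sprintf("row %d has an invalid event_date '%s' (need YYYY-MM-DD)",
                            which(is.na(dates))[1],
                            raw$event_date[which(is.na(dates))[1]]))
  }
  validate_contacts(tibble(household_id = raw$household_id,
                           channel = raw$channel, event_date = dates))
}

#' Write a contacts table to CSV
#'
#' @param contacts A validated contacts tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  contacts <- validate_contacts(contacts)
  out <- tibble(household_id = contacts$household_id,
                channel = contacts$channel,
                event_date = format(contacts$event_date, "%Y-%m-%d"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a ranked effort-risk report
#'
#' Renders the scored diagnoses as a tab-separated report with the eight
#' columns of the standard presentation: diagnosis code (or label), the six
#' per-diagnosis factor averages, and the total effort-risk score, all
#' rendered to two decimals (half-up) and sorted by descending unrounded
#' total.
#'
#' @param scores A scored-diagnoses tibble from [score_diagnoses()] /
#'   [rank_diagnoses()].
#' @param path Output path for the TSV report.
#' @return `path`, invisibly.
#' @export
write_report <- function(scores, path) {
  scores <- rank_diagnoses(scores)
  mean_cols <- paste0("mean_", effort_factors())
  out <- tibble(diagnosis = scores$code)
  pretty <- c("avg_people_in_household", "avg_out_of_network_visits",
              "avg_claim_adjustments", "avg_claim_denials",
              "avg_phone_inquiries", "avg_web_mobile_inquiries")
  for (i in seq_along(mean_cols)) {
    out[[pretty[i]]] <- format2(scores[[mean_cols[i]]])
  }
  out$total_effort_risk <- format2(scores$total)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
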