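#' Per-household effort-factor counts
#'
#' Tallies, for every household appearing in the claims table, the six
#' countable effort factors over the analysis window: distinct members with
#' claims, claim lines from out-of-network providers, claim lines that
#' required adjustment, claim lines denied by the payer, phone inquiries,
#' and web-portal plus mobile-app inquiries. Denied and adjusted are counted
#' independently — a claim flagged both increments both, since a denial and
#' the adjustment it triggers are distinct effort events.
#'
#' Households appearing only in the contacts table (no claims) are retained
#' with zero claim-side counts and flagged with a warning, since inquiries
#' without claims usually indicate a linkage problem upstream.
#'
#' @param claims A validated claims tibble.
#' @param contacts A validated contacts tibble.
#' @return A tibble with one row per household: `household_id`,
#'   `n_members_with_claims`, `n_out_of_network`, `n_adjustments`,
#'   `n_denials`, `n_phone`, `n_web_mobile`.
#' @export
household_factor_counts <- function(claims, contacts) {
  claims <- validate_claims(claims)
  contacts <- validate_contacts(contacts)

  by_hh <- dplyr::summarise(
    dplyr::group_by(claims, .data$household_id),
    n_members_with_claims = dplyr::n_distinct(.data$member_id),
    n_out_of_network = sum(.data$out_of_network),
    n_adjustments = sum(.data$adjusted),
    n_denials = sum(.data$denied),
    .groups = "drop")

  ph <- table(contacts$household_id[contacts$channel == "phone"])
  wm <- table(contacts$household_id[contacts$channel %in% c("web", "mobile")])

  orphan <- setdiff(contacts$household_id, by_hh$household_id)
  if (length(orphan) > 0) {
    warn(sprintf(
      "%d household(s) have contacts but no claims (e.g. %s); retained with zero claim counts",
      length(orphan), paste(utils::head(orphan, 3), collapse = ", ")))
    by_hh <- dplyr::bind_rows(by_hh, tibble(
      household_id = orphan, n_members_with_claims = 0L,
      n_out_of_network = 0L, n_adjustments = 0L, n_denials = 0L))
  }

  by_hh$n_phone <- as.integer(ph[by_hh$household_id])
  by_hh$n_phone[is.na(by_hh$n_phone)] <- 0L
  by_hh$n_web_mobile <- as.integer(wm[by_hh$household_id])
  by_hh$n_web_mobile[is.na(by_hh$n_web_mobile)] <- 0L
  dplyr::arrange(by_hh, .data$household_id)
}

#' Index households by diagnosis code
#'
#' A household is listed under every diagnosis code appearing on any of its
#' claim lines (set semantics: once per code, however many claims repeat
#' it). A household carrying several codes appears under each of them.
#'
#' @param claims A validated claims tibble.
#' @return A tibble with columns `code` and `household_id`, one row per
#'   distinct (code, household) pair, sorted by code then household.
#' @export
household_diagnosis_index <- function(claims) {
  claims <- validate_claims(claims)
  n_codes <- lengths(claims$diagnosis_codes)
  idx <- tibble(
    code = unlist(claims$diagnosis_codes, use.names = FALSE),
    household_id = rep.int(claims$household_id, n_codes))
  dplyr::arrange(dplyr::distinct(idx), .data$code, .data$household_id)
}

#' Per-diagnosis factor averages
#'
#' For each in-scope diagnosis code, computes the mean and median over that
#' code's households of each of the six effort-factor counts. A household's
#' whole-year, whole-household counts contribute in full to every code the
#' household carries: no apportionment of calls or denials to individual
#' diagnoses is attempted, because contact events cannot be attributed to a
#' diagnosis and claims-side effort frequently spans a household's
#' conditions.
#'
#' The median of an even-sized sample is the midpoint of the two central
#' values. Medians are reported for completeness; scoring uses means.
#'
#' @param counts Per-household counts from [household_factor_counts()].
#' @param index Code-to-household index from [household_diagnosis_index()].
#' @param scoped Optional `scoped_codes` object (or character vector of
#'   codes) restricting the output; scoped codes absent from the index are
#'   dropped with a warning. Default `NULL` keeps every indexed code.
#' @return A tibble with one row per code: `code`, `n_households`, then
#'   `mean_*` and `median_*` for each of `household`, `out_of_network`,
#'   `adjustments`, `denials`, `calls`, `web_mobile`.
#' @export
per_diagnosis_averages <- function(counts, index, scoped = NULL) {
  if (!is.null(scoped)) {
    codes <- if (inherits(scoped, "scoped_codes")) scoped$codes else as.character(scoped)
    absent <- setdiff(codes, index$code)
    if (length(absent) > 0) {
      warn(sprintf("%d scoped code(s) absent from the claims index (e.g. %s); excluded",
                   length(absent), paste(utils::head(absent, 3), collapse = ", ")))
    }
    index <- index[index$code %in% codes, ]
  }
  joined <- dplyr::inner_join(index, counts, by = "household_id")
  src <- household_count_cols()
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$code),
    n_households = dplyr::n(),
    dplyr::across(dplyr::all_of(src),
                  list(mean = mean, median = stats::median)),
    .groups = "drop")
  for (i in seq_along(src)) {
    names(out)[names(out) == paste0(src[i], "_mean")] <-
      paste0("mean_", effort_factors()[i])
    names(out)[names(out) == paste0(src[i], "_median")] <-
      paste0("median_", effort_factors()[i])
  }
  ord <- c("code", "n_households",
           paste0("mean_", effort_factors()),
           paste0("median_", effort_factors()))
  dplyr::arrange(out[ord], .data$code)
}

#' Write/read a per-diagnosis averages table
#'
#' Tab-separated, full precision (plain decimal notation), one row per code.
#'
#' @param averages Tibble from [per_diagnosis_averages()].
#' @param path File path.
#' @return `write_averages()` returns `path` invisibly; `read_averages()`
#'   returns the averages tibble.
#' @export
write_averages <- function(averages, path) {
  readr::write_tsv(averages, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_averages
#' @export
read_averages <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("averages file not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    code = readr::col_character(), n_households = readr::col_integer(),
    .default = readr::col_double()), progress = FALSE)
}
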