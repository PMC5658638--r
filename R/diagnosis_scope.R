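#' Count diagnosis-code occurrences
#'
#' One occurrence is one diagnosis code on one claim line: a claim line
#' carrying k codes contributes k occurrences, and repeat codes across a
#' household's claims all count. This is the counting convention under which
#' the number of diagnosis occurrences in a claims extract exceeds the
#' number of claims severalfold.
#'
#' @param claims A validated claims tibble (see [read_claims()]).
#' @return A diagnosis-frequency tibble with columns `code`,
#'   `occurrences`, and `share` (fraction of all occurrences), sorted by
#'   descending count with ties broken by ascending code.
#' @examples
#' claims <- toy_claims(list(c("A"), c("A", "B"), c("B")))
#' count_diagnoses(claims)
#' @export
count_diagnoses <- function(claims) {
  claims <- validate_claims(claims)
  if (nrow(claims) == 0) {
    abort("cannot count diagnoses of an empty claims table",
          class = "effortrisk_empty_input_error")
  }
  codes <- unlist(claims$diagnosis_codes, use.names = FALSE)
  tab <- table(codes)
  freq <- tibble(code = names(tab), occurrences = as.integer(tab))
  freq <- freq[order(-freq$occurrences, freq$code), ]
  freq$share <- freq$occurrences / sum(freq$occurrences)
  freq
}

#' Select the diagnosis codes covering a cumulative occurrence share
#'
#' Applies the scoping rule used to narrow a claims extract to its common
#' diagnoses: walk the frequency table in descending-count order and keep
#' codes until their cumulative share of all occurrences first reaches the
#' threshold (default 0.80). The achieved coverage of the selected prefix is
#' reported to full precision; it is at least the threshold and typically
#' slightly above it. Ties in counts are broken by ascending code so the
#' prefix is deterministic.
#'
#' @param freq A diagnosis-frequency tibble from [count_diagnoses()].
#' @param threshold Cumulative occurrence fraction to cover, in (0, 1].
#' @return A `scoped_codes` object: list with `codes` (character vector, in
#'   descending-frequency order), `coverage` (achieved cumulative share),
#'   and `threshold`.
#' @examples
#' freq <- count_diagnoses(toy_claims(list("A", "A", "A", "B", "B", "C")))
#' select_top_coverage(freq, threshold = 0.8)
#' @export
select_top_coverage <- function(freq, threshold = 0.80) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop_parameter("coverage threshold must be a single number in (0, 1]")
  }
  freq <- freq[order(-freq$occurrences, freq$code), ]
  cum <- cumsum(freq$share)
  # guard against cumulative floating error leaving the last entry below 1
  cum[length(cum)] <- 1
  k <- which(cum >= threshold - 1e-12)[1]
  structure(list(codes = freq$code[seq_len(k)],
                 coverage = sum(freq$share[seq_len(k)]),
                 threshold = threshold),
            class = "scoped_codes")
}

#' @export
print.scoped_codes <- function(x, ...) {
  cat(sprintf("Scoped diagnosis codes: %d code(s) covering %.4f of occurrences (threshold %.2f)\n",
              length(x$codes), x$coverage, x$threshold))
  invisible(x)
}

#' Write/read a scoped-codes list
#'
#' Plain-text, one code per line, preceded by a comment line recording the
#' achieved coverage and threshold.
#'
#' @param scoped A `scoped_codes` object from [select_top_coverage()].
#' @param path File path.
#' @return `write_scoped_codes()` returns `path` invisibly;
#'   `read_scoped_codes()` returns a `scoped_codes` object.
#' @export
write_scoped_codes <- function(scoped, path) {
  stopifnot(inherits(scoped, "scoped_codes"))
  header <- sprintf("# coverage=%.17g threshold=%.17g",
                    scoped$coverage, scoped$threshold)
  writeLines(c(header, scoped$codes), path)
  invisible(path)
}

#' @rdname write_scoped_codes
#' @export
read_scoped_codes <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("scoped-codes file not found: %s", path))
  lines <- readLines(path)
  meta <- c(coverage = NA_real_, threshold = NA_real_)
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], gregexpr("[a-z]+=[0-9.eE+-]+", lines[1]))[[1]]
    for (kv in m) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (parts[1] %in% names(meta)) meta[parts[1]] <- as.numeric(parts[2])
    }
    lines <- lines[-1]
  }
  structure(list(codes = lines[nzchar(lines)],
                 coverage = unname(meta["coverage"]),
                 threshold = unname(meta["threshold"])),
            class = "scoped_codes")
}
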