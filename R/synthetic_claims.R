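#' Default per-code factor event-rate table
#'
#' Deterministic, quasi-randomly spread mean yearly event rates per
#' diagnosis code, spanning the ranges observed in published per-diagnosis
#' averages from a large payer's 12-month extract: out-of-network claim
#' lines roughly 0.5-11.5/yr, adjustments 0.2-1.5/yr, denials 3-16/yr,
#' phone inquiries 0.3-1.2/yr, web/mobile inquiries 0.5-2.5/yr. Rates are a
#' fixed golden-ratio (low-discrepancy) sequence of the code's rank, so the
#' table is reproducible without a random seed and every factor varies
#' across codes without being collinear with the others.
#'
#' @param n_codes Number of diagnosis codes in the vocabulary.
#' @return A tibble with columns `code` ("D001", "D002", ...) and the five
#'   event-rate columns `out_of_network`, `adjustments`, `denials`,
#'   `calls`, `web_mobile` (mean events per household-code pair per year).
#' @export
default_rate_table <- function(n_codes) {
  stopifnot(n_codes >= 1)
  phi <- (sqrt(5) - 1) / 2
  frac <- function(x) x - floor(x)
  i <- seq_len(n_codes)
  tibble(
    code = sprintf("D%03d", i),
    out_of_network = 0.5 + 11.0 * frac(i * phi),
    adjustments = 0.2 + 1.3 * frac(i * phi + 0.17),
    denials = 3.0 + 13.0 * frac(i * phi + 0.41),
    calls = 0.3 + 0.9 * frac(i * phi + 0.59),
    web_mobile = 0.5 + 2.0 * frac(i * phi + 0.83)
  )
}

#' Simulation configuration
#'
#' Defines the synthetic population: a 12-month claims extract for
#' `n_households` households, each with `1 + Poisson(household_size_mean - 1)`
#' members, carrying diagnosis codes drawn from a Zipf-shaped prevalence
#' distribution over a vocabulary of `n_codes` codes. Code carriage is an
#' independent Bernoulli inclusion per (household, code) with probability
#' proportional to `rank^-zipf_exponent`, scaled so the expected number of
#' carried codes equals `diagnoses_per_household_mean`; households that
#' draw no code are redrawn, so every household carries at least one.
#'
#' For each carried code, yearly counts of the five event factors are
#' independent Poisson draws with the per-code means of
#' `factor_rate_table`. Every member also files one ordinary (unflagged,
#' in-network, paid) base claim, and every carried code appears on at least
#' one claim line, so household size and code carriage are observable in
#' the claims table even under low event rates.
#'
#' @param n_households Number of households (>= 1).
#' @param seed Integer seed; the simulation is fully reproducible given the
#'   config.
#' @param n_codes Size of the diagnosis-code vocabulary.
#' @param zipf_exponent Prevalence skew across codes (> 0); near 1 gives the
#'   characteristic pattern where a modest fraction of codes accounts for
#'   ~80% of all diagnosis occurrences.
#' @param household_size_mean Expected members per household (>= 1).
#' @param diagnoses_per_household_mean Expected number of distinct codes
#'   carried per household.
#' @param factor_rate_table Per-code mean event rates; see
#'   [default_rate_table()].
#' @return A `sim_config` object (validated list of the above).
#' @export
sim_config <- function(n_households = 1000, seed = 1, n_codes = 150,
                       zipf_exponent = 1.0, household_size_mean = 2.5,
                       diagnoses_per_household_mean = 3.0,
                       factor_rate_table = default_rate_table(n_codes)) {
  if (!is.numeric(n_households) || n_households < 1) {
    stop_parameter("n_households must be a positive integer")
  }
  if (!is.numeric(zipf_exponent) || zipf_exponent <= 0) {
    stop_parameter("zipf_exponent must be > 0")
  }
  if (!is.numeric(household_size_mean) || household_size_mean < 1) {
    stop_parameter("household_size_mean must be >= 1")
  }
  if (!is.numeric(diagnoses_per_household_mean) ||
      diagnoses_per_household_mean <= 0) {
    stop_parameter("diagnoses_per_household_mean must be > 0")
  }
  rate_cols <- c("out_of_network", "adjustments", "denials", "calls", "web_mobile")
  missing <- setdiff(c("code", rate_cols), names(factor_rate_table))
  if (length(missing) > 0) {
    stop_schema(sprintf("factor_rate_table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(factor_rate_table) != n_codes) {
    stop_parameter("factor_rate_table must have one row per code (n_codes rows)")
  }
  if (any(as.matrix(factor_rate_table[rate_cols]) < 0)) {
    stop_validation("all factor rates must be non-negative")
  }
  p <- carriage_probabilities(n_codes, zipf_exponent, diagnoses_per_household_mean)
  if (any(p >= 1)) {
    stop_parameter("diagnoses_per_household_mean too large for this vocabulary/skew: a carriage probability reaches 1")
  }
  structure(list(n_households = as.integer(n_households),
                 seed = as.integer(seed), n_codes = as.integer(n_codes),
                 zipf_exponent = zipf_exponent,
                 household_size_mean = household_size_mean,
                 diagnoses_per_household_mean = diagnoses_per_household_mean,
                 factor_rate_table = as_tibble(factor_rate_table)),
            class = "sim_config")
}

# Zipf-shaped inclusion probabilities, scaled to the target mean number of
# carried codes per household.
carriage_probabilities <- function(n_codes, zipf_exponent, mean_codes) {
  q <- (seq_len(n_codes))^(-zipf_exponent)
  q / sum(q) * mean_codes
}

#' Closed-form ground truth for a simulation configuration
#'
#' Under whole-household attribution (the convention the aggregation stage
#' uses: a household's whole-year factor counts count in full toward every
#' code it carries), the true per-code mean of factor f is
#' `rate[c, f] + sum over other codes c' of p[c'] * rate[c', f]`, because
#' code carriage is independent across codes, so conditioning on carrying c
#' leaves the other codes' carriage probabilities unchanged. The
#' household-size factor is independent of carriage, so its true per-code
#' mean is `household_size_mean` for every code. Truth and estimator share
#' the attribution convention by construction; a truth stated per-code
#' *rate* would not be the estimand the pipeline estimates.
#'
#' @param config A [sim_config()] object.
#' @param weights Optional [effort_weights()]; when supplied, a
#'   `true_total` column (the weighted sum of the true means) is appended.
#' @return A tibble with one row per code: `code`, `p_carry`, the six
#'   `true_mean_*` columns, and (if `weights` given) `true_total`.
#' @export
expected_scores <- function(config, weights = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rt <- config$factor_rate_table
  p <- carriage_probabilities(config$n_codes, config$zipf_exponent,
                              config$diagnoses_per_household_mean)
  rate_cols <- c("out_of_network", "adjustments", "denials", "calls", "web_mobile")
  truth <- tibble(code = rt$code, p_carry = p,
                  true_mean_household = config$household_size_mean)
  for (f in rate_cols) {
    s <- sum(p * rt[[f]])
    truth[[paste0("true_mean_", f)]] <- rt[[f]] * (1 - p) + s
  }
  truth <- truth[c("code", "p_carry",
                   paste0("true_mean_", effort_factors()))]
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "effort_weights"))
    w <- as.numeric(weights)[match(effort_factors(), names(weights))] / 100
    truth$true_total <- as.numeric(
      as.matrix(truth[paste0("true_mean_", effort_factors())]) %*% w)
  }
  truth
}

#' Simulate a 12-month claims extract with known ground truth
#'
#' Generates claims and contact-event tables with the statistical structure
#' the analysis assumes — Zipf-skewed code prevalence, household-level
#' factor events at per-code mean rates, contacts recorded at household
#' level only — together with the closed-form true per-code factor means
#' (see [expected_scores()]), so every downstream stage can be tested
#' against known truth.
#'
#' The emitted tables are byte-identical across runs with the same config
#' (including its seed); the caller's RNG state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `claims` (validated claims tibble),
#'   `contacts` (validated contacts tibble), and `truth` (per-code true
#'   factor means).
#' @examples
#' sim <- simulate_claims(sim_config(n_households = 50, seed = 7))
#' nrow(sim$claims)
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rt <- config$factor_rate_table
  rate_cols <- c("out_of_network", "adjustments", "denials", "calls", "web_mobile")
  if (all(as.matrix(rt[rate_cols]) == 0)) {
    warn("all factor event rates are zero: claims will contain only unflagged base claims")
  }
  withr::with_seed(config$seed, simulate_claims_impl(config))
}

simulate_claims_impl <- function(config) {
  nh <- config$n_households
  nc <- config$n_codes
  rt <- config$factor_rate_table
  p <- carriage_probabilities(nc, config$zipf_exponent,
                              config$diagnoses_per_household_mean)

  # code carriage: independent Bernoulli per (household, code); redraw
  # households that carry nothing (conditioning on >= 1 code does not alter
  # the conditional carriage of the other codes given any carried code)
  inc <- matrix(stats::runif(nh * nc), nrow = nh) <
    matrix(p, nrow = nh, ncol = nc, byrow = TRUE)
  repeat {
    empty <- which(rowSums(inc) == 0L)
    if (length(empty) == 0) break
    inc[empty, ] <- matrix(stats::runif(length(empty) * nc),
                           nrow = length(empty)) <
      matrix(p, nrow = length(empty), ncol = nc, byrow = TRUE)
  }

  sizes <- 1L + stats::rpois(nh, config$household_size_mean - 1)
  hh_id <- sprintf("H%06d", seq_len(nh))

  pairs <- which(inc, arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2])
  pair_h <- pairs[ord, 1]
  pair_c <- pairs[ord, 2]
  n_pairs <- length(pair_h)

  ev <- lapply(c("out_of_network", "adjustments", "denials", "calls", "web_mobile"),
               function(f) stats::rpois(n_pairs, rt[[f]][pair_c]))
  names(ev) <- c("out_of_network", "adjustments", "denials", "calls", "web_mobile")

  # --- claims ------------------------------------------------------------
  # one unflagged base claim per carried code; extra base claims so every
  # member files at least one claim; one flagged claim line per event
  k <- tabulate(pair_h, nbins = nh)
  extra_n <- pmax(0L, sizes - k)
  first_code <- pair_c[!duplicated(pair_h)]      # pair_h sorted ascending

  ev_h <- c(pair_h, rep.int(seq_len(nh), extra_n),
            rep.int(pair_h, ev$out_of_network),
            rep.int(pair_h, ev$adjustments),
            rep.int(pair_h, ev$denials))
  ev_c <- c(pair_c, rep.int(first_code, extra_n),
            rep.int(pair_c, ev$out_of_network),
            rep.int(pair_c, ev$adjustments),
            rep.int(pair_c, ev$denials))
  n_base <- n_pairs + sum(extra_n)
  n_oon <- sum(ev$out_of_network)
  n_adj <- sum(ev$adjustments)
  n_den <- sum(ev$denials)
  flag_oon <- c(rep(FALSE, n_base), rep(TRUE, n_oon), rep(FALSE, n_adj + n_den))
  flag_adj <- c(rep(FALSE, n_base + n_oon), rep(TRUE, n_adj), rep(FALSE, n_den))
  flag_den <- c(rep(FALSE, n_base + n_oon + n_adj), rep(TRUE, n_den))

  o <- order(ev_h)                               # stable radix sort
  ev_h <- ev_h[o]; ev_c <- ev_c[o]
  flag_oon <- flag_oon[o]; flag_adj <- flag_adj[o]; flag_den <- flag_den[o]

  per_h <- tabulate(ev_h, nbins = nh)
  pos <- sequence(per_h[per_h > 0])              # 1..n within each household
  sz <- sizes[ev_h]
  # cycling through members guarantees the first `size` lines hit distinct
  # members, so members-with-claims always equals household size
  member_idx <- (pos - 1L) %% sz + 1L

  n_claims <- length(ev_h)
  claims <- tibble(
    claim_id = sprintf("C%08d", seq_len(n_claims)),
    household_id = hh_id[ev_h],
    member_id = paste0(hh_id[ev_h], "-M", member_idx),
    service_date = as.Date("2014-01-01") +
      floor(stats::runif(n_claims) * 365),
    diagnosis_codes = as.list(rt$code[ev_c]),
    out_of_network = flag_oon,
    denied = flag_den,
    adjusted = flag_adj
  )

  # --- contacts ----------------------------------------------------------
  ct_h <- c(rep.int(pair_h, ev$calls), rep.int(pair_h, ev$web_mobile))
  n_phone <- sum(ev$calls)
  n_wm <- sum(ev$web_mobile)
  channel <- c(rep("phone", n_phone),
               ifelse(stats::runif(n_wm) < 0.5, "web", "mobile"))
  contacts <- tibble(
    household_id = hh_id[ct_h],
    channel = channel,
    event_date = as.Date("2014-01-01") +
      floor(stats::runif(length(ct_h)) * 365)
  )
  contacts <- contacts[order(contacts$household_id, contacts$channel,
                             contacts$event_date), ]

  list(claims = validate_claims(claims),
       contacts = validate_contacts(contacts),
       truth = expected_scores(config))
}

#' Build a minimal claims table for examples and tests
#'
#' One claim line per element of `codes`, all for one household/member by
#' default, with optional flag vectors (recycled).
#'
#' @param codes List of character vectors (or a character vector) of
#'   diagnosis codes, one element per claim line.
#' @param household_id,member_id Identifiers, recycled across lines.
#' @param out_of_network,denied,adjusted Logical flags, recycled.
#' @return A validated claims tibble.
#' @export
toy_claims <- function(codes, household_id = "H1", member_id = NULL,
                       out_of_network = FALSE, denied = FALSE,
                       adjusted = FALSE) {
  if (is.character(codes)) codes <- as.list(codes)
  n <- length(codes)
  household_id <- rep_len(household_id, n)
  if (is.null(member_id)) member_id <- paste0(household_id, "-M1")
  validate_claims(tibble(
    claim_id = sprintf("C%04d", seq_len(n)),
    household_id = household_id,
    member_id = rep_len(member_id, n),
    service_date = as.Date("2014-06-15"),
    diagnosis_codes = codes,
    out_of_network = rep_len(out_of_network, n),
    denied = rep_len(denied, n),
    adjusted = rep_len(adjusted, n)
  ))
}
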