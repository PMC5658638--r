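fixture_household <- function() {
  claims <- tibble::tibble(
    claim_id = c("C1", "C2", "C3"),
    household_id = "H1",
    member_id = "H1-M1",
    service_date = as.Date("2014-05-01") + 0:2,
    diagnosis_codes = list("A", "A", "A"),
    out_of_network = FALSE,
    denied = c(TRUE, FALSE, TRUE),
    adjusted = c(FALSE, FALSE, TRUE))
  contacts <- tibble::tibble(
    household_id = "H1",
    channel = c("phone", "web", "mobile"),
    event_date = as.Date("2014-06-01") + 0:2)
  list(claims = claims, contacts = contacts)
}

test_that("household counts tally the six factors from a hand-counted fixture", {
  fx <- fixture_household()
  counts <- household_factor_counts(fx$claims, fx$contacts)
  expect_equal(nrow(counts), 1)
  expect_equal(counts$n_members_with_claims, 1L)
  expect_equal(counts$n_denials, 2L)       # denied, denied+adjusted
  expect_equal(counts$n_adjustments, 1L)   # both flags increment both counts
  expect_equal(counts$n_out_of_network, 0L)
  expect_equal(counts$n_phone, 1L)
  expect_equal(counts$n_web_mobile, 2L)    # web + mobile pooled
})

test_that("members with claims are counted distinctly and zero-event households stay zero", {
  claims <- toy_claims(list("A", "B"), member_id = c("H1-M1", "H1-M2"))
  counts <- household_factor_counts(claims, toy_contacts(0))
  expect_equal(counts$n_members_with_claims, 2L)
  expect_equal(counts$n_denials + counts$n_adjustments +
                 counts$n_out_of_network + counts$n_phone +
                 counts$n_web_mobile, 0L)
})

test_that("contacts without claims are retained with a warning", {
  claims <- toy_claims(list("A"))
  contacts <- tibble::tibble(household_id = "H9", channel = "phone",
                             event_date = as.Date("2014-03-03"))
  expect_warning(counts <- household_factor_counts(claims, contacts),
                 "H9")
  orphan <- counts[counts$household_id == "H9", ]
  expect_equal(orphan$n_phone, 1L)
  expect_equal(orphan$n_members_with_claims, 0L)
})

test_that("the diagnosis index lists a household once under each of its codes", {
  claims <- tibble::tibble(
    claim_id = c("C1", "C2", "C3"),
    household_id = c("H1", "H2", "H2"),
    member_id = c("H1-M1", "H2-M1", "H2-M1"),
    service_date = as.Date("2014-02-02"),
    diagnosis_codes = list("A", c("A", "B"), "A"),
    out_of_network = FALSE, denied = FALSE, adjusted = FALSE)
  idx <- household_diagnosis_index(claims)
  expect_equal(idx$code, c("A", "A", "B"))
  expect_equal(idx$household_id, c("H1", "H2", "H2"))  # H2 once under A
})

test_that("per-diagnosis means and medians follow hand arithmetic", {
  mk <- function(denials_by_household) {
    hh <- names(denials_by_household)
    claims <- dplyr::bind_rows(lapply(hh, function(h) {
      n <- max(1L, denials_by_household[[h]])
      tibble::tibble(
        claim_id = sprintf("%s-C%d", h, seq_len(n)),
        household_id = h, member_id = paste0(h, "-M1"),
        service_date = as.Date("2014-04-04"),
        diagnosis_codes = replicate(n, "A", simplify = FALSE),
        out_of_network = FALSE,
        denied = seq_len(n) <= denials_by_household[[h]],
        adjusted = FALSE)
    }))
    claims
  }
  claims <- mk(c(H1 = 2L, H2 = 4L))
  avg <- per_diagnosis_averages(
    household_factor_counts(claims, toy_contacts(0)),
    household_diagnosis_index(claims))
  expect_equal(avg$mean_denials, 3.0)
  expect_equal(avg$median_denials, 3.0)    # even sample: midpoint of 2 and 4

  claims3 <- mk(c(H1 = 0L, H2 = 0L, H3 = 9L))
  avg3 <- per_diagnosis_averages(
    household_factor_counts(claims3, toy_contacts(0)),
    household_diagnosis_index(claims3))
  expect_equal(avg3$mean_denials, 3.0)
  expect_equal(avg3$median_denials, 0.0)

  one <- mk(c(H1 = 2L))
  avg1 <- per_diagnosis_averages(
    household_factor_counts(one, toy_contacts(0)),
    household_diagnosis_index(one))
  expect_equal(avg1$mean_denials, avg1$median_denials)
  expect_equal(avg1$n_households, 1L)
})

test_that("scoped codes absent from the index are excluded with a warning", {
  claims <- toy_claims(list("A"))
  counts <- household_factor_counts(claims, toy_contacts(0))
  idx <- household_diagnosis_index(claims)
  expect_warning(avg <- per_diagnosis_averages(counts, idx, c("A", "ZZZ")),
                 "ZZZ")
  expect_equal(avg$code, "A")
})

test_that("aggregation is invariant to input row order", {
  td <- random_toy_data(401)
  base_counts <- household_factor_counts(td$claims, td$contacts)
  base_avg <- per_diagnosis_averages(base_counts,
                                     household_diagnosis_index(td$claims))
  for (seed in 1:5) {
    set.seed(seed)
    cl <- td$claims[sample(nrow(td$claims)), ]
    ct <- td$contacts[sample(nrow(td$contacts)), ]
    counts <- household_factor_counts(cl, ct)
    expect_equal(counts, base_counts)
    expect_equal(per_diagnosis_averages(counts, household_diagnosis_index(cl)),
                 base_avg)
  }
})

test_that("adding a claim with a new code only touches that code and household", {
  td <- random_toy_data(402)
  before <- per_diagnosis_averages(
    household_factor_counts(td$claims, td$contacts),
    household_diagnosis_index(td$claims))
  h <- td$claims$household_id[1]
  extra <- tibble::tibble(
    claim_id = "CNEW", household_id = h,
    member_id = td$claims$member_id[1],
    service_date = as.Date("2014-09-09"),
    diagnosis_codes = list("NEWCODE"),
    out_of_network = FALSE, denied = FALSE, adjusted = FALSE)
  claims2 <- dplyr::bind_rows(td$claims, extra)
  after <- per_diagnosis_averages(
    household_factor_counts(claims2, td$contacts),
    household_diagnosis_index(claims2))
  expect_true("NEWCODE" %in% after$code)
  idx <- household_diagnosis_index(td$claims)
  untouched <- setdiff(before$code, idx$code[idx$household_id == h])
  expect_equal(after[after$code %in% untouched, ],
               before[before$code %in% untouched, ])
})
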