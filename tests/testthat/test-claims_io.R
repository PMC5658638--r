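test_that("claims tables round-trip through CSV exactly", {
  claims <- tibble::tibble(
    claim_id = c("C1", "C2", "C3"),
    household_id = c("H1", "H1", "H2"),
    member_id = c("H1-M1", "H1-M2", "H2-M1"),
    service_date = as.Date(c("2014-01-05", "2014-07-19", "2014-12-31")),
    diagnosis_codes = list("D001", c("D001", "D002"), "D003"),
    out_of_network = c(FALSE, TRUE, FALSE),
    denied = c(TRUE, FALSE, TRUE),
    adjusted = c(TRUE, TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_claims(claims, f)
  back <- read_claims(f)
  expect_identical(as.data.frame(back), as.data.frame(validate_claims(claims)))

  g <- withr::local_tempfile(fileext = ".csv")
  write_claims(back, g)
  expect_identical(readLines(f), readLines(g))
})

test_that("a header-only claims file parses to an empty table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("claim_id", "household_id", "member_id", "service_date",
                     "diagnosis_codes", "out_of_network", "denied", "adjusted"),
                   collapse = ","), f)
  claims <- read_claims(f)
  expect_equal(nrow(claims), 0)
  expect_true(is.list(claims$diagnosis_codes))
})

test_that("schema violations are reported by column and row", {
  header <- "claim_id,household_id,member_id,service_date,diagnosis_codes,out_of_network,denied,adjusted"
  row1 <- "C1,H1,H1-M1,2014-03-02,D001;D002,false,true,false"

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(sub(",adjusted", "", header), sub(",false$", "", row1)), f)
  expect_error(read_claims(f), "adjusted", class = "effortrisk_schema_error")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste0(header, ",extra"), paste0(row1, ",x")), g)
  expect_error(read_claims(g), "extra", class = "effortrisk_schema_error")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, row1, "C2,H1,H1-M1,2014-03-02,D001,maybe,true,false"), h)
  expect_error(read_claims(h), "row 2", class = "effortrisk_validation_error")
})

test_that("a member appearing under two households is an integrity error", {
  bad <- tibble::tibble(
    claim_id = c("C1", "C2"), household_id = c("H1", "H2"),
    member_id = c("M1", "M1"),
    service_date = as.Date("2014-06-15"),
    diagnosis_codes = list("A", "B"),
    out_of_network = FALSE, denied = FALSE, adjusted = FALSE)
  expect_error(validate_claims(bad), "M1", class = "effortrisk_integrity_error")
})

test_that("empty or blank diagnosis codes are row-level validation errors", {
  header <- "claim_id,household_id,member_id,service_date,diagnosis_codes,out_of_network,denied,adjusted"
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header,
               "C1,H1,H1-M1,2014-03-02,D001,false,false,false",
               "C2,H1,H1-M1,2014-03-05,,false,false,false"), f)
  expect_error(read_claims(f), "row 2", class = "effortrisk_validation_error")
})

test_that("booleans are parsed case-insensitively", {
  header <- "claim_id,household_id,member_id,service_date,diagnosis_codes,out_of_network,denied,adjusted"
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header,
               "C1,H1,H1-M1,2014-03-02,D001,TRUE,False,true"), f)
  claims <- read_claims(f)
  expect_true(claims$out_of_network)
  expect_false(claims$denied)
  expect_true(claims$adjusted)
})

test_that("contacts parse the three channels and reject others", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("household_id,channel,event_date",
               "H1,phone,2014-02-01", "H1,web,2014-02-02",
               "H2,mobile,2014-02-03"), f)
  contacts <- read_contacts(f)
  expect_equal(nrow(contacts), 3)
  expect_setequal(contacts$channel, c("phone", "web", "mobile"))

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("household_id,channel,event_date", "H1,fax,2014-02-01"), g)
  expect_error(read_contacts(g), "fax", class = "effortrisk_validation_error")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines("household_id,channel,event_date", h)
  expect_equal(nrow(read_contacts(h)), 0)
})

test_that("weights configs are accepted exactly when the six values sum to 100", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("calls_pct: 40", "denials_pct: 25", "web_mobile_pct: 15",
               "out_of_network_pct: 8", "adjustments_pct: 7",
               "household_pct: 5"), f)
  w <- read_weights(f)
  expect_s3_class(w, "effort_weights")
  expect_equal(sum(w), 100)

  g <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste0(c("calls_pct", "denials_pct", "web_mobile_pct",
                      "out_of_network_pct", "adjustments_pct",
                      "household_pct"), ": 16.6"), g)
  expect_error(read_weights(g), "99[.]6", class = "effortrisk_weight_sum_error")

  h <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("calls_pct: 100", "denials_pct: 0", "web_mobile_pct: 0",
               "out_of_network_pct: 0", "adjustments_pct: 0",
               "household_pct: 0"), h)
  expect_equal(as.numeric(read_weights(h)["calls"]), 100)

  i <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("calls_pct: 40", "denials_pct: 25", "web_mobile_pct: 15",
               "out_of_network_pct: 8", "adjustments_pct: 12"), i)
  expect_error(read_weights(i), "household_pct",
               class = "effortrisk_schema_error")
})

test_that("weights round-trip through YAML and JSON", {
  w <- default_weights()
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_weights(w, f)
    expect_equal(as.numeric(read_weights(f)), as.numeric(w))
  }
})

test_that("reports render two-decimal totals in descending order", {
  ref <- reference_averages()
  knee <- ref[ref$code == "Dislocation of the knee", ]
  scored <- score_diagnoses(knee, default_weights())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(scored, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_match(lines[2], "\t2\\.80$")

  all_scored <- score_diagnoses(ref, default_weights())
  g <- withr::local_tempfile(fileext = ".tsv")
  write_report(all_scored, g)
  body <- readLines(g)[-1]
  totals <- as.numeric(vapply(strsplit(body, "\t"), function(x) x[8], ""))
  expect_equal(totals, sort(totals, decreasing = TRUE))
  expect_equal(ncol(readr::read_tsv(g, show_col_types = FALSE)), 8)

  h <- withr::local_tempfile(fileext = ".tsv")
  write_report(all_scored[0, ], h)
  expect_length(readLines(h), 1)
})
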