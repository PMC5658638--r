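# Brute-force oracles: deliberately naive base-R rescans, independent of the
# vectorized implementations they check.

oracle_count_diagnoses <- function(claims) {
  tally <- list()
  for (i in seq_len(nrow(claims))) {
    for (code in claims$diagnosis_codes[[i]]) {
      tally[[code]] <- (tally[[code]] %||% 0L) + 1L
    }
  }
  codes <- names(tally)
  counts <- unlist(tally, use.names = FALSE)
  ord <- order(-counts, codes)
  data.frame(code = codes[ord], occurrences = counts[ord],
             share = counts[ord] / sum(counts), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# for each code: rescan all claims and contacts from scratch, per household
oracle_averages <- function(claims, contacts, codes = NULL) {
  all_codes <- sort(unique(unlist(claims$diagnosis_codes)))
  if (!is.null(codes)) all_codes <- intersect(all_codes, codes)
  rows <- list()
  for (code in all_codes) {
    hhs <- character()
    for (i in seq_len(nrow(claims))) {
      if (code %in% claims$diagnosis_codes[[i]]) {
        hhs <- union(hhs, claims$household_id[i])
      }
    }
    hhs <- sort(hhs)
    vals <- matrix(0, nrow = length(hhs), ncol = 6)
    for (j in seq_along(hhs)) {
      h <- hhs[j]
      members <- character()
      oon <- adj <- den <- 0L
      for (i in seq_len(nrow(claims))) {
        if (claims$household_id[i] == h) {
          members <- union(members, claims$member_id[i])
          oon <- oon + as.integer(claims$out_of_network[i])
          adj <- adj + as.integer(claims$adjusted[i])
          den <- den + as.integer(claims$denied[i])
        }
      }
      phone <- wm <- 0L
      for (i in seq_len(nrow(contacts))) {
        if (contacts$household_id[i] == h) {
          if (contacts$channel[i] == "phone") phone <- phone + 1L
          else wm <- wm + 1L
        }
      }
      vals[j, ] <- c(length(members), oon, adj, den, phone, wm)
    }
    rows[[code]] <- c(n = length(hhs),
                      means = colMeans(vals),
                      medians = apply(vals, 2, stats::median))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("n_households",
                  paste0("mean_", effortrisk:::effort_factors()),
                  paste0("median_", effortrisk:::effort_factors()))
  out$code <- rownames(out)
  rownames(out) <- NULL
  out[order(out$code), ]
}

# shortest prefix of the descending-frequency table reaching the threshold,
# found by scanning every prefix
oracle_top_coverage <- function(freq, threshold) {
  freq <- freq[order(-freq$occurrences, freq$code), ]
  for (k in seq_len(nrow(freq))) {
    if (sum(freq$share[seq_len(k)]) >= threshold - 1e-12) {
      return(list(codes = freq$code[seq_len(k)],
                  coverage = sum(freq$share[seq_len(k)])))
    }
  }
}

# randomized toy claims + contacts tables (<= 50 households)
random_toy_data <- function(seed) {
  set.seed(seed)
  nh <- sample(1:50, 1)
  vocab <- sprintf("X%02d", seq_len(sample(3:10, 1)))
  claims <- list()
  cid <- 0L
  for (h in seq_len(nh)) {
    hid <- sprintf("H%03d", h)
    n_members <- sample(1:3, 1)
    n_claims <- sample(1:6, 1)
    for (k in seq_len(n_claims)) {
      cid <- cid + 1L
      claims[[cid]] <- tibble::tibble(
        claim_id = sprintf("C%05d", cid),
        household_id = hid,
        member_id = sprintf("%s-M%d", hid, sample(n_members, 1)),
        service_date = as.Date("2014-01-01") + sample(0:364, 1),
        diagnosis_codes = list(sample(vocab, sample(1:3, 1))),
        out_of_network = runif(1) < 0.3,
        denied = runif(1) < 0.4,
        adjusted = runif(1) < 0.25)
    }
  }
  claims <- dplyr::bind_rows(claims)
  n_contacts <- sample(0:(3 * nh), 1)
  contacts <- tibble::tibble(
    household_id = sprintf("H%03d", sample(nh, n_contacts, replace = TRUE)),
    channel = sample(c("phone", "web", "mobile"), n_contacts, replace = TRUE),
    event_date = as.Date("2014-01-01") + sample(0:364, n_contacts, replace = TRUE))
  list(claims = claims, contacts = contacts)
}

toy_contacts <- function(n, household_id = "H1",
                         channel = c("phone", "web", "mobile")) {
  if (n == 0) {
    return(tibble::tibble(household_id = character(), channel = character(),
                          event_date = as.Date(character())))
  }
  tibble::tibble(household_id = rep_len(household_id, n),
                 channel = rep_len(channel, n),
                 event_date = as.Date("2014-06-01") + seq_len(n))
}
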