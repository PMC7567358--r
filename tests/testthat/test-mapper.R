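test_that("shipped rule table loads with 33 conditions and tiered thresholds", {
  rules <- read_condition_rules()
  expect_length(unique(rules$condition), 33L)
  expect_true(all(rules$min_rx_per_year %in% 1:3))
  expect_true(all(rules$flag != "wrong"))  # wrong associations inactive
  with_wrong <- read_condition_rules(include_flagged = TRUE)
  expect_gt(nrow(with_wrong), nrow(rules))
  # every condition carries metadata for the simulator
  expect_setequal(mcds_conditions()$condition, unique(rules$condition))
})

test_that("overlapping patterns without exceptions are rejected at load", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "condition,atc_pattern,min_rx_per_year,exception_codes,flag",
    "one,N05A,2,,",
    "two,N05AN01,1,,",
    sep = "\n"
  ), f)
  expect_error(read_condition_rules(f), "overlap")
})

test_that("prescription counting respects patterns, exceptions and window", {
  rules <- tiny_rules()
  claims <- make_claims(
    c("P1", "P1", "P1", "P1", "P2", "P2", "P3"),
    c("A10BA02", "A10BB01", "A10BA02", "N05AN01", "N05AH04", "N05AH04",
      "A10BA02"),
    c("2016-02-01", "2016-06-01", "2017-03-01", "2016-04-01",
      "2016-05-01", "2016-05-02", "2015-12-31")
  )
  counts <- count_condition_rx(claims, rules)
  # P1 diabetes: 2 in 2016, 1 in 2017
  expect_equal(counts$n_rx[counts$patient_id == "P1" &
                             counts$condition == "diabetes"], c(2L, 1L))
  # lithium is an exception to the antipsychotic rule: bipolar, not psychosis
  p1 <- counts[counts$patient_id == "P1", ]
  expect_false("psychosis" %in% p1$condition)
  expect_equal(p1$n_rx[p1$condition == "bipolar"], 1L)
  # record before the window contributes nothing
  expect_false("P3" %in% counts$patient_id)
  # whole-calendar-year windows enforced
  expect_error(count_condition_rx(claims, rules, "2016-03-01"),
               "calendar year")
})

test_that("flagging applies per-year thresholds with a pooled option", {
  rules <- tiny_rules()
  pats <- c("P1", "P2", "P3", "P4")
  counts <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P4", "P4"),
    condition = c("ppi", "ppi", "diabetes", "diabetes", "bipolar",
                  "diabetes", "diabetes"),
    year = c(2016L, 2017L, 2016L, 2017L, 2017L, 2016L, 2017L),
    n_rx = c(2L, 3L, 1L, 1L, 1L, 2L, 1L)
  )
  prof <- flag_conditions(counts, rules, pats)
  expect_equal(prof$ppi[prof$patient_id == "P1"], 1L)       # 3 in one year
  expect_equal(prof$diabetes[prof$patient_id == "P2"], 0L)  # 1 + 1, per-year
  expect_equal(prof$bipolar[prof$patient_id == "P3"], 1L)   # threshold 1
  expect_equal(prof$diabetes[prof$patient_id == "P4"], 1L)  # 2 in 2016
  # pooling across years is the documented alternative reading
  pooled <- flag_conditions(counts, rules, pats, pooled = TRUE)
  expect_equal(pooled$diabetes[pooled$patient_id == "P2"], 1L)
  # a patient with no prescriptions keeps an all-zero profile
  empty <- flag_conditions(counts[0, ], rules, "P9")
  expect_equal(sum(as.matrix(empty[-1])), 0L)
})

test_that("profiles are monotone in records and invariant to record order", {
  rules <- tiny_rules()
  atcs <- c("A10BA02", "A10BB01", "N05AH04", "N05AN01", "A02BC01")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 15L
    claims <- make_claims(
      sample(c("P1", "P2", "P3"), n, replace = TRUE),
      sample(atcs, n, replace = TRUE),
      as.Date("2016-01-01") + sample(0:729, n, replace = TRUE)
    )
    pats <- c("P1", "P2", "P3")
    base <- mcds_profile(claims, rules, pats)
    # order invariance
    shuffled <- claims[sample(n), ]
    expect_identical(mcds_profile(shuffled, rules, pats), base)
    # monotonicity: one extra record never clears a flag
    extra <- rbind(claims, make_claims("P1", sample(atcs, 1), "2017-06-01"))
    more <- mcds_profile(extra, rules, pats)
    expect_true(all(as.matrix(more[-1]) >= as.matrix(base[-1])))
  }
})

test_that("flags match an exhaustive per-record re-derivation", {
  rules <- tiny_rules()
  naive_flags <- function(claims, rules, pats) {
    conds <- unique(rules$condition)
    out <- matrix(0L, length(pats), length(conds),
                  dimnames = list(pats, conds))
    for (cond in conds) {
      rows <- which(rules$condition == cond)
      exc <- unique(unlist(rules$exception_codes[rows]))
      thr <- min(rules$min_rx_per_year[rows])
      for (p in pats) {
        for (yr in c(2016, 2017)) {
          cnt <- 0L
          for (r in seq_len(nrow(claims))) {
            if (claims$patient_id[r] != p) next
            if (format(claims$dispense_date[r], "%Y") != yr) next
            code <- claims$atc_code[r]
            hit <- any(vapply(rules$atc_pattern[rows], startsWith,
                              logical(1), x = code))
            if (hit && !(code %in% exc)) cnt <- cnt + 1L
          }
          if (cnt >= thr) out[p, cond] <- 1L
        }
      }
    }
    out
  }
  atcs <- c("A10BA02", "N05AH04", "N05AN01", "A02BC01", "C09AA05")
  for (seed in 1:8) {
    set.seed(100 + seed)
    n <- sample(5:20, 1)
    pats <- c("P1", "P2", "P3", "P4")
    claims <- make_claims(
      sample(pats, n, replace = TRUE),
      sample(atcs, n, replace = TRUE),
      as.Date("2016-01-01") + sample(0:729, n, replace = TRUE)
    )
    got <- mcds_profile(claims, rules, pats)
    expect_equal(unname(as.matrix(got[-1])),
                 unname(naive_flags(claims, rules, pats)))
  }
})

test_that("prevalence floor drops rare conditions and reports them", {
  prof <- data.frame(patient_id = sprintf("P%d", 1:5),
                     common = c(1L, 1L, 1L, 0L, 0L),
                     rare = c(1L, 0L, 0L, 0L, 0L),
                     absent = 0L)
  expect_message(fl <- apply_prevalence_floor(prof, min_cases = 2),
                 "rare")
  expect_equal(fl$active, "common")
  expect_setequal(fl$dropped, c("rare", "absent"))
  expect_named(fl$profiles, c("patient_id", "common"))
  # min_cases = 0 is the identity
  id <- apply_prevalence_floor(prof, min_cases = 0)
  expect_equal(names(id$profiles), names(prof))
  expect_error(apply_prevalence_floor(prof[, c("patient_id", "absent")], 2),
               "every condition")
})
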