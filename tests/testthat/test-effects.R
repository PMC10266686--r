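# survival construction, Cox estimation, robustness filter

test_that("survival records encode events and censoring per outcome", {
  reg <- toy_registry()
  coh <- suppressMessages(select_cohort(reg))
  nr <- build_survival(reg, coh, "non_response")
  # A stopped for non-response at day 200 -> event
  expect_equal(nr$time[nr$patient_id == "A"], 200)
  expect_equal(nr$event[nr$patient_id == "A"], 1L)
  # C stopped for another reason at day 100 -> censored at 100
  expect_equal(nr$time[nr$patient_id == "C"], 100)
  expect_equal(nr$event[nr$patient_id == "C"], 0L)
  # D ongoing, record ends day 300 -> censored at 300
  expect_equal(nr$time[nr$patient_id == "D"], 300)
  expect_equal(nr$event[nr$patient_id == "D"], 0L)

  re <- build_survival(reg, coh, "response20")
  # A: entry DAS28 4.0, visit day 90 at 3.2 = exactly 20% down -> event
  expect_equal(re$time[re$patient_id == "A"], 90)
  expect_equal(re$event[re$patient_id == "A"], 1L)
  # D: no post-entry DAS28, record ends day 300 -> censored
  expect_equal(re$time[re$patient_id == "D"], 300)
  expect_equal(re$event[re$patient_id == "D"], 0L)
})

test_that("ongoing records are capped at the 15-month follow-up", {
  reg <- toy_registry()
  reg$patients$record_end_day <- 600L
  reg$treatments$stop_day <- NA_integer_
  reg$treatments$stop_reason <- "none"
  coh <- suppressMessages(select_cohort(reg))
  nr <- build_survival(reg, coh, "non_response")
  expect_true(all(nr$time == 456))
  expect_true(all(nr$event == 0L))
  expect_true(all(nr$time > 0 & nr$time <= 456))
})

test_that("a response after discontinuation does not count as an event", {
  reg <- toy_registry()
  # A discontinued (non-response) at day 200; response visit is at day 90
  # -> still an event.  Move the response visit after the stop: censored at
  # the stop.
  reg$visits$day[reg$visits$patient_id == "A" & reg$visits$day == 90] <- 250L
  coh <- suppressMessages(select_cohort(reg))
  re <- build_survival(reg, coh, "response20")
  expect_equal(re$time[re$patient_id == "A"], 200)
  expect_equal(re$event[re$patient_id == "A"], 0L)
})

test_that("null effects keep the Cox estimate near 1", {
  rec <- make_cox_records(n = 2000, hr = 1, seed = 1)
  est <- fit_cox(rec, "drug")
  e <- est[est$exposure == "tocilizumab", ]
  expect_false(e$suppressed)
  expect_gt(e$hr, 0.85)
  expect_lt(e$hr, 1.18)
})

test_that("a planted HR of 2 is recovered with nominal CI coverage", {
  hrs <- numeric(20)
  covered <- logical(20)
  for (s in 1:20) {
    rec <- make_cox_records(n = 2000, hr = 2, seed = 100 + s)
    e <- fit_cox(rec, "drug")
    e <- e[e$exposure == "tocilizumab", ]
    hrs[s] <- e$hr
    covered[s] <- e$ci_low <= 2 && 2 <= e$ci_high
  }
  expect_lt(abs(mean(hrs) - 2) / 2, 0.10)  # mean within 10%
  expect_gte(sum(covered), 17)             # >= 17/20 seeds
})

test_that("small event counts are suppressed; class coding uses TNFi ref", {
  rec <- make_cox_records(n = 600, hr = 1, seed = 3)
  # keep only 3 events for tocilizumab
  toci_events <- which(rec$drug == "tocilizumab" & rec$event == 1)
  drop <- toci_events[-(1:3)]
  rec$event[drop] <- 0L
  est <- fit_cox(rec, "drug")
  e <- est[est$exposure == "tocilizumab", ]
  expect_true(e$suppressed)
  expect_true(is.na(e$hr))
  expect_equal(e$n_events, 3)
  cls <- fit_cox(rec, "class")
  expect_true(all(cls$reference == "TNFi"))
  expect_true(all(cls$exposure != "TNFi"))
})

test_that("zero events in the reference suppresses instead of crashing", {
  rec <- make_cox_records(n = 200, hr = 1, seed = 4)
  rec$event[rec$drug == "adalimumab"] <- 0L
  est <- fit_cox(rec, "drug")
  expect_true(all(est$suppressed))
})

test_that("per-cluster effects cover every cluster, outcome and coding", {
  rec <- make_cox_records(n = 300, hr = 1, seed = 5,
                          drugs = c("adalimumab", "tocilizumab",
                                    "golimumab"))
  rec2 <- rec
  rec2$outcome_type <- "non_response"
  asg <- tibble::tibble(
    patient_id = rep(rec$patient_id, 2),
    run_id = rep(c("r1", "r2"), each = 300),
    spec_id = 1L, k = 2L,
    cluster = rep(rep(1:2, 150), 2), q_max = 1)
  est <- per_cluster_effects(asg, list(non_response = rec2,
                                       response20 = rec))
  cells <- dplyr::distinct(est[, c("run_id", "cluster", "outcome_type",
                                   "coding")])
  expect_equal(nrow(cells), 2 * 2 * 2 * 2)
})

test_that("robustness filter applies the majority rule exactly", {
  mem <- tibble::tibble(run_id = sprintf("r%d", 1:5), cluster = 1L,
                        unit = sprintf("r%d_c1", 1:5), group_id = 1L)
  groups <- structure(list(membership = mem), class = "ra_cluster_groups")
  base <- tibble::tibble(
    run_id = sprintf("r%d", 1:5), cluster = 1L, scope = NA_character_,
    outcome_type = "response20", coding = "drug", exposure = "tocilizumab",
    reference = "adalimumab", n_events = 10, hr = 2, ci_low = 1.2,
    ci_high = 3.5, suppressed = FALSE, significant = TRUE)

  # significant in 4 of 5 -> reported with the HR range of supporters
  est4 <- base
  est4$significant[5] <- FALSE
  est4$hr <- c(1.8, 2.0, 2.2, 2.6, 9)
  out4 <- robustness_filter(est4, groups)
  expect_equal(nrow(out4), 1)
  expect_equal(out4$n_support, 4)
  expect_equal(out4$direction, "benefit")
  expect_equal(c(out4$hr_min, out4$hr_max), c(1.8, 2.6))

  # significant in 1 of 5 -> not reported
  est1 <- base
  est1$significant[2:5] <- FALSE
  expect_equal(nrow(robustness_filter(est1, groups)), 0)

  # exactly half (2 of 4 clusters) is not a majority
  mem4 <- mem[1:4, ]
  groups4 <- structure(list(membership = mem4),
                       class = "ra_cluster_groups")
  est2 <- base[1:4, ]
  est2$significant[3:4] <- FALSE
  expect_equal(nrow(robustness_filter(est2, groups4)), 0)
})

test_that("adding a non-significant cluster can only weaken a finding", {
  mem <- tibble::tibble(run_id = sprintf("r%d", 1:3), cluster = 1L,
                        unit = sprintf("r%d_c1", 1:3), group_id = 1L)
  base <- tibble::tibble(
    run_id = sprintf("r%d", 1:3), cluster = 1L, scope = NA_character_,
    outcome_type = "non_response", coding = "drug", exposure = "golimumab",
    reference = "adalimumab", n_events = 10, hr = 2.5, ci_low = 1.3,
    ci_high = 4.8, suppressed = FALSE, significant = TRUE)
  g3 <- structure(list(membership = mem), class = "ra_cluster_groups")
  expect_equal(nrow(robustness_filter(base, g3)), 1)   # 3/3 harm finding
  # grow the group with non-significant clusters until the majority is lost
  for (extra in 1:4) {
    mem_x <- dplyr::bind_rows(mem, tibble::tibble(
      run_id = sprintf("x%d", 1:extra), cluster = 1L,
      unit = sprintf("x%d_c1", 1:extra), group_id = 1L))
    gx <- structure(list(membership = mem_x), class = "ra_cluster_groups")
    est_x <- dplyr::bind_rows(base, dplyr::mutate(
      base[rep(1, extra), ], run_id = sprintf("x%d", 1:extra),
      significant = FALSE))
    n_found <- nrow(robustness_filter(est_x, gx))
    expect_equal(n_found, as.integer(3 > (3 + extra) / 2))
  }
})

test_that("direction labels benefit and harm per outcome", {
  mem <- tibble::tibble(run_id = "r1", cluster = 1L, unit = "r1_c1",
                        group_id = 1L)
  g <- structure(list(membership = mem), class = "ra_cluster_groups")
  mk <- function(outcome, hr) tibble::tibble(
    run_id = "r1", cluster = 1L, scope = NA_character_,
    outcome_type = outcome, coding = "drug", exposure = "d",
    reference = "adalimumab", n_events = 10, hr = hr,
    ci_low = ifelse(hr > 1, 1.1, hr / 2),
    ci_high = ifelse(hr > 1, hr * 2, 0.9),
    suppressed = FALSE, significant = TRUE)
  expect_equal(robustness_filter(mk("response20", 2), g)$direction,
               "benefit")
  expect_equal(robustness_filter(mk("response20", 0.5), g)$direction,
               "harm")
  expect_equal(robustness_filter(mk("non_response", 2), g)$direction,
               "harm")
  expect_equal(robustness_filter(mk("non_response", 0.5), g)$direction,
               "benefit")
})
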