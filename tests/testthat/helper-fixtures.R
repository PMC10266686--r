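# shared fixtures, built in code

# tiny hand-written registry: 4 patients exercising the eligibility rules
toy_registry <- function() {
  patients <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    sex = c("female", "male", "female", "female"),
    age_at_entry = c(50, 60, 45, 55),
    bmi = c(24, 28, NA, 22),
    smoking = c("never", "ever", "never", NA),
    family_history = c("no", NA, "yes", "no"),
    rf_status = c("positive", "positive", "negative", NA),
    acpa_status = c("positive", NA, "negative", "negative"),
    ra_duration_years = c(5, 12, 2, 8),
    record_end_day = c(600L, 600L, 600L, 300L))
  visits <- tibble::tibble(
    patient_id = c("A", "B", "C", "D", "A"),
    day = c(0L, -200L, -30L, -10L, 90L),
    das28 = c(4.0, 5.0, 4.5, 5.5, 3.2),
    esr = c(30, NA, 25, 40, 28),
    haq = c(1.0, 1.5, NA, 2.0, 0.8),
    pain_vas = c(5, 6, 4, NA, 3),
    activity_vas = c(5, 6, 4, 7, 3),
    sf12_phys = c(35, 30, NA, 28, 38),
    sf12_ment = c(45, 40, 50, NA, 46),
    swollen = c(5, 8, 3, 10, 2),
    tender = c(6, 9, 4, 12, 3))
  medications <- tibble::tibble(
    patient_id = c("A", "A", "B", "C"),
    agent = c("methotrexate", "prednisone", "methotrexate", "leflunomide"),
    start_day = c(-300L, -100L, -400L, -500L),
    stop_day = c(NA_integer_, 200L, -250L, NA_integer_))
  treatments <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    drug = c("adalimumab", "tocilizumab", "etanercept", "golimumab"),
    start_day = 0L,
    stop_day = c(200L, NA_integer_, 100L, NA_integer_),
    stop_reason = c("non_response", "none", "other", "none"))
  structure(list(patients = patients, visits = visits,
                 medications = medications, treatments = treatments,
                 ground_truth = NULL, config = NULL),
            class = "ra_registry")
}

# small simulated cohort shared by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 300, seed = 42L)
      cache <<- suppressMessages(simulate_registry(cfg))
    }
    cache
  }
})

# k spherical blobs in d dimensions with exact pairwise separation `sep`
# (centers sit on orthonormal directions scaled by sep/sqrt(2))
make_blobs <- function(n = 300, d = 5, k = 3, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  dirs <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  centers <- t(dirs) * sep / sqrt(2)
  labels <- rep(seq_len(k), length.out = n)
  x <- centers[labels, ] + matrix(stats::rnorm(n * d, sd = sd), n, d)
  list(x = x, mask = matrix(1, n, d), labels = labels)
}

# adjusted Rand index between two labellings (contingency-table form)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# survival records with exponential event times and planted hazard ratios,
# used as a direct fixture for Cox-level tests (bypasses the registry)
make_cox_records <- function(n = 2000, hr = 1, seed = 1,
                             drugs = c("adalimumab", "tocilizumab"),
                             base_hazard = 8e-4, censor = 456) {
  set.seed(seed)
  drug <- sample(drugs, n, replace = TRUE)
  rate <- base_hazard * ifelse(drug == drugs[2], hr, 1)
  t <- stats::rexp(n, rate)
  time <- pmin(t, censor)
  tibble::tibble(
    patient_id = sprintf("S%04d", seq_len(n)), time = time,
    event = as.integer(t <= censor), outcome_type = "response20",
    drug = drug,
    drug_class = ifelse(drug == "adalimumab", "TNFi", "non-TNFi"),
    age = stats::rnorm(n, 55, 10),
    sex = sample(c("female", "male"), n, replace = TRUE))
}
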