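#' Generate a synthetic first-b/tsDMARD cohort
#'
#' Draws a registry-like cohort with planted latent phenotypes.  Each patient
#' gets demographics, serostatus, co-medication episodes, one pre-entry visit
#' carrying the clinical scores (day 0 = start of the first b/tsDMARD), and an
#' assigned b/tsDMARD.  Feature-level missingness is applied after value
#' generation by masking each feature independently at its configured rate.
#' Treatment outcomes are not drawn here; see [generate_outcomes()].
#'
#' @param config an [sim_config()] object.
#' @return An `ra_registry`: a list of tibbles `patients`, `visits`,
#'   `medications`, `treatments`, `ground_truth`, plus the config.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "ra_sim_config"), "config must be sim_config()")
  with_seed(derive_seed(config$seed, 0L), generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  G <- length(config$group_weights)
  group <- sample.int(G, n, replace = TRUE, prob = config$group_weights)
  pid <- sprintf("P%05d", seq_len(n))
  prof <- config$feature_profiles
  pget <- function(field) vapply(prof, function(p) p[[field]], numeric(1))[group]
  # missingness_rates: one shared named vector (MCAR) or a list with one
  # vector per latent group (group-dependent missingness)
  miss_tab <- config$missingness_rates
  miss <- if (is.list(miss_tab)) {
    stats::setNames(lapply(names(miss_tab[[1]]), function(f) {
      vapply(miss_tab, `[[`, numeric(1), f)[group]
    }), names(miss_tab[[1]]))
  } else as.list(miss_tab)
  mask_na <- function(x, rate) {
    if (all(rate <= 0)) return(x)
    x[stats::runif(length(x)) < rate] <- NA
    x
  }

  sex <- ifelse(stats::runif(n) < pget("female"), "female", "male")
  age <- pmin(90, pmax(18, stats::rnorm(n, pget("age_mean"), pget("age_sd"))))
  bmi <- mask_na(pmax(15, stats::rnorm(n, pget("bmi_mean"), pget("bmi_sd"))),
                 miss[["bmi"]])
  smoking <- mask_na(ifelse(stats::runif(n) < pget("smoking_ever"),
                            "ever", "never"), miss[["smoking"]])
  famhx <- mask_na(ifelse(stats::runif(n) < pget("family_history_yes"),
                          "yes", "no"), miss[["family_history"]])
  rf <- ifelse(stats::runif(n) < pget("rf_positive"), "positive", "negative")
  p_acpa <- ifelse(rf == "positive", pget("acpa_pos_given_rfpos"),
                   pget("acpa_pos_given_rfneg"))
  acpa <- ifelse(stats::runif(n) < p_acpa, "positive", "negative")
  rf <- mask_na(rf, miss[["rf_status"]])
  acpa <- mask_na(acpa, miss[["acpa_status"]])
  duration <- stats::rlnorm(n, pget("duration_meanlog"), pget("duration_sdlog"))

  patients <- tibble::tibble(
    patient_id = pid, sex = sex, age_at_entry = round(age, 1),
    bmi = round(bmi, 1), smoking = smoking, family_history = famhx,
    rf_status = rf, acpa_status = acpa,
    ra_duration_years = round(duration, 2),
    record_end_day = NA_integer_)

  # one pre-entry visit holding the clinical scores; DAS28-esr always present
  # (cohort eligibility requires a DAS28 within 6 months before entry)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  sf_missing <- stats::runif(n) < miss[["sf12"]]
  visits <- tibble::tibble(
    patient_id = pid,
    day = -sample.int(61, n, replace = TRUE) + 1L,  # uniform on [-60, 0]
    das28 = round(clip(stats::rnorm(n, pget("das28_mean"), pget("das28_sd")),
                       0.5, 9.5), 2),
    esr = mask_na(round(pmax(2, stats::rnorm(n, pget("esr_mean"),
                                             pget("esr_sd")))), miss[["esr"]]),
    haq = mask_na(round(clip(stats::rnorm(n, pget("haq_mean"), pget("haq_sd")),
                             0, 3), 2), miss[["haq"]]),
    pain_vas = mask_na(round(clip(stats::rnorm(n, pget("pain_mean"),
                                               pget("pain_sd")), 0, 10), 1),
                       miss[["pain"]]),
    activity_vas = mask_na(round(clip(stats::rnorm(n, pget("activity_mean"),
                                                   pget("activity_sd")),
                                      0, 10), 1), miss[["activity"]]),
    sf12_phys = round(stats::rnorm(n, pget("sf12p_mean"), pget("sf12p_sd")), 1),
    sf12_ment = round(stats::rnorm(n, pget("sf12m_mean"), pget("sf12m_sd")), 1),
    swollen = mask_na(round(pmax(0, stats::rnorm(n, pget("swollen_mean"),
                                                 pget("swollen_sd")))),
                      miss[["swollen"]]),
    tender = mask_na(round(pmax(0, stats::rnorm(n, pget("tender_mean"),
                                                pget("tender_sd")))),
                     miss[["tender"]]))
  visits$sf12_phys[sf_missing] <- NA_real_
  visits$sf12_ment[sf_missing] <- NA_real_

  # csDMARD / prednisone episodes; "users" have an episode spanning entry
  # (day 0); some non-users carry an already-stopped historical episode
  meds <- purrr::map_dfr(
    c(methotrexate = "mtx", leflunomide = "lef", sulfasalazine = "ssz",
      prednisone = "prednisone"),
    function(field) {
      p_use <- pget(field)
      user <- stats::runif(n) < p_use
      past <- !user & stats::runif(n) < 0.10
      idx_u <- which(user)
      idx_p <- which(past)
      cur <- tibble::tibble(
        patient_id = pid[idx_u],
        start_day = -sample(30:1095, length(idx_u), replace = TRUE),
        stop_day = ifelse(stats::runif(length(idx_u)) < 0.7, NA_integer_,
                          sample(30:400, length(idx_u), replace = TRUE)))
      old <- tibble::tibble(
        patient_id = pid[idx_p],
        start_day = -sample(500:1500, length(idx_p), replace = TRUE),
        stop_day = -sample(60:400, length(idx_p), replace = TRUE))
      old$stop_day <- pmax(old$stop_day, old$start_day + 30L)
      dplyr::bind_rows(cur, old)
    }, .id = "agent")
  medications <- dplyr::arrange(
    meds[, c("patient_id", "agent", "start_day", "stop_day")],
    .data$patient_id, .data$agent)

  drug_tabs <- config$drug_assignment
  if (is.data.frame(drug_tabs)) drug_tabs <- rep(list(drug_tabs), G)
  drug <- character(n)
  for (g in seq_len(G)) {
    idx <- which(group == g)
    if (length(idx)) {
      drug[idx] <- sample(drug_tabs[[g]]$drug, length(idx), replace = TRUE,
                          prob = drug_tabs[[g]]$prob)
    }
  }
  treatments <- tibble::tibble(
    patient_id = pid, drug = drug, start_day = 0L,
    stop_day = NA_integer_, stop_reason = "none")

  structure(list(patients = patients, visits = visits,
                 medications = medications, treatments = treatments,
                 ground_truth = tibble::tibble(patient_id = pid,
                                               group = as.integer(group)),
                 config = config),
            class = "ra_registry")
}

# log HR lookup: (group, drug, outcome) -> planted log hazard ratio (0 if
# the combination is not in the effect table)
planted_log_hr <- function(effects, group, drug, outcome) {
  out <- numeric(length(group))
  tab <- effects$log_hr[effects$log_hr$outcome == outcome, , drop = FALSE]
  if (nrow(tab) == 0) return(out)
  key <- paste(group, drug)
  tkey <- paste(tab$group, tab$drug)
  hit <- match(key, tkey)
  out[!is.na(hit)] <- tab$log_hr[hit[!is.na(hit)]]
  out
}

#' Draw treatment outcomes for a generated cohort
#'
#' For each patient, draws exponential event times for the two outcomes with
#' hazard `baseline_hazard * exp(log_hr[group, drug, outcome])`, an
#' independent other-cause discontinuation time, and a registry dropout time.
#' The earliest of non-response / other discontinuation before the end of
#' record closes the treatment episode with its reason; a response event
#' before the end of record emits a post-entry visit whose DAS28-esr is
#' reduced by more than 20% from the entry value.  Routine follow-up visits
#' (every 90 days, DAS28 fluctuating above the response threshold) are added
#' up to the end of record.
#'
#' @param registry an `ra_registry` from [generate_cohort()].
#' @param config the same [sim_config()]; its `effects` and `censoring`
#'   entries drive the event mechanism.
#' @return The registry with `treatments` stop columns, patient
#'   `record_end_day`, and post-entry visits filled in.
#' @export
generate_outcomes <- function(registry, config = registry$config) {
  assert_that(inherits(registry, "ra_registry"), "registry required")
  assert_that(all(registry$treatments$start_day == 0L),
              "patients must have a first b/tsDMARD episode at day 0")
  assert_that(all(config$effects$baseline_hazard > 0),
              "baseline hazards must be positive")
  with_seed(derive_seed(config$seed, 1000003L),
            generate_outcomes_impl(registry, config))
}

generate_outcomes_impl <- function(registry, config) {
  trt <- registry$treatments
  truth <- registry$ground_truth
  stopifnot(identical(trt$patient_id, truth$patient_id))
  n <- nrow(trt)
  eff <- config$effects
  g <- truth$group
  d <- trt$drug

  rexp_safe <- function(n, rate) {
    if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
  }
  h_nr <- eff$baseline_hazard[["non_response"]] *
    exp(planted_log_hr(eff, g, d, "non_response"))
  h_re <- eff$baseline_hazard[["response20"]] *
    exp(planted_log_hr(eff, g, d, "response20"))
  t_nr <- stats::rexp(n, 1) / h_nr
  t_re <- stats::rexp(n, 1) / h_re
  t_other <- rexp_safe(n, eff$other_discontinuation_hazard)
  t_drop <- rexp_safe(n, config$censoring$dropout_rate)
  record_end <- pmax(1, ceiling(pmin(t_drop, config$censoring$horizon)))

  stop_time <- pmin(t_nr, t_other)
  stopped <- is.finite(stop_time) & stop_time <= record_end
  stop_day <- ifelse(stopped, pmax(1, ceiling(stop_time)), NA_integer_)
  reason <- ifelse(stopped, ifelse(t_nr <= t_other, "non_response", "other"),
                   "none")
  trt$stop_day <- as.integer(stop_day)
  trt$stop_reason <- reason
  registry$treatments <- trt
  registry$patients$record_end_day <- as.integer(record_end)

  # entry DAS28 = the pre-entry visit value (one pre-entry visit per patient)
  entry_das <- registry$visits$das28[match(trt$patient_id,
                                           registry$visits$patient_id)]

  responded <- is.finite(t_re) & t_re <= record_end
  resp_day <- pmax(1, round(t_re))
  resp_visits <- tibble::tibble(
    patient_id = trt$patient_id[responded],
    day = as.integer(resp_day[responded]),
    das28 = round(0.75 * entry_das[responded], 2))

  # routine visits every 90 days until end of record, staying above the 20%
  # reduction threshold so only the planted response event triggers response
  max_k <- floor(max(record_end) / 90)
  routine <- purrr::map_dfr(seq_len(max_k), function(k) {
    idx <- which(record_end >= 90 * k)
    tibble::tibble(patient_id = trt$patient_id[idx], day = 90L * k,
                   das28 = round(entry_das[idx] *
                                   stats::runif(length(idx), 0.85, 1.05), 2))
  })
  post <- dplyr::bind_rows(resp_visits, routine)
  if (nrow(post)) {
    empty_cols <- setdiff(names(registry$visits), names(post))
    for (cl in empty_cols) post[[cl]] <- registry$visits[[cl]][NA_integer_]
    registry$visits <- dplyr::arrange(
      dplyr::bind_rows(registry$visits, post[, names(registry$visits)]),
      .data$patient_id, .data$day)
  }
  registry
}

#' Simulate a complete synthetic registry
#'
#' Convenience wrapper: [generate_cohort()] then [generate_outcomes()].
#'
#' @inheritParams generate_cohort
#' @return An `ra_registry` with outcomes drawn.
#' @export
simulate_registry <- function(config = sim_config()) {
  generate_outcomes(generate_cohort(config), config)
}

#' @export
print.ra_registry <- function(x, ...) {
  cat("<ra_registry>\n")
  cat("  patients:   ", nrow(x$patients), "\n")
  cat("  visits:     ", nrow(x$visits), "\n")
  cat("  medications:", nrow(x$medications), "\n")
  cat("  treatments: ", nrow(x$treatments), "\n")
  if (!is.null(x$ground_truth)) {
    cat("  ground truth groups:",
        paste(table(x$ground_truth$group), collapse = " / "), "\n")
  }
  invisible(x)
}

#' Write a registry to delimited text files
#'
#' Writes `patients.csv`, `visits.csv`, `medications.csv`, `treatments.csv`
#' and `ground_truth.csv` (dates as integer day offsets from cohort entry).
#'
#' @param registry an `ra_registry`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("patients", "visits", "medications", "treatments",
                "ground_truth")) {
    utils::write.csv(registry[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a registry from delimited text files written by [write_registry()]
#'
#' @param dir directory holding the CSV tables.
#' @return An `ra_registry` (without a config).
#' @export
read_registry <- function(dir) {
  rd <- function(f) tibble::as_tibble(
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  gt <- file.path(dir, "ground_truth.csv")
  structure(list(patients = rd("patients.csv"), visits = rd("visits.csv"),
                 medications = rd("medications.csv"),
                 treatments = rd("treatments.csv"),
                 ground_truth = if (file.exists(gt)) rd("ground_truth.csv"),
                 config = NULL),
            class = "ra_registry")
}
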