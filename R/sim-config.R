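#' Default b/tsDMARD catalogue
#'
#' The ten first-line biologic / targeted-synthetic DMARDs modelled by the
#' synthetic registry, their drug class, and the default assignment
#' probability (shared by all latent groups, so treatment is unconfounded by
#' phenotype unless the assignment table is edited).
#'
#' @return A tibble with columns `drug`, `class` (TNFi, non-TNFi, JAKi) and
#'   `prob`.
#' @export
drug_catalogue <- function() {
  tibble::tribble(
    ~drug,          ~class,     ~prob,
    "adalimumab",   "TNFi",     0.21,
    "etanercept",   "TNFi",     0.21,
    "infliximab",   "TNFi",     0.12,
    "golimumab",    "TNFi",     0.07,
    "certolizumab", "TNFi",     0.04,
    "abatacept",    "non-TNFi", 0.08,
    "rituximab",    "non-TNFi", 0.06,
    "tocilizumab",  "non-TNFi", 0.13,
    "baricitinib",  "JAKi",     0.02,
    "tofacitinib",  "JAKi",     0.06
  )
}

# Per-group generative profiles for the five planted phenotypes:
#   1 combination-therapy: high csDMARD + prednisone use, seropositive leaning
#   2 male: almost all men, highest smoking and BMI
#   3 seronegative: RF negative, low prednisone, mostly women
#   4 seropositive high-burden: long duration, high DAS28/HAQ/pain/activity
#   5 low-burden: low disease activity and disability
default_feature_profiles <- function() {
  base <- list(
    female = 0.96, age_mean = 55.4, age_sd = 13.6,
    bmi_mean = 25.2, bmi_sd = 5.0,
    smoking_ever = 0.35, family_history_yes = 0.35,
    rf_positive = 0.82, acpa_pos_given_rfpos = 0.90, acpa_pos_given_rfneg = 0.15,
    duration_meanlog = log(5.8), duration_sdlog = 1.0,
    das28_mean = 4.5, das28_sd = 1.0,
    esr_mean = 30, esr_sd = 15,
    haq_mean = 1.1, haq_sd = 0.55,
    pain_mean = 5.0, pain_sd = 2.0,
    activity_mean = 5.0, activity_sd = 2.0,
    sf12p_mean = 34.5, sf12p_sd = 9, sf12m_mean = 45.6, sf12m_sd = 11.9,
    swollen_mean = 5, swollen_sd = 3.5, tender_mean = 6, tender_sd = 4,
    mtx = 0.58, lef = 0.15, ssz = 0.09, prednisone = 0.40
  )
  amend <- function(...) utils::modifyList(base, list(...))
  list(
    amend(mtx = 0.88, lef = 0.55, ssz = 0.45, prednisone = 0.80,
          family_history_yes = 0.25),
    amend(female = 0.005, smoking_ever = 0.75, bmi_mean = 28.5, bmi_sd = 4.5,
          rf_positive = 0.72, prednisone = 0.42),
    amend(rf_positive = 0.005, prednisone = 0.28),
    amend(rf_positive = 0.85, das28_mean = 5.1, das28_sd = 0.9,
          haq_mean = 1.6, haq_sd = 0.45,
          pain_mean = 6.8, pain_sd = 1.8, activity_mean = 6.6,
          activity_sd = 1.8, duration_meanlog = log(11),
          duration_sdlog = 0.8, esr_mean = 38, esr_sd = 14,
          sf12p_mean = 29, sf12p_sd = 8,
          swollen_mean = 8, swollen_sd = 3, tender_mean = 9, tender_sd = 3.5,
          prednisone = 0.42),
    amend(das28_mean = 3.5, das28_sd = 0.9, haq_mean = 0.55,
          haq_sd = 0.35, pain_mean = 2.8, pain_sd = 1.5, activity_mean = 3.0,
          activity_sd = 1.5, duration_meanlog = log(4.8), sf12p_mean = 41,
          sf12p_sd = 8, esr_mean = 22, esr_sd = 12,
          swollen_mean = 2.5, swollen_sd = 2, tender_mean = 3,
          tender_sd = 2.5, prednisone = 0.35)
  )
}

#' Default per-feature missingness rates
#'
#' Per-feature probability of being unobserved (MCAR masking applied after
#' value generation).  Marginal rates follow the overall cohort description;
#' DAS28 at entry is never missing because eligibility requires it.
#'
#' @return Named numeric vector of masking probabilities.
#' @export
default_missingness_rates <- function() {
  c(bmi = 0.10, smoking = 0.15, family_history = 0.324,
    rf_status = 0.042, acpa_status = 0.274,
    das28 = 0, esr = 0.05, haq = 0.122, pain = 0.113, activity = 0.12,
    sf12 = 0.206, swollen = 0.05, tender = 0.05)
}

#' Planted group-by-drug treatment effects
#'
#' Encodes the data-generating hazards of the synthetic registry: a constant
#' baseline hazard per outcome plus a table of log hazard ratios indexed by
#' (latent group, drug, outcome).  Drug/group combinations absent from the
#' table have log HR 0.  The default plants a single differential effect:
#' tocilizumab triples the response hazard in the male phenotype (group 2).
#'
#' @param baseline_hazard named numeric: events/day for `non_response` and
#'   `response20`.
#' @param log_hr tibble with columns `group`, `drug`, `outcome`, `log_hr`.
#' @param other_discontinuation_hazard events/day hazard of stopping the drug
#'   for reasons other than non-response (a censoring process downstream).
#' @return An object of class `ra_effect_spec`.
#' @export
treatment_effect_spec <- function(
    baseline_hazard = c(non_response = 4.5e-4, response20 = 1.1e-3),
    log_hr = tibble::tibble(group = 2L, drug = "tocilizumab",
                            outcome = "response20", log_hr = log(3)),
    other_discontinuation_hazard = 3e-4) {
  assert_that(all(baseline_hazard > 0), "baseline_hazard must be positive")
  assert_that(all(is.finite(log_hr$log_hr)), "log_hr must be finite")
  assert_that(other_discontinuation_hazard >= 0,
              "other_discontinuation_hazard must be non-negative")
  structure(list(baseline_hazard = baseline_hazard, log_hr = log_hr,
                 other_discontinuation_hazard = other_discontinuation_hazard),
            class = "ra_effect_spec")
}

#' Synthetic registry configuration
#'
#' Bundles every parameter of the synthetic first-b/tsDMARD cohort: latent
#' phenotype mixture, per-group feature distributions, feature-level
#' missingness, drug assignment, planted treatment effects, and censoring.
#' Defaults reproduce the marginal characteristics of a ~3,500-patient
#' first-biologic RA cohort (76% women, mean DAS28-esr 4.3, 27% missing ACPA)
#' with five planted phenotypes.
#'
#' @param n_patients number of patients to simulate.
#' @param group_weights probability of each latent phenotype; must sum to 1.
#' @param feature_profiles list (one element per group) of distribution
#'   parameters; see `default_feature_profiles()`.
#' @param missingness_rates named per-feature masking probabilities in
#'   `[0,1]` (MCAR), or a list of one such vector per latent group for
#'   group-dependent missingness.
#' @param drug_assignment either a single drug/class/prob tibble shared by all
#'   groups or a list of one tibble per group.
#' @param effects an `ra_effect_spec`.
#' @param censoring list with `horizon` (administrative end of record, days)
#'   and `dropout_rate` (per-day hazard of leaving the registry).
#' @param seed integer master seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @return An object of class `ra_sim_config`.
#' @export
sim_config <- function(n_patients = 3516,
                       group_weights = c(0.19, 0.21, 0.15, 0.16, 0.29),
                       feature_profiles = default_feature_profiles(),
                       missingness_rates = default_missingness_rates(),
                       drug_assignment = drug_catalogue(),
                       effects = treatment_effect_spec(),
                       censoring = list(horizon = 600, dropout_rate = 1e-4),
                       seed = 1L) {
  assert_that(is.numeric(n_patients) && n_patients >= 1,
              "n_patients must be >= 1")
  assert_that(abs(sum(group_weights) - 1) < 1e-12,
              "group_weights must sum to 1")
  assert_that(all(group_weights >= 0), "group_weights must be non-negative")
  assert_that(length(feature_profiles) == length(group_weights),
              "one feature profile per group is required")
  if (is.list(missingness_rates)) {
    assert_that(length(missingness_rates) == length(group_weights),
                "per-group missingness needs one rate vector per group")
    for (mr in missingness_rates) {
      assert_that(is_prob(mr), "missingness_rates must lie in [0, 1]")
    }
  } else {
    assert_that(is_prob(missingness_rates),
                "missingness_rates must lie in [0, 1]")
  }
  assert_that(inherits(effects, "ra_effect_spec"),
              "effects must be a treatment_effect_spec()")
  assert_that(censoring$horizon > 0 && censoring$dropout_rate >= 0,
              "censoring horizon must be positive, dropout_rate >= 0")
  if (!is.data.frame(drug_assignment)) {
    assert_that(length(drug_assignment) == length(group_weights),
                "drug_assignment must be one table or one per group")
    for (tab in drug_assignment) {
      assert_that(abs(sum(tab$prob) - 1) < 1e-9,
                  "drug assignment probabilities must sum to 1")
    }
  } else {
    assert_that(abs(sum(drug_assignment$prob) - 1) < 1e-9,
                "drug assignment probabilities must sum to 1")
  }
  structure(list(n_patients = as.integer(n_patients),
                 group_weights = group_weights,
                 feature_profiles = feature_profiles,
                 missingness_rates = missingness_rates,
                 drug_assignment = drug_assignment,
                 effects = effects, censoring = censoring,
                 seed = as.integer(seed)),
            class = "ra_sim_config")
}

#' @export
print.ra_sim_config <- function(x, ...) {
  cat("<ra_sim_config>\n")
  cat("  patients:", x$n_patients, " groups:", length(x$group_weights),
      " seed:", x$seed, "\n")
  cat("  group weights:", paste(format(x$group_weights), collapse = " "), "\n")
  cat("  planted effects:", nrow(x$effects$log_hr), "\n")
  invisible(x)
}
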