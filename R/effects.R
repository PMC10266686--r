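#' Build time-to-event records for one outcome
#'
#' Follow-up starts at cohort entry (first b/tsDMARD start) and is capped at
#' 456 days (15 months).  For `non_response`, the event is drug
#' discontinuation with reason non-response; censoring is the earliest of
#' discontinuation for another reason, end of record, or the follow-up cap.
#' For `response20`, the event is the first post-entry visit whose DAS28-esr
#' is at or below 80% of the entry value; censoring is the earliest of any
#' discontinuation, end of record, or the cap.
#'
#' @param registry an `ra_registry`.
#' @param cohort output of [select_cohort()]; entry DAS28 must be present.
#' @param outcome_type `"non_response"` or `"response20"`.
#' @param drug_classes tibble mapping `drug` to `class` (default
#'   [drug_catalogue()]).
#' @return Tibble with `patient_id`, `time` (days, in `(0, 456]`), `event`,
#'   `outcome_type`, `drug`, `drug_class`, `age`, `sex`.
#' @export
build_survival <- function(registry, cohort,
                           outcome_type = c("non_response", "response20"),
                           drug_classes = drug_catalogue()) {
  outcome_type <- match.arg(outcome_type)
  assert_that(all(!is.na(cohort$entry_das28)),
              "entry DAS28 missing for some patients; cohort must be eligible")
  trt <- registry$treatments |>
    dplyr::inner_join(cohort[, c("patient_id", "entry_day", "entry_das28")],
                      by = "patient_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$start_day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pat <- registry$patients[match(trt$patient_id,
                                 registry$patients$patient_id), ]
  # end of record relative to entry (fall back to last observed activity)
  last_seen <- registry$visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(last_day = max(.data$day), .groups = "drop")
  rec_end_abs <- pat$record_end_day
  fallback <- pmax(last_seen$last_day[match(trt$patient_id,
                                            last_seen$patient_id)],
                   trt$stop_day, trt$start_day, na.rm = TRUE)
  rec_end_abs[is.na(rec_end_abs)] <- fallback[is.na(rec_end_abs)]
  rec_end <- rec_end_abs - trt$entry_day

  stop_rel <- trt$stop_day - trt$entry_day

  if (outcome_type == "non_response") {
    t_event <- ifelse(!is.na(stop_rel) & trt$stop_reason == "non_response",
                      stop_rel, Inf)
    t_other <- ifelse(!is.na(stop_rel) & trt$stop_reason != "non_response",
                      stop_rel, Inf)
    t_cens <- pmin(t_other, rec_end, FOLLOWUP_DAYS)
  } else {
    thresh <- 0.8 * trt$entry_das28
    resp <- registry$visits |>
      dplyr::inner_join(trt[, c("patient_id", "entry_day")],
                        by = "patient_id") |>
      dplyr::filter(.data$day > .data$entry_day, !is.na(.data$das28)) |>
      dplyr::mutate(rel = .data$day - .data$entry_day)
    resp <- resp[resp$das28 <= 0.8 *
                   trt$entry_das28[match(resp$patient_id, trt$patient_id)], ]
    first_resp <- resp |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(t_resp = min(.data$rel), .groups = "drop")
    t_event <- first_resp$t_resp[match(trt$patient_id,
                                       first_resp$patient_id)]
    t_event[is.na(t_event)] <- Inf
    t_any_stop <- ifelse(!is.na(stop_rel), stop_rel, Inf)
    t_cens <- pmin(t_any_stop, rec_end, FOLLOWUP_DAYS)
  }

  time <- pmin(t_event, t_cens)
  event <- as.integer(is.finite(t_event) & t_event <= t_cens)
  out <- tibble::tibble(
    patient_id = trt$patient_id, time = time, event = event,
    outcome_type = outcome_type, drug = trt$drug,
    drug_class = drug_classes$class[match(trt$drug, drug_classes$drug)],
    age = pat$age_at_entry, sex = pat$sex)
  out[out$time > 0, ]
}

#' Cox proportional-hazards comparative effectiveness
#'
#' Partial-likelihood fit (Efron tie handling) of the exposure against its
#' reference: TNFi under class coding, adalimumab under drug coding.  Wald
#' 95% confidence intervals.  Exposure levels with fewer events than
#' `min_events`, and fits that fail or degenerate, are reported with
#' `suppressed = TRUE` and no estimate.
#'
#' @param records survival records from [build_survival()].
#' @param exposure_coding `"class"` or `"drug"`.
#' @param adjustment subset of `c("age", "sex")` added as covariates (crude
#'   fit when empty); a covariate with a single observed level is dropped.
#' @param min_events suppression threshold on the exposure-level event count.
#' @param scope label carried into the output (cluster or stratum id).
#' @return Tibble of effect estimates: one row per non-reference exposure
#'   level with `hr`, `ci_low`, `ci_high`, `n_events`, `suppressed`,
#'   `significant` (95% CI excludes 1).
#' @export
fit_cox <- function(records, exposure_coding = c("class", "drug"),
                    adjustment = character(), min_events = 5,
                    scope = NA_character_) {
  exposure_coding <- match.arg(exposure_coding)
  ref <- if (exposure_coding == "class") "TNFi" else "adalimumab"
  expo <- if (exposure_coding == "class") records$drug_class else records$drug
  levs <- c(ref, sort(setdiff(unique(expo), ref)))
  dat <- data.frame(time = records$time, event = records$event,
                    exposure = factor(expo, levels = levs),
                    age = records$age,
                    sex = records$sex, stringsAsFactors = FALSE)
  dat <- dat[!is.na(dat$exposure), ]
  events_by_level <- tapply(dat$event, dat$exposure, sum, default = 0L)
  out_levels <- setdiff(levs, ref)
  base <- tibble::tibble(
    scope = scope, outcome_type = records$outcome_type[1] %||% NA_character_,
    coding = exposure_coding, exposure = out_levels, reference = ref,
    n_events = as.numeric(events_by_level[out_levels]),
    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    suppressed = TRUE, significant = FALSE)
  if (!ref %in% dat$exposure || length(unique(dat$exposure)) < 2 ||
      sum(events_by_level) == 0 || events_by_level[[ref]] == 0) {
    return(base)
  }
  adjustment <- intersect(adjustment, c("age", "sex"))
  for (cov in adjustment) {
    if (length(unique(dat[[cov]][!is.na(dat[[cov]])])) < 2) {
      adjustment <- setdiff(adjustment, cov)
    }
  }
  fml <- stats::reformulate(c("exposure", adjustment),
                            response = "survival::Surv(time, event)")
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(base)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  for (i in seq_len(nrow(base))) {
    nm <- paste0("exposure", base$exposure[i])
    if (!nm %in% names(cf) || !is.finite(cf[nm]) || !is.finite(se[nm]) ||
        se[nm] > 50) next
    if (base$n_events[i] < min_events) next  # small-count suppression
    base$hr[i] <- exp(cf[nm])
    base$ci_low[i] <- exp(cf[nm] - 1.96 * se[nm])
    base$ci_high[i] <- exp(cf[nm] + 1.96 * se[nm])
    base$suppressed[i] <- FALSE
    base$significant[i] <- base$ci_low[i] > 1 || base$ci_high[i] < 1
  }
  base
}

#' Per-cluster comparative effectiveness
#'
#' Fits crude Cox models for both outcomes and both exposure codings within
#' every cluster of every run.
#'
#' @param design an `ra_run_design` (or its assignments tibble).
#' @param records_by_outcome named list with elements `non_response` and
#'   `response20`, each from [build_survival()] on the full cohort.
#' @param min_events suppression threshold.
#' @return Tibble of effect estimates with `run_id` and `cluster` columns.
#' @export
per_cluster_effects <- function(design, records_by_outcome, min_events = 5) {
  assignments <- if (inherits(design, "ra_run_design")) {
    design$assignments
  } else design
  cells <- dplyr::distinct(assignments[, c("run_id", "cluster")])
  purrr::pmap_dfr(cells, function(run_id, cluster) {
    ids <- assignments$patient_id[assignments$run_id == run_id &
                                    assignments$cluster == cluster]
    purrr::map_dfr(names(records_by_outcome), function(oc) {
      rec <- records_by_outcome[[oc]]
      rec <- rec[rec$patient_id %in% ids, ]
      purrr::map_dfr(c("class", "drug"), function(coding) {
        est <- fit_cox(rec, coding, min_events = min_events,
                       scope = sprintf("%s_c%d", run_id, cluster))
        est$outcome_type <- oc
        dplyr::mutate(est, run_id = run_id, cluster = cluster, .before = 1)
      })
    })
  })
}

#' Cross-cluster robustness filter
#'
#' A (group, outcome, exposure, direction) result is reported iff it is
#' significant with a consistent direction in more than half of the group's
#' clusters (the majority rule).  Direction is `benefit` for HR > 1 under
#' `response20` and HR < 1 under `non_response`, otherwise `harm`.
#'
#' @param estimates per-cluster estimates from [per_cluster_effects()].
#' @param groups an `ra_cluster_groups`.
#' @param rule currently `"majority"`; the fraction of the group's clusters
#'   that must support a finding is `> 0.5`.
#' @return Tibble of robust findings: `group_id`, `outcome_type`, `coding`,
#'   `exposure`, `direction`, `n_support`, `n_clusters`, `hr_min`, `hr_max`.
#' @export
robustness_filter <- function(estimates, groups, rule = "majority") {
  assert_that(identical(rule, "majority"), "only the majority rule is
              implemented")
  membership <- if (inherits(groups, "ra_cluster_groups")) {
    groups$membership
  } else groups
  group_sizes <- dplyr::count(membership, .data$group_id, name = "n_clusters")
  est <- estimates |>
    dplyr::inner_join(membership[, c("run_id", "cluster", "group_id")],
                      by = c("run_id", "cluster")) |>
    dplyr::filter(!.data$suppressed, .data$significant) |>
    dplyr::mutate(direction = dplyr::if_else(
      (.data$outcome_type == "response20") == (.data$hr > 1),
      "benefit", "harm"))
  if (nrow(est) == 0) {
    return(tibble::tibble(
      group_id = integer(), outcome_type = character(),
      coding = character(), exposure = character(),
      direction = character(), n_support = integer(),
      n_clusters = integer(), hr_min = numeric(), hr_max = numeric()))
  }
  est |>
    dplyr::group_by(.data$group_id, .data$outcome_type, .data$coding,
                    .data$exposure, .data$direction) |>
    dplyr::summarise(n_support = dplyr::n_distinct(paste(.data$run_id,
                                                         .data$cluster)),
                     hr_min = min(.data$hr), hr_max = max(.data$hr),
                     .groups = "drop") |>
    dplyr::left_join(group_sizes, by = "group_id") |>
    dplyr::filter(.data$n_support > .data$n_clusters / 2) |>
    dplyr::select("group_id", "outcome_type", "coding", "exposure",
                  "direction", "n_support", "n_clusters", "hr_min", "hr_max")
}
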