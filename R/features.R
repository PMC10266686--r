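#' Clustering feature specification
#'
#' Defines the feature set used for clustering and its lookback rules.  Two
#' specifications are supported: spec 1 is the plain feature set; spec 2 adds,
#' for every 6-month-lookback feature, a recency channel equal to (days since
#' the measurement)/183, masked whenever the parent feature is masked.
#'
#' Lookback classes: `ever_before` features use any record up to cohort entry
#' (demographics, serostatus, lifestyle); `at_entry` features are medication
#' flags true iff an episode spans the entry day; `window_6mo` features take
#' the most recent measurement within the closed window `[entry - 183, entry]`
#' and are otherwise masked.
#'
#' @param spec_id 1 or 2.
#' @param features optional tibble with columns `name`, `lookback`
#'   (`ever_before`, `at_entry`, `window_6mo`) and `type` (`continuous`,
#'   `binary`) overriding the default feature list.
#' @return An object of class `ra_feature_spec`.
#' @export
feature_spec <- function(spec_id = 1L, features = default_feature_table()) {
  if (!spec_id %in% c(1L, 2L)) {
    stop("unknown spec_id: ", spec_id, " (must be 1 or 2)", call. = FALSE)
  }
  stopifnot(all(c("name", "lookback", "type") %in% names(features)))
  structure(list(spec_id = as.integer(spec_id), features = features,
                 include_recency = spec_id == 2L),
            class = "ra_feature_spec")
}

#' @rdname feature_spec
#' @export
default_feature_table <- function() {
  tibble::tribble(
    ~name,            ~lookback,     ~type,
    "age",            "ever_before", "continuous",
    "sex_male",       "ever_before", "binary",
    "bmi",            "ever_before", "continuous",
    "smoking_ever",   "ever_before", "binary",
    "family_history", "ever_before", "binary",
    "rf_positive",    "ever_before", "binary",
    "acpa_positive",  "ever_before", "binary",
    "ra_duration",    "ever_before", "continuous",
    "methotrexate",   "at_entry",    "binary",
    "leflunomide",    "at_entry",    "binary",
    "sulfasalazine",  "at_entry",    "binary",
    "prednisone",     "at_entry",    "binary",
    "csdmard_count",  "at_entry",    "continuous",
    "das28",          "window_6mo",  "continuous",
    "esr",            "window_6mo",  "continuous",
    "haq",            "window_6mo",  "continuous",
    "pain_vas",       "window_6mo",  "continuous",
    "activity_vas",   "window_6mo",  "continuous",
    "sf12_phys",      "window_6mo",  "continuous",
    "sf12_ment",      "window_6mo",  "continuous",
    "swollen",        "window_6mo",  "continuous",
    "tender",         "window_6mo",  "continuous"
  )
}

LOOKBACK_DAYS <- 183L   # 6 months
FOLLOWUP_DAYS <- 456L   # 15 months

#' Apply cohort eligibility
#'
#' Keeps patients who (a) have a first b/tsDMARD episode, (b) started it on or
#' after their first recorded visit, and (c) have a DAS28-esr measurement in
#' the closed 6-month window `[entry - 183, entry]`.  Entry (day 0 of
#' follow-up) is the start of the first b/tsDMARD.
#'
#' @param registry an `ra_registry` (or any list with `patients`, `visits`,
#'   `treatments` tibbles in the documented schema).
#' @return Tibble with `patient_id`, `entry_day`, `entry_das28`,
#'   `entry_das28_day`; excluded patients are recorded in the `"excluded"`
#'   attribute with their reason.
#' @export
select_cohort <- function(registry) {
  trt <- registry$treatments
  vis <- registry$visits
  entry <- trt |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(entry_day = min(.data$start_day), .groups = "drop")

  first_visit <- vis |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_visit_day = min(.data$day), .groups = "drop")

  all_ids <- unique(registry$patients$patient_id)
  tab <- tibble::tibble(patient_id = all_ids) |>
    dplyr::left_join(entry, by = "patient_id") |>
    dplyr::left_join(first_visit, by = "patient_id")

  das <- vis |>
    dplyr::filter(!is.na(.data$das28)) |>
    dplyr::inner_join(entry, by = "patient_id") |>
    dplyr::filter(.data$day >= .data$entry_day - LOOKBACK_DAYS,
                  .data$day <= .data$entry_day) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", entry_das28 = "das28",
                  entry_das28_day = "day")

  tab <- dplyr::left_join(tab, das, by = "patient_id")
  reason <- dplyr::case_when(
    is.na(tab$entry_day) ~ "no_btsdmard",
    is.na(tab$first_visit_day) | tab$entry_day < tab$first_visit_day ~
      "btsdmard_before_first_visit",
    is.na(tab$entry_das28) ~ "no_das28_in_window",
    TRUE ~ "eligible")
  excluded <- tibble::tibble(patient_id = tab$patient_id,
                             reason = reason)[reason != "eligible", ]
  if (nrow(excluded)) {
    message(nrow(excluded), " patient(s) excluded (",
            paste(sprintf("%s: %d", names(table(excluded$reason)),
                          table(excluded$reason)), collapse = ", "), ")")
  }
  out <- tab[reason == "eligible",
             c("patient_id", "entry_day", "entry_das28", "entry_das28_day")]
  attr(out, "excluded") <- excluded
  out
}

# most recent observed value of each visit-level measure within the 6-month
# pre-entry window, plus its day
window_measurements <- function(visits, cohort, feats) {
  measures <- intersect(feats$name[feats$lookback == "window_6mo"],
                        names(visits))
  long <- visits |>
    dplyr::inner_join(cohort[, c("patient_id", "entry_day")],
                      by = "patient_id") |>
    dplyr::filter(.data$day >= .data$entry_day - LOOKBACK_DAYS,
                  .data$day <= .data$entry_day) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "feature",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$patient_id, .data$feature) |>
    dplyr::slice_max(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(days_since = .data$entry_day - .data$day)
  long[, c("patient_id", "feature", "value", "days_since")]
}

# medication flags: episode spans the entry day (start <= entry <= stop,
# open-ended episodes span)
entry_medication_flags <- function(medications, cohort) {
  agents <- c(methotrexate = "methotrexate", leflunomide = "leflunomide",
              sulfasalazine = "sulfasalazine", prednisone = "prednisone")
  act <- medications |>
    dplyr::inner_join(cohort[, c("patient_id", "entry_day")],
                      by = "patient_id") |>
    dplyr::filter(.data$start_day <= .data$entry_day,
                  is.na(.data$stop_day) | .data$stop_day >= .data$entry_day,
                  .data$agent %in% agents) |>
    dplyr::distinct(.data$patient_id, .data$agent) |>
    dplyr::mutate(flag = 1)
  wide <- tidyr::pivot_wider(act, names_from = "agent",
                             values_from = "flag", values_fill = 0)
  out <- tibble::tibble(patient_id = cohort$patient_id)
  for (a in agents) {
    out[[a]] <- if (a %in% names(wide)) {
      v <- wide[[a]][match(out$patient_id, wide$patient_id)]
      ifelse(is.na(v), 0, v)
    } else 0
  }
  out$csdmard_count <- out$methotrexate + out$leflunomide + out$sulfasalazine
  out
}

#' Build clustering feature vectors
#'
#' Assembles per-patient feature vectors with an observation mask under a
#' [feature_spec()].  Continuous features are z-scored using observed values
#' only; masked positions carry a sentinel value of 0 that downstream code
#' must never read as data (the mask is authoritative).  Under spec 2, each
#' 6-month-window feature gains a recency channel `(days since
#' measurement)/183` in `[0, 1]`, masked with its parent.
#'
#' @param registry an `ra_registry`.
#' @param cohort output of [select_cohort()] (defaults to selecting from
#'   `registry`).
#' @param spec a [feature_spec()] or a spec id (1 or 2).
#' @return An object of class `ra_features`: list with `patient_id`, matrix
#'   `x` (n x d, standardized, sentinel 0 where masked), binary matrix `mask`
#'   (1 = observed), `spec_id`, `scaling` (per-feature centre/scale), and
#'   `raw` (unscaled values with `NA` where masked, used for profiling).
#' @export
build_features <- function(registry, cohort = select_cohort(registry),
                           spec = feature_spec(1L)) {
  if (is.numeric(spec)) spec <- feature_spec(spec)
  assert_that(inherits(spec, "ra_feature_spec"), "spec must be feature_spec()")
  feats <- spec$features
  pat <- registry$patients[match(cohort$patient_id,
                                 registry$patients$patient_id), ]

  raw <- tibble::tibble(patient_id = cohort$patient_id)
  recency <- list()
  add <- function(raw, name, values) { raw[[name]] <- values; raw }

  # ever-before features from the patient table
  ever_map <- list(
    age = pat$age_at_entry,
    sex_male = as.numeric(pat$sex == "male"),
    bmi = pat$bmi,
    smoking_ever = as.numeric(pat$smoking == "ever"),
    family_history = as.numeric(pat$family_history == "yes"),
    rf_positive = as.numeric(pat$rf_status == "positive"),
    acpa_positive = as.numeric(pat$acpa_status == "positive"),
    ra_duration = pat$ra_duration_years)
  med <- entry_medication_flags(registry$medications, cohort)
  med <- med[match(cohort$patient_id, med$patient_id), ]
  win <- window_measurements(registry$visits, cohort, feats)

  for (i in seq_len(nrow(feats))) {
    nm <- feats$name[i]
    if (feats$lookback[i] == "ever_before") {
      assert_that(nm %in% names(ever_map),
                  paste0("unknown ever_before feature: ", nm))
      raw <- add(raw, nm, ever_map[[nm]])
    } else if (feats$lookback[i] == "at_entry") {
      raw <- add(raw, nm, med[[nm]])
    } else {
      rows <- win[win$feature == nm, ]
      idx <- match(cohort$patient_id, rows$patient_id)
      raw <- add(raw, nm, rows$value[idx])
      recency[[nm]] <- rows$days_since[idx] / LOOKBACK_DAYS
    }
  }

  value_cols <- feats$name
  vals <- as.matrix(raw[, value_cols])
  mask <- 1 - is.na(vals)

  # two-level categoricals (demographics, lifestyle, serostatus) are one-hot
  # encoded: the complement channel shares the mask, so a missing category
  # masks the whole one-hot block
  complements <- c(sex_male = "sex_female", smoking_ever = "smoking_never",
                   family_history = "family_history_no",
                   rf_positive = "rf_negative",
                   acpa_positive = "acpa_negative")
  for (nm in intersect(names(complements), value_cols)) {
    cn <- complements[[nm]]
    vals <- cbind(vals, 1 - vals[, nm])
    colnames(vals)[ncol(vals)] <- cn
    mask <- cbind(mask, mask[, nm])
    colnames(mask)[ncol(mask)] <- cn
  }
  value_cols <- colnames(vals)

  # standardize every channel over observed entries only (binary flags too,
  # so defining traits are not drowned out by the continuous channels)
  scaling <- tibble::tibble(feature = value_cols, center = 0, scale = 1)
  for (i in seq_along(value_cols)) {
    obs <- vals[, i][mask[, i] == 1]
    mu <- mean(obs)
    sd_ <- stats::sd(obs)
    if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
    scaling$center[i] <- mu
    scaling$scale[i] <- sd_
    vals[, i] <- (vals[, i] - mu) / sd_
  }

  if (spec$include_recency) {
    for (nm in names(recency)) {
      cn <- paste0(nm, "_recency")
      vals <- cbind(vals, recency[[nm]])
      colnames(vals)[ncol(vals)] <- cn
      mask <- cbind(mask, 1 - is.na(recency[[nm]]))
      colnames(mask)[ncol(mask)] <- cn
    }
  }
  vals[is.na(vals)] <- 0   # sentinel; the mask is authoritative
  dimnames(mask) <- dimnames(vals)

  structure(list(patient_id = cohort$patient_id, x = vals, mask = mask,
                 spec_id = spec$spec_id, scaling = scaling, raw = raw,
                 feature_table = feats),
            class = "ra_features")
}

#' @export
print.ra_features <- function(x, ...) {
  cat("<ra_features> spec", x$spec_id, ":", nrow(x$x), "patients x",
      ncol(x$x), "channels;",
      sprintf("%.1f%% observed\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Tidy a feature object into a long tibble
#'
#' @param x an `ra_features` object.
#' @param ... unused.
#' @return Long tibble with `patient_id`, `feature`, `value` (standardized;
#'   `NA` where masked) and `observed`.
#' @export
tidy.ra_features <- function(x, ...) {
  vals <- x$x
  vals[x$mask == 0] <- NA
  tibble::as_tibble(vals) |>
    dplyr::mutate(patient_id = x$patient_id, .before = 1) |>
    tidyr::pivot_longer(-"patient_id", names_to = "feature",
                        values_to = "value") |>
    dplyr::mutate(observed = !is.na(.data$value))
}
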