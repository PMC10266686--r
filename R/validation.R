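#' Stratified validation of robustness-filtered findings
#'
#' Re-estimates comparative effectiveness within each clinically defined
#' stratum, crude and age-(and sex-)adjusted, then checks each robust
#' finding against the adjusted estimate in the strata derived from its
#' cluster group: `confirmed` if significant with the same direction,
#' `not_confirmed` if estimable but not significant (or opposite in
#' direction), `inestimable` if suppressed.  Sex is omitted from the
#' adjustment in sex-restricted strata.
#'
#' @param strata list of `ra_stratum` from [derive_strata()].
#' @param features an `ra_features` (or raw feature tibble) used to evaluate
#'   stratum predicates.
#' @param records_by_outcome named list of survival-record tibbles
#'   (`non_response`, `response20`) for the full cohort.
#' @param findings robust findings from [robustness_filter()] (may be empty).
#' @param min_events suppression threshold.
#' @return An object of class `ra_validation`: `estimates` (per stratum x
#'   outcome x coding x exposure, crude and adjusted), `concordance`
#'   (per finding x stratum), and `stratum_sizes`.
#' @export
validate_strata <- function(strata, features, records_by_outcome,
                            findings = NULL, min_events = 5) {
  raw <- if (inherits(features, "ra_features")) features$raw else features
  estimates <- purrr::map_dfr(strata, function(st) {
    ids <- apply_stratum(raw, st)$patient_id
    adj <- c("age", if (!stratum_constrains(st$predicate, "sex_male")) "sex")
    purrr::map_dfr(names(records_by_outcome), function(oc) {
      rec <- records_by_outcome[[oc]]
      rec <- rec[rec$patient_id %in% ids, ]
      purrr::map_dfr(c("class", "drug"), function(coding) {
        crude <- fit_cox(rec, coding, adjustment = character(),
                         min_events = min_events, scope = st$stratum_id)
        adjst <- fit_cox(rec, coding, adjustment = adj,
                         min_events = min_events, scope = st$stratum_id)
        crude$outcome_type <- oc
        dplyr::bind_cols(
          dplyr::rename(crude, stratum_id = "scope", hr_crude = "hr",
                        ci_low_crude = "ci_low", ci_high_crude = "ci_high",
                        suppressed_crude = "suppressed",
                        significant_crude = "significant"),
          dplyr::select(adjst, hr_adj = "hr", ci_low_adj = "ci_low",
                        ci_high_adj = "ci_high",
                        suppressed_adj = "suppressed",
                        significant_adj = "significant")) |>
          dplyr::mutate(n_stratum = length(ids),
                        adjustment = paste(adj, collapse = "+"))
      })
    })
  })

  concordance <- NULL
  if (!is.null(findings) && nrow(findings)) {
    stratum_index <- purrr::map_dfr(strata, function(st) {
      tibble::tibble(stratum_id = st$stratum_id, group_id = st$group_id,
                     refined = st$refined)
    })
    concordance <- findings |>
      dplyr::inner_join(stratum_index, by = "group_id",
                        relationship = "many-to-many") |>
      dplyr::left_join(
        estimates[, c("stratum_id", "outcome_type", "coding", "exposure",
                      "hr_adj", "suppressed_adj", "significant_adj")],
        by = c("stratum_id", "outcome_type", "coding", "exposure"))
    concordance$status <- with(concordance, dplyr::case_when(
      is.na(suppressed_adj) | suppressed_adj ~ "inestimable",
      significant_adj &
        ((outcome_type == "response20") == (hr_adj > 1) &
           direction == "benefit" |
           (outcome_type == "response20") == (hr_adj < 1) &
           direction == "harm") ~ "confirmed",
      TRUE ~ "not_confirmed"))
  }
  sizes <- purrr::map_dfr(strata, function(st) {
    tibble::tibble(stratum_id = st$stratum_id, group_id = st$group_id,
                   label = st$label, refined = st$refined,
                   n = length(apply_stratum(raw, st)$patient_id))
  })
  structure(list(estimates = estimates, concordance = concordance,
                 stratum_sizes = sizes),
            class = "ra_validation")
}

#' @export
print.ra_validation <- function(x, ...) {
  cat("<ra_validation>", nrow(x$stratum_sizes), "strata\n")
  print(x$stratum_sizes[, c("stratum_id", "n", "label")])
  if (!is.null(x$concordance) && nrow(x$concordance)) {
    cat("finding concordance:\n")
    print(x$concordance[, c("stratum_id", "outcome_type", "exposure",
                            "direction", "status")])
  }
  invisible(x)
}

#' @export
tidy.ra_validation <- function(x, ...) x$estimates

#' @export
glance.ra_validation <- function(x, ...) {
  conc <- x$concordance
  tibble::tibble(
    n_strata = nrow(x$stratum_sizes),
    n_findings = if (is.null(conc)) 0L else
      dplyr::n_distinct(conc[, c("group_id", "outcome_type", "coding",
                                 "exposure", "direction")]),
    n_confirmed = if (is.null(conc)) 0L else
      sum(conc$status == "confirmed"))
}
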