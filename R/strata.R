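#' Default threshold library for stratum derivation
#'
#' Maps extreme-signature elements (feature, direction) to atomic clinical
#' conditions used to translate a cluster group's consensus signature into an
#' evaluable stratum.  Atoms sharing an `or_group` are combined with OR (a
#' patient qualifies on any one of them); distinct atoms are combined with
#' AND.  Thresholds encode conventional RA cutpoints (DAS28-esr remission /
#' high-activity bounds, HAQ disability, VAS pain); all values are
#' configuration and can be replaced.
#'
#' @return Tibble with columns `feature`, `direction`, `target`, `op`,
#'   `value`, `or_group`.
#' @export
threshold_library_default <- function() {
  tibble::tribble(
    ~feature,         ~direction, ~target,          ~op,  ~value, ~or_group,
    "csdmard_count",  "highest",  "csdmard_count",  ">=", 2,      NA,
    "methotrexate",   "highest",  "csdmard_count",  ">=", 2,      NA,
    "leflunomide",    "highest",  "csdmard_count",  ">=", 2,      NA,
    "sulfasalazine",  "highest",  "csdmard_count",  ">=", 2,      NA,
    "prednisone",     "highest",  "prednisone",     "==", 1,      NA,
    "prednisone",     "lowest",   "prednisone",     "==", 0,      NA,
    "sex_male",       "highest",  "sex_male",       "==", 1,      NA,
    "sex_male",       "lowest",   "sex_male",       "==", 0,      NA,
    "rf_positive",    "highest",  "rf_positive",    "==", 1,      NA,
    "rf_positive",    "lowest",   "rf_positive",    "==", 0,      NA,
    "acpa_positive",  "highest",  "acpa_positive",  "==", 1,      NA,
    "acpa_positive",  "lowest",   "acpa_positive",  "==", 0,      NA,
    "ra_duration",    "highest",  "ra_duration",    ">",  8,      NA,
    "das28",          "highest",  "das28",          ">",  5.1,    "burden_high",
    "haq",            "highest",  "haq",            ">",  1.5,    "burden_high",
    "pain_vas",       "highest",  "pain_vas",       ">",  6,      "burden_high",
    "activity_vas",   "highest",  "activity_vas",   ">",  6,      "burden_high",
    "das28",          "lowest",   "das28",          "<=", 3.2,    "burden_low",
    "haq",            "lowest",   "haq",            "<",  0.7,    "burden_low",
    "pain_vas",       "lowest",   "pain_vas",       "<",  4,      "burden_low",
    "activity_vas",   "lowest",   "activity_vas",   "<",  4,      "burden_low"
  )
}

#' Atomic stratum condition
#'
#' @param target feature name the condition applies to.
#' @param op comparison operator: one of `<`, `<=`, `>`, `>=`, `==`.
#' @param value threshold or category code.
#' @return A predicate leaf usable in stratum definitions and refinements.
#' @export
atom <- function(target, op, value) {
  list(feature = target, op = op, value = value)
}

predicate_label <- function(pred) {
  if (!is.null(pred$feature)) {
    return(paste(pred$feature, pred$op, pred$value))
  }
  glue <- if (pred$logic == "and") " & " else " | "
  inner <- vapply(pred$args, predicate_label, "")
  if (length(inner) == 1) inner else paste0("(", paste(inner, collapse = glue),
                                            ")")
}

#' Derive clinical strata from cluster-group signatures
#'
#' Translates each group's consensus signature into a stratum predicate via a
#' threshold library: every signature element maps to its configured atomic
#' condition, atoms sharing an `or_group` are OR-combined, and everything
#' else is AND-combined.  Signature features absent from the library are
#' skipped with a warning.  For each base stratum, refined strata (e.g.
#' additionally restricted to women) are emitted per `refinements` unless the
#' base already constrains that feature.
#'
#' @param groups an `ra_cluster_groups` (or its `consensus` tibble).
#' @param library a threshold library tibble; see
#'   [threshold_library_default()].
#' @param refinements named list of extra atoms appended as refined strata;
#'   default adds a women-only refinement.
#' @param min_or_atoms an OR block (e.g. the disease-burden composite) only
#'   enters a stratum when at least this many of its member atoms are
#'   supported by the consensus signature; a single extreme burden measure is
#'   treated as a chance extreme, not a defining characteristic.
#' @param min_support minimum fraction of the group's member clusters that
#'   must share a signature element before it is treated as defining.
#' @return List of `ra_stratum` objects (fields `stratum_id`, `group_id`,
#'   `label`, `predicate`, `refined`).
#' @export
derive_strata <- function(groups, library = threshold_library_default(),
                          refinements = list(
                            female = atom("sex_male", "==", 0)),
                          min_or_atoms = 2, min_support = 2 / 3) {
  consensus <- if (inherits(groups, "ra_cluster_groups")) {
    groups$consensus
  } else groups
  # only strongly shared signature elements count as "most distinct"
  if ("support" %in% names(consensus)) {
    consensus <- consensus[consensus$support >= min_support, ]
  }
  strata <- list()
  for (g in sort(unique(consensus$group_id))) {
    sig <- consensus[consensus$group_id == g, ]
    hit <- dplyr::inner_join(sig, library, by = c("feature", "direction"))
    missed <- dplyr::anti_join(sig, library, by = c("feature", "direction"))
    if (nrow(missed)) {
      warning("group ", g, ": no threshold mapping for ",
              paste(paste0(missed$feature, ":", missed$direction),
                    collapse = ", "), "; skipped", call. = FALSE)
    }
    if (!nrow(hit)) {
      warning("group ", g, ": empty consensus after mapping; no stratum",
              call. = FALSE)
      next
    }
    hit <- dplyr::distinct(hit, .data$target, .data$op, .data$value,
                           .data$or_group)
    args <- list()
    for (og in unique(hit$or_group[!is.na(hit$or_group)])) {
      blk <- hit[!is.na(hit$or_group) & hit$or_group == og, ]
      if (nrow(blk) < min_or_atoms) next  # lone extreme: not defining
      args <- c(args, list(list(
        logic = "or",
        args = purrr::pmap(blk[, c("target", "op", "value")],
                           function(target, op, value) atom(target, op,
                                                            value)))))
    }
    plain <- hit[is.na(hit$or_group), ]
    args <- c(args, purrr::pmap(plain[, c("target", "op", "value")],
                                function(target, op, value)
                                  atom(target, op, value)))
    if (!length(args)) {
      warning("group ", g, ": no defining atoms after mapping; no stratum",
              call. = FALSE)
      next
    }
    pred <- if (length(args) == 1 && !is.null(args[[1]]$feature)) {
      args[[1]]
    } else list(logic = "and", args = args)
    base <- structure(list(stratum_id = sprintf("group%d", g),
                           group_id = g, label = predicate_label(pred),
                           predicate = pred, refined = FALSE),
                      class = "ra_stratum")
    strata[[base$stratum_id]] <- base
    for (rn in names(refinements)) {
      rf <- refinements[[rn]]
      if (stratum_constrains(pred, rf$feature)) next
      pred2 <- list(logic = "and", args = list(pred, rf))
      st <- structure(list(stratum_id = sprintf("group%d_%s", g, rn),
                           group_id = g, label = predicate_label(pred2),
                           predicate = pred2, refined = TRUE),
                      class = "ra_stratum")
      strata[[st$stratum_id]] <- st
    }
  }
  strata
}

# does the predicate tree mention `feature` anywhere?
stratum_constrains <- function(pred, feature) {
  if (!is.null(pred$feature)) return(pred$feature == feature)
  any(vapply(pred$args, stratum_constrains, logical(1), feature = feature))
}

#' @export
print.ra_stratum <- function(x, ...) {
  cat("<ra_stratum>", x$stratum_id, ":", x$label, "\n")
  invisible(x)
}

# Evaluate a predicate tree on a feature tibble; an atom over a missing
# value is FALSE (the patient can still qualify through OR branches).
eval_predicate <- function(pred, data) {
  if (!is.null(pred$feature)) {
    assert_that(pred$feature %in% names(data),
                paste0("stratum feature not in data: ", pred$feature))
    v <- data[[pred$feature]]
    res <- switch(pred$op,
                  "<" = v < pred$value,
                  "<=" = v <= pred$value,
                  ">" = v > pred$value,
                  ">=" = v >= pred$value,
                  "==" = v == pred$value,
                  stop("unknown operator: ", pred$op, call. = FALSE))
    res[is.na(res)] <- FALSE
    return(res)
  }
  parts <- lapply(pred$args, eval_predicate, data = data)
  Reduce(if (pred$logic == "and") `&` else `|`, parts)
}

#' Apply a stratum predicate to the cohort
#'
#' @param features an `ra_features` object (its `raw` slot is used) or a raw
#'   feature tibble containing `patient_id` and the predicate's features.
#' @param stratum an `ra_stratum`.
#' @return Tibble of qualifying patients (`patient_id`); the number excluded
#'   because the deciding features were missing is attached as attribute
#'   `n_missing_excluded`.
#' @export
apply_stratum <- function(features, stratum) {
  data <- if (inherits(features, "ra_features")) features$raw else features
  keep <- eval_predicate(stratum$predicate, data)
  out <- tibble::tibble(patient_id = data$patient_id[keep])
  if (nrow(out) == 0) {
    warning("stratum ", stratum$stratum_id, " is empty", call. = FALSE)
  }
  attr(out, "n_missing_excluded") <-
    sum(!keep & !stats::complete.cases(data))
  out
}
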