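#' Describe clusters by patient characteristics
#'
#' Per-cluster summaries of the raw (unstandardized) feature values, computed
#' over observed values only: mean and SD for continuous features, frequency
#' for binary ones.  An overall cohort profile is emitted under
#' `run_id = "cohort"`.
#'
#' @param design an `ra_run_design` (or its `assignments` tibble with columns
#'   `patient_id`, `run_id`, `cluster`).
#' @param features an `ra_features` object; its `raw` slot supplies the
#'   unscaled values and its `feature_table` the types.
#' @return Tibble with `run_id`, `cluster`, `n`, `feature`, `type`,
#'   `value` (mean or frequency), `sd`, `n_obs`.
#' @export
profile_clusters <- function(design, features) {
  assignments <- if (inherits(design, "ra_run_design")) {
    design$assignments
  } else design
  raw <- features$raw
  types <- features$feature_table
  long <- raw |>
    tidyr::pivot_longer(-"patient_id", names_to = "feature",
                        values_to = "value") |>
    dplyr::left_join(types[, c("name", "type")],
                     by = c(feature = "name"))
  summarise_block <- function(df) {
    df |>
      dplyr::group_by(.data$run_id, .data$cluster, .data$feature,
                      .data$type) |>
      dplyr::summarise(
        n = dplyr::n_distinct(.data$patient_id),
        n_obs = sum(!is.na(.data$value)),
        sd = if (.data$type[1] == "continuous") {
          stats::sd(.data$value, na.rm = TRUE)
        } else NA_real_,
        value = if (sum(!is.na(.data$value)) > 0) {
          mean(.data$value, na.rm = TRUE)
        } else NA_real_,
        .groups = "drop")
  }
  cohort <- long |>
    dplyr::mutate(run_id = "cohort", cluster = NA_integer_) |>
    summarise_block()
  per_cluster <- assignments[, c("patient_id", "run_id", "cluster")] |>
    dplyr::inner_join(long, by = "patient_id",
                      relationship = "many-to-many") |>
    summarise_block()
  dplyr::bind_rows(cohort, per_cluster)[, c("run_id", "cluster", "n",
                                            "feature", "type", "value",
                                            "sd", "n_obs")]
}

#' Mark each run's most extreme cluster characteristics
#'
#' Within every clustering run and for every feature, flags the cluster(s)
#' holding the highest and the lowest summary value (ties flag all tied
#' clusters).  Features unobserved in a whole run are skipped.
#'
#' @param profiles output of [profile_clusters()].
#' @return Signature tibble with `run_id`, `cluster`, `feature`, `direction`
#'   (`highest` / `lowest`).
#' @export
mark_extremes <- function(profiles) {
  prof <- profiles[profiles$run_id != "cohort" & !is.na(profiles$cluster), ]
  runs <- split(prof, prof$run_id)
  out <- purrr::map_dfr(runs, function(rp) {
    assert_that(dplyr::n_distinct(rp$cluster) >= 2,
                "extreme marking needs >= 2 clusters per run")
    purrr::map_dfr(split(rp, rp$feature), function(fp) {
      vals <- fp$value
      if (all(is.na(vals))) {
        message("feature ", fp$feature[1], " unobserved in run ",
                fp$run_id[1], "; skipped")
        return(NULL)
      }
      hi <- which(vals == max(vals, na.rm = TRUE))
      lo <- which(vals == min(vals, na.rm = TRUE))
      dplyr::bind_rows(
        tibble::tibble(run_id = fp$run_id[hi], cluster = fp$cluster[hi],
                       feature = fp$feature[hi], direction = "highest"),
        tibble::tibble(run_id = fp$run_id[lo], cluster = fp$cluster[lo],
                       feature = fp$feature[lo], direction = "lowest"))
    })
  })
  dplyr::arrange(out, .data$run_id, .data$cluster, .data$feature,
                 .data$direction)
}

# Jaccard similarity between two signature string sets
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Group clusters across runs by signature similarity
#'
#' Average-linkage agglomeration on the Jaccard similarity of extreme-feature
#' signatures, cut at `target_groups` groups.  Merging is deterministic and
#' order-invariant: among equally close pairs the lexicographically smallest
#' pair of cluster identifiers is merged first.
#'
#' @param signatures output of [mark_extremes()].
#' @param target_groups number of phenotype groups to form.
#' @param min_jaccard groups whose mean within-group signature similarity
#'   falls below this value are flagged in the output (`low_cohesion`).
#' @return An object of class `ra_cluster_groups`: `membership` tibble
#'   (`run_id`, `cluster`, `unit`, `group_id`), `consensus` tibble of
#'   feature-direction pairs shared by at least half of each group's members,
#'   and `group_summary`.
#' @export
group_clusters <- function(signatures, target_groups = 5, min_jaccard = 0.3) {
  units <- signatures |>
    dplyr::mutate(unit = paste0(.data$run_id, "_c", .data$cluster),
                  element = paste0(.data$feature, ":", .data$direction))
  sets <- split(units$element, units$unit)
  ids <- sort(names(sets))
  m <- length(ids)
  assert_that(target_groups <= m,
              "target_groups cannot exceed the number of clusters")
  # pairwise Jaccard distance between cluster signatures
  D <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j > i) D[i, j] <- D[j, i] <- 1 - jaccard(sets[[ids[i]]],
                                                 sets[[ids[j]]])
  }
  # average linkage with lexicographic tie-break on the smallest member label
  groups <- as.list(ids)
  while (length(groups) > target_groups) {
    ng <- length(groups)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      d_ij <- mean(D[groups[[i]], groups[[j]]])
      key <- c(min(groups[[i]][1], groups[[j]][1]),
               max(groups[[i]][1], groups[[j]][1]))
      if (d_ij < best_d - 1e-12 ||
          (abs(d_ij - best_d) <= 1e-12 && !is.null(best) &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, key = key)
        best_d <- d_ij
      }
    }
    merged <- sort(c(groups[[best$i]], groups[[best$j]]))
    groups <- c(groups[-c(best$i, best$j)], list(merged))
  }
  # deterministic group ids: order by smallest member label
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  membership <- purrr::imap_dfr(groups, function(members, gid) {
    tibble::tibble(unit = members, group_id = as.integer(gid))
  }) |>
    dplyr::left_join(dplyr::distinct(units[, c("unit", "run_id", "cluster")]),
                     by = "unit") |>
    dplyr::select("run_id", "cluster", "unit", "group_id")
  consensus <- purrr::imap_dfr(groups, function(members, gid) {
    elems <- unlist(lapply(members, function(u) unique(sets[[u]])))
    tab <- table(elems) / length(members)
    keep <- names(tab)[tab >= 0.5]
    if (!length(keep)) return(NULL)
    parts <- strsplit(keep, ":", fixed = TRUE)
    tibble::tibble(group_id = as.integer(gid),
                   feature = vapply(parts, `[`, "", 1),
                   direction = vapply(parts, `[`, "", 2),
                   support = as.numeric(tab[keep]))
  })
  group_summary <- purrr::imap_dfr(groups, function(members, gid) {
    sims <- if (length(members) > 1) {
      1 - mean(D[members, members][upper.tri(D[members, members])])
    } else 1
    tibble::tibble(group_id = as.integer(gid), n_clusters = length(members),
                   mean_similarity = sims, low_cohesion = sims < min_jaccard)
  })
  structure(list(membership = membership, consensus = consensus,
                 group_summary = group_summary),
            class = "ra_cluster_groups")
}

#' @export
print.ra_cluster_groups <- function(x, ...) {
  cat("<ra_cluster_groups>", max(x$membership$group_id), "groups over",
      nrow(x$membership), "clusters\n")
  for (g in sort(unique(x$membership$group_id))) {
    sig <- x$consensus[x$consensus$group_id == g, ]
    cat(sprintf("  group %d (%d clusters): %s\n", g,
                sum(x$membership$group_id == g),
                paste(paste0(sig$feature, " ", sig$direction),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Grouping purity against planted phenotypes
#'
#' Each cluster is labelled by the majority planted group of its patients;
#' purity is the fraction of clusters whose majority label matches the modal
#' majority label of their assigned cluster group.
#'
#' @param groups an `ra_cluster_groups`.
#' @param assignments assignments tibble (`patient_id`, `run_id`, `cluster`).
#' @param ground_truth tibble with `patient_id` and planted `group`.
#' @return Scalar purity in `[0, 1]`.
#' @export
grouping_purity <- function(groups, assignments, ground_truth) {
  maj <- assignments |>
    dplyr::left_join(ground_truth, by = "patient_id") |>
    dplyr::group_by(.data$run_id, .data$cluster) |>
    dplyr::summarise(majority = as.integer(names(which.max(
      table(.data$group)))), .groups = "drop")
  tab <- dplyr::left_join(groups$membership, maj,
                          by = c("run_id", "cluster")) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(modal = as.integer(names(which.max(
      table(.data$majority))))) |>
    dplyr::ungroup()
  mean(tab$majority == tab$modal)
}
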