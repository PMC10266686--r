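# cluster profiling, extreme marking, grouping, stratum derivation

make_assignments <- function(labels_by_run, ids) {
  purrr::imap_dfr(labels_by_run, function(labels, run_id) {
    tibble::tibble(patient_id = ids, run_id = run_id, spec_id = 1L,
                   k = length(unique(labels)), cluster = labels,
                   q_max = 1)
  })
}

toy_features <- function() {
  raw <- tibble::tibble(
    patient_id = sprintf("P%d", 1:5),
    sex_male = c(1, 1, 0, 0, 0),
    das28 = c(5.0, 5.5, 4.0, NA, 3.0),
    haq = c(2, 1.5, 1, 0.5, NA),
    prednisone = c(1, 1, 0, 0, 1))
  ft <- tibble::tibble(
    name = c("sex_male", "das28", "haq", "prednisone"),
    lookback = "ever_before",
    type = c("binary", "continuous", "continuous", "binary"))
  structure(list(raw = raw, feature_table = ft,
                 patient_id = raw$patient_id),
            class = "ra_features")
}

test_that("profiles summarize observed values only (hand tally)", {
  feats <- toy_features()
  asg <- make_assignments(list(run1 = c(1L, 1L, 2L, 2L, 2L)),
                          feats$patient_id)
  prof <- profile_clusters(asg, feats)
  c2_das <- prof[prof$run_id == "run1" & prof$cluster == 2 &
                   prof$feature == "das28", ]
  expect_equal(c2_das$value, mean(c(4.0, 3.0)))  # NA excluded
  expect_equal(c2_das$n_obs, 2)
  expect_equal(c2_das$n, 3)
  overall <- prof[prof$run_id == "cohort" & prof$feature == "sex_male", ]
  expect_equal(overall$value, 0.4)
  c1 <- prof[prof$run_id == "run1" & prof$cluster == 1 &
               prof$feature == "sex_male", ]
  expect_equal(c1$value, 1)
  expect_equal(c1$sd, NA_real_)  # binary: frequency, no SD
})

test_that("cluster of identical patients has zero SDs", {
  feats <- toy_features()
  feats$raw$das28 <- 4
  feats$raw$haq <- 1
  asg <- make_assignments(list(r = c(1L, 1L, 1L, 2L, 2L)),
                          feats$patient_id)
  prof <- profile_clusters(asg, feats)
  sds <- prof$sd[prof$run_id == "r" & prof$type == "continuous"]
  expect_true(all(sds == 0))
})

test_that("cohort profile of the default cohort shows the expected DAS28", {
  reg <- small_sim()
  coh <- suppressMessages(select_cohort(reg))
  f <- build_features(reg, coh, feature_spec(1))
  asg <- tibble::tibble(patient_id = f$patient_id, run_id = "r",
                        spec_id = 1L, k = 1L, cluster = 1L, q_max = 1)
  prof <- profile_clusters(asg, f)
  das <- prof$value[prof$run_id == "cohort" & prof$feature == "das28"]
  expect_equal(das, 4.3, tolerance = 0.06)  # mean DAS28-esr of the cohort
})

test_that("extreme marking flags rank-1 clusters with ties included", {
  feats <- toy_features()
  asg <- make_assignments(list(r = c(1L, 2L, 2L, 3L, 3L)),
                          feats$patient_id)
  prof <- profile_clusters(asg, feats)
  sig <- mark_extremes(prof)
  male_hi <- sig[sig$feature == "sex_male" & sig$direction == "highest", ]
  expect_equal(male_hi$cluster, 1L)
  # prednisone: cluster1 = 1, cluster2 = 0.5, cluster3 = 0.5 ->
  # clusters 2 and 3 tie for lowest
  pred_lo <- sig[sig$feature == "prednisone" & sig$direction == "lowest", ]
  expect_setequal(pred_lo$cluster, c(2L, 3L))
  # k = 2 runs flag exactly one highest and one lowest per feature
  asg2 <- make_assignments(list(r = c(1L, 1L, 2L, 2L, 2L)),
                           feats$patient_id)
  sig2 <- mark_extremes(profile_clusters(asg2, feats))
  counts <- dplyr::count(sig2, .data$feature, .data$direction)
  expect_true(all(counts$n == 1))
})

test_that("grouping partitions clusters and is order-invariant", {
  sig <- tibble::tibble(
    run_id = rep(c("a", "b", "c", "d"), each = 2),
    cluster = rep(1:2, 4),
    feature = rep(c("sex_male", "das28"), 4),
    direction = rep(c("highest", "lowest"), 4))
  g <- group_clusters(sig, target_groups = 2)
  expect_equal(nrow(g$membership), 8)
  expect_true(all(table(g$membership$unit) == 1))  # partition
  # permuting input rows leaves the grouping unchanged
  g2 <- group_clusters(sig[sample(nrow(sig)), ], target_groups = 2)
  expect_identical(dplyr::arrange(g$membership, .data$unit),
                   dplyr::arrange(g2$membership, .data$unit))
})

test_that("grouping degenerate cases behave", {
  sig <- tibble::tibble(run_id = c("a", "a", "b", "b"),
                        cluster = c(1L, 2L, 1L, 2L),
                        feature = "das28",
                        direction = c("highest", "lowest",
                                      "highest", "lowest"))
  g1 <- group_clusters(sig, target_groups = 1)
  expect_true(all(g1$membership$group_id == 1))
  g4 <- group_clusters(sig, target_groups = 4)
  expect_equal(sort(unique(g4$membership$group_id)), 1:4)
  expect_error(group_clusters(sig, target_groups = 9), "cannot exceed")
  # identical signatures merge first: the two "highest" clusters pair up
  g2 <- group_clusters(sig, target_groups = 2)
  hi <- g2$membership$group_id[g2$membership$unit %in% c("a_c1", "b_c1")]
  expect_equal(hi[1], hi[2])
})

test_that("consensus keeps elements supported by at least half the group", {
  sig <- tibble::tibble(
    run_id = c("a", "a", "b", "b", "c", "c"),
    cluster = rep(1L, 6),
    feature = c("sex_male", "das28", "sex_male", "haq", "sex_male", "esr"),
    direction = "highest")
  sig$cluster <- c(1L, 1L, 1L, 1L, 1L, 1L)
  g <- group_clusters(sig, target_groups = 1)
  cons <- g$consensus
  expect_true("sex_male" %in% cons$feature)      # 3/3 members
  expect_false("das28" %in% cons$feature)        # 1/3 members
})

test_that("stratum derivation maps signatures through the threshold library", {
  cons <- tibble::tibble(
    group_id = c(1L, 1L, 1L, 1L, 1L),
    feature = c("rf_positive", "das28", "haq", "pain_vas", "ra_duration"),
    direction = c("highest", "highest", "highest", "highest", "highest"),
    support = 1)
  st <- derive_strata(cons)
  base <- st[["group1"]]
  expect_match(base$label, "rf_positive == 1")
  expect_match(base$label, "das28 > 5.1")
  expect_match(base$label, "haq > 1.5")
  expect_match(base$label, "pain_vas > 6")
  expect_match(base$label, "ra_duration > 8")
  # the burden atoms sit inside an OR block
  expect_match(base$label, "das28 > 5.1 \\| haq > 1.5")
  # refined women-only stratum emitted
  expect_true("group1_female" %in% names(st))
  expect_match(st[["group1_female"]]$label, "sex_male == 0")
})

test_that("low-burden signatures map to the low-activity cutpoints", {
  cons <- tibble::tibble(
    group_id = 5L,
    feature = c("das28", "haq", "pain_vas", "activity_vas"),
    direction = "lowest", support = 1)
  st <- derive_strata(cons)
  lab <- st[["group5"]]$label
  expect_match(lab, "das28 <= 3.2")
  expect_match(lab, "haq < 0.7")
  expect_match(lab, "pain_vas < 4")
  expect_match(lab, "activity_vas < 4")
})

test_that("unmapped features are skipped with a warning; lone burden atoms
          and empty consensus produce no stratum", {
  cons <- tibble::tibble(group_id = 1L, feature = "bmi",
                         direction = "highest", support = 1)
  expect_warning(
    expect_warning(st <- derive_strata(cons), "no threshold mapping"),
    "empty consensus")
  expect_length(st, 0)
  # a single burden extreme is not defining
  cons2 <- tibble::tibble(group_id = 1L, feature = "haq",
                          direction = "lowest", support = 1)
  expect_warning(st2 <- derive_strata(cons2), "no defining atoms")
  expect_length(st2, 0)
})

test_that("male strata do not get a female refinement", {
  cons <- tibble::tibble(group_id = 2L, feature = "sex_male",
                         direction = "highest", support = 1)
  st <- derive_strata(cons)
  expect_named(st, "group2")
  expect_equal(st[["group2"]]$label, "sex_male == 1")
})

test_that("grouping purity is 1 for a perfect grouping and lower otherwise", {
  ids <- sprintf("P%d", 1:40)
  truth <- tibble::tibble(patient_id = ids, group = rep(1:2, each = 20))
  asg <- tibble::tibble(
    patient_id = rep(ids, 2),
    run_id = rep(c("a", "b"), each = 40),
    cluster = rep(rep(1:2, each = 20), 2))
  mem <- tibble::tibble(run_id = c("a", "a", "b", "b"),
                        cluster = c(1L, 2L, 1L, 2L),
                        unit = c("a_c1", "a_c2", "b_c1", "b_c2"),
                        group_id = c(1L, 2L, 1L, 2L))
  g <- structure(list(membership = mem), class = "ra_cluster_groups")
  expect_equal(grouping_purity(g, asg, truth), 1)
  mem_bad <- mem
  mem_bad$group_id <- c(1L, 2L, 2L, 1L)
  g_bad <- structure(list(membership = mem_bad),
                     class = "ra_cluster_groups")
  expect_lt(grouping_purity(g_bad, asg, truth), 1)
})
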