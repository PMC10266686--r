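# DEC primitives against closed forms and brute-force oracles

test_that("soft assignment matches the Student-t kernel closed form", {
  # z at distance 0 from mu1 and squared distance 3 from mu2, alpha = 1:
  # q1 = 1 / (1 + 1/4) = 0.8
  Z <- matrix(c(0, 0), 1, 2)
  centroids <- rbind(c(0, 0), c(sqrt(3), 0))
  Q <- soft_assign(Z, centroids, alpha = 1)
  expect_equal(Q[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(Q[1, 2], 0.2, tolerance = 1e-12)
})

test_that("soft assignment is uniform at equidistant points and rows sum to 1", {
  centroids <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  Q <- soft_assign(matrix(0, 1, 2), centroids)
  expect_equal(as.vector(Q), rep(0.25, 4), tolerance = 1e-12)

  set.seed(7)
  Z <- matrix(rnorm(60), 20, 3)
  mu <- matrix(rnorm(12), 4, 3)
  Q <- soft_assign(Z, mu, alpha = 2)
  expect_equal(rowSums(Q), rep(1, 20), tolerance = 1e-9)
  expect_true(all(Q > 0 & Q < 1))
})

test_that("soft assignment equals a per-pair brute-force kernel evaluation", {
  set.seed(11)
  for (alpha in c(0.5, 1, 3)) {
    Z <- matrix(rnorm(50 * 4), 50, 4)
    mu <- matrix(rnorm(5 * 4), 5, 4)
    Q <- soft_assign(Z, mu, alpha)
    oracle <- matrix(0, 50, 5)
    for (i in 1:50) {
      for (j in 1:5) {
        oracle[i, j] <- (1 + sum((Z[i, ] - mu[j, ])^2) / alpha)^
          (-(alpha + 1) / 2)
      }
      oracle[i, ] <- oracle[i, ] / sum(oracle[i, ])
    }
    expect_equal(Q, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("soft assignment rejects duplicate centroids", {
  expect_error(soft_assign(matrix(0, 2, 2), rbind(c(1, 1), c(1, 1))),
               "duplicate")
})

test_that("target distribution matches hand arithmetic and sharpens", {
  Q <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  P <- target_distribution(Q)
  # f = (1, 1); p11 = 0.64 / (0.64 + 0.04) = 0.9412
  expect_equal(P, rbind(c(0.64, 0.04) / 0.68, c(0.04, 0.64) / 0.68),
               tolerance = 1e-4)
  entropy <- function(m) -rowSums(ifelse(m > 0, m * log(m), 0))
  expect_true(all(entropy(P) <= entropy(Q) + 1e-12))
})

test_that("target distribution fixes one-hot rows and stays row-stochastic", {
  Q1 <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(target_distribution(Q1), Q1)
  set.seed(3)
  Q <- matrix(rexp(40 * 4), 40, 4)
  Q <- Q / rowSums(Q)
  expect_equal(rowSums(target_distribution(Q)), rep(1, 40),
               tolerance = 1e-9)
  expect_error(target_distribution(cbind(rep(1, 5), rep(0, 5))), "empty")
})

test_that("KL loss matches direct evaluation and the Gibbs inequality", {
  expect_equal(kl_loss(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2),
               tolerance = 1e-12)
  Q <- rbind(c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(kl_loss(Q, Q), 0)
  set.seed(5)
  for (i in 1:20) {
    P <- matrix(rexp(12), 4, 3); P <- P / rowSums(P)
    Q <- matrix(rexp(12), 4, 3); Q <- Q / rowSums(Q)
    v <- kl_loss(P, Q)
    oracle <- sum(P * log(P / Q))
    expect_equal(v, oracle, tolerance = 1e-12)
    expect_gte(v, 0)
  }
  expect_error(kl_loss(rbind(c(1, 0)), rbind(c(0, 1))), "undefined")
})

test_that("silhouette scores the analytic duplicated-points case exactly 1", {
  pts <- matrix(c(0, 0, 10, 10), 4, 1)
  expect_identical(silhouette_score(pts, c("A", "A", "B", "B")), 1)
})

test_that("silhouette follows conventions: singletons 0, one cluster error", {
  pts <- matrix(c(0, 5, 10), 3, 1)
  expect_identical(silhouette_score(pts, c("a", "b", "c")), 0)
  expect_error(silhouette_score(pts, c("a", "a", "a")), "2 clusters")
})

test_that("silhouette equals the brute-force pairwise oracle", {
  brute_silhouette <- function(points, labels) {
    n <- nrow(points)
    s <- numeric(n)
    for (i in seq_len(n)) {
      di <- function(j) sqrt(sum((points[i, ] - points[j, ])^2))
      own <- setdiff(which(labels == labels[i]), i)
      if (length(own) == 0) { s[i] <- 0; next }
      a <- mean(vapply(own, di, 0))
      b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
        mean(vapply(which(labels == l), di, 0))
      }, 0))
      s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    mean(s)
  }
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(8:50, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_score(pts, labels),
                 brute_silhouette(pts, labels), tolerance = 1e-12)
  }
})

test_that("DEC recovers three well-separated planted blobs", {
  blobs <- make_blobs(n = 300, d = 8, sep = 10, seed = 21)
  feats <- list(x = blobs$x, mask = blobs$mask)
  ae <- pretrain(feats, ae_config(hidden = c(16), latent = 3, epochs = 40,
                                  seed = 1))
  run <- train_dec(feats, ae, dec_config(k = 3, seed = 2))
  expect_gte(ari(run$labels, blobs$labels), 0.9)
  expect_gte(run$silhouette, 0.5)
  expect_equal(rowSums(run$Q), rep(1, 300), tolerance = 1e-9)
})

test_that("DEC stops after the first refresh when tolerance is 1 - eps", {
  blobs <- make_blobs(n = 60, d = 4, sep = 8, seed = 5)
  feats <- list(x = blobs$x, mask = blobs$mask)
  ae <- pretrain(feats, ae_config(hidden = c(8), latent = 2, epochs = 5,
                                  seed = 1))
  run <- train_dec(feats, ae, dec_config(k = 3, tol = 0.999, seed = 2))
  expect_true(run$converged)
  expect_lte(run$iterations, 2)
})

test_that("DEC with one point per cluster makes every point its own cluster", {
  set.seed(31)
  x <- matrix(rnorm(6 * 3), 6, 3) * 5
  feats <- list(x = x, mask = matrix(1, 6, 3))
  ae <- pretrain(feats, ae_config(hidden = c(4), latent = 2, epochs = 3,
                                  seed = 1))
  run <- train_dec(feats, ae, dec_config(k = 6, seed = 2, max_iter = 5,
                                         kmeans_restarts = 5))
  expect_setequal(run$labels, 1:6)
  expect_identical(run$silhouette, 0)  # all singletons
})

test_that("DEC is deterministic under a fixed seed", {
  blobs <- make_blobs(n = 80, d = 4, sep = 6, seed = 6)
  feats <- list(x = blobs$x, mask = blobs$mask)
  ae <- pretrain(feats, ae_config(hidden = c(8), latent = 2, epochs = 5,
                                  seed = 3))
  r1 <- train_dec(feats, ae, dec_config(k = 3, seed = 4, max_iter = 10))
  r2 <- train_dec(feats, ae, dec_config(k = 3, seed = 4, max_iter = 10))
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$Q, r2$Q, tolerance = 1e-12)
})

test_that("the full design yields one run per (spec, k) and 24 clusters", {
  blobs <- make_blobs(n = 120, d = 6, sep = 8, seed = 8)
  f1 <- list(x = blobs$x, mask = blobs$mask, spec_id = 1)
  f2 <- list(x = blobs$x, mask = blobs$mask, spec_id = 2)
  cfg_ae <- ae_config(hidden = c(8), latent = 2, epochs = 3)
  cfg_dec <- dec_config(max_iter = 3)
  design <- run_design(f1, f2, ks = c(3, 4, 5), ae_cfg = cfg_ae,
                       dec_cfg = cfg_dec, seed = 1)
  expect_length(design$runs, 6)
  expect_identical(design$total_clusters, 24L)
  design2 <- run_design(f1, NULL, ks = 2, ae_cfg = cfg_ae,
                        dec_cfg = cfg_dec, seed = 1)
  expect_length(design2$runs, 1)
  expect_identical(design2$total_clusters, 2L)
  # determinism across re-execution
  design3 <- run_design(f1, f2, ks = c(3, 4, 5), ae_cfg = cfg_ae,
                        dec_cfg = cfg_dec, seed = 1)
  expect_identical(design$assignments, design3$assignments)
})

test_that("k-means baseline recovers fully observed blobs and guards k", {
  blobs <- make_blobs(n = 150, d = 6, sep = 10, seed = 10)
  feats <- list(x = blobs$x, mask = blobs$mask)
  km <- kmeans_baseline(feats, 3, "zero_fill", seed = 1)
  expect_gte(ari(km$labels, blobs$labels), 0.9)
  expect_error(kmeans_baseline(feats, 1), ">= 2")
  km2 <- kmeans_baseline(feats, 3, "mean_fill", seed = 1)
  expect_gte(ari(km2$labels, blobs$labels), 0.9)
})
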