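#' Deep embedded clustering configuration
#'
#' @param k number of clusters (>= 2).
#' @param alpha Student-t kernel degrees of freedom (1 = the DEC default).
#' @param tol convergence tolerance: stop when the fraction of hard labels
#'   changing between target refreshes falls below this.
#' @param max_iter maximum number of target-distribution refreshes.
#' @param steps_per_refresh encoder/centroid gradient steps between refreshes.
#' @param kmeans_restarts random restarts for the k-means centroid
#'   initialization.
#' @param learning_rate Adam step size for the clustering phase.
#' @param seed RNG seed.
#' @return An object of class `ra_dec_config`.
#' @export
dec_config <- function(k = 3L, alpha = 1, tol = 0.001, max_iter = 200L,
                       steps_per_refresh = 5L, kmeans_restarts = 20L,
                       learning_rate = 1e-3, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(alpha > 0, "alpha must be positive")
  assert_that(tol > 0 && tol < 1, "tol must lie in (0, 1)")
  structure(list(k = as.integer(k), alpha = alpha, tol = tol,
                 max_iter = as.integer(max_iter),
                 steps_per_refresh = as.integer(steps_per_refresh),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ra_dec_config")
}

# squared Euclidean distances between rows of Z (n x L) and centroids (k x L)
sq_dist <- function(Z, centroids) {
  n <- nrow(Z)
  k <- nrow(centroids)
  d2 <- matrix(rowSums(Z^2), n, k) +
    matrix(rowSums(centroids^2), n, k, byrow = TRUE) -
    2 * Z %*% t(centroids)
  pmax(d2, 0)
}

#' Student-t soft cluster assignment
#'
#' `q_ij` proportional to `(1 + ||z_i - mu_j||^2 / alpha)^-((alpha+1)/2)`,
#' normalized over clusters, as in deep embedded clustering.
#'
#' @param Z n x L matrix of latent embeddings.
#' @param centroids k x L matrix of cluster centres (distinct rows).
#' @param alpha kernel degrees of freedom.
#' @return n x k row-stochastic matrix Q.
#' @export
soft_assign <- function(Z, centroids, alpha = 1) {
  Z <- as.matrix(Z)
  centroids <- as.matrix(centroids)
  assert_that(nrow(centroids) >= 2, "need at least 2 centroids")
  if (anyDuplicated(round(centroids, 12))) {
    stop("duplicate centroids", call. = FALSE)
  }
  num <- (1 + sq_dist(Z, centroids) / alpha)^(-(alpha + 1) / 2)
  num / rowSums(num)
}

#' Self-sharpening target distribution
#'
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with cluster frequency
#' `f_j = sum_i q_ij`; squaring sharpens each row towards its dominant
#' cluster while the frequency term guards against degenerate clusters.
#'
#' @param Q n x k row-stochastic soft-assignment matrix.
#' @return n x k row-stochastic target matrix P.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  if (any(f <= 0)) stop("empty cluster", call. = FALSE)
  W <- sweep(Q^2, 2, f, "/")
  W / rowSums(W)
}

#' Kullback-Leibler clustering objective
#'
#' `sum_ij p_ij log(p_ij / q_ij)` with the convention `0 log 0 = 0`.
#'
#' @param P,Q row-stochastic matrices of identical shape; Q must be positive
#'   wherever P is.
#' @return Non-negative scalar; zero iff P equals Q.
#' @export
kl_loss <- function(P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  assert_that(all(dim(P) == dim(Q)), "P and Q must have identical shapes")
  if (any(Q == 0 & P > 0)) {
    stop("q_ij = 0 where p_ij > 0: KL divergence undefined", call. = FALSE)
  }
  pos <- P > 0
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Mean silhouette score
#'
#' Per point, `(b - a) / max(a, b)` where `a` is the mean distance to the
#' point's own cluster and `b` the smallest mean distance to another cluster;
#' singleton clusters score 0 by convention.  Result lies in `[-1, 1]`.
#'
#' @param points numeric matrix (rows = points) or vector.
#' @param labels cluster labels, one per point; at least two distinct values.
#' @return Scalar mean silhouette.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  assert_that(length(labels) == nrow(points),
              "one label per point is required")
  ulab <- unique(labels)
  if (length(ulab) < 2) stop("silhouette requires >= 2 clusters",
                             call. = FALSE)
  D <- as.matrix(stats::dist(points))
  n <- nrow(points)
  # mean distance from every point to every cluster
  sums <- vapply(ulab, function(l) rowSums(D[, labels == l, drop = FALSE]),
                 numeric(n))
  sizes <- vapply(ulab, function(l) sum(labels == l), numeric(1))
  own <- match(labels, ulab)
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[own[i]] == 1) { s[i] <- 0; next }
    a <- sums[i, own[i]] / (sizes[own[i]] - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Train deep embedded clustering on the autoencoder latent space
#'
#' Initializes centroids by seeded k-means on the initial embeddings, then
#' alternates: refresh the target distribution P, take
#' `steps_per_refresh` full-batch Adam steps on the encoder and the centroids
#' against the KL objective, and stop when the fraction of hard labels that
#' changed since the previous refresh falls below `tol` (or `max_iter`
#' refreshes).  A cluster that empties at a refresh is re-seeded at the point
#' farthest from its nearest centroid.
#'
#' @param features an `ra_features` object (or list with `x`, `mask`).
#' @param ae pretrained autoencoder (`ra_ae` or a parameter list).
#' @param config a [dec_config()].
#' @return An object of class `ra_dec_run` with soft assignments `Q`, hard
#'   `labels` (ties broken toward the lowest cluster index), `centroids`,
#'   final embeddings `Z`, `silhouette`, and convergence diagnostics.
#' @export
train_dec <- function(features, ae, config = dec_config()) {
  params <- if (inherits(ae, "ra_ae")) ae$params else ae
  fm <- xm(features)
  n <- nrow(fm$x)
  k <- config$k
  assert_that(k <= n, "k cannot exceed the number of points")

  enc <- params$enc
  Z <- encoder_forward(fm$x, fm$mask, enc)$z
  mu <- with_seed(derive_seed(config$seed, 11L), {
    km <- tryCatch(
      stats::kmeans(Z, centers = k, nstart = config$kmeans_restarts,
                    iter.max = 50),
      error = function(e) NULL)
    if (!is.null(km)) km$centers else {
      # fewer distinct embeddings than k: seed on distinct points, jittered
      uz <- unique(Z)
      idx <- rep_len(seq_len(nrow(uz)), k)
      uz[idx, , drop = FALSE] +
        matrix(stats::rnorm(k * ncol(Z), sd = 1e-4), k)
    }
  })

  st_enc <- adam_state(enc)
  st_mu <- list(list(W = mu * 0, b = numeric(0)))
  labels_prev <- NULL
  change_trace <- numeric(0)
  converged <- FALSE
  t <- 0
  coef_kl <- (config$alpha + 1) / config$alpha

  for (it in seq_len(config$max_iter)) {
    Z <- encoder_forward(fm$x, fm$mask, enc)$z
    # empty-cluster guard: re-seed at the point farthest from any centroid
    repeat {
      Q <- soft_assign(Z, mu, config$alpha)
      hard <- max.col(Q, ties.method = "first")
      empty <- setdiff(seq_len(k), unique(hard))
      if (!length(empty)) break
      d2 <- sq_dist(Z, mu)
      far <- which.max(apply(d2, 1, min))
      message("re-seeding empty cluster ", empty[1], " at point ", far)
      mu[empty[1], ] <- Z[far, ] + 1e-6
    }
    P <- target_distribution(Q)
    if (!is.null(labels_prev)) {
      changed <- mean(hard != labels_prev)
      change_trace <- c(change_trace, changed)
      if (changed < config$tol) { converged <- TRUE; break }
    }
    labels_prev <- hard

    for (step in seq_len(config$steps_per_refresh)) {
      ef <- encoder_forward(fm$x, fm$mask, enc)
      Z <- ef$z
      Q <- soft_assign(Z, mu, config$alpha)
      # dKL/dz_i and dKL/dmu_j for the Student-t kernel
      wgt <- coef_kl * (P - Q) / (1 + sq_dist(Z, mu) / config$alpha)
      dZ <- (rowSums(wgt) * Z) - wgt %*% mu
      dMu <- colSums(wgt) * mu - t(wgt) %*% Z
      t <- t + 1
      ge <- encoder_backward(ef$cache, enc, dZ)
      up <- adam_update(enc, ge, st_enc, config$learning_rate, t)
      enc <- up$layers; st_enc <- up$state
      res <- adam_apply_mu(mu, dMu, st_mu, config$learning_rate, t)
      mu <- res$mu; st_mu <- res$state
    }
  }

  Z <- encoder_forward(fm$x, fm$mask, enc)$z
  Q <- soft_assign(Z, mu, config$alpha)
  hard <- max.col(Q, ties.method = "first")
  sil <- if (length(unique(hard)) >= 2) silhouette_score(Z, hard) else NA_real_
  structure(list(patient_id = fm$patient_id, Q = Q, labels = hard,
                 centroids = mu, Z = Z, silhouette = sil,
                 k = k, config = config, encoder = enc,
                 iterations = if (exists("it")) it else 0L,
                 converged = converged, label_change = change_trace),
            class = "ra_dec_run")
}

adam_apply_mu <- function(mu, dMu, state, lr, t,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  s <- state[[1]]
  s$W <- if (is.null(s$W)) mu * 0 else s$W
  s$mW <- if (is.null(s$mW)) mu * 0 else s$mW
  s$vW <- if (is.null(s$vW)) mu * 0 else s$vW
  s$mW <- beta1 * s$mW + (1 - beta1) * dMu
  s$vW <- beta2 * s$vW + (1 - beta2) * dMu^2
  mu <- mu - lr * (s$mW / (1 - beta1^t)) / (sqrt(s$vW / (1 - beta2^t)) + eps)
  list(mu = mu, state = list(s))
}

#' @export
print.ra_dec_run <- function(x, ...) {
  cat("<ra_dec_run> k =", x$k, " n =", length(x$labels),
      " silhouette =", format(x$silhouette, digits = 3),
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.ra_dec_run <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_id, cluster = x$labels,
                 q_max = apply(x$Q, 1, max))
}

#' @export
glance.ra_dec_run <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), silhouette = x$silhouette,
                 iterations = x$iterations, converged = x$converged)
}

#' Run the full clustering design
#'
#' One DEC run per (feature specification, k): with the default
#' `ks = c(3, 4, 5)` and two specifications this yields 6 runs and
#' 3 + 4 + 5 = 12 clusters per specification, 24 clusters in total.
#'
#' @param features_spec1,features_spec2 `ra_features` built under specs 1
#'   and 2 (pass `features_spec2 = NULL` to run a single specification).
#' @param ks integer vector of cluster counts.
#' @param ae_cfg an [ae_config()] (one autoencoder pretrained per spec).
#' @param dec_cfg a [dec_config()] template; its `k` and `seed` are set per
#'   run.
#' @param seed master seed; per-run seeds are derived from it.
#' @return An object of class `ra_run_design`: list of `ra_dec_run`s,
#'   a combined `assignments` tibble (patient, run, spec, k, cluster, q_max)
#'   and a `summary` tibble with one row per run.
#' @export
run_design <- function(features_spec1, features_spec2 = NULL,
                       ks = c(3L, 4L, 5L),
                       ae_cfg = ae_config(), dec_cfg = dec_config(),
                       seed = 1L) {
  specs <- list(features_spec1)
  if (!is.null(features_spec2)) specs <- c(specs, list(features_spec2))
  runs <- list()
  for (s in seq_along(specs)) {
    feats <- specs[[s]]
    spec_id <- if (inherits(feats, "ra_features")) feats$spec_id else s
    cfg_ae <- ae_cfg
    cfg_ae$seed <- derive_seed(seed, 100L * s)
    ae <- pretrain(feats, cfg_ae)
    for (k in ks) {
      cfg <- dec_cfg
      cfg$k <- as.integer(k)
      cfg$seed <- derive_seed(seed, 100L * s + k)
      run <- train_dec(feats, ae, cfg)
      run$run_id <- sprintf("spec%d_k%d", spec_id, k)
      run$spec_id <- spec_id
      runs[[run$run_id]] <- run
    }
  }
  assignments <- purrr::map_dfr(runs, function(r) {
    dplyr::mutate(tidy(r), run_id = r$run_id, spec_id = r$spec_id, k = r$k,
                  .after = "patient_id")
  })
  summary <- purrr::map_dfr(runs, function(r) {
    dplyr::mutate(glance(r), run_id = r$run_id, spec_id = r$spec_id,
                  .before = 1)
  })
  structure(list(runs = runs, assignments = assignments, summary = summary,
                 total_clusters = sum(vapply(runs, `[[`, 0L, "k"))),
            class = "ra_run_design")
}

#' @export
print.ra_run_design <- function(x, ...) {
  cat("<ra_run_design>", length(x$runs), "runs,", x$total_clusters,
      "clusters total\n")
  print(x$summary)
  invisible(x)
}

#' k-means baseline on imputed raw features
#'
#' The comparison method: plain k-means on the feature matrix with masked
#' entries imputed (`zero_fill` keeps the standardized sentinel 0;
#' `mean_fill` uses the observed column mean).  Silhouette is computed in the
#' imputed raw feature space.
#'
#' @param features an `ra_features` object (or list with `x`, `mask`).
#' @param k number of clusters (>= 2).
#' @param impute_rule `"zero_fill"` or `"mean_fill"`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return List with `labels`, `centroids`, `silhouette`, `impute_rule`.
#' @export
kmeans_baseline <- function(features, k, impute_rule = c("zero_fill",
                                                         "mean_fill"),
                            seed = 1L, nstart = 20L) {
  impute_rule <- match.arg(impute_rule)
  assert_that(k >= 2, "k must be >= 2")
  fm <- xm(features)
  x <- fm$x
  if (impute_rule == "mean_fill") {
    for (j in seq_len(ncol(x))) {
      obs <- fm$mask[, j] == 1
      fill <- if (any(obs)) mean(x[obs, j]) else 0
      x[!obs, j] <- fill
    }
  } else {
    x[fm$mask == 0] <- 0
  }
  km <- with_seed(derive_seed(seed, 13L),
                  stats::kmeans(x, centers = k, nstart = nstart,
                                iter.max = 50))
  list(labels = as.integer(km$cluster), centroids = km$centers,
       silhouette = silhouette_score(x, km$cluster),
       impute_rule = impute_rule)
}
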