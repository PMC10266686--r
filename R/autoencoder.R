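#' Autoencoder configuration
#'
#' Architecture and training hyper-parameters for the missingness-adaptive
#' autoencoder.  The encoder maps d -> hidden ... -> latent with
#' piecewise-linear (ReLU) hidden activations and a linear latent layer; the
#' decoder mirrors it.  Inputs are (values, mask) pairs: masked positions are
#' zeroed before the first layer and the first-layer pre-activation is
#' rescaled by d / (number observed) per sample, so the representation never
#' reads imputed values and its scale is comparable across missingness levels.
#'
#' @param hidden integer vector of hidden widths (encoder side).
#' @param latent latent dimension L (must be < d at fit time).
#' @param epochs pretraining epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return An object of class `ra_ae_config`.
#' @export
ae_config <- function(hidden = c(64L, 32L), latent = 10L, epochs = 100L,
                      batch_size = 256L, learning_rate = 1e-3, seed = 1L) {
  assert_that(all(c(hidden, latent) > 0), "layer widths must be positive")
  structure(list(hidden = as.integer(hidden), latent = as.integer(latent),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ra_ae_config")
}

relu <- function(x) pmax(x, 0)

new_layer <- function(fan_in, fan_out) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

#' Initialize autoencoder parameters
#'
#' @param d input dimension.
#' @param config an [ae_config()].
#' @return Parameter list with `enc` and `dec` layer lists (seeded, so
#'   identical seeds give identical parameters).
#' @export
ae_init <- function(d, config = ae_config()) {
  assert_that(config$latent < d, "latent dimension must be < input dimension")
  with_seed(config$seed, {
    enc_sizes <- c(d, config$hidden, config$latent)
    dec_sizes <- rev(enc_sizes)
    enc <- purrr::map(seq_len(length(enc_sizes) - 1),
                      ~ new_layer(enc_sizes[.x], enc_sizes[.x + 1]))
    dec <- purrr::map(seq_len(length(dec_sizes) - 1),
                      ~ new_layer(dec_sizes[.x], dec_sizes[.x + 1]))
    list(enc = enc, dec = dec, d = d, latent = config$latent)
  })
}

# resolve (x, mask) matrices from an ra_features object or a plain list
xm <- function(features) {
  if (inherits(features, "ra_features")) {
    list(x = features$x, mask = features$mask, patient_id = features$patient_id)
  } else {
    assert_that(!is.null(features$x) && !is.null(features$mask),
                "features must provide x and mask matrices")
    list(x = as.matrix(features$x), mask = as.matrix(features$mask),
         patient_id = features$patient_id %||% seq_len(nrow(features$x)))
  }
}

# encoder forward pass with cache for backprop.
# Masked entries are zeroed so stored sentinel values cannot leak; the
# first-layer pre-activation is rescaled by d/#observed per sample.
encoder_forward <- function(x, mask, enc) {
  n <- nrow(x)
  d <- ncol(x)
  nobs <- rowSums(mask)
  if (any(nobs == 0)) {
    stop("no observed features for row(s): ",
         paste(utils::head(which(nobs == 0), 5), collapse = ", "),
         call. = FALSE)
  }
  scale <- d / nobs
  x0 <- x * mask
  a <- x0
  cache <- list(x0 = x0, scale = scale, pre = vector("list", length(enc)),
                act = vector("list", length(enc)))
  for (l in seq_along(enc)) {
    pre <- a %*% enc[[l]]$W
    if (l == 1) pre <- pre * scale
    pre <- sweep(pre, 2, enc[[l]]$b, "+")
    a <- if (l < length(enc)) relu(pre) else pre  # latent layer is linear
    cache$pre[[l]] <- pre
    cache$act[[l]] <- a
  }
  list(z = a, cache = cache)
}

# gradient of a scalar loss wrt encoder parameters, given dL/dz
encoder_backward <- function(cache, enc, dZ) {
  L <- length(enc)
  grads <- vector("list", L)
  delta <- dZ  # latent layer linear
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1) cache$x0 else cache$act[[l - 1]]
    if (l == 1) {
      grads[[l]] <- list(W = t(a_prev * cache$scale) %*% delta,
                         b = colSums(delta))
      break
    }
    grads[[l]] <- list(W = t(a_prev) %*% delta, b = colSums(delta))
    delta <- (delta %*% t(enc[[l]]$W)) * (cache$pre[[l - 1]] > 0)
  }
  grads
}

decoder_forward <- function(z, dec) {
  a <- z
  cache <- list(pre = vector("list", length(dec)),
                act = vector("list", length(dec)), z = z)
  for (l in seq_along(dec)) {
    pre <- sweep(a %*% dec[[l]]$W, 2, dec[[l]]$b, "+")
    a <- if (l < length(dec)) relu(pre) else pre  # linear reconstruction
    cache$pre[[l]] <- pre
    cache$act[[l]] <- a
  }
  list(xhat = a, cache = cache)
}

decoder_backward <- function(cache, dec, dXhat) {
  L <- length(dec)
  grads <- vector("list", L)
  delta <- dXhat
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1) cache$z else cache$act[[l - 1]]
    grads[[l]] <- list(W = t(a_prev) %*% delta, b = colSums(delta))
    delta <- delta %*% t(dec[[l]]$W)
    if (l > 1) delta <- delta * (cache$pre[[l - 1]] > 0)
  }
  list(grads = grads, dZ = delta)
}

#' Encode feature vectors into the latent space
#'
#' Deterministic function of (observed values, mask, parameters): masked
#' positions contribute exactly nothing to the first-layer pre-activation,
#' which is rescaled by d / (number observed) per sample.
#'
#' @param features an `ra_features` object, or a list with matrices `x` and
#'   `mask`.
#' @param params autoencoder parameters ([ae_init()] or [pretrain()]`$params`).
#' @return Tibble with `patient_id` and latent coordinates `z1..zL`.
#' @export
encode <- function(features, params) {
  if (inherits(params, "ra_ae")) params <- params$params
  fm <- xm(features)
  z <- encoder_forward(fm$x, fm$mask, params$enc)$z
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  dplyr::bind_cols(tibble::tibble(patient_id = fm$patient_id),
                   tibble::as_tibble(z))
}

# latent matrix form used internally
encode_matrix <- function(features, params) {
  if (inherits(params, "ra_ae")) params <- params$params
  fm <- xm(features)
  encoder_forward(fm$x, fm$mask, params$enc)$z
}

#' Masked reconstruction loss
#'
#' Mean squared error over observed entries only; masked entries contribute
#' exactly zero.
#'
#' @param x input value matrix (n x d).
#' @param xhat reconstruction (same shape).
#' @param mask binary observation matrix (1 = observed).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x, xhat, mask) {
  x <- as.matrix(x); xhat <- as.matrix(xhat); mask <- as.matrix(mask)
  assert_that(all(dim(x) == dim(xhat)) && all(dim(x) == dim(mask)),
              "x, xhat and mask must have identical shapes")
  n_obs <- sum(mask)
  assert_that(n_obs > 0, "no observed entries in batch")
  sum(((xhat - x) * mask)^2) / n_obs
}

# one Adam optimizer for a flat list of layer lists
adam_state <- function(layers) {
  purrr::map(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    s <- state[[l]]
    g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

#' Pretrain the masked autoencoder
#'
#' Minimizes the masked reconstruction loss with Adam over shuffled
#' minibatches.  Fully deterministic given the config seed.
#'
#' @param features an `ra_features` object (or list with `x`, `mask`).
#' @param config an [ae_config()].
#' @return An object of class `ra_ae`: `params`, per-epoch `losses` tibble,
#'   and the config.
#' @export
pretrain <- function(features, config = ae_config()) {
  fm <- xm(features)
  n <- nrow(fm$x)
  assert_that(n >= 2, "pretraining requires at least 2 patients")
  d <- ncol(fm$x)
  params <- ae_init(d, config)
  if (config$epochs == 0) {
    return(structure(list(params = params,
                          losses = tibble::tibble(epoch = integer(),
                                                  loss = numeric()),
                          config = config), class = "ra_ae"))
  }
  st_enc <- adam_state(params$enc)
  st_dec <- adam_state(params$dec)
  losses <- numeric(config$epochs)
  t <- 0
  with_seed(derive_seed(config$seed, 7L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        xb <- fm$x[idx, , drop = FALSE]
        mb <- fm$mask[idx, , drop = FALSE]
        ef <- encoder_forward(xb, mb, params$enc)
        df <- decoder_forward(ef$z, params$dec)
        n_obs <- sum(mb)
        loss <- sum(((df$xhat - xb) * mb)^2) / n_obs
        if (!is.finite(loss)) {
          stop("pretraining diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        dXhat <- 2 * (df$xhat - xb) * mb / n_obs
        db <- decoder_backward(df$cache, params$dec, dXhat)
        ge <- encoder_backward(ef$cache, params$enc, db$dZ)
        t <- t + 1
        up <- adam_update(params$dec, db$grads, st_dec,
                          config$learning_rate, t)
        params$dec <- up$layers; st_dec <- up$state
        up <- adam_update(params$enc, ge, st_enc, config$learning_rate, t)
        params$enc <- up$layers; st_enc <- up$state
      }
      losses[epoch] <- epoch_loss / n
    }
  })
  structure(list(params = params,
                 losses = tibble::tibble(epoch = seq_len(config$epochs),
                                         loss = losses),
                 config = config),
            class = "ra_ae")
}

#' @export
print.ra_ae <- function(x, ...) {
  cat("<ra_ae> d =", x$params$d, "latent =", x$params$latent, "\n")
  if (nrow(x$losses)) {
    cat("  epochs:", nrow(x$losses),
        " final masked MSE:", format(utils::tail(x$losses$loss, 1)), "\n")
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' Save / load autoencoder checkpoints as portable JSON
#'
#' Parameters are stored as nested JSON arrays (full double precision) next
#' to the training curve (`<stem>_losses.csv`), so checkpoints are
#' text-only and portable.
#'
#' @param ae an `ra_ae` from [pretrain()].
#' @param path output `.json` path.
#' @return `path` (write) or an `ra_ae` (read), invisibly/visibly.
#' @export
write_ae_checkpoint <- function(ae, path) {
  assert_that(inherits(ae, "ra_ae"), "ae must be a pretrained ra_ae")
  ser <- function(layers) lapply(layers, function(l) {
    list(W = unclass(l$W), b = l$b)
  })
  jsonlite::write_json(
    list(d = ae$params$d, latent = ae$params$latent,
         enc = ser(ae$params$enc), dec = ser(ae$params$dec),
         config = unclass(ae$config)),
    path, digits = NA, auto_unbox = TRUE)
  utils::write.csv(ae$losses,
                   sub("\\.json$", "_losses.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_ae_checkpoint
#' @export
read_ae_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(layers) lapply(layers, function(l) {
    list(W = do.call(rbind, lapply(l$W, unlist)),
         b = as.numeric(unlist(l$b)))
  })
  raw$config <- lapply(raw$config, unlist)
  loss_file <- sub("\\.json$", "_losses.csv", path)
  losses <- if (file.exists(loss_file)) {
    tibble::as_tibble(utils::read.csv(loss_file))
  } else tibble::tibble(epoch = integer(), loss = numeric())
  structure(list(params = list(enc = de(raw$enc), dec = de(raw$dec),
                               d = as.integer(raw$d),
                               latent = as.integer(raw$latent)),
                 losses = losses,
                 config = do.call(ae_config, raw$config[c(
                   "hidden", "latent", "epochs", "batch_size",
                   "learning_rate", "seed")])),
            class = "ra_ae")
}

#' @export
glance.ra_ae <- function(x, ...) {
  tibble::tibble(
    d = x$params$d, latent = x$params$latent, epochs = nrow(x$losses),
    initial_loss = if (nrow(x$losses)) x$losses$loss[1] else NA_real_,
    final_loss = if (nrow(x$losses)) utils::tail(x$losses$loss, 1) else NA_real_)
}
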