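#' Variational autoencoder configuration
#'
#' Two VAEs extract the deep imaging features: VAE 1 consumes the two-channel
#' lesion stack (core + edema), VAE 2 the one-channel brain mask. Each encoder
#' maps a 24-slice binary stack to a 48-dimensional latent Gaussian
#' (`mu`, `logvar`); the decoder maps a latent sample back to per-voxel
#' logits. The encoder front-end is a fixed 3D average-pooling stage (the
#' `pool` factors) followed by fully connected layers; the decoder mirrors it,
#' emitting one logit per pooled block that is shared by all voxels of the
#' block, so the reconstruction term is still the exact full-resolution
#' binary cross-entropy.
#'
#' @param latent_dim Latent dimensionality (48 in the reference analysis).
#' @param input_channels 2 for the lesion VAE, 1 for the brain-mask VAE.
#' @param input_shape Slices x height x width of one stack (depth must be 24
#'   in the reference analysis).
#' @param hidden_width Width of the fully connected encoder/decoder layer.
#' @param pool Integer length-3 pooling factors (slice, row, column); each
#'   must divide the corresponding input dimension.
#' @param kl_weight Weight of the KL term in the ELBO (1 = plain VAE).
#' @param epochs,batch_size,learning_rate,seed Training settings.
#' @param swa_epochs Average the weights over the final `swa_epochs` epochs
#'   (stochastic weight averaging; 0 disables). Damps the minibatch noise of
#'   short training runs, making the extracted latents less sensitive to the
#'   optimization trajectory.
#' @return A `vae_config` list.
#' @export
vae_config <- function(latent_dim = 48L, input_channels = 2L,
                       input_shape = c(24L, 64L, 64L), hidden_width = 128L,
                       pool = c(2L, 4L, 4L), kl_weight = 1,
                       epochs = 10L, batch_size = 16L, learning_rate = 1e-3,
                       seed = 1L, swa_epochs = 0L) {
  input_shape <- as.integer(input_shape)
  pool <- as.integer(pool)
  if (any(input_shape %% pool != 0L))
    stop("input shape (", paste(input_shape, collapse = "x"),
         ") is not divisible by the pooling factors (",
         paste(pool, collapse = "x"), ")")
  structure(list(latent_dim = as.integer(latent_dim),
                 input_channels = as.integer(input_channels),
                 input_shape = input_shape, hidden_width = as.integer(hidden_width),
                 pool = pool, kl_weight = kl_weight, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 swa_epochs = as.integer(swa_epochs)),
            class = "vae_config")
}

# Per-channel 3D block sums; a (D,H,W) array -> vector of block sums.
block_sum_3d <- function(a, pool) {
  d <- dim(a)
  nb <- d %/% pool
  dim(a) <- c(pool[1], nb[1], pool[2], nb[2], pool[3], nb[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(pool), prod(nb))
  colSums(a)
}

# Flatten a stack's channel subset into pooled block-sum rows.
stack_block_sums <- function(stack, channels, pool) {
  arr <- if (channels == 2L) stack$lesion else stack$brain_mask
  do.call(c, lapply(seq_len(dim(arr)[4]),
                    function(k) block_sum_3d(arr[, , , k], pool)))
}

#' Build a variational autoencoder
#'
#' Initializes encoder and decoder weights from the configuration's seed.
#'
#' @param config A [vae_config()].
#' @return A `kps_vae` with elements `params`, `config`, `n_parameters`.
#' @export
build_vae <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  nb <- prod(config$input_shape %/% config$pool) * config$input_channels
  h <- config$hidden_width
  L <- config$latent_dim
  set.seed(config$seed)
  params <- list(
    enc = dense_init(nb, h),
    mu = dense_init(h, L),
    logvar = dense_init(h, L),
    dec = dense_init(L, h),
    out = dense_init(h, nb))
  structure(list(params = params, config = config,
                 n_parameters = count_parameters(params),
                 loss_history = NULL),
            class = "kps_vae")
}

#' @export
print.kps_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<kps_vae> input %s x %d ch, pool %s, hidden %d, latent %d (%d parameters)%s\n",
    paste(cfg$input_shape, collapse = "x"), cfg$input_channels,
    paste(cfg$pool, collapse = "x"), cfg$hidden_width, cfg$latent_dim,
    x$n_parameters, if (is.null(x$loss_history)) ", untrained" else ", trained"))
  invisible(x)
}

# Encoder forward pass on pooled block means (rows = samples).
vae_encode_means <- function(vae, Xmeans) {
  H <- relu(dense_forward(Xmeans, vae$params$enc))
  list(H = H,
       mu = dense_forward(H, vae$params$mu),
       logvar = pmin(pmax(dense_forward(H, vae$params$logvar), -10), 10))
}

#' Evidence lower bound loss
#'
#' Reconstruction term: mean binary cross-entropy between the binary stack and
#' the sigmoid of the reconstruction logits, averaged over every voxel (and
#' sample). KL term: Gaussian KL to the standard normal prior, summed over
#' latent dimensions and averaged over the batch:
#' \eqn{-\tfrac12 \sum_d (1 + \log\sigma_d^2 - \mu_d^2 - \sigma_d^2)}.
#'
#' @param x Binary array (any shape; first dimension = batch if `mu` has
#'   rows), matching `recon_logits`.
#' @param recon_logits Real array, same shape as `x`.
#' @param mu,logvar Latent Gaussian parameters; vectors (one sample) or
#'   batch x latent matrices.
#' @param kl_weight Weight on the KL term.
#' @return List with `total`, `reconstruction`, `kl`.
#' @export
elbo_loss <- function(x, recon_logits, mu, logvar, kl_weight = 1) {
  if (!all(is.finite(recon_logits)) || !all(is.finite(mu)) ||
      !all(is.finite(logvar)))
    stop("non-finite inputs to elbo_loss")
  if (!identical(dim(x), dim(recon_logits)) && length(x) != length(recon_logits))
    stop("`x` and `recon_logits` shapes disagree")
  t <- as.numeric(recon_logits)
  recon <- mean(softplus(-t) + (1 - as.numeric(x)) * t)
  if (is.null(dim(mu))) { mu <- matrix(mu, 1); logvar <- matrix(logvar, 1) }
  kl <- mean(-0.5 * rowSums(1 + logvar - mu^2 - exp(logvar)))
  list(total = recon + kl_weight * kl, reconstruction = recon, kl = kl)
}

#' Pretrain a VAE on slice stacks
#'
#' Minibatch Adam optimization of the ELBO. The reconstruction gradient is
#' computed exactly from per-block voxel sums, so training cost scales with
#' the pooled grid, not the full voxel grid. Training is reproducible: the
#' seed drives initialization, shuffling and the reparameterization draws.
#'
#' @param vae A [build_vae()] model.
#' @param stacks List of `slice_stack`s (see [split_channels()]).
#' @param epochs,batch_size,learning_rate Override the config values if given.
#' @return The trained `kps_vae`, with `loss_history` (one mean total loss per
#'   epoch, plus its reconstruction/KL decomposition).
#' @export
pretrain <- function(vae, stacks, epochs = NULL, batch_size = NULL,
                     learning_rate = NULL) {
  stopifnot(inherits(vae, "kps_vae"))
  if (length(stacks) == 0L) stop("empty pretraining dataset")
  cfg <- vae$config
  Nvox <- prod(cfg$input_shape) * cfg$input_channels
  S <- t(vapply(stacks, stack_block_sums, numeric(Nvox / prod(cfg$pool)),
                channels = cfg$input_channels, pool = cfg$pool))
  pretrain_sums(vae, S, epochs = epochs, batch_size = batch_size,
                learning_rate = learning_rate)
}

# Training core on a precomputed matrix of per-block voxel sums (one row per
# stack); lets large corpora stream into pooled rows without keeping the full
# stacks in memory.
pretrain_sums <- function(vae, S, epochs = NULL, batch_size = NULL,
                          learning_rate = NULL) {
  cfg <- vae$config
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate

  Bsz <- prod(cfg$pool)                       # voxels per pooled block
  Nvox <- prod(cfg$input_shape) * cfg$input_channels
  Xm <- S / Bsz                               # pooled means: encoder input
  n <- nrow(S)

  params <- copy_params(vae$params)   # optimization updates in place
  opt <- adam_init(params)
  set.seed(cfg$seed)
  history <- data.frame(epoch = integer(), total = numeric(),
                        reconstruction = numeric(), kl = numeric())
  swa_from <- if (is.null(cfg$swa_epochs) || cfg$swa_epochs <= 0L)
    epochs + 1L else max(1L, epochs - cfg$swa_epochs + 1L)
  swa_sum <- NULL
  swa_n <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_tot <- ep_rec <- ep_kl <- 0
    nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      b <- length(idx)
      Xb <- Xm[idx, , drop = FALSE]
      Sb <- S[idx, , drop = FALSE]

      H <- relu(add_bias(Xb %*% params$enc$W, params$enc$b))
      mu <- add_bias(H %*% params$mu$W, params$mu$b)
      lv <- pmin(pmax(add_bias(H %*% params$logvar$W, params$logvar$b),
                      -10), 10)
      epsz <- matrix(stats::rnorm(b * ncol(mu)), b)
      z <- mu + epsz * exp(lv / 2)
      G <- relu(add_bias(z %*% params$dec$W, params$dec$b))
      Tl <- add_bias(G %*% params$out$W, params$out$b)   # block logits

      # exact full-resolution BCE from block sums:
      # per block: B*softplus(-t) + (B - s)*t
      rec <- sum(Bsz * softplus(-Tl) + (Bsz - Sb) * Tl) / (Nvox * b)
      kl <- mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
      if (!is.finite(rec) || !is.finite(kl))
        stop(sprintf("VAE training diverged at epoch %d (recon=%g, kl=%g)",
                     ep, rec, kl))
      ep_tot <- ep_tot + rec + cfg$kl_weight * kl
      ep_rec <- ep_rec + rec; ep_kl <- ep_kl + kl; nb <- nb + 1L

      dT <- (Bsz * sigmoid(Tl) - Sb) / (Nvox * b)
      d_out <- list(W = crossprod(G, dT), b = colSums(dT))
      dG <- (dT %*% t(params$out$W)) * (G > 0)
      d_dec <- list(W = crossprod(z, dG), b = colSums(dG))
      dz <- dG %*% t(params$dec$W)
      dmu <- dz + cfg$kl_weight * mu / b
      dlv <- dz * epsz * exp(lv / 2) / 2 +
        cfg$kl_weight * (exp(lv) - 1) / (2 * b)
      dlv[lv <= -10 | lv >= 10] <- 0
      d_mu <- list(W = crossprod(H, dmu), b = colSums(dmu))
      d_lv <- list(W = crossprod(H, dlv), b = colSums(dlv))
      dH <- (dmu %*% t(params$mu$W) + dlv %*% t(params$logvar$W)) * (H > 0)
      d_enc <- list(W = crossprod(Xb, dH), b = colSums(dH))

      grads <- list(enc = d_enc, mu = d_mu, logvar = d_lv,
                    dec = d_dec, out = d_out)
      stepped <- adam_step(params, grads, opt, lr)
      params <- stepped$params
      opt <- stepped$state
    }
    history <- rbind(history,
                     data.frame(epoch = ep, total = ep_tot / nb,
                                reconstruction = ep_rec / nb, kl = ep_kl / nb))
    if (ep >= swa_from) {
      swa_n <- swa_n + 1L
      swa_sum <- if (is.null(swa_sum)) rapply(params, identity,
                                              how = "replace")
        else mapply(function(a, b) mapply(function(u, v) u + v, a, b,
                                          SIMPLIFY = FALSE),
                    swa_sum, params, SIMPLIFY = FALSE)
    }
  }
  if (swa_n > 0L)
    params <- rapply(swa_sum, function(p) p / swa_n, how = "replace")
  vae$params <- params
  vae$loss_history <- history
  vae
}

#' Save / load a VAE checkpoint
#'
#' Checkpoints round-trip bit-compatibly: latents extracted after reloading
#' are identical to those from the in-memory model.
#' @param vae A `kps_vae`.
#' @param path File path (`.rds`).
#' @export
save_vae <- function(vae, path) {
  stopifnot(inherits(vae, "kps_vae"))
  saveRDS(vae, path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  vae <- readRDS(path)
  if (!inherits(vae, "kps_vae")) stop("not a kps_vae checkpoint: ", path)
  vae
}

#' Extract latent features from a slice stack
#'
#' Deterministic extraction: returns the encoder's posterior mean `mu` (no
#' sampling), tagged with its feature group (`timepoint` x channel type).
#'
#' @param vae A trained `kps_vae`.
#' @param stack A `slice_stack`.
#' @return A `latent_features` list: `mu`, `logvar` (length `latent_dim`),
#'   `group`.
#' @export
extract_latent <- function(vae, stack) {
  stopifnot(inherits(vae, "kps_vae"), inherits(stack, "slice_stack"))
  cfg <- vae$config
  arr <- if (cfg$input_channels == 2L) stack$lesion else stack$brain_mask
  if (!identical(dim(arr)[1:3], cfg$input_shape) ||
      dim(arr)[4] != cfg$input_channels)
    stop(sprintf("stack shape %s x %d does not match VAE input %s x %d",
                 paste(dim(arr)[1:3], collapse = "x"), dim(arr)[4],
                 paste(cfg$input_shape, collapse = "x"), cfg$input_channels))
  s <- stack_block_sums(stack, cfg$input_channels, cfg$pool)
  enc <- vae_encode_means(vae, matrix(s / prod(cfg$pool), 1))
  type <- if (cfg$input_channels == 2L) "lesion" else "mask"
  structure(list(mu = as.numeric(enc$mu), logvar = as.numeric(enc$logvar),
                 group = paste(stack$timepoint, type, sep = "_")),
            class = "latent_features")
}

#' Assemble the per-patient MRI feature vector
#'
#' Concatenates the four 48-dimensional latent mean vectors in the fixed order
#' pre_lesion, post_lesion, pre_mask, post_mask (192 features). With
#' `augment = TRUE`, four scalar summaries (total pre/post lesion-core area
#' and pre/post edema area over the window, mm^2) are appended, giving 196
#' features.
#'
#' @param pre_stack,post_stack `slice_stack`s for the two timepoints.
#' @param vae1 Trained lesion VAE (2 channels).
#' @param vae2 Trained brain-mask VAE (1 channel).
#' @param augment Append the 4 scalar area summaries (default `FALSE`).
#' @return List with `values` (named numeric vector) and `groups` (character
#'   vector of the same length).
#' @export
assemble_mri_features <- function(pre_stack, post_stack, vae1, vae2,
                                  augment = FALSE) {
  if (is.null(pre_stack) || is.null(post_stack))
    stop("both pre- and postoperative stacks are required")
  stopifnot(identical(pre_stack$timepoint, "pre"),
            identical(post_stack$timepoint, "post"))
  parts <- list(
    pre_lesion = extract_latent(vae1, pre_stack)$mu,
    post_lesion = extract_latent(vae1, post_stack)$mu,
    pre_mask = extract_latent(vae2, pre_stack)$mu,
    post_mask = extract_latent(vae2, post_stack)$mu)
  values <- unlist(lapply(names(parts), function(g)
    stats::setNames(parts[[g]], sprintf("%s_%02d", g, seq_along(parts[[g]])))))
  groups <- rep(names(parts), vapply(parts, length, 1L))
  if (augment) {
    area <- function(stack, ch) {
      sum(stack$lesion[, , , ch]) * stack$spacing[2] * stack$spacing[3]
    }
    extra <- c(pre_core_area = area(pre_stack, 1),
               post_core_area = area(post_stack, 1),
               pre_edema_area = area(pre_stack, 2),
               post_edema_area = area(post_stack, 2))
    values <- c(values, extra)
    groups <- c(groups, c("pre_lesion", "post_lesion", "pre_lesion",
                          "post_lesion"))
  }
  list(values = values, groups = groups)
}
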