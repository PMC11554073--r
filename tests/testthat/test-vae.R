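test_that("configuration validates shape/pool compatibility and builds", {
  expect_error(vae_config(input_shape = c(24, 30, 30), pool = c(2, 4, 4)),
               "not divisible")
  v <- build_vae(small_vae_config(2L))
  expect_s3_class(v, "kps_vae")
  expect_gt(v$n_parameters, 0)
  toy <- build_vae(vae_config(latent_dim = 1L, input_channels = 1L,
                              input_shape = c(24L, 8L, 8L),
                              hidden_width = 4L, pool = c(2L, 2L, 2L)))
  expect_equal(toy$config$latent_dim, 1L)
})

test_that("ELBO terms match their closed forms", {
  set.seed(1)
  x <- array(rbinom(2 * 24 * 8 * 8, 1, 0.3), c(2, 24, 8, 8))
  logits <- array(rnorm(length(x)), dim(x))

  # posterior equal to the prior: zero KL
  l0 <- elbo_loss(x, logits, mu = rep(0, 48), logvar = rep(0, 48))
  expect_equal(l0$kl, 0)
  expect_equal(l0$total, l0$reconstruction)

  # unit mean in one dimension, unit variance: KL = 1/2 (sum over dims)
  mu <- c(1, rep(0, 47))
  l1 <- elbo_loss(x, logits, mu = mu, logvar = rep(0, 48))
  expect_equal(l1$kl, 0.5)

  # beta-weighting scales only the KL contribution
  l2 <- elbo_loss(x, logits, mu = mu, logvar = rep(0, 48), kl_weight = 0.1)
  expect_equal(l2$total, l2$reconstruction + 0.05)

  # saturated reconstruction drives the BCE to zero
  sat_logits <- ifelse(x == 1, 40, -40)
  ls <- elbo_loss(x, sat_logits, rep(0, 48), rep(0, 48))
  expect_lt(ls$reconstruction, 1e-10)

  expect_error(elbo_loss(x, logits[1, , , ], rep(0, 48), rep(0, 48)),
               "disagree")
  expect_error(elbo_loss(x, logits, c(NA, rep(0, 47)), rep(0, 48)),
               "non-finite")
})

test_that("the KL term is nonnegative and zero only at the prior", {
  set.seed(2)
  x <- array(0, c(1, 4, 4)); logits <- array(0, c(1, 4, 4))
  for (i in 1:50) {
    mu <- rnorm(8); lv <- rnorm(8, sd = 0.8)
    expect_gte(elbo_loss(x, logits, mu, lv)$kl, -1e-12)
  }
  expect_gt(elbo_loss(x, logits, c(0.2, rep(0, 7)), rep(0, 8))$kl, 0)
})

test_that("pretraining reduces the loss, reproducibly, and checkpoints", {
  co <- small_cohort()
  stacks <- unlist(lapply(co$studies[1:10], function(s)
    list(split_channels(s$pre), split_channels(s$post))), recursive = FALSE)

  vae <- pretrain(build_vae(small_vae_config(2L)), stacks)
  h <- vae$loss_history
  expect_equal(nrow(h), 5L)
  expect_lt(h$total[5], h$total[1])

  vae_again <- pretrain(build_vae(small_vae_config(2L)), stacks)
  expect_identical(vae_again$loss_history, h)

  path <- tempfile(fileext = ".rds")
  save_vae(vae, path)
  reloaded <- load_vae(path)
  st <- split_channels(co$studies[[11]]$pre)
  expect_identical(extract_latent(vae, st)$mu,
                   extract_latent(reloaded, st)$mu)
})

test_that("an all-zero dataset is reconstructed almost perfectly", {
  zero_stack <- structure(
    list(lesion = array(0, c(24, 32, 32, 2)),
         brain_mask = array(0, c(24, 32, 32, 1)),
         window_start = 1L, spacing = c(3, 1, 1),
         patient_id = "Z", timepoint = "pre"),
    class = "slice_stack")
  vae <- pretrain(build_vae(small_vae_config(2L)),
                  rep(list(zero_stack), 8), epochs = 3, batch_size = 2,
                  learning_rate = 0.2)
  expect_lt(utils::tail(vae$loss_history$reconstruction, 1), 0.05)
})

test_that("latent extraction is deterministic, 48-dim and shape-checked", {
  v <- small_vaes()
  co <- small_cohort()
  st <- split_channels(co$studies[[1]]$pre)
  f1 <- extract_latent(v$vae1, st)
  expect_length(f1$mu, 48)
  expect_true(all(is.finite(f1$mu)))
  expect_identical(f1$group, "pre_lesion")
  expect_identical(extract_latent(v$vae1, st)$mu, f1$mu)
  expect_identical(extract_latent(v$vae2, st)$group, "pre_mask")

  # a single distant voxel changes the code: the encoder is not constant
  vol2 <- co$studies[[1]]$pre
  vol2$labels[1, 1, 1] <- 3L
  f2 <- extract_latent(v$vae1, split_channels(vol2,
                                              st$window_start))
  expect_false(identical(f2$mu, f1$mu))

  bad <- split_channels(label_volume(array(1L, c(30, 8, 8))), window = 24)
  expect_error(extract_latent(v$vae1, bad), "does not match")
})

test_that("latents linearly separate small from large tumors", {
  set.seed(7)
  stacks <- list(); cls <- integer(0)
  for (i in 1:44) {
    small <- i %% 2 == 0
    g <- test_geometry()
    g$core_radii <- if (small) c(2, 4, 4) else c(4, 9, 9)
    g$center <- g$center + c(runif(1, -0.5, 0.5), runif(2, -1.5, 1.5))
    vol <- simulate_tumor_volume(g, grid_shape = c(16, 32, 32), jitter = 0.1,
                                 seed = 1000 + i)
    stacks[[i]] <- split_channels(vol)
    cls[i] <- as.integer(!small)
  }
  vae <- pretrain(build_vae(small_vae_config(2L)), stacks, epochs = 6)
  M <- t(vapply(stacks, function(s) extract_latent(vae, s)$mu, numeric(48)))
  train <- seq_len(22); test <- 23:44
  dir <- colMeans(M[train, ][cls[train] == 1, , drop = FALSE]) -
    colMeans(M[train, ][cls[train] == 0, , drop = FALSE])
  score <- M[test, ] %*% dir
  auc <- kpsfusion:::roc_auc(cls[test], as.numeric(score))
  expect_gt(auc, 0.9)
})

test_that("the assembled MRI vector has the documented layout", {
  v <- small_vaes()
  co <- small_cohort()
  pre <- split_channels(co$studies[[1]]$pre)
  post <- split_channels(co$studies[[1]]$post)

  f <- assemble_mri_features(pre, post, v$vae1, v$vae2)
  expect_length(f$values, 192)
  expect_equal(as.vector(table(f$groups)[c("pre_lesion", "post_lesion",
                                           "pre_mask", "post_mask")]),
               rep(48L, 4))
  expect_identical(f$groups[1:48], rep("pre_lesion", 48))

  fa <- assemble_mri_features(pre, post, v$vae1, v$vae2, augment = TRUE)
  expect_length(fa$values, 196)
  expect_identical(unname(fa$values[1:192]), unname(f$values))

  expect_error(assemble_mri_features(NULL, post, v$vae1, v$vae2),
               "both pre- and postoperative")
})
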