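# Shared fixtures. Everything is generated in code at test time; expensive
# objects are built once per session and cached.

.kps_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .kps_cache))
    assign(key, expr, envir = .kps_cache)
  get(key, envir = .kps_cache)
}

small_config <- function(...) {
  cohort_config(grid_shape = c(16L, 32L, 32L), ...)
}

small_cohort <- function() {
  cached("cohort", simulate_cohort(30, ordering_outcome_model(),
                                   config = small_config(), seed = 3))
}

small_vae_config <- function(channels, seed = channels) {
  vae_config(input_channels = channels, input_shape = c(24L, 32L, 32L),
             hidden_width = 32L, pool = c(2L, 4L, 4L), kl_weight = 1e-3,
             epochs = 5L, batch_size = 8L, learning_rate = 3e-3, seed = seed)
}

small_vaes <- function() {
  cached("vaes", pretrain_cohort_vaes(12, small_vae_config(2L),
                                      small_vae_config(1L), seed = 99,
                                      config = small_config()))
}

feature_cohort <- function() {
  cached("feature_cohort", {
    v <- small_vaes()
    extract_cohort_features(small_cohort(), v$vae1, v$vae2)
  })
}

# a clearly separable two-feature binary problem
toy_separable <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(x1 = rnorm(n, ifelse(y == 1, 2, -2), 0.5),
             x2 = rnorm(n))
  list(X = X, y = y)
}

# test tumor geometry that fits the small grid
test_geometry <- function() {
  list(center = c(8, 16, 16), core_radii = c(3, 5, 5), edema_margin = 2,
       brain = list(center = c(8.5, 16.5, 16.5), radii = c(7, 13, 13)))
}
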