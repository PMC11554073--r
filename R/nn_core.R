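# Minimal dense-network machinery shared by the VAE and the softmax classifier.
# All math is plain BLAS-backed matrix algebra; parameters are lists of
# matrices/vectors so checkpoints serialize exactly with saveRDS().

dense_init <- function(n_in, n_out) {
  # He initialization, suited to ReLU units
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

dense_forward <- function(X, layer) {
  add_bias(X %*% layer$W, layer$b)
}

relu <- function(x) {
  x * (x > 0)
}

softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Adam optimizer over a two-level parameter list (layers of W/b arrays).
adam_init <- function(params) {
  # m and v must be distinct allocations: the optimizer updates them in place
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  adam_update_inplace(params, grads, state$m, state$v, lr, beta1, beta2,
                      eps, state$t)
  list(params = params, state = state)
}

# deep copy of a two-level parameter list, so in-place optimization never
# touches memory shared with a caller's object
copy_params <- function(params) {
  rapply(params, function(p) p + 0, how = "replace")
}

count_parameters <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
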