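# Minimal layer toolkit used by both networks. Parameters live in flat named
# lists of R arrays; every layer exposes a forward returning (output, cache)
# and a backward returning (input gradient, parameter gradients). All heavy
# kernels are C++ (see src/kernels.cpp).

he_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  array(rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
}

new_conv_params <- function(k, cin, cout, bn = TRUE) {
  p <- list(w = he_init(k, cin, cout), b = numeric(cout))
  if (bn) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
    p$rmean <- numeric(cout)  # running stats, not trainable
    p$rvar <- rep(1, cout)
  }
  p
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Conv -> BN -> ReLU stage. `prm` is an environment slot so running stats can
# be updated in place during training.
conv_bn_relu_fwd <- function(x, prm, training = TRUE) {
  z <- conv2d_fwd(x, prm$w, prm$b, 1L, 1L)
  if (training) {
    bn <- bn_fwd(z, prm$gamma, prm$beta, BN_EPS)
    a <- leaky_fwd(bn$y, 0)
    list(
      y = a,
      cache = list(x = x, z = z, mean = bn$mean, var = bn$var, h = bn$y),
      rmean = (1 - BN_MOMENTUM) * prm$rmean + BN_MOMENTUM * bn$mean,
      rvar = (1 - BN_MOMENTUM) * prm$rvar + BN_MOMENTUM * bn$var
    )
  } else {
    h <- bn_eval(z, prm$gamma, prm$beta, prm$rmean, prm$rvar, BN_EPS)
    list(y = leaky_fwd(h, 0), cache = NULL)
  }
}

conv_bn_relu_bwd <- function(gy, prm, cache) {
  gh <- leaky_bwd(cache$h, 0, gy)
  bn <- bn_bwd(cache$z, prm$gamma, cache$mean, cache$var, BN_EPS, gh)
  cv <- conv2d_bwd(cache$x, prm$w, bn$gx, 1L, 1L)
  list(gx = cv$gx,
       grads = list(w = cv$gw, b = cv$gb, gamma = bn$ggamma, beta = bn$gbeta))
}

# Channel-concatenate a list of (H, W, C_i, B) arrays; split is its adjoint.
concat_channels <- function(xs) concat_channels_cpp(xs)

split_channels <- function(g, sizes) split_channels_cpp(g, as.integer(sizes))

# Adam optimizer over a flat named list of numeric arrays.
adam_new <- function(params, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  zero <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, m = zero, v = zero)
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}

# One-hot encode an integer label map (H, W, B) with values 0..C-1 into
# a (H, W, C, B) probability-style array.
one_hot_labels <- function(labels, num_classes) {
  d <- dim(labels)
  if (length(d) == 2) {
    labels <- array(labels, dim = c(d, 1L))
    d <- dim(labels)
  }
  out <- array(0, dim = c(d[1], d[2], num_classes, d[3]))
  for (c in seq_len(num_classes) - 1L) {
    out[, , c + 1L, ] <- (labels == c) * 1
  }
  out
}

# Per-pixel argmax over channels, ties broken toward the lowest class index.
# Input (H, W, C, B) -> integer array (H, W, B) with values 0..C-1.
channel_argmax <- function(p) {
  d <- dim(p)
  m <- matrix(aperm(p, c(3, 1, 2, 4)), nrow = d[3])
  lab <- max.col(t(m), ties.method = "first") - 1L
  array(as.integer(lab), dim = c(d[1], d[2], d[4]))
}
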