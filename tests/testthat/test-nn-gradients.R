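# Analytic backward passes against central finite differences; these are the
# load-bearing checks for the hand-written training engine.

test_that("convolution kernels match a naive direct-convolution oracle", {
  set.seed(101)
  x <- array(rnorm(9 * 7 * 3 * 2), dim = c(9, 7, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), dim = c(3, 3, 3, 4))
  b <- rnorm(4)
  expect_equal(ns$conv2d_fwd(x, w, b, 1L, 1L), naive_conv3(x, w, b),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 1x1 projection path
  w1 <- array(rnorm(1 * 1 * 3 * 2), dim = c(1, 1, 3, 2))
  y1 <- ns$conv2d_fwd(x, w1, c(0, 0), 1L, 0L)
  expect_equal(y1[3, 4, 2, 1], sum(x[3, 4, , 1] * w1[1, 1, , 2]), tolerance = 1e-12)
})

test_that("conv backward gradients match finite differences (both paths)", {
  set.seed(102)
  for (geom in list(list(k = 3L, s = 1L, p = 1L), list(k = 4L, s = 2L, p = 2L))) {
    x <- array(rnorm(8 * 6 * 3 * 2), dim = c(8, 6, 3, 2))
    w <- array(rnorm(geom$k^2 * 3 * 2) * 0.4, dim = c(geom$k, geom$k, 3, 2))
    b <- rnorm(2)
    y <- ns$conv2d_fwd(x, w, b, geom$s, geom$p)
    lw <- array(rnorm(length(y)), dim = dim(y))
    bwd <- ns$conv2d_bwd(x, w, lw, geom$s, geom$p)
    fx <- function(xx) sum(ns$conv2d_fwd(xx, w, b, geom$s, geom$p) * lw)
    fwf <- function(ww) sum(ns$conv2d_fwd(x, ww, b, geom$s, geom$p) * lw)
    ix <- sample(length(x), 12)
    iw <- sample(length(w), 12)
    expect_equal(bwd$gx[ix], fd_grad(fx, x, ix), tolerance = 1e-6)
    expect_equal(bwd$gw[iw], fd_grad(fwf, w, iw), tolerance = 1e-6)
    expect_equal(bwd$gb, vapply(1:2, function(co) sum(lw[, , co, ]), numeric(1)),
                 tolerance = 1e-9)
  }
})

test_that("batch-norm, pooling, upsampling and softmax backprop correctly", {
  set.seed(103)
  x <- array(rnorm(6 * 6 * 3 * 2), dim = c(6, 6, 3, 2))
  lw <- array(rnorm(length(x)), dim = dim(x))
  gam <- runif(3, 0.5, 1.5); bet <- rnorm(3)
  fb <- function(xx) sum(ns$bn_fwd(xx, gam, bet, 1e-5)$y * lw)
  r <- ns$bn_fwd(x, gam, bet, 1e-5)
  gb <- ns$bn_bwd(x, gam, r$mean, r$var, 1e-5, lw)
  ix <- sample(length(x), 10)
  expect_equal(gb$gx[ix], fd_grad(fb, x, ix, eps = 1e-5), tolerance = 1e-4)
  # batch-norm output is standardized per channel
  for (cc in 1:3) {
    z <- (r$y[, , cc, ] - bet[cc]) / gam[cc]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(var(as.vector(z)) * (length(z) - 1) / length(z), 1, tolerance = 1e-3)
  }

  mp <- ns$maxpool2_fwd(x)
  lm <- array(rnorm(length(mp$y)), dim = dim(mp$y))
  fm <- function(xx) { m <- ns$maxpool2_fwd(xx); sum(m$y * lm) }
  gm <- ns$maxpool2_bwd(mp$idx, lm, dim(x))
  expect_equal(gm[ix], fd_grad(fm, x, ix), tolerance = 1e-6)

  yu <- ns$upsample2_fwd(x)
  expect_equal(dim(yu), c(12, 12, 3, 2))
  # constant fields are preserved exactly by bilinear interpolation
  const <- array(3.5, dim = c(5, 4, 1, 1))
  expect_true(all(ns$upsample2_fwd(const) == 3.5))
  lu <- array(rnorm(length(yu)), dim = dim(yu))
  fu <- function(xx) sum(ns$upsample2_fwd(xx) * lu)
  gu <- ns$upsample2_bwd(lu, dim(x))
  expect_equal(gu[ix], fd_grad(fu, x, ix), tolerance = 1e-6)

  p <- ns$channel_softmax(x)
  expect_equal(apply(p, c(1, 2, 4), sum), array(1, dim = c(6, 6, 2)),
               tolerance = 1e-12)
  ls <- array(rnorm(length(x)), dim = dim(x))
  fs <- function(xx) sum(ns$channel_softmax(xx) * ls)
  gs <- ns$channel_softmax_bwd(p, ls)
  expect_equal(gs[ix], fd_grad(fs, x, ix), tolerance = 1e-6)
})

test_that("the full generator backward matches finite differences", {
  set.seed(104)
  cfg <- generator_config(filters = c(2L, 4L, 8L, 16L, 32L), num_classes = 4L)
  gen <- build_nested_generator(cfg)
  x <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array(sample(0:3, 16 * 16 * 2, TRUE), dim = c(16, 16, 2))
  loss_of <- function(g) {
    fw <- generator_forward(g, x, training = TRUE)
    ns$seg_loss_value_grad(fw$probs, y, "ce", want_grad = FALSE)$value
  }
  fw <- generator_forward(gen, x, training = TRUE)
  sl <- ns$seg_loss_value_grad(fw$probs, y, "ce")
  glog <- ns$channel_softmax_bwd(fw$probs, sl$grad)
  grads <- ns$flatten_grads(ns$generator_backward(gen, glog, fw$cache))
  for (probe in list(c("x0_0.c1", "w", 3), c("x2_1.c1", "w", 11),
                     c("x0_4.c2", "gamma", 1), c("head", "w", 2))) {
    key <- probe[1]; field <- probe[2]; idx <- as.integer(probe[3])
    eps <- 1e-5
    gp <- gen; gp$params[[key]][[field]][idx] <- gp$params[[key]][[field]][idx] + eps
    gm <- gen; gm$params[[key]][[field]][idx] <- gm$params[[key]][[field]][idx] - eps
    num <- (loss_of(gp) - loss_of(gm)) / (2 * eps)
    ana <- grads[[paste0(key, "/", field)]][idx]
    expect_equal(ana, num, tolerance = 1e-3,
                 label = paste("d loss /", key, field))
  }
})

test_that("discriminator backward reaches both parameters and inputs", {
  set.seed(105)
  dc <- discriminator_config(in_channels = 5L, widths = c(4L, 8L, 16L, 32L, 64L))
  disc <- build_discriminator(dc)
  xi <- array(runif(16 * 16 * 5 * 2), dim = c(16, 16, 5, 2))
  dloss <- function(xx) {
    f <- ns$discriminator_forward(disc, xx, training = TRUE)
    mean((f$score - 1)^2)
  }
  f <- ns$discriminator_forward(disc, xi, training = TRUE)
  bd <- ns$discriminator_backward(disc, 2 * (f$score - 1) / length(f$score),
                                  f$score, f$cache)
  ix <- sample(length(xi), 8)
  expect_equal(bd$gx[ix], fd_grad(dloss, xi, ix), tolerance = 1e-5)
  dg <- ns$flatten_grads(bd$grads)
  dl_of <- function(d) {
    f <- ns$discriminator_forward(d, xi, training = TRUE)
    mean((f$score - 1)^2)
  }
  eps <- 1e-6
  dp <- disc; dp$params[["d3"]]$w[5] <- dp$params[["d3"]]$w[5] + eps
  dm <- disc; dm$params[["d3"]]$w[5] <- dm$params[["d3"]]$w[5] - eps
  num <- (dl_of(dp) - dl_of(dm)) / (2 * eps)
  expect_equal(dg[["d3/w"]][5], num, tolerance = 1e-5)
})

test_that("channel concat and split are mutual inverses", {
  set.seed(106)
  a <- array(rnorm(5 * 4 * 2 * 3), dim = c(5, 4, 2, 3))
  b <- array(rnorm(5 * 4 * 3 * 3), dim = c(5, 4, 3, 3))
  cc <- ns$concat_channels(list(a, b))
  expect_equal(dim(cc), c(5, 4, 5, 3))
  expect_equal(cc[, , 1:2, ], a, ignore_attr = TRUE)
  expect_equal(cc[, , 3:5, ], b, ignore_attr = TRUE)
  parts <- ns$split_channels(cc, c(2, 3))
  expect_equal(parts[[1]], a, ignore_attr = TRUE)
  expect_equal(parts[[2]], b, ignore_attr = TRUE)
})
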