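test_that("connectivity table enumerates the 15 nested nodes with Eq-style channels", {
  tab <- connectivity_table(generator_config())
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$i + tab$j <= 4))
  # encoder nodes have one input; decoder node (i, j) has j + 1 inputs
  expect_equal(purrr::map_int(tab$inputs, length), tab$j + 1L)
  n00 <- tab[tab$node == "x0_0", ]
  expect_equal(n00$in_channels, 1L)
  expect_equal(n00$mid_channels, 64L)
  n21 <- tab[tab$node == "x2_1", ]
  expect_equal(n21$in_channels, 256L * 1L + 512L)   # preserve-mode up-sampling
  lit <- connectivity_table(generator_config(channel_mode = "eq2_literal"))
  expect_equal(lit$in_channels[lit$node == "x2_1"], 256L * 1L + 256L)
  # output channels always equal the depth's filter width
  f <- c(64L, 128L, 256L, 512L, 1024L)
  expect_equal(tab$out_channels, f[tab$i + 1L])
  expect_equal(tab$mid_channels, tab$out_channels)
})

test_that("nested generator reproduces the published parameter count", {
  g <- build_nested_generator(generator_config())
  expect_equal(count_parameters(g), 36628676)
  expect_equal(round(count_parameters(g) / 1e6, 2), 36.63)
})

test_that("parameter counting sums exactly the trainable scalars", {
  # single 3x3 conv with bias, 1 -> 1 channel: 9 + 1
  net <- ns$new_seg_network("probe", list(),
                            list(only = ns$new_conv_params(3L, 1L, 1L, bn = FALSE)))
  expect_equal(count_parameters(net), 10)
  # batch-norm adds scale + shift only (running stats are buffers)
  net_bn <- ns$new_seg_network("probe", list(),
                               list(only = ns$new_conv_params(3L, 1L, 1L, bn = TRUE)))
  expect_equal(count_parameters(net_bn), 10 + 2)
  bn64 <- ns$new_conv_params(1L, 1L, 64L, bn = TRUE)
  expect_equal(length(bn64$gamma) + length(bn64$beta), 128)
})

test_that("plain baseline is strictly smaller and shares the shape contract", {
  u <- build_unet_baseline(generator_config())
  g <- build_nested_generator(generator_config())
  expect_lt(count_parameters(u), count_parameters(g))
  cfg <- tiny_gen_config()
  ut <- build_unet_baseline(cfg)
  x <- array(runif(64 * 64), dim = c(64, 64, 1, 1))
  fw <- generator_forward(ut, x)
  expect_equal(dim(fw$probs), c(64, 64, 4, 1))
  sums <- apply(fw$probs, c(1, 2, 4), sum)
  expect_true(max(abs(sums - 1)) < 1e-6)
})

test_that("forward pass keeps resolution and emits normalized confidences", {
  cfg <- tiny_gen_config()
  g <- build_nested_generator(cfg)
  x <- array(runif(64 * 64 * 2), dim = c(64, 64, 1, 2))
  fw <- generator_forward(g, x)
  expect_equal(dim(fw$probs), c(64, 64, 4, 2))
  sums <- apply(fw$probs, c(1, 2, 4), sum)
  expect_true(max(abs(sums - 1)) < 1e-6)
  # spatial size must be divisible by 16
  bad <- array(runif(60 * 60), dim = c(60, 60, 1, 1))
  expect_error(generator_forward(g, bad), "divisible by 16")
  expect_error(generator_forward(g, array(0, c(64, 64, 2, 1))), "channels")
})

test_that("doubling filter widths scales conv parameters ~4x", {
  count_conv_only <- function(net) {
    total <- 0
    for (nm in names(net$params)) {
      if (nm == "head") next
      p <- net$params[[nm]]
      total <- total + length(p$w)   # conv weights: the quadratic part
    }
    total
  }
  g1 <- build_nested_generator(generator_config(filters = c(8L, 16L, 32L, 64L, 128L)))
  g2 <- build_nested_generator(generator_config(filters = c(16L, 32L, 64L, 128L, 256L)))
  ratio <- count_conv_only(g2) / count_conv_only(g1)
  expect_lt(abs(ratio - 4), 4 * 0.02)
})

test_that("eq2_literal mode carries a channel-reducing lateral projection", {
  cfg <- generator_config(filters = c(4L, 8L, 16L, 32L, 64L),
                          channel_mode = "eq2_literal")
  g <- build_nested_generator(cfg)
  expect_true("x0_1.proj" %in% names(g$params))
  expect_equal(dim(g$params[["x0_1.proj"]]$w), c(1, 1, 8, 4))
  x <- array(runif(32 * 32), dim = c(32, 32, 1, 1))
  fw <- generator_forward(g, x)
  expect_equal(dim(fw$probs), c(32, 32, 4, 1))
  # literal mode differs from preserve mode in size
  gp <- build_nested_generator(generator_config(filters = c(4L, 8L, 16L, 32L, 64L)))
  expect_false(count_parameters(g) == count_parameters(gp))
})
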