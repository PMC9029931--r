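test_that("straight unrotated strip rasterizes to an exact rectangle", {
  st <- make_strip(20, 5, curvature = 0, angle = 0, center = c(30, 30),
                   canvas = c(64L, 64L), seed = 1)
  expect_equal(sum(st$mask), 100)
  bb <- which(st$mask, arr.ind = TRUE)
  expect_equal(diff(range(bb[, 1])) + 1, 5)   # width across rows
  expect_equal(diff(range(bb[, 2])) + 1, 20)  # length across columns
})

test_that("strips are connected, deterministic, and fail when oversized", {
  skip_if_not_installed("EBImage")
  set.seed(99)
  for (i in 1:8) {
    st <- make_strip(length = sample(30:50, 1), width = sample(4:8, 1),
                     curvature = runif(1, 0, 0.25), bands = sample(3:7, 1),
                     canvas = c(64L, 64L))
    expect_gt(sum(st$mask), 0)
    expect_equal(max(EBImage::bwlabel(st$mask)), 1)
  }
  a <- make_strip(30, 5, curvature = 0.1, canvas = c(64L, 64L), seed = 7)
  b <- make_strip(30, 5, curvature = 0.1, canvas = c(64L, 64L), seed = 7)
  expect_identical(a$mask, b$mask)
  expect_identical(a$texture, b$texture)
  expect_error(make_strip(200, 5, canvas = c(64L, 64L), angle = 0),
               "does not fit")
  expect_error(make_strip(2, 5, canvas = c(64L, 64L)), ">= 3")
})

test_that("compose_pair implements the set semantics of the label map", {
  cfg <- tiny_synth_config(noise_sd = 0, overlap_guarantee = FALSE)
  a <- make_strip(20, 5, angle = 0, center = c(16, 32), canvas = c(64L, 64L),
                  intensity = 100, seed = 1)
  b <- make_strip(20, 5, angle = 0, center = c(48, 32), canvas = c(64L, 64L),
                  intensity = 180, seed = 2)
  s <- compose_pair(a, b, cfg)          # disjoint
  expect_false(any(s$label == 3))
  expect_equal(sum(s$label == 1), sum(a$mask))
  expect_equal(sum(s$label == 2), sum(b$mask))
  # identical strips: full overlap
  s2 <- compose_pair(a, a, cfg)
  expect_equal(sum(s2$label == 1), 0)
  expect_equal(sum(s2$label == 2), 0)
  expect_equal(sum(s2$label == 3), sum(a$mask))
  # overlap_guarantee on disjoint strips errors
  cfg_g <- tiny_synth_config(noise_sd = 0, overlap_guarantee = TRUE)
  expect_error(compose_pair(a, b, cfg_g), class = "chromseg_generation_error")
})

test_that("overlap rendering is no brighter than either strip body", {
  cfg <- tiny_synth_config(noise_sd = 0)
  a <- make_strip(40, 9, angle = 0, center = c(32, 32), canvas = c(64L, 64L),
                  intensity = 120, seed = 3)
  b <- make_strip(40, 9, angle = pi / 2, center = c(32, 32), canvas = c(64L, 64L),
                  intensity = 170, seed = 4)
  s <- compose_pair(a, b, cfg)
  ov <- s$label == 3
  expect_gt(sum(ov), 0)
  # pixelwise min oracle (+1 gray level of rounding headroom)
  lim <- pmin(a$texture[ov], b$texture[ov])
  expect_true(all(s$image[ov] <= lim + 1))
})

test_that("generated datasets satisfy the declared invariants", {
  cfg <- tiny_synth_config(seed = 321L)
  ds <- generate_dataset(12, cfg)
  expect_length(ds, 12)
  h <- attr(ds, "class_histogram")
  expect_equal(sum(h), 12 * 64 * 64)                       # pixel conservation
  expect_true(all(vapply(ds, function(s) any(s$label == 3L), logical(1))))
  for (s in ds[1:4]) {
    expect_true(all(s$label %in% 0:3))
    expect_equal(dim(s$image), dim(s$label))
    bg <- s$label == 0L
    expect_true(all(s$image[bg] >= 255 - 3 * cfg$noise_sd - 1))
  }
  # class 1 is canonically the darker body than class 2
  for (s in ds[1:4]) {
    expect_lt(mean(s$image[s$label == 1L]), mean(s$image[s$label == 2L]))
  }
  # background dominates by construction
  expect_gt(h[["class0"]] / sum(h), 0.5)
  # bit-identical regeneration under the same seed
  ds2 <- generate_dataset(12, cfg)
  expect_identical(lapply(ds, `[[`, "image"), lapply(ds2, `[[`, "image"))
  expect_identical(lapply(ds, `[[`, "label"), lapply(ds2, `[[`, "label"))
})

test_that("dataset generation at native resolution matches the 94x93 frame", {
  ds <- generate_dataset(3, synthetic_config(seed = 5L))
  expect_equal(dim(ds[[1]]$image), c(94, 93))
  expect_equal(sum(attr(ds, "class_histogram")), 3 * 94 * 93)
  td <- tidy(ds)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td[1, -1]), 94 * 93)
})
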