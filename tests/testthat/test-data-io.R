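test_that("HDF5 round-trip is bit-exact in both layouts", {
  ds <- generate_dataset(5, tiny_synth_config(seed = 11L))
  for (layout in c("stacked", "named")) {
    path <- tempfile(fileext = ".h5")
    write_h5_dataset(ds, path, layout = layout)
    back <- load_h5_dataset(path)
    expect_length(back, 5)
    for (i in 1:5) {
      expect_identical(back[[i]]$image, ds[[i]]$image)
      expect_identical(back[[i]]$label, ds[[i]]$label)
    }
    unlink(path)
  }
  expect_error(load_h5_dataset(tempfile(fileext = ".h5")), "not found")
})

test_that("HDF5 loader rejects invalid label alphabets", {
  ds <- generate_dataset(2, tiny_synth_config(seed = 12L))
  ds[[1]]$label[1, 1] <- 7L
  path <- tempfile(fileext = ".h5")
  write_h5_dataset(ds, path)
  expect_error(load_h5_dataset(path), "outside", class = "chromseg_format_error")
  unlink(path)
})

test_that("pad_and_normalize centers content and preserves labels", {
  ds <- generate_dataset(1, synthetic_config(seed = 13L))  # 94 x 93
  mi <- pad_and_normalize(ds[[1]])
  expect_equal(dim(mi$image), c(128, 128))
  expect_equal(mi$image[1, 1], 1)         # padded corner is white / 255
  expect_equal(mi$label[1, 1], 0L)
  expect_true(all(mi$image >= 0 & mi$image <= 1))
  # label multiset on the footprint is preserved
  expect_equal(sort(table(mi$label[mi$label > 0])),
               sort(table(ds[[1]]$label[ds[[1]]$label > 0])))
  # inverse crop recovers the original to numerical precision
  back <- crop_model_input(mi)
  expect_equal(back$image, ds[[1]]$image, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$label, ds[[1]]$label)
  # no-op padding and normalization end-members
  full <- structure(list(image = matrix(255, 128, 128),
                         label = matrix(0L, 128, 128)), class = "labeled_sample")
  expect_true(all(pad_and_normalize(full)$image == 1))
  big <- structure(list(image = matrix(0, 130, 130), label = matrix(0L, 130, 130)),
                   class = "labeled_sample")
  expect_error(pad_and_normalize(big), "larger")
})

test_that("the train/test split is a pure seeded partition", {
  sp <- split_dataset(10, 0.8, seed = 123L)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(split_dataset(10, 0.8, 123L), sp)
  expect_false(identical(split_dataset(10, 0.8, 7L)$train, sp$train))
  # the published dataset arithmetic: floor(0.8 * 13434)
  big <- split_dataset(13434, 0.8, seed = 123L)
  expect_length(big$train, 10747)
  expect_length(big$test, 2687)
  td <- tidy(sp)
  expect_equal(nrow(td), 10)
})

test_that("overlap filter keeps exactly the class-3-bearing samples", {
  cfg <- tiny_synth_config(overlap_guarantee = FALSE, seed = 14L)
  ds <- generate_dataset(30, cfg)
  kept <- filter_test_overlap(ds)
  has3 <- vapply(ds, function(s) any(s$label == 3L), logical(1))
  expect_length(kept, sum(has3))
  # boundary case: exactly one overlap pixel
  one <- ds[[1]]
  one$label[] <- 0L
  one$label[5, 5] <- 3L
  expect_length(filter_test_overlap(list(one)), 1)
  expect_length(filter_test_overlap(list()), 0)
})

test_that("PNG pairs round-trip image and palette labels", {
  ds <- generate_dataset(1, tiny_synth_config(seed = 15L))
  ip <- tempfile(fileext = ".png"); lp <- tempfile(fileext = ".png")
  write_png_pair(ds[[1]], ip, lp)
  back <- read_png_pair(ip, lp)
  expect_identical(back$label, ds[[1]]$label)
  expect_identical(back$image, ds[[1]]$image)
  unlink(c(ip, lp))
})
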