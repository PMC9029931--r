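test_that("confusion tensor counts exactly", {
  truth <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 1L, 1L, 1L)
  P <- confusion_tensor(pred, truth, num_classes = 2L)
  expect_equal(unclass(P)[, ], matrix(c(1L, 0L, 1L, 2L), 2, 2), ignore_attr = TRUE)
  # identical maps are purely diagonal, counts conserve pixels
  set.seed(3)
  m <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  P2 <- confusion_tensor(m, m)
  expect_equal(sum(P2), 100L)
  expect_equal(sum(diag(P2)), 100L)
  expect_error(confusion_tensor(c(0L, 4L), c(0L, 0L)), "outside")
})

test_that("scalar metrics satisfy the defining arithmetic", {
  # TP=9, FN=1, FP=0 for class 1 of a 2-class problem (rows = true class)
  P <- matrix(c(5L, 0L, 1L, 9L), 2, 2, byrow = TRUE)
  class(P) <- c("confusion_tensor", class(P))
  r <- scalar_metrics(P, average_classes = 1)
  pc <- r$per_class[r$per_class$class == 1, ]
  expect_equal(pc$recall, 0.9)
  expect_equal(pc$fnr, 0.1)
  expect_equal(pc$precision, 1)
  # perfect prediction
  Pp <- confusion_tensor(rep(0:3, 5), rep(0:3, 5))
  rp <- scalar_metrics(Pp)
  expect_equal(rp$accuracy, 1)
  expect_equal(unname(rp$averages[c("dice", "iou", "precision", "recall")]),
               rep(1, 4))
  expect_equal(unname(rp$averages[c("fnr", "fpr")]), c(0, 0))
})

test_that("metric identities hold on random confusion tensors", {
  set.seed(17)
  for (i in 1:200) {
    P <- matrix(rpois(16, lambda = sample(c(1, 20, 300), 1)), 4, 4)
    if (sum(P) == 0) P[1, 1] <- 1
    class(P) <- c("confusion_tensor", class(P))
    r <- scalar_metrics(P, average_classes = 0:3)
    pc <- r$per_class
    ok <- !is.na(pc$iou)
    expect_equal(pc$dice[ok], 2 * pc$iou[ok] / (1 + pc$iou[ok]), tolerance = 1e-12)
    ok2 <- (pc$tp + pc$fn) > 0
    expect_equal(pc$recall[ok2] + pc$fnr[ok2], rep(1, sum(ok2)), tolerance = 1e-12)
    expect_equal(r$accuracy, sum(diag(unclass(P))) / sum(P), tolerance = 1e-15)
  }
})

test_that("hausdorff distance matches brute force and known geometry", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(hausdorff_distance(a, b), 5)              # 3-4-5 triangle
  expect_equal(hausdorff_distance(a, a), 0)
  # identical nonempty, symmetric, triangle inequality on random masks
  set.seed(23)
  masks <- replicate(9, matrix(runif(16 * 16) < 0.2, 16, 16), simplify = FALSE)
  masks <- purrr::keep(masks, ~ any(.x))
  for (i in 1:(length(masks) - 1)) {
    m1 <- masks[[i]]; m2 <- masks[[i + 1]]
    expect_equal(hausdorff_distance(m1, m2), brute_hausdorff(m1, m2), tolerance = 1e-12)
    expect_equal(hausdorff_distance(m1, m2), hausdorff_distance(m2, m1))
  }
  d12 <- hausdorff_distance(masks[[1]], masks[[2]])
  d23 <- hausdorff_distance(masks[[2]], masks[[3]])
  d13 <- hausdorff_distance(masks[[1]], masks[[3]])
  expect_lte(d13, d12 + d23 + 1e-12)
  # empty-set conventions
  z <- matrix(0, 8, 8)
  expect_equal(hausdorff_distance(z, z), 0)
  expect_equal(hausdorff_distance(a, z), sqrt(128))
})

test_that("evaluate_image aggregates per-class metrics coherently", {
  set.seed(31)
  truth <- matrix(sample(0:3, 400, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)), 20, 20)
  pred <- truth
  flip <- sample(400, 40)
  pred[flip] <- sample(0:3, 40, replace = TRUE)
  row <- evaluate_image(pred, truth)
  # independent recount from raw pixels
  ct <- confusion_tensor(pred, truth)
  ref <- scalar_metrics(ct)
  expect_equal(row$acc, ref$accuracy)
  expect_equal(row$dice, unname(ref$averages["dice"]))
  # relabeling symmetry: swapping classes 1 and 2 in both maps is invariant
  swp <- function(m) { m2 <- m; m2[m == 1L] <- 2L; m2[m == 2L] <- 1L; m2 }
  row2 <- evaluate_image(swp(pred), swp(truth))
  expect_equal(row2$dice, row$dice, tolerance = 1e-12)
  expect_equal(row2$hausdorff, row$hausdorff, tolerance = 1e-12)
  # perfect prediction end-member
  rp <- evaluate_image(truth, truth)
  expect_equal(rp$dice, 1)
  expect_equal(rp$hausdorff, 0)
})

test_that("confusion reports tidy into percentage and long forms", {
  P <- confusion_tensor(rep(0:3, times = c(5, 3, 1, 1)), rep(0:3, times = c(4, 4, 1, 1)))
  pct <- confusion_percent(P)
  expect_true(all(abs(rowSums(pct)[rowSums(unclass(P)) > 0] - 100) < 1e-9))
  td <- tidy(P)
  expect_equal(sum(td$pixels), sum(P))
  rep_ <- scalar_metrics(P)
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_equal(glance(rep_)$accuracy, rep_$accuracy)
})
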