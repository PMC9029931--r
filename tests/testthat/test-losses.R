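test_that("lovasz_grad matches the hand-evaluated cumulative formula", {
  expect_equal(lovasz_grad(1), 1)
  expect_equal(lovasz_grad(c(1, 0)), c(1, 0))
  expect_equal(lovasz_grad(c(0, 1)), c(0.5, 0.5))
  # generic properties on random binary vectors
  set.seed(42)
  for (i in 1:25) {
    gt <- sample(0:1, sample(1:12, 1), replace = TRUE)
    g <- lovasz_grad(gt)
    expect_true(all(g >= -1e-12))
    # weights telescope to the final cumulative Jaccard loss, which is 1
    # for any non-empty vector (the running intersection is exhausted)
    expect_equal(sum(g), 1, tolerance = 1e-12)
  }
  expect_error(lovasz_grad(numeric(0)), "non-empty")
  expect_error(lovasz_grad(c(0, 2)), "binary")
})

test_that("lovasz_softmax hits its closed-form endpoints", {
  y <- c(0L, 1L, 2L, 3L, 1L, 2L)
  perfect <- matrix(0, 6, 4)
  perfect[cbind(1:6, y + 1L)] <- 1
  expect_equal(lovasz_softmax(perfect, y), 0)
  # everywhere wrong one-hot: each present class has Jaccard 0 -> loss 1
  wrong <- perfect[, c(2, 3, 4, 1)]
  expect_equal(lovasz_softmax(wrong, y), 1)
})

test_that("lovasz_softmax equals 1 - Jaccard on hard predictions", {
  # spot sample of the hypercube (the exhaustive sweep runs in acceptance)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    gt <- sample(0:1, n, replace = TRUE)
    pr <- sample(0:1, n, replace = TRUE)
    probs <- cbind(1 - pr, pr)
    loss <- lovasz_softmax(probs, gt, class_policy = "all", per_class = TRUE)
    expect_equal(unname(loss["class1"]), brute_jaccard_loss(gt, pr),
                 tolerance = 1e-12)
  }
})

test_that("lovasz_softmax is monotone as correct-class probability rises", {
  set.seed(11)
  y <- sample(0:3, 40, replace = TRUE)
  p <- rand_probs(40, 4)
  base <- lovasz_softmax(p, y)
  # push 0.2 of mass from wrong classes onto the correct class, renormalized
  p2 <- p
  for (i in seq_len(40)) {
    ci <- y[i] + 1
    others <- setdiff(1:4, ci)
    take <- 0.2 * p2[i, others]
    p2[i, others] <- p2[i, others] - take
    p2[i, ci] <- p2[i, ci] + sum(take)
  }
  expect_lte(lovasz_softmax(p2, y), base + 1e-12)
})

test_that("least-squares adversarial losses match their closed forms", {
  expect_equal(lsgan_d_loss(1, 0), 0)
  expect_equal(lsgan_d_loss(0.5, 0.5), 0.5)
  expect_equal(lsgan_d_loss(c(1, 0.5), c(0.5, 0)), 0.25)
  expect_equal(lsgan_g_loss(1), 0)
  expect_equal(lsgan_g_loss(0), 1)
  expect_equal(lsgan_g_loss(0.5), 0.25)
  # nonnegative, zero exactly at target
  set.seed(5)
  d <- runif(20)
  expect_gte(lsgan_d_loss(d, d), 0)
  expect_gt(lsgan_g_loss(runif(10, 0, 0.99)), 0)
})

test_that("combined objective weights the segmentation term by lambda", {
  expect_equal(generator_objective(0, 0, lambda = 10), 0)
  expect_equal(generator_objective(0.25, 0.1, lambda = 10), 1.25)
  expect_equal(generator_objective(0.3, 0.7, lambda = 0), 0.3)
  expect_error(generator_objective(Inf, 0), "finite")
})

test_that("ablation losses agree with closed forms and degenerate weights", {
  y <- c(0L, 1L, 2L, 3L)
  perfect <- diag(4)
  for (kind in c("ce", "weighted_ce", "dice", "weighted_dice")) {
    expect_equal(ablation_seg_loss(perfect, y, kind), 0, tolerance = 1e-9)
  }
  uniform <- matrix(0.25, 4, 4)
  expect_equal(ablation_seg_loss(uniform, y, "ce"), log(4), tolerance = 1e-12)
  # equal class frequencies: weighted == unweighted
  set.seed(9)
  y2 <- rep(0:3, each = 25)
  p2 <- rand_probs(100, 4)
  expect_equal(ablation_seg_loss(p2, y2, "weighted_ce"),
               ablation_seg_loss(p2, y2, "ce"), tolerance = 1e-12)
  expect_equal(ablation_seg_loss(p2, y2, "weighted_dice"),
               ablation_seg_loss(p2, y2, "dice"), tolerance = 1e-12)
  expect_error(ablation_seg_loss(p2, y2, "huber"))
})

test_that("every segmentation loss gradient matches finite differences", {
  set.seed(21)
  p <- rand_probs(30, 4)
  y <- sample(0:3, 30, replace = TRUE)
  for (kind in c("lovasz", "ce", "weighted_ce", "dice", "weighted_dice")) {
    vg <- ns$seg_loss_value_grad(p, y, kind)
    idx <- sample(length(p), 12)
    num <- fd_grad(function(pp) ns$seg_loss_value_grad(pp, y, kind, want_grad = FALSE)$value,
                   p, idx)
    expect_equal(vg$grad[idx], num, tolerance = 1e-5, label = kind)
  }
})
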