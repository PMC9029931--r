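# Segmentation and adversarial losses. Every segmentation loss exposes both
# a value and an analytic gradient with respect to the per-pixel class
# probabilities, since training backpropagates through the softmax head.

#' Gradient of the Lovasz extension of the Jaccard loss
#'
#' Given a binary ground-truth vector already sorted by decreasing prediction
#' error, returns the vector of weights that the Lovasz extension assigns to
#' the sorted errors. With `S = sum(gt_sorted)`,
#' `intersection_k = S - cumsum(gt_sorted)_k` and
#' `union_k = S + cumsum(1 - gt_sorted)_k`, the cumulative Jaccard losses are
#' `j_k = 1 - intersection_k / union_k` and the weights are their first
#' differences.
#'
#' @param gt_sorted Binary (0/1) vector, length >= 1.
#' @return Nonnegative weight vector summing to the final cumulative Jaccard
#'   loss.
#' @export
lovasz_grad <- function(gt_sorted) {
  if (length(gt_sorted) == 0) abort("`gt_sorted` must be non-empty")
  if (!all(gt_sorted %in% c(0, 1))) abort("`gt_sorted` must be binary")
  S <- sum(gt_sorted)
  intersection <- S - cumsum(gt_sorted)
  union <- S + cumsum(1 - gt_sorted)
  jacc <- 1 - intersection / union
  if (length(jacc) > 1) c(jacc[1], diff(jacc)) else jacc
}

# Flatten probs (H,W,C,B) or (N,C) + labels into a plain (N, C) matrix + vec.
flatten_loss_inputs <- function(probs, labels) {
  if (is.matrix(probs)) {
    list(p = probs, y = as.integer(labels))
  } else {
    d <- dim(probs)
    stopifnot(length(d) == 4)
    p <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = d[3])
    list(p = p, y = as.integer(labels))
  }
}

loss_classes <- function(y, C, class_policy) {
  if (identical(class_policy, "all")) 0:(C - 1) else sort(unique(y))
}

#' Lovasz-Softmax segmentation loss
#'
#' Jaccard surrogate loss for multiclass segmentation. For each class `c`,
#' pixel errors are `m_i = 1 - p_i(c)` where the ground truth is `c` and
#' `p_i(c)` elsewhere; errors are sorted in decreasing order and weighted by
#' [lovasz_grad()] of the equally-sorted ground-truth indicator. The loss is
#' the mean over the evaluated classes and lies in `[0, 1]`; on hard (0/1)
#' predictions it equals `1 - Jaccard` exactly.
#'
#' @param probs Per-pixel class probabilities: `(H, W, C, B)` array or
#'   `(N, C)` matrix, rows summing to 1.
#' @param labels Integer ground-truth classes in `0..C-1`, same pixel count.
#' @param class_policy `"present"` (default) averages over classes present in
#'   the ground truth; `"all"` over all `C` classes.
#' @param per_class Return the per-class losses instead of their mean?
#' @return Scalar loss (or named per-class vector).
#' @export
lovasz_softmax <- function(probs, labels, class_policy = c("present", "all"),
                           per_class = FALSE) {
  class_policy <- match.arg(class_policy)
  fl <- flatten_loss_inputs(probs, labels)
  C <- ncol(fl$p)
  cls <- loss_classes(fl$y, C, class_policy)
  if (length(cls) == 0) {
    warn("no class qualifies under the class policy; loss defined as 0")
    return(0)
  }
  losses <- vapply(cls, function(cc) {
    fg <- as.numeric(fl$y == cc)
    p <- fl$p[, cc + 1]
    m <- fg + p - 2 * fg * p   # 1 - p on the class, p off it
    ord <- order(m, decreasing = TRUE)
    sum(m[ord] * lovasz_grad(fg[ord]))
  }, numeric(1))
  names(losses) <- paste0("class", cls)
  if (per_class) losses else mean(losses)
}

# Gradient of lovasz_softmax w.r.t. probs, same shape as probs.
lovasz_softmax_grad <- function(probs, labels, class_policy = "present") {
  fl <- flatten_loss_inputs(probs, labels)
  C <- ncol(fl$p)
  cls <- loss_classes(fl$y, C, class_policy)
  g <- matrix(0, nrow(fl$p), C)
  if (length(cls) > 0) {
    for (cc in cls) {
      fg <- as.numeric(fl$y == cc)
      p <- fl$p[, cc + 1]
      m <- fg + p - 2 * fg * p
      ord <- order(m, decreasing = TRUE)
      w <- numeric(length(m))
      w[ord] <- lovasz_grad(fg[ord])
      # dm/dp = -1 on the true class pixels, +1 elsewhere
      g[, cc + 1] <- g[, cc + 1] + (1 - 2 * fg) * w / length(cls)
    }
  }
  reshape_grad_like(g, probs)
}

reshape_grad_like <- function(g, probs) {
  if (is.matrix(probs)) return(g)
  d <- dim(probs)
  aperm(array(g, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Least-squares GAN losses
#'
#' The discriminator loss drives real-pair scores toward 1 and generated-pair
#' scores toward 0: `mean((d_real - 1)^2) + mean(d_fake^2)`. The generator
#' adversarial term drives generated-pair scores toward 1:
#' `mean((d_fake - 1)^2)`. Expectations are means over batch and patch
#' positions.
#'
#' @param d_real,d_fake Discriminator outputs in `[0, 1]` (any shape).
#' @return Scalar loss.
#' @export
lsgan_d_loss <- function(d_real, d_fake) {
  mean((d_real - 1)^2) + mean(d_fake^2)
}

#' @rdname lsgan_d_loss
#' @export
lsgan_g_loss <- function(d_fake) {
  mean((d_fake - 1)^2)
}

#' Combined generator objective
#'
#' `adv_term + lambda * seg_term`: the least-squares adversarial term plus
#' the weighted segmentation loss (weight `lambda`, default 10).
#'
#' @param adv_term,seg_term Finite scalars.
#' @param lambda Positive weight on the segmentation loss.
#' @return Scalar objective.
#' @export
generator_objective <- function(adv_term, seg_term, lambda = 10) {
  if (!is.finite(adv_term) || !is.finite(seg_term)) {
    abort("objective terms must be finite")
  }
  if (lambda < 0) abort("`lambda` must be >= 0")
  adv_term + lambda * seg_term
}

# Inverse-frequency class weights from a label vector, clipped to [0.1, 10].
inv_freq_weights <- function(y, cls) {
  n <- vapply(cls, function(cc) sum(y == cc), numeric(1))
  w <- (length(y) / (length(cls) * pmax(n, 1)))
  pmin(pmax(w, 0.1), 10)
}

#' Ablation segmentation losses
#'
#' The alternative segmentation objectives used to benchmark the Lovasz
#' surrogate: multiclass cross-entropy, inverse-frequency-weighted
#' cross-entropy, soft Dice loss (one minus the mean per-class soft Dice),
#' and its inverse-frequency-weighted version. Class weights are computed per
#' batch and clipped to `[0.1, 10]`; Dice-family losses average over classes
#' present in the ground truth.
#'
#' @inheritParams lovasz_softmax
#' @param kind One of `"ce"`, `"weighted_ce"`, `"dice"`, `"weighted_dice"`.
#' @return Scalar loss (0 for a perfect one-hot prediction).
#' @export
ablation_seg_loss <- function(probs, labels,
                              kind = c("ce", "weighted_ce", "dice", "weighted_dice")) {
  kind <- match.arg(kind)
  seg_loss_value_grad(probs, labels, kind, want_grad = FALSE)$value
}

EPS_P <- 1e-12

# Shared value+gradient evaluator for every segmentation loss, addressable by
# name; the training loop draws from this registry. The Lovasz surrogate is
# applied per image and averaged (the standard form: each image gets its own
# sorted error surrogate) when `per_image` is set and probs is a batch.
seg_loss_value_grad <- function(probs, labels, kind, want_grad = TRUE,
                                class_policy = "present", per_image = TRUE) {
  if (kind == "lovasz") {
    if (per_image && !is.matrix(probs) && dim(probs)[4] > 1) {
      B <- dim(probs)[4]
      vals <- numeric(B)
      grad <- if (want_grad) array(0, dim = dim(probs)) else NULL
      for (b in seq_len(B)) {
        pb <- probs[, , , b, drop = FALSE]
        yb <- labels[, , b]
        vals[b] <- lovasz_softmax(pb, yb, class_policy)
        if (want_grad) {
          grad[, , , b] <- lovasz_softmax_grad(pb, yb, class_policy) / B
        }
      }
      return(list(value = mean(vals), grad = grad))
    }
    val <- lovasz_softmax(probs, labels, class_policy)
    grad <- if (want_grad) lovasz_softmax_grad(probs, labels, class_policy) else NULL
    return(list(value = val, grad = grad))
  }
  fl <- flatten_loss_inputs(probs, labels)
  p <- fl$p; y <- fl$y
  C <- ncol(p); N <- nrow(p)
  g <- matrix(0, N, C)
  idx <- cbind(seq_len(N), y + 1L)
  if (kind %in% c("ce", "weighted_ce")) {
    w <- if (kind == "weighted_ce") {
      cls <- 0:(C - 1)
      wc <- inv_freq_weights(y, cls)
      wc[y + 1L]
    } else rep(1, N)
    py <- pmax(p[idx], EPS_P)
    val <- sum(w * (-log(py))) / sum(w)
    if (want_grad) g[idx] <- -w / (py * sum(w))
  } else {
    cls <- sort(unique(y))
    wc <- if (kind == "weighted_dice") inv_freq_weights(y, cls) else rep(1, length(cls))
    wc <- wc / sum(wc)
    val <- 0
    for (k in seq_along(cls)) {
      cc <- cls[k]
      t <- as.numeric(y == cc)
      pc <- p[, cc + 1]
      num <- 2 * sum(pc * t)
      den <- sum(pc) + sum(t)
      val <- val + wc[k] * (1 - num / den)
      if (want_grad) {
        g[, cc + 1] <- g[, cc + 1] - wc[k] * (2 * t * den - num) / den^2
      }
    }
  }
  list(value = val, grad = if (want_grad) reshape_grad_like(g, probs) else NULL)
}

seg_loss_kinds <- function() c("lovasz", "ce", "weighted_ce", "dice", "weighted_dice")
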