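# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (brute force / closed form) and independent
# of the implementation paths they check.

ns <- asNamespace("chromseg")

tiny_synth_config <- function(seed = 123L, canvas = 64L, ...) {
  synthetic_config(canvas_height = canvas, canvas_width = canvas,
                   seed = seed, ...)
}

tiny_gen_config <- function(filters = c(4L, 8L, 16L, 32L, 64L)) {
  generator_config(filters = filters, in_channels = 1L, num_classes = 4L)
}

# Naive zero-padded direct convolution (any k, stride 1), the oracle for the
# GEMM-based kernels.
naive_conv3 <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  p <- (k - 1) / 2
  y <- array(0, dim = c(H, W, Cout, B))
  xp <- array(0, dim = c(H + 2 * p, W + 2 * p, Cin, B))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  for (bb in seq_len(B)) for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
      acc <- acc + xp[ki + seq_len(H) - 1, kj + seq_len(W) - 1, ci, bb] * w[ki, kj, ci, co]
    }
    y[, , co, bb] <- acc
  }
  y
}

# Brute-force Jaccard loss between binary vectors; 0 when both sets empty.
brute_jaccard_loss <- function(gt, pred) {
  inter <- sum(gt == 1 & pred == 1)
  union <- sum(gt == 1 | pred == 1)
  if (union == 0) 0 else 1 - inter / union
}

# O(n * m) Hausdorff oracle over coordinate sets.
brute_hausdorff <- function(mask_a, mask_b) {
  A <- which(mask_a != 0, arr.ind = TRUE)
  B <- which(mask_b != 0, arr.ind = TRUE)
  directed <- function(P, Q) {
    max(apply(P, 1, function(p) {
      min(sqrt((Q[, 1] - p[1])^2 + (Q[, 2] - p[2])^2))
    }))
  }
  max(directed(A, B), directed(B, A))
}

# Central-difference gradient of a scalar function at selected indices.
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

rand_probs <- function(n, C) {
  p <- matrix(runif(n * C), n, C)
  p / rowSums(p)
}
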