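#' Generator configuration
#'
#' Describes the nested U-shaped generator: five filter widths (one per
#' encoder depth), the input channel count, the number of output classes and
#' the channel bookkeeping mode used when deeper features are up-sampled into
#' a skip level.
#'
#' @param filters Integer vector of 5 strictly increasing channel widths,
#'   one per depth. Default `c(64, 128, 256, 512, 1024)`.
#' @param in_channels Number of image channels (1 for grayscale).
#' @param num_classes Number of segmentation classes (>= 2).
#' @param channel_mode `"upsample_preserve"` (default): plain bilinear 2x
#'   up-sampling keeps the deeper node's `f(i+1)` channels, so a block at
#'   depth `i`, skip index `j > 0` receives `f(i)*j + f(i+1)` channels.
#'   `"eq2_literal"`: the up-sampled tensor is first projected to `f(i)`
#'   channels by a trainable 1x1 convolution, so the block receives
#'   `f(i)*(j+1)` channels.
#' @return A `generator_config` list.
#' @export
generator_config <- function(filters = c(64L, 128L, 256L, 512L, 1024L),
                             in_channels = 1L, num_classes = 4L,
                             channel_mode = c("upsample_preserve", "eq2_literal")) {
  channel_mode <- match.arg(channel_mode)
  if (length(filters) != 5L) abort("`filters` must have exactly 5 entries")
  if (any(diff(filters) <= 0)) abort("`filters` must be strictly increasing")
  if (num_classes < 2L) abort("`num_classes` must be >= 2")
  structure(list(filters = as.integer(filters),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 channel_mode = channel_mode),
            class = "generator_config")
}

#' Node-level connectivity of the nested generator
#'
#' Enumerates the 15 nested convolution blocks `X(i, j)` with `i + j <= 4`.
#' Encoder nodes (`j = 0`) take one max-pooled input from `X(i-1, 0)` (the
#' source image for `X(0, 0)`); decoder nodes (`j > 0`) concatenate all
#' same-depth predecessors `X(i, 0..j-1)` with the up-sampled output of
#' `X(i+1, j-1)`. Input channel counts follow the configured `channel_mode`.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per node: `i`, `j`, `in_channels`,
#'   `mid_channels`, `out_channels` and a list-column `inputs` naming each
#'   source node and the resize operation applied to it.
#' @export
connectivity_table <- function(config = generator_config()) {
  f <- config$filters
  rows <- list()
  for (j in 0:4) {
    for (i in 0:(4 - j)) {
      if (j == 0) {
        ins <- if (i == 0) {
          list(list(src = "source", op = "none"))
        } else {
          list(list(src = sprintf("x%d_%d", i - 1, 0), op = "down"))
        }
        icn <- if (i == 0) config$in_channels else f[i]
      } else {
        ins <- c(
          lapply(0:(j - 1), function(k) list(src = sprintf("x%d_%d", i, k), op = "none")),
          list(list(src = sprintf("x%d_%d", i + 1, j - 1), op = "up"))
        )
        up_ch <- if (config$channel_mode == "upsample_preserve") f[i + 2] else f[i + 1]
        icn <- f[i + 1] * j + up_ch
      }
      rows[[length(rows) + 1]] <- tibble(
        node = sprintf("x%d_%d", i, j), i = i, j = j,
        in_channels = as.integer(icn),
        mid_channels = f[i + 1], out_channels = f[i + 1],
        inputs = list(ins)
      )
    }
  }
  bind_rows(rows)
}

# ---- network constructors ---------------------------------------------------

new_seg_network <- function(kind, config, params, meta = list()) {
  structure(list(kind = kind, config = config, params = params, meta = meta),
            class = "seg_network")
}

#' @export
print.seg_network <- function(x, ...) {
  cat(sprintf("<seg_network: %s>\n", x$kind))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Build the nested U-shaped generator
#'
#' Constructs the dense-skip encoder-decoder network: every nested block is
#' two Conv(3x3, pad 1, stride 1)-BatchNorm-ReLU stages, depths are connected
#' by 2x2 max-pooling on the way down and bilinear 2x up-sampling on the way
#' up, and the final node feeds a 1x1 convolution with a per-pixel softmax
#' head that emits class probabilities.
#'
#' @param config A [generator_config()].
#' @return A `seg_network` object.
#' @export
build_nested_generator <- function(config = generator_config()) {
  tab <- connectivity_table(config)
  params <- list()
  for (r in seq_len(nrow(tab))) {
    nd <- tab$node[r]
    params[[paste0(nd, ".c1")]] <- new_conv_params(3L, tab$in_channels[r], tab$mid_channels[r])
    params[[paste0(nd, ".c2")]] <- new_conv_params(3L, tab$mid_channels[r], tab$out_channels[r])
    if (config$channel_mode == "eq2_literal" && tab$j[r] > 0) {
      # 1x1 lateral projection bringing the up-sampled f(i+1) channels to f(i)
      f <- config$filters
      params[[paste0(nd, ".proj")]] <-
        new_conv_params(1L, f[tab$i[r] + 2], f[tab$i[r] + 1], bn = FALSE)
    }
  }
  params[["head"]] <- new_conv_params(1L, config$filters[1], config$num_classes, bn = FALSE)
  new_seg_network("nested_unet", config, params, meta = list(table = tab))
}

#' Build the plain U-shaped baseline generator
#'
#' Classic encoder-decoder with the same filter widths, one skip connection
#' per depth and the same softmax head; used for ablation comparisons against
#' the nested generator.
#'
#' @inheritParams build_nested_generator
#' @return A `seg_network` object.
#' @export
build_unet_baseline <- function(config = generator_config()) {
  f <- config$filters
  params <- list()
  for (i in 0:4) {
    cin <- if (i == 0) config$in_channels else f[i]
    params[[sprintf("enc%d.c1", i)]] <- new_conv_params(3L, cin, f[i + 1])
    params[[sprintf("enc%d.c2", i)]] <- new_conv_params(3L, f[i + 1], f[i + 1])
  }
  for (i in 3:0) {
    up_ch <- if (config$channel_mode == "upsample_preserve") f[i + 2] else f[i + 1]
    if (config$channel_mode == "eq2_literal") {
      params[[sprintf("dec%d.proj", i)]] <- new_conv_params(1L, f[i + 2], f[i + 1], bn = FALSE)
    }
    params[[sprintf("dec%d.c1", i)]] <- new_conv_params(3L, f[i + 1] + up_ch, f[i + 1])
    params[[sprintf("dec%d.c2", i)]] <- new_conv_params(3L, f[i + 1], f[i + 1])
  }
  params[["head"]] <- new_conv_params(1L, f[1], config$num_classes, bn = FALSE)
  new_seg_network("unet", config, params)
}

#' Count trainable parameters of a network
#'
#' Sums every trainable scalar: convolution weights and biases plus
#' batch-norm scale and shift. Batch-norm running statistics are buffers,
#' not parameters, and are excluded.
#'
#' @param network A `seg_network`.
#' @return Integer-valued count (as a double, counts exceed `.Machine$integer.max / 50` routinely).
#' @export
count_parameters <- function(network) {
  total <- 0
  for (p in network$params) {
    for (nm in c("w", "b", "gamma", "beta")) {
      if (!is.null(p[[nm]])) total <- total + length(p[[nm]])
    }
  }
  total
}

# ---- forward / backward -----------------------------------------------------

# Two-stage nested block. Returns output plus caches; updates running BN
# statistics into `net$params` copies handed back via `updates`.
run_block <- function(x, net, name, training) {
  p1 <- net$params[[paste0(name, ".c1")]]
  p2 <- net$params[[paste0(name, ".c2")]]
  s1 <- conv_bn_relu_fwd(x, p1, training)
  s2 <- conv_bn_relu_fwd(s1$y, p2, training)
  upd <- NULL
  if (training) {
    upd <- list()
    upd[[paste0(name, ".c1")]] <- list(rmean = s1$rmean, rvar = s1$rvar)
    upd[[paste0(name, ".c2")]] <- list(rmean = s2$rmean, rvar = s2$rvar)
  }
  list(y = s2$y, cache = list(s1 = s1$cache, s2 = s2$cache), updates = upd)
}

block_bwd <- function(gy, net, name, cache) {
  b2 <- conv_bn_relu_bwd(gy, net$params[[paste0(name, ".c2")]], cache$s2)
  b1 <- conv_bn_relu_bwd(b2$gx, net$params[[paste0(name, ".c1")]], cache$s1)
  grads <- list()
  grads[[paste0(name, ".c1")]] <- b1$grads
  grads[[paste0(name, ".c2")]] <- b2$grads
  list(gx = b1$gx, grads = grads)
}

check_input_size <- function(x) {
  d <- dim(x)
  if (length(d) != 4) abort("expected a (H, W, C, B) array")
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    abort(sprintf("spatial size %dx%d must be divisible by 16", d[1], d[2]))
  }
}

#' Forward pass of a generator
#'
#' @param net A `seg_network` built by [build_nested_generator()] or
#'   [build_unet_baseline()].
#' @param x Input array `(H, W, in_channels, B)`, values in `[0, 1]`,
#'   spatial size divisible by 16.
#' @param training Use batch statistics (and record caches for backward)?
#' @return List with `probs` (per-pixel class probabilities, channel sums 1)
#'   and, when `training = TRUE`, internal caches consumed by the training
#'   loop.
#' @export
generator_forward <- function(net, x, training = FALSE) {
  check_input_size(x)
  if (dim(x)[3] != net$config$in_channels) {
    abort(sprintf("input has %d channels, generator expects %d",
                  dim(x)[3], net$config$in_channels))
  }
  if (net$kind == "nested_unet") nested_forward(net, x, training)
  else unet_forward(net, x, training)
}

nested_forward <- function(net, x, training) {
  cfg <- net$config
  out <- list()       # node outputs
  caches <- list()
  pools <- list()     # maxpool argmax caches, keyed by target node
  updates <- list()
  literal <- cfg$channel_mode == "eq2_literal"

  for (j in 0:4) {
    for (i in 0:(4 - j)) {
      nd <- sprintf("x%d_%d", i, j)
      if (j == 0) {
        if (i == 0) {
          xin <- x
        } else {
          mp <- maxpool2_fwd(out[[sprintf("x%d_%d", i - 1, 0)]])
          pools[[nd]] <- mp$idx
          xin <- mp$y
        }
        parts_dims <- NULL
      } else {
        same <- lapply(0:(j - 1), function(k) out[[sprintf("x%d_%d", i, k)]])
        deep <- upsample2_fwd(out[[sprintf("x%d_%d", i + 1, j - 1)]])
        if (literal) {
          pp <- net$params[[paste0(nd, ".proj")]]
          caches[[paste0(nd, ".projx")]] <- deep
          deep <- conv2d_fwd(deep, pp$w, pp$b, 1L, 0L)
        }
        parts <- c(same, list(deep))
        parts_dims <- vapply(parts, function(p) dim(p)[3], integer(1))
        xin <- concat_channels(parts)
      }
      blk <- run_block(xin, net, nd, training)
      out[[nd]] <- blk$y
      if (training) {
        caches[[nd]] <- blk$cache
        caches[[paste0(nd, ".splits")]] <- parts_dims
        updates <- c(updates, blk$updates)
      }
    }
  }
  hp <- net$params[["head"]]
  logits <- conv2d_fwd(out[["x0_4"]], hp$w, hp$b, 1L, 0L)
  probs <- channel_softmax(logits)
  res <- list(probs = probs)
  if (training) {
    caches$head_in <- out[["x0_4"]]
    res$cache <- list(node_out = out, caches = caches, pools = pools, x = x)
    res$bn_updates <- updates
  }
  res
}

# Backward through the nested generator given the gradient w.r.t. the
# pre-softmax logits. Returns flat grads keyed like net$params.
nested_backward <- function(net, glogits, cache) {
  cfg <- net$config
  literal <- cfg$channel_mode == "eq2_literal"
  hp <- net$params[["head"]]
  hb <- conv2d_bwd(cache$caches$head_in, hp$w, glogits, 1L, 0L)
  grads <- list(head = list(w = hb$gw, b = hb$gb))
  gout <- list(x0_4 = hb$gx)  # accumulated gradient on each node output

  add_g <- function(acc, nm, g) {
    if (is.null(acc[[nm]])) acc[[nm]] <- g else acc[[nm]] <- acc[[nm]] + g
    acc
  }

  for (j in 4:0) {
    for (i in (4 - j):0) {
      nd <- sprintf("x%d_%d", i, j)
      g <- gout[[nd]]
      if (is.null(g)) next
      bb <- block_bwd(g, net, nd, cache$caches[[nd]])
      grads <- c(grads, bb$grads)
      gin <- bb$gx
      if (j == 0) {
        if (i > 0) {
          src <- sprintf("x%d_%d", i - 1, 0)
          gsrc <- maxpool2_bwd(cache$pools[[nd]], gin,
                               dim(cache$node_out[[src]]))
          gout <- add_g(gout, src, gsrc)
        }
      } else {
        sizes <- cache$caches[[paste0(nd, ".splits")]]
        pieces <- split_channels(gin, sizes)
        for (k in 0:(j - 1)) {
          gout <- add_g(gout, sprintf("x%d_%d", i, k), pieces[[k + 1]])
        }
        gdeep <- pieces[[j + 1]]
        src <- sprintf("x%d_%d", i + 1, j - 1)
        if (literal) {
          pp <- net$params[[paste0(nd, ".proj")]]
          pb <- conv2d_bwd(cache$caches[[paste0(nd, ".projx")]], pp$w, gdeep, 1L, 0L)
          grads[[paste0(nd, ".proj")]] <- list(w = pb$gw, b = pb$gb)
          gdeep <- pb$gx
        }
        gsrc <- upsample2_bwd(gdeep, dim(cache$node_out[[src]]))
        gout <- add_g(gout, src, gsrc)
      }
    }
  }
  grads
}

unet_forward <- function(net, x, training) {
  cfg <- net$config
  literal <- cfg$channel_mode == "eq2_literal"
  out <- list(); caches <- list(); pools <- list(); updates <- list()
  xin <- x
  for (i in 0:4) {
    nd <- sprintf("enc%d", i)
    if (i > 0) {
      mp <- maxpool2_fwd(out[[sprintf("enc%d", i - 1)]])
      pools[[nd]] <- mp$idx
      xin <- mp$y
    }
    blk <- run_block(xin, net, nd, training)
    out[[nd]] <- blk$y
    if (training) { caches[[nd]] <- blk$cache; updates <- c(updates, blk$updates) }
  }
  prev <- out[["enc4"]]
  for (i in 3:0) {
    nd <- sprintf("dec%d", i)
    deep <- upsample2_fwd(prev)
    if (literal) {
      pp <- net$params[[paste0(nd, ".proj")]]
      caches[[paste0(nd, ".projx")]] <- deep
      deep <- conv2d_fwd(deep, pp$w, pp$b, 1L, 0L)
    }
    parts <- list(out[[sprintf("enc%d", i)]], deep)
    caches[[paste0(nd, ".splits")]] <- vapply(parts, function(p) dim(p)[3], integer(1))
    xin <- concat_channels(parts)
    blk <- run_block(xin, net, nd, training)
    out[[nd]] <- blk$y
    if (training) { caches[[nd]] <- blk$cache; updates <- c(updates, blk$updates) }
    prev <- out[[nd]]
  }
  hp <- net$params[["head"]]
  logits <- conv2d_fwd(prev, hp$w, hp$b, 1L, 0L)
  probs <- channel_softmax(logits)
  res <- list(probs = probs)
  if (training) {
    caches$head_in <- prev
    res$cache <- list(node_out = out, caches = caches, pools = pools, x = x)
    res$bn_updates <- updates
  }
  res
}

unet_backward <- function(net, glogits, cache) {
  literal <- net$config$channel_mode == "eq2_literal"
  hp <- net$params[["head"]]
  hb <- conv2d_bwd(cache$caches$head_in, hp$w, glogits, 1L, 0L)
  grads <- list(head = list(w = hb$gw, b = hb$gb))
  genc <- list()  # gradients pending on encoder outputs
  g <- hb$gx
  for (i in 0:3) {
    nd <- sprintf("dec%d", i)
    bb <- block_bwd(g, net, nd, cache$caches[[nd]])
    grads <- c(grads, bb$grads)
    pieces <- split_channels(bb$gx, cache$caches[[paste0(nd, ".splits")]])
    genc[[sprintf("enc%d", i)]] <- pieces[[1]]
    gdeep <- pieces[[2]]
    if (literal) {
      pp <- net$params[[paste0(nd, ".proj")]]
      pb <- conv2d_bwd(cache$caches[[paste0(nd, ".projx")]], pp$w, gdeep, 1L, 0L)
      grads[[paste0(nd, ".proj")]] <- list(w = pb$gw, b = pb$gb)
      gdeep <- pb$gx
    }
    src <- if (i == 3) "enc4" else sprintf("dec%d", i + 1)
    g <- upsample2_bwd(gdeep, dim(cache$node_out[[src]]))
  }
  # g now sits on enc4; walk the encoder back down
  for (i in 4:0) {
    nd <- sprintf("enc%d", i)
    gtot <- g
    if (!is.null(genc[[nd]])) gtot <- gtot + genc[[nd]]
    bb <- block_bwd(gtot, net, nd, cache$caches[[nd]])
    grads <- c(grads, bb$grads)
    if (i > 0) {
      src <- sprintf("enc%d", i - 1)
      g <- maxpool2_bwd(cache$pools[[nd]], bb$gx, dim(cache$node_out[[src]]))
    }
  }
  grads
}

generator_backward <- function(net, glogits, cache) {
  if (net$kind == "nested_unet") nested_backward(net, glogits, cache)
  else unet_backward(net, glogits, cache)
}

# Apply recorded running-stat updates onto a network's parameter list.
apply_bn_updates <- function(net, updates) {
  for (nm in names(updates)) {
    net$params[[nm]]$rmean <- updates[[nm]]$rmean
    net$params[[nm]]$rvar <- updates[[nm]]$rvar
  }
  net
}

# Flatten nested grads (one list per conv stage) into the shape Adam expects:
# a list parallel to net$params where each element has w/b(/gamma/beta).
merge_grads <- function(grads) {
  # duplicate names can appear if a node contributes twice; sum them
  out <- list()
  for (nm in names(grads)) {
    if (is.null(out[[nm]])) {
      out[[nm]] <- grads[[nm]]
    } else {
      for (f in names(grads[[nm]])) out[[nm]][[f]] <- out[[nm]][[f]] + grads[[nm]][[f]]
    }
  }
  out
}
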