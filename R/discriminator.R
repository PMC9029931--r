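# Patch-wise conditional discriminator: scores concatenated (source image,
# segmentation map) stacks with a fully convolutional 4x4 stack and a
# sigmoid, so each output unit judges one receptive-field patch.

#' Discriminator configuration
#'
#' @param in_channels Input channels: source channels + class count
#'   (1 + 4 = 5 by default).
#' @param widths Channel widths of the five 4x4 convolution layers.
#' @param leak Negative slope of the leaky rectifier.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(in_channels = 5L,
                                 widths = c(64L, 128L, 256L, 512L, 1024L),
                                 leak = 0.2) {
  if (length(widths) != 5L) abort("`widths` must have exactly 5 entries")
  structure(list(in_channels = as.integer(in_channels),
                 widths = as.integer(widths), leak = leak),
            class = "discriminator_config")
}

# Layer list: four stride-2 4x4 convs, one stride-1 4x4 conv, then a
# stride-1 4x4 projection to one channel; pad 2 throughout; leaky rectifier
# after every layer except the projection, sigmoid on the output.
disc_layer_table <- function(config) {
  w <- config$widths
  tibble(
    layer = 1:6,
    in_channels = c(config$in_channels, w[1:5]),
    out_channels = c(w, 1L),
    kernel = 4L,
    stride = c(2L, 2L, 2L, 2L, 1L, 1L),
    pad = 2L,
    activation = c(rep("leaky_relu", 5), "sigmoid")
  )
}

#' Build the patch critic
#'
#' @param config A [discriminator_config()].
#' @return A `seg_network` of kind `"patch_critic"`; its `meta$layers`
#'   tibble records the layer list (kernel, stride, padding, activation).
#' @export
build_discriminator <- function(config = discriminator_config()) {
  tab <- disc_layer_table(config)
  params <- list()
  for (r in seq_len(nrow(tab))) {
    params[[sprintf("d%d", r)]] <-
      new_conv_params(4L, tab$in_channels[r], tab$out_channels[r], bn = FALSE)
  }
  new_seg_network("patch_critic", config, params, meta = list(layers = tab))
}

#' Stack a source image with a segmentation map
#'
#' Channel concatenation with the source first: channel 1 is the source
#' image, channels 2..(C+1) the per-pixel class scores. Integer label maps
#' are one-hot encoded first; generator outputs are passed as soft
#' probabilities.
#'
#' @param source_image `(H, W, 1, B)` array (or `(H, W)` matrix for B = 1).
#' @param seg_map `(H, W, C, B)` probability array, or an integer label map
#'   `(H, W)` / `(H, W, B)`.
#' @param num_classes Class count used when one-hot encoding label maps.
#' @return `(H, W, 1 + C, B)` array.
#' @export
make_discriminator_input <- function(source_image, seg_map, num_classes = 4L) {
  if (is.matrix(source_image)) {
    source_image <- array(source_image, dim = c(dim(source_image), 1L, 1L))
  }
  if (length(dim(seg_map)) != 4) {
    seg_map <- one_hot_labels(seg_map, num_classes)
  }
  ds <- dim(source_image); dm <- dim(seg_map)
  if (!all(ds[c(1, 2, 4)] == dm[c(1, 2, 4)])) {
    abort(sprintf("source (%s) and map (%s) shapes do not align",
                  paste(ds, collapse = "x"), paste(dm, collapse = "x")))
  }
  concat_channels(list(source_image, seg_map))
}

# Forward through the critic. Returns sigmoid patch scores plus caches for
# backward.
discriminator_forward <- function(net, x, training = FALSE) {
  tab <- net$meta$layers
  leak <- net$config$leak
  caches <- list()
  h <- x
  for (r in seq_len(nrow(tab))) {
    prm <- net$params[[sprintf("d%d", r)]]
    z <- conv2d_fwd(h, prm$w, prm$b, tab$stride[r], tab$pad[r])
    if (tab$activation[r] == "leaky_relu") {
      if (training) caches[[r]] <- list(x = h, z = z)
      h <- leaky_fwd(z, leak)
    } else {
      if (training) caches[[r]] <- list(x = h, z = z)
      h <- 1 / (1 + exp(-z))
    }
  }
  out <- list(score = h)
  if (training) out$cache <- caches
  out
}

# Backward from gradient on the sigmoid scores; returns parameter grads and
# the gradient w.r.t. the input stack (used to reach the generator).
discriminator_backward <- function(net, gscore, score, cache) {
  tab <- net$meta$layers
  leak <- net$config$leak
  g <- gscore * score * (1 - score)   # through the sigmoid
  grads <- list()
  for (r in rev(seq_len(nrow(tab)))) {
    prm <- net$params[[sprintf("d%d", r)]]
    if (tab$activation[r] == "leaky_relu") {
      g <- leaky_bwd(cache[[r]]$z, leak, g)
    }
    cv <- conv2d_bwd(cache[[r]]$x, prm$w, g, tab$stride[r], tab$pad[r])
    grads[[sprintf("d%d", r)]] <- list(w = cv$gw, b = cv$gb)
    g <- cv$gx
  }
  list(grads = grads, gx = g)
}

#' Receptive field of one critic output unit
#'
#' Computed by the standard stride/kernel recursion over the built layer
#' stack: each output score judges a `K x K` input patch.
#'
#' @param net A patch critic from [build_discriminator()].
#' @return Patch size `K` in pixels.
#' @export
discriminator_receptive_field <- function(net) {
  tab <- net$meta$layers
  rf <- 1; jump <- 1
  for (r in seq_len(nrow(tab))) {
    rf <- rf + (tab$kernel[r] - 1) * jump
    jump <- jump * tab$stride[r]
  }
  rf
}

# Output spatial size for a given input size, from the stride arithmetic.
discriminator_output_size <- function(net, input_size) {
  tab <- net$meta$layers
  n <- input_size
  for (r in seq_len(nrow(tab))) {
    n <- floor((n + 2 * tab$pad[r] - tab$kernel[r]) / tab$stride[r]) + 1
  }
  n
}
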