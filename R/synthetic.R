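# Synthetic overlapping-chromosome image generator. Emulates the structure
# of the public overlapping-chromosome benchmark: two darker, bent, banded
# strips on a white (255) background, the overlap region darker still, with
# the 4-class label map 0 = background, 1/2 = the two exclusive chromosome
# bodies, 3 = overlap.

#' Synthetic dataset configuration
#'
#' All geometric ranges are in pixels on the configured canvas; intensity in
#' gray levels on `[0, 255]`. Defaults scale with the canvas so the two
#' strips occupy a realistic minority of the image and almost always cross.
#' The two strips of a pair are drawn with base intensities at least 25 gray
#' levels apart and class 1 is canonically the darker strip, so the 1-vs-2
#' assignment is locally identifiable from intensity (see the methods
#' vignette).
#'
#' @param canvas_height,canvas_width Canvas size in pixels (defaults 94 x 93,
#'   the native resolution of the public dataset).
#' @param strip_length_range,strip_width_range Length/width ranges (pixels).
#' @param curvature_range Dimensionless bend amplitude range; the centerline
#'   lateral offset is `curvature * length * ((2t - 1)^2 - 1/3)`.
#' @param band_count_range Integer range of transverse intensity bands.
#' @param intensity_range Base body intensity range (gray levels).
#' @param overlap_guarantee Require >= 1 overlap (class 3) pixel per sample?
#' @param noise_sd Additive Gaussian noise standard deviation (gray levels).
#' @param seed Integer seed making generation fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(canvas_height = 94L, canvas_width = 93L,
                             strip_length_range = NULL,
                             strip_width_range = NULL,
                             curvature_range = c(0, 0.25),
                             band_count_range = c(3L, 7L),
                             intensity_range = c(90, 200),
                             overlap_guarantee = TRUE,
                             noise_sd = 4,
                             seed = 123L) {
  s <- min(canvas_height, canvas_width)
  if (is.null(strip_length_range)) strip_length_range <- round(c(0.55, 0.85) * s)
  if (is.null(strip_width_range)) strip_width_range <- pmax(3, round(c(0.08, 0.13) * s))
  cfg <- list(canvas_height = as.integer(canvas_height),
              canvas_width = as.integer(canvas_width),
              strip_length_range = strip_length_range,
              strip_width_range = strip_width_range,
              curvature_range = curvature_range,
              band_count_range = band_count_range,
              intensity_range = intensity_range,
              overlap_guarantee = isTRUE(overlap_guarantee),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  for (nm in grep("_range$", names(cfg), value = TRUE)) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2]) abort(sprintf("`%s` must be a non-empty interval", nm))
  }
  if (any(cfg$intensity_range < 0) || any(cfg$intensity_range > 255)) {
    abort("`intensity_range` must lie within [0, 255]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Rasterize one bent, banded chromosome strip
#'
#' Sweeps a quadratic-bend centerline of the given length with constant
#' width, rotates it and places it on the canvas. The texture is the base
#' intensity modulated by transverse cosine bands.
#'
#' @param length,width Strip dimensions in pixels (>= 3).
#' @param curvature Dimensionless bend amplitude (0 = straight).
#' @param bands Number of transverse intensity bands.
#' @param intensity Base body gray level.
#' @param canvas `c(height, width)` of the target canvas.
#' @param center Strip center `c(row, col)`; random placement that fits when
#'   `NULL`.
#' @param angle Rotation in radians; random when `NULL`.
#' @param band_amplitude Band modulation depth in gray levels.
#' @param seed Optional seed for the random placement/phase.
#' @return List with `mask` (logical canvas matrix, a single 4-connected
#'   component) and `texture` (numeric canvas matrix, `NA` off-strip), plus
#'   the realized placement in `meta`.
#' @export
make_strip <- function(length, width, curvature = 0, bands = 4,
                       intensity = 128, canvas = c(94L, 93L),
                       center = NULL, angle = NULL,
                       band_amplitude = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length < 3 || width < 3) abort("strip `length` and `width` must be >= 3 pixels")
  H <- canvas[1]; W <- canvas[2]

  # centerline in strip coordinates: u along the strip, v = bend offset
  step <- 0.25
  t <- seq(0, 1, by = step / max(length - 1, 1))
  u <- t * (length - 1)
  v <- curvature * length * ((2 * t - 1)^2 - 1 / 3)
  # tangent -> unit normal for the constant-width sweep
  du <- c(diff(u), utils::tail(diff(u), 1))
  dv <- c(diff(v), utils::tail(diff(v), 1))
  nrm <- sqrt(du^2 + dv^2)
  nx <- -dv / nrm
  ny <- du / nrm

  offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = step)
  px <- outer(u, offs, function(uu, ss) uu) + outer(nx, offs)
  py <- outer(v, offs, function(vv, ss) vv) + outer(ny, offs)
  tt <- matrix(t, nrow = length(t), ncol = length(offs))

  # center the sheet at its own centroid before rotating/placing
  px <- px - mean(range(px)); py <- py - mean(range(py))
  ext_r <- max(abs(py)); ext_c <- max(abs(px)) # pre-rotation extents

  if (is.null(angle)) angle <- runif(1, 0, pi)
  ca <- cos(angle); sa <- sin(angle)
  rr <- py * ca - px * sa
  cc <- py * sa + px * ca

  half_h <- max(abs(rr)); half_w <- max(abs(cc))
  if (2 * half_h + 1 > H) {
    abort(sprintf("strip does not fit canvas: needs %.0f rows, canvas has %d",
                  2 * half_h + 1, H))
  }
  if (2 * half_w + 1 > W) {
    abort(sprintf("strip does not fit canvas: needs %.0f columns, canvas has %d",
                  2 * half_w + 1, W))
  }
  if (is.null(center)) {
    center <- c(runif(1, half_h + 1, H - half_h), runif(1, half_w + 1, W - half_w))
  }
  phase <- runif(1, 0, 2 * pi)

  ri <- floor(rr + center[1] + 0.5)
  ci <- floor(cc + center[2] + 0.5)
  keep <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  if (!all(keep)) {
    abort("strip does not fit canvas at the requested center")
  }
  mask <- matrix(FALSE, H, W)
  texture <- matrix(NA_real_, H, W)
  tex_vals <- intensity + band_amplitude * cos(2 * pi * bands * tt + phase)
  idx <- cbind(ri[keep], ci[keep])
  mask[idx] <- TRUE
  texture[idx] <- tex_vals[keep]
  list(mask = mask, texture = texture,
       meta = list(length = length, width = width, curvature = curvature,
                   bands = bands, intensity = intensity,
                   center = center, angle = angle))
}

#' Compose two strips into a labeled sample
#'
#' Labels: 0 outside both masks, 1 on the first strip only, 2 on the second
#' only, 3 on the intersection. The image is a white (255) background with
#' each strip's texture on its exclusive region; the overlap is rendered
#' darker than either body (`0.85 * pmin` of the two textures). Gaussian
#' noise of sd `noise_sd` is added and gray levels are clipped to
#' `[0, 255]` and rounded. When `order_by_intensity` is `TRUE` (default) the
#' darker strip is canonically assigned class 1.
#'
#' @param strip_a,strip_b Strips from [make_strip()] on the same canvas.
#' @param config A [synthetic_config()] (supplies `noise_sd` and
#'   `overlap_guarantee`).
#' @param order_by_intensity Relabel so class 1 is the darker strip?
#' @return A `labeled_sample`: list with integer `image` (gray levels),
#'   integer `label` (values 0-3) and `meta`.
#' @export
compose_pair <- function(strip_a, strip_b, config = synthetic_config(),
                         order_by_intensity = TRUE) {
  if (!all(dim(strip_a$mask) == dim(strip_b$mask))) {
    abort("strips must share a canvas")
  }
  if (order_by_intensity) {
    ia <- mean(strip_a$texture[strip_a$mask])
    ib <- mean(strip_b$texture[strip_b$mask])
    if (ia > ib) {
      tmp <- strip_a; strip_a <- strip_b; strip_b <- tmp
    }
  }
  ma <- strip_a$mask; mb <- strip_b$mask
  both <- ma & mb
  if (config$overlap_guarantee && !any(both)) {
    abort("overlap_guarantee is set but the strips do not intersect",
          class = "chromseg_generation_error")
  }
  label <- matrix(0L, nrow(ma), ncol(ma))
  label[ma & !mb] <- 1L
  label[mb & !ma] <- 2L
  label[both] <- 3L

  img <- matrix(255, nrow(ma), ncol(ma))
  img[ma & !mb] <- strip_a$texture[ma & !mb]
  img[mb & !ma] <- strip_b$texture[mb & !ma]
  img[both] <- 0.85 * pmin(strip_a$texture[both], strip_b$texture[both])
  if (config$noise_sd > 0) {
    # truncated at 3 sd so background pixels stay provably near white
    e <- rnorm(length(img), sd = config$noise_sd)
    img <- img + pmin(pmax(e, -3 * config$noise_sd), 3 * config$noise_sd)
  }
  img <- matrix(as.integer(pmin(pmax(floor(img + 0.5), 0), 255)),
                nrow(ma), ncol(ma))
  structure(list(image = img, label = label,
                 meta = list(strip_a = strip_a$meta, strip_b = strip_b$meta)),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf("<labeled_sample %dx%d> class pixels: %s\n",
              nrow(x$image), ncol(x$image),
              paste(tabulate(x$label + 1L, 4L), collapse = "/")))
  invisible(x)
}

draw_range <- function(r) if (r[1] == r[2]) r[1] else runif(1, r[1], r[2])
draw_int_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

# One strip with parameters drawn from the config, placed to fit the canvas.
draw_strip <- function(config, intensity) {
  make_strip(
    length = draw_int_range(round(config$strip_length_range)),
    width = draw_int_range(round(config$strip_width_range)),
    curvature = draw_range(config$curvature_range),
    bands = draw_int_range(round(config$band_count_range)),
    intensity = intensity,
    canvas = c(config$canvas_height, config$canvas_width)
  )
}

MAX_OVERLAP_RETRIES <- 50L
MIN_INTENSITY_GAP <- 25

#' Generate a synthetic labeled dataset
#'
#' Draws `n` image/label pairs under the configured geometry; with
#' `overlap_guarantee` the second strip is re-placed (up to 50 times) until
#' the pair intersects. Generation is a pure function of `config$seed`.
#'
#' @param n Number of samples (>= 1).
#' @param config A [synthetic_config()].
#' @return A `chromo_dataset`: list of `labeled_sample`s with a
#'   `class_histogram` attribute (total pixels per class over the dataset).
#' @export
generate_dataset <- function(n, config = synthetic_config()) {
  if (n < 1) abort("`n` must be >= 1")
  set.seed(config$seed)
  ir <- config$intensity_range
  samples <- vector("list", n)
  for (s in seq_len(n)) {
    i1 <- draw_range(ir)
    i2 <- draw_range(ir)
    for (tries in seq_len(MAX_OVERLAP_RETRIES)) {
      if (abs(i1 - i2) >= min(MIN_INTENSITY_GAP, diff(ir))) break
      i2 <- draw_range(ir)
    }
    a <- draw_strip(config, i1)
    smp <- NULL
    for (tries in seq_len(MAX_OVERLAP_RETRIES)) {
      b <- draw_strip(config, i2)
      if (!config$overlap_guarantee || any(a$mask & b$mask)) {
        smp <- compose_pair(a, b, config)
        break
      }
    }
    if (is.null(smp)) {
      abort(sprintf("no overlapping placement found for sample %d after %d retries",
                    s, MAX_OVERLAP_RETRIES),
            class = "chromseg_generation_error")
    }
    smp$meta$index <- s
    samples[[s]] <- smp
  }
  hist <- Reduce(`+`, lapply(samples, function(x) tabulate(x$label + 1L, 4L)))
  structure(samples, class = "chromo_dataset",
            class_histogram = setNames(hist, paste0("class", 0:3)),
            config = config)
}

#' @export
print.chromo_dataset <- function(x, ...) {
  h <- attr(x, "class_histogram")
  cat(sprintf("<chromo_dataset> %d samples; class pixels %s\n",
              length(x), paste(h, collapse = "/")))
  invisible(x)
}

#' @rdname generate_dataset
#' @param x A `chromo_dataset`.
#' @param ... Unused.
#' @return `tidy()`: one row per sample with per-class pixel counts.
#' @method tidy chromo_dataset
#' @export
tidy.chromo_dataset <- function(x, ...) {
  bind_rows(lapply(seq_along(x), function(i) {
    counts <- tabulate(x[[i]]$label + 1L, 4L)
    tibble(sample = i, class0 = counts[1], class1 = counts[2],
           class2 = counts[3], class3 = counts[4])
  }))
}

#' Plot a labeled sample
#'
#' Side-by-side raster of the grayscale image and the colorized label map
#' (black/red/green/blue for classes 0-3).
#'
#' @param object A `labeled_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot labeled_sample
#' @export
autoplot.labeled_sample <- function(object, ...) {
  img_df <- tidyr::expand_grid(row = seq_len(nrow(object$image)),
                               col = seq_len(ncol(object$image)))
  img_df$gray <- as.vector(object$image)
  img_df$class <- factor(as.vector(object$label), levels = 0:3)
  long <- bind_rows(
    mutate(img_df, panel = "image", fill = grDevices::gray(.data$gray / 255)),
    mutate(img_df, panel = "label",
           fill = c("black", "red", "green3", "blue")[as.integer(.data$class)])
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
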