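# Dataset input/output and preprocessing: HDF5 and PNG round-trips,
# pad-and-normalize, the seeded train/test split and the overlap-only test
# filter.

h5_bridge <- function() {
  system.file("python", "h5_bridge.py", package = "chromseg", mustWork = TRUE)
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("no `python` interpreter with h5py found on PATH (needed for HDF5 i/o)")
  p
}

# Flat uint8 shuttle layout shared with inst/python/h5_bridge.py:
# N*H*W image bytes then N*H*W label bytes, C order (sample, row, col).
samples_to_raw <- function(samples) {
  imgs <- lapply(samples, function(s) as.raw(t(s$image)))
  labs <- lapply(samples, function(s) as.raw(t(s$label)))
  c(do.call(c, imgs), do.call(c, labs))
}

raw_to_samples <- function(bytes, n, h, w) {
  per <- h * w
  vals <- as.integer(bytes)
  lapply(seq_len(n), function(i) {
    img <- matrix(vals[((i - 1) * per + 1):(i * per)], h, w, byrow = TRUE)
    lab <- matrix(vals[n * per + ((i - 1) * per + 1):(i * per)], h, w, byrow = TRUE)
    if (any(lab > 3)) {
      abort(sprintf("sample %d: label values outside {0,1,2,3}", i),
            class = "chromseg_format_error")
    }
    structure(list(image = img, label = lab, meta = list(index = i)),
              class = "labeled_sample")
  })
}

#' Write a labeled dataset to HDF5
#'
#' Two dialects are supported: `"stacked"` mirrors the public
#' overlapping-chromosome layout, a single `(N, H, W, 2)` uint8 array named
#' `dataset` with images in slot 1 and labels in slot 2; `"named"` writes
#' separate `images` and `labels` arrays.
#'
#' @param samples A `chromo_dataset` or list of `labeled_sample`s sharing one
#'   resolution.
#' @param path Output `.h5` path.
#' @param layout `"stacked"` (default) or `"named"`.
#' @return `path`, invisibly.
#' @export
write_h5_dataset <- function(samples, path, layout = c("stacked", "named")) {
  layout <- match.arg(layout)
  h <- nrow(samples[[1]]$image); w <- ncol(samples[[1]]$image)
  bin <- tempfile(fileext = ".bin")
  on.exit(unlink(bin), add = TRUE)
  writeBin(samples_to_raw(samples), bin)
  status <- system2(python_bin(),
                    c(h5_bridge(), "write", shQuote(path), shQuote(bin),
                      length(samples), h, w, layout),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    abort(paste("HDF5 write failed:", paste(status, collapse = "\n")))
  }
  invisible(path)
}

#' Load a labeled dataset from HDF5
#'
#' Auto-detects the layout: any 4-D array whose last axis has extent 2 is
#' read as stacked image/label pairs; otherwise a pair of equally shaped
#' arrays with recognizable names (`images`/`labels`, `image`/`label`, ...)
#' is used. Unrecognized files raise a format error listing every array name
#' and shape found; label values outside `{0, 1, 2, 3}` are rejected.
#'
#' @param path Path to the `.h5` file.
#' @return List of `labeled_sample`s at native resolution.
#' @export
load_h5_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  bin <- tempfile(fileext = ".bin")
  on.exit(unlink(bin), add = TRUE)
  err <- tempfile()
  on.exit(unlink(err), add = TRUE)
  out <- suppressWarnings(
    system2(python_bin(), c(h5_bridge(), "read", shQuote(path), shQuote(bin)),
            stdout = TRUE, stderr = err)
  )
  st <- attr(out, "status")
  if (!is.null(st) && st != 0) {
    abort(paste(c("unrecognized HDF5 layout:", readLines(err)), collapse = "\n"),
          class = "chromseg_format_error")
  }
  dims <- as.integer(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  n <- dims[1]; h <- dims[2]; w <- dims[3]
  bytes <- readBin(bin, "raw", n = 2 * n * h * w)
  raw_to_samples(bytes, n, h, w)
}

#' Pad and normalize one sample for the network
#'
#' Centers the image on a white (255) canvas of `size x size`, the label on
#' a zero canvas (odd margins split floor top/left, ceiling bottom/right),
#' then scales the image to `[0, 1]` by dividing by 255.
#'
#' @param sample A `labeled_sample`.
#' @param size Target square size (default 128); must be >= the sample and
#'   divisible by 16 for the networks.
#' @return A `model_input`: list with `image` (numeric in `[0, 1]`), `label`
#'   (integer) and the crop `offset` for inverse recovery.
#' @export
pad_and_normalize <- function(sample, size = 128L) {
  h <- nrow(sample$image); w <- ncol(sample$image)
  if (h > size || w > size) {
    abort(sprintf("sample is %dx%d, larger than the %d-pixel canvas", h, w, size))
  }
  top <- floor((size - h) / 2); left <- floor((size - w) / 2)
  img <- matrix(255, size, size)
  lab <- matrix(0L, size, size)
  img[top + seq_len(h), left + seq_len(w)] <- sample$image
  lab[top + seq_len(h), left + seq_len(w)] <- sample$label
  structure(list(image = img / 255, label = lab,
                 offset = c(top = top, left = left, height = h, width = w)),
            class = "model_input")
}

#' Undo the padding of a model input
#'
#' @param input A `model_input` from [pad_and_normalize()].
#' @return A `labeled_sample` with the original footprint (image back on the
#'   0-255 scale).
#' @export
crop_model_input <- function(input) {
  o <- input$offset
  rows <- o[["top"]] + seq_len(o[["height"]])
  cols <- o[["left"]] + seq_len(o[["width"]])
  structure(list(image = input$image[rows, cols] * 255,
                 label = input$label[rows, cols],
                 meta = list()),
            class = "labeled_sample")
}

#' Deterministic train/test split
#'
#' Shuffles `1:N` with the given seed and assigns the first
#' `floor(fraction_train * N)` indices to training. The split is a pure
#' function of `(N, seed, fraction_train)`.
#'
#' @param N Number of samples (>= 2).
#' @param fraction_train Training fraction (default 0.8).
#' @param seed Integer seed (default 123).
#' @return A `dataset_split` with `train` and `test` index vectors.
#' @export
split_dataset <- function(N, fraction_train = 0.8, seed = 123L) {
  if (N < 2) abort("`N` must be >= 2")
  set.seed(seed)
  perm <- sample.int(N)
  ntr <- floor(fraction_train * N)
  structure(list(train = sort(perm[seq_len(ntr)]),
                 test = sort(perm[setdiff(seq_len(N), seq_len(ntr))]),
                 seed = as.integer(seed), fraction_train = fraction_train),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Keep only samples containing an overlap region
#'
#' Retains exactly the samples whose label map contains at least one class-3
#' (overlap) pixel, the filter applied to evaluation sets so the overlap
#' class is always represented.
#'
#' @param samples List of `labeled_sample`s.
#' @return The filtered list (possibly empty).
#' @export
filter_test_overlap <- function(samples) {
  keep(samples, function(s) any(s$label == 3L))
}

CLASS_PALETTE <- c("#000000", "#FF0000", "#00CC00", "#0000FF")

#' Write a sample to paired PNG files
#'
#' Grayscale image plus a colorized label rendering (black/red/green/blue
#' for classes 0-3).
#'
#' @param sample A `labeled_sample`.
#' @param image_path,label_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_png_pair <- function(sample, image_path, label_path) {
  png::writePNG(sample$image / 255, image_path)
  cols <- grDevices::col2rgb(CLASS_PALETTE) / 255
  lab <- sample$label
  arr <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (cc in 0:3) {
    m <- lab == cc
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[m] <- cols[ch, cc + 1]
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, label_path)
  invisible(c(image_path, label_path))
}

#' Read a paired PNG sample
#'
#' Inverse of [write_png_pair()]: recovers gray levels and the class map
#' from the palette colors.
#'
#' @param image_path,label_path Paths written by [write_png_pair()].
#' @return A `labeled_sample`.
#' @export
read_png_pair <- function(image_path, label_path) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  rgb <- png::readPNG(label_path)
  cols <- grDevices::col2rgb(CLASS_PALETTE) / 255
  lab <- matrix(0L, nrow(rgb), ncol(rgb))
  for (cc in 1:3) {
    m <- abs(rgb[, , 1] - cols[1, cc + 1]) < 1e-3 &
      abs(rgb[, , 2] - cols[2, cc + 1]) < 1e-3 &
      abs(rgb[, , 3] - cols[3, cc + 1]) < 1e-3
    lab[m] <- cc
  }
  structure(list(image = matrix(as.integer(round(img * 255)), nrow(lab), ncol(lab)),
                 label = lab, meta = list()),
            class = "labeled_sample")
}

#' Split indices as a tidy table
#'
#' @param x A `dataset_split`.
#' @param ... Unused.
#' @return Tibble with columns `index` and `role`.
#' @method tidy dataset_split
#' @export
tidy.dataset_split <- function(x, ...) {
  bind_rows(tibble(index = x$train, role = "train"),
            tibble(index = x$test, role = "test"))
}
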