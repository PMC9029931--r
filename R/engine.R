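# Alternating adversarial training: one discriminator step (least-squares
# real/fake objective) then one generator step (adversarial term + lambda x
# segmentation loss) per batch, with best-training-Dice checkpointing and a
# patience stop on the generator objective.

#' Training configuration
#'
#' @param batch_size Samples per step (default 64).
#' @param lr Adam learning rate (default 2e-4).
#' @param beta1,beta2 Adam momentum parameters (defaults 0.5, 0.999).
#' @param lambda Weight of the segmentation loss in the generator objective
#'   (default 10).
#' @param seed Global seed for initialization and shuffling (default 123).
#' @param patience_epochs Stop when the epoch-mean generator objective has
#'   not decreased for this many consecutive epochs (default 200).
#' @param max_epochs Hard epoch cap for desk-scale runs.
#' @param use_gan Train adversarially? `FALSE` trains the generator alone on
#'   the segmentation loss.
#' @param seg_loss One of `"lovasz"`, `"ce"`, `"weighted_ce"`, `"dice"`,
#'   `"weighted_dice"`.
#' @param generator `"nested"` or `"unet"`.
#' @param gen_filters,disc_widths Channel widths for the two networks.
#' @param eval_classes Classes entering macro Dice/IoU (default `1:3`).
#' @param class_policy Lovasz class policy, `"present"` or `"all"`.
#' @param verbose Print one line per epoch?
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, lr = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, lambda = 10, seed = 123L,
                         patience_epochs = 200L, max_epochs = 100L,
                         use_gan = TRUE, seg_loss = "lovasz",
                         generator = c("nested", "unet"),
                         gen_filters = c(64L, 128L, 256L, 512L, 1024L),
                         disc_widths = NULL,
                         eval_classes = 1:3,
                         class_policy = "present",
                         verbose = FALSE) {
  generator <- match.arg(generator)
  if (!seg_loss %in% seg_loss_kinds()) {
    abort(sprintf("unknown seg_loss '%s'", seg_loss))
  }
  if (lr <= 0 || batch_size < 1 || patience_epochs < 1) {
    abort("rates must be positive and patience >= 1")
  }
  if (is.null(disc_widths)) disc_widths <- gen_filters
  structure(list(batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, lambda = lambda, seed = as.integer(seed),
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs), use_gan = isTRUE(use_gan),
                 seg_loss = seg_loss, generator = generator,
                 gen_filters = as.integer(gen_filters),
                 disc_widths = as.integer(disc_widths),
                 eval_classes = eval_classes, class_policy = class_policy,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Stack model inputs into batch tensors.
samples_to_tensors <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  B <- length(samples)
  x <- array(0, dim = c(H, W, 1L, B))
  y <- array(0L, dim = c(H, W, B))
  for (b in seq_len(B)) {
    img <- samples[[b]]$image
    if (max(img) > 1) img <- img / 255   # accept raw labeled samples too
    x[, , 1, b] <- img
    y[, , b] <- samples[[b]]$label
  }
  list(x = x, y = y)
}

batch_dice <- function(pred_labels, true_labels, classes) {
  ds <- vapply(classes, function(cc) {
    p <- pred_labels == cc
    t <- true_labels == cc
    denom <- sum(p) + sum(t)
    if (denom == 0) return(NA_real_)
    2 * sum(p & t) / denom
  }, numeric(1))
  mean(ds, na.rm = TRUE)
}

check_finite <- function(value, term) {
  if (!is.finite(value)) {
    abort(sprintf("non-finite loss in term '%s' (%g); training aborted", term, value))
  }
  value
}

#' Train the adversarial segmentation framework
#'
#' Builds the configured generator (and, with `use_gan`, the patch critic),
#' then alternates one discriminator update minimizing the least-squares
#' real/fake objective with one generator update minimizing
#' `adversarial + lambda * segmentation` per batch. Training Dice (macro over
#' `eval_classes`) is accumulated from the training batches themselves and
#' the generator weights at the best epoch are checkpointed; training stops
#' at `max_epochs` or when the epoch-mean generator objective has not
#' decreased for `patience_epochs` epochs.
#'
#' @param samples List of `labeled_sample`s / `model_input`s with a common
#'   spatial size divisible by 16.
#' @param config A [train_config()].
#' @return An `amfl_fit`: `generator` (best checkpoint), `final_generator`,
#'   `discriminator` (or `NULL`), `history` tibble (per-epoch loss bundle
#'   means and training Dice), `best_epoch`, `config`.
#' @export
train_segmenter <- function(samples, config = train_config()) {
  if (length(samples) < 1) abort("need at least one training sample")
  set.seed(config$seed)
  tens <- samples_to_tensors(samples)
  H <- dim(tens$x)[1]; W <- dim(tens$x)[2]; N <- dim(tens$x)[4]
  num_classes <- 4L

  gcfg <- generator_config(filters = config$gen_filters, in_channels = 1L,
                           num_classes = num_classes)
  gen <- if (config$generator == "nested") build_nested_generator(gcfg)
         else build_unet_baseline(gcfg)
  g_opt <- adam_new(flatten_params(gen$params), lr = config$lr,
                    beta1 = config$beta1, beta2 = config$beta2)

  disc <- NULL; d_opt <- NULL
  if (config$use_gan) {
    dcfg <- discriminator_config(in_channels = 1L + num_classes,
                                 widths = config$disc_widths)
    disc <- build_discriminator(dcfg)
    d_opt <- adam_new(flatten_params(disc$params), lr = config$lr,
                      beta1 = config$beta1, beta2 = config$beta2)
  }

  history <- list()
  best_dice <- -Inf; best_epoch <- NA_integer_; best_params <- NULL
  best_obj <- Inf; stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(N)
    nb <- ceiling(N / config$batch_size)
    acc <- c(d_loss = 0, g_adv = 0, seg_loss = 0, g_obj = 0, dice = 0)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, N)]
      xb <- tens$x[, , , idx, drop = FALSE]
      yb <- tens$y[, , idx, drop = FALSE]

      fw <- generator_forward(gen, xb, training = TRUE)
      gen <- apply_bn_updates(gen, fw$bn_updates)
      probs <- fw$probs

      d_loss_val <- 0; g_adv_val <- 0; grad_probs_adv <- NULL
      if (config$use_gan) {
        real_in <- make_discriminator_input(xb, yb, num_classes)
        fake_in <- make_discriminator_input(xb, probs, num_classes)

        # --- discriminator step ---
        fr <- discriminator_forward(disc, real_in, training = TRUE)
        ff <- discriminator_forward(disc, fake_in, training = TRUE)
        d_loss_val <- check_finite(lsgan_d_loss(fr$score, ff$score), "lsgan_d")
        nr <- length(fr$score); nf <- length(ff$score)
        br <- discriminator_backward(disc, 2 * (fr$score - 1) / nr, fr$score, fr$cache)
        bf <- discriminator_backward(disc, 2 * ff$score / nf, ff$score, ff$cache)
        dgr <- merge_flat(flatten_grads(br$grads), flatten_grads(bf$grads))
        st <- adam_step(d_opt, flatten_params(disc$params), dgr)
        d_opt <- st$state
        disc$params <- unflatten_params(st$params, disc$params)

        # --- adversarial gradient for the generator (through updated D) ---
        ff2 <- discriminator_forward(disc, fake_in, training = TRUE)
        g_adv_val <- check_finite(lsgan_g_loss(ff2$score), "lsgan_g")
        b2 <- discriminator_backward(disc, 2 * (ff2$score - 1) / length(ff2$score),
                                     ff2$score, ff2$cache)
        grad_probs_adv <- b2$gx[, , 2:(num_classes + 1), , drop = FALSE]
      }

      sl <- seg_loss_value_grad(probs, yb, config$seg_loss,
                                class_policy = config$class_policy)
      seg_val <- check_finite(sl$value, config$seg_loss)
      grad_probs <- config$lambda * sl$grad
      if (!is.null(grad_probs_adv)) grad_probs <- grad_probs + grad_probs_adv
      glogits <- channel_softmax_bwd(probs, grad_probs)
      ggr <- flatten_grads(generator_backward(gen, glogits, fw$cache))
      st <- adam_step(g_opt, flatten_params(gen$params), ggr)
      g_opt <- st$state
      gen$params <- unflatten_params(st$params, gen$params)

      g_obj <- if (config$use_gan) generator_objective(g_adv_val, seg_val, config$lambda)
               else config$lambda * seg_val
      pred <- channel_argmax(probs)
      wb <- length(idx) / N
      acc <- acc + wb * c(d_loss_val, g_adv_val, seg_val, g_obj,
                          batch_dice(pred, yb, config$eval_classes))
    }
    history[[epoch]] <- tibble(epoch = epoch, d_loss = acc[["d_loss"]],
                               g_adv = acc[["g_adv"]], seg_loss = acc[["seg_loss"]],
                               g_obj = acc[["g_obj"]], train_dice = acc[["dice"]])
    if (config$verbose) {
      message(sprintf("epoch %3d  d %.4f  adv %.4f  seg %.4f  obj %.4f  dice %.4f",
                      epoch, acc[["d_loss"]], acc[["g_adv"]], acc[["seg_loss"]],
                      acc[["g_obj"]], acc[["dice"]]))
    }
    if (acc[["dice"]] > best_dice) {
      best_dice <- acc[["dice"]]; best_epoch <- epoch
      best_params <- gen$params
    }
    if (acc[["g_obj"]] < best_obj - 1e-12) {
      best_obj <- acc[["g_obj"]]; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience_epochs) break
    }
  }

  best_gen <- gen
  best_gen$params <- best_params
  structure(list(generator = best_gen, final_generator = gen,
                 discriminator = disc,
                 history = bind_rows(history),
                 best_epoch = best_epoch, best_train_dice = best_dice,
                 config = config),
            class = "amfl_fit")
}

#' @export
print.amfl_fit <- function(x, ...) {
  cat(sprintf("<amfl_fit> %s generator, %d epochs, best train Dice %.4f (epoch %d)\n",
              x$config$generator, nrow(x$history), x$best_train_dice, x$best_epoch))
  invisible(x)
}

#' Per-epoch training history
#'
#' @param x An `amfl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: loss bundle means and training
#'   Dice.
#' @method tidy amfl_fit
#' @export
tidy.amfl_fit <- function(x, ...) x$history

#' @rdname tidy.amfl_fit
#' @method glance amfl_fit
#' @export
glance.amfl_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_train_dice = x$best_train_dice,
         final_g_obj = x$history$g_obj[nrow(x$history)],
         use_gan = x$config$use_gan, seg_loss = x$config$seg_loss,
         generator = x$config$generator)
}

#' Training curves
#'
#' Loss components and training Dice against epoch.
#'
#' @param object An `amfl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amfl_fit
#' @export
autoplot.amfl_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Evaluate a trained generator
#'
#' Runs the generator in inference mode, hardens the confidence map by
#' per-pixel argmax and scores every sample with the eight-metric suite;
#' the aggregate is the mean of the per-image rows.
#'
#' @param fit An `amfl_fit` (its best checkpoint is used) or a
#'   `seg_network` generator.
#' @param samples Non-empty list of evaluation samples.
#' @param eval_classes Classes entering macro averages.
#' @param batch_size Forward batch size.
#' @return List with `summary` (one-row tibble) and `per_image` tibble.
#' @export
evaluate_segmenter <- function(fit, samples, eval_classes = 1:3,
                               batch_size = 16L) {
  gen <- if (inherits(fit, "amfl_fit")) fit$generator else fit
  if (length(samples) == 0) abort("empty evaluation set")
  tens <- samples_to_tensors(samples)
  N <- dim(tens$x)[4]
  rows <- list()
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    fw <- generator_forward(gen, tens$x[, , , idx, drop = FALSE], training = FALSE)
    pred <- channel_argmax(fw$probs)
    for (k in seq_along(idx)) {
      rows[[idx[k]]] <- evaluate_image(pred[, , k], tens$y[, , idx[k]],
                                       average_classes = eval_classes)
    }
  }
  per_image <- bind_rows(rows)
  summary <- summarise(per_image, across(dplyr::everything(),
                                         ~ mean(.x, na.rm = TRUE)))
  list(summary = summary, per_image = per_image)
}

#' Segment one image
#'
#' @param fit An `amfl_fit` or generator network.
#' @param image Numeric matrix in `[0, 1]` (preprocessed via
#'   [pad_and_normalize()]), spatial size divisible by 16.
#' @return List with `label` (integer map, argmax with ties toward the lower
#'   class), `probs` and `palette` colors for rendering.
#' @export
segment_image <- function(fit, image) {
  gen <- if (inherits(fit, "amfl_fit")) fit$generator else fit
  if (is.list(image) && !is.null(image$image)) image <- image$image
  if (max(image) > 1 + 1e-9) {
    abort("image must be normalized to [0, 1]; run pad_and_normalize() first")
  }
  x <- array(image, dim = c(nrow(image), ncol(image), 1L, 1L))
  fw <- generator_forward(gen, x, training = FALSE)
  lab <- channel_argmax(fw$probs)[, , 1]
  list(label = lab, probs = fw$probs[, , , 1], palette = CLASS_PALETTE)
}

#' Ablation grid
#'
#' Trains and evaluates one model per grid row (columns `use_gan` and
#' `seg_loss`, optionally `generator`), holding every other setting and the
#' seed fixed so differences are attributable to the varied factor.
#'
#' @param grid Data frame with columns `use_gan`, `seg_loss` and optionally
#'   `generator`.
#' @param train_samples,test_samples Sample lists.
#' @param base_config Settings shared by every cell.
#' @return Tibble: one row per cell with the aggregated metrics.
#' @export
ablation_matrix <- function(grid, train_samples, test_samples,
                            base_config = train_config()) {
  stopifnot(all(c("use_gan", "seg_loss") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- base_config
    cfg$use_gan <- isTRUE(grid$use_gan[r])
    cfg$seg_loss <- grid$seg_loss[r]
    if ("generator" %in% names(grid)) cfg$generator <- grid$generator[r]
    fit <- train_segmenter(train_samples, cfg)
    ev <- evaluate_segmenter(fit, test_samples, eval_classes = cfg$eval_classes)
    bind_cols(tibble(use_gan = cfg$use_gan, seg_loss = cfg$seg_loss,
                     generator = cfg$generator), ev$summary)
  })
  bind_rows(rows)
}

# ---- parameter flattening helpers ------------------------------------------

# Adam works on a flat named list "node.stage/field" -> array.
flatten_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    for (f in c("w", "b", "gamma", "beta")) {
      if (!is.null(params[[nm]][[f]])) out[[paste0(nm, "/", f)]] <- params[[nm]][[f]]
    }
  }
  out
}

flatten_grads <- function(grads) {
  grads <- merge_grads(grads)
  out <- list()
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) out[[paste0(nm, "/", f)]] <- grads[[nm]][[f]]
  }
  out
}

unflatten_params <- function(flat, template) {
  for (nm in names(template)) {
    for (f in c("w", "b", "gamma", "beta")) {
      key <- paste0(nm, "/", f)
      if (!is.null(flat[[key]])) template[[nm]][[f]] <- flat[[key]]
    }
  }
  template
}

merge_flat <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
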