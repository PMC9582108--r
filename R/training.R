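#' Training configuration
#'
#' @param architecture network architecture, see [network_spec()].
#' @param input_size `c(height, width)` the network trains at; images/masks
#'   are resized to this. Default 384 x 512.
#' @param epochs number of passes over the training set (100 in the reference
#'   protocol; far fewer for smoke tests).
#' @param batch_size images per optimizer step (per-image losses are averaged).
#' @param optimizer `"adam"` (the only implemented optimizer).
#' @param learning_rate Adam step size.
#' @param tversky a [tversky_params()] used by the Focal Tversky loss.
#' @param seed seed covering weight init, shuffling and any augmentation order.
#' @param checkpoint_dir directory for checkpoints; tempdir-based default.
#' @param selection_metric validation metric for model selection, `"dice"` or
#'   `"jaccard"`. The best-validation epoch is checkpointed; without a
#'   validation set the final epoch is kept.
#' @return A `"train_config"` object.
#' @export
train_config <- function(architecture = "attention_squeeze_unet",
                         input_size = c(384L, 512L), epochs = 100L,
                         batch_size = 8L, optimizer = "adam",
                         learning_rate = 1e-3,
                         tversky = tversky_params(), seed = 42L,
                         checkpoint_dir = file.path(tempdir(), "asunet_ckpt"),
                         selection_metric = c("dice", "jaccard")) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            inherits(tversky, "tversky_params"))
  optimizer <- match.arg(optimizer, "adam")
  selection_metric <- match.arg(selection_metric)
  structure(list(architecture = match.arg(architecture, ARCHITECTURES),
                 input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, tversky = tversky,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 selection_metric = selection_metric),
            class = "train_config")
}

adam_init <- function(nodes) {
  for (p in nodes) { p$m <- 0 * p$value; p$v <- 0 * p$value }
  invisible(NULL)
}

adam_step <- function(nodes, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (p in nodes) {
    g <- if (is.null(p$grad)) 0 * p$value else p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / c1) / (sqrt(p$v / c2) + eps)
  }
  invisible(NULL)
}

prep_pair <- function(s, input_size) {
  s <- resize_normalize(s, input_size)
  list(image = s$image, mask = as.matrix(s$mask))
}

#' Train a segmentation network
#'
#' Seeded training loop minimizing the mean per-image Focal Tversky loss on
#' the foreground probability channel with Adam. Logs the training loss each
#' epoch and, when a validation set is given, the validation Dice and Jaccard;
#' the checkpoint of the best validation epoch (by the configured selection
#' metric) is kept. Aborts with the last finite epoch if the loss diverges.
#'
#' @param config a [train_config()].
#' @param train_data list of `"image_sample"` objects with masks (e.g. from
#'   [generate_samples()] or [load_dataset()]).
#' @param val_data optional validation list of the same form.
#' @param verbose print one line per epoch.
#' @return List with `log` (data.frame: epoch, train_loss, val_dice, val_jsi),
#'   `checkpoint` (path to the selected checkpoint), `best_epoch`, and `net`
#'   (the final-epoch network).
#' @export
train <- function(config, train_data, val_data = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"), length(train_data) >= 1)
  if (any(vapply(train_data, function(s) is.null(s$mask), logical(1))))
    stop("every training sample needs a mask")
  set.seed(config$seed)

  spec <- network_spec(config$architecture, config$input_size,
                       seed = config$seed)
  net <- build_network(spec)
  wrapped <- wrap_params(net$params)
  nodes <- param_nodes(wrapped)
  adam_init(nodes)

  tr <- lapply(train_data, prep_pair, input_size = config$input_size)
  va <- if (!is.null(val_data))
    lapply(val_data, prep_pair, input_size = config$input_size)

  dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(tr)
  tp <- config$tversky
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice = numeric(), val_jsi = numeric())
  best_metric <- -Inf; best_epoch <- NA_integer_
  best_path <- file.path(config$checkpoint_dir, "best.rds")
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      ag_zero_grad(nodes)
      losses <- lapply(idx, function(i) {
        x <- ag_leaf(tr[[i]]$image)
        probs <- net_forward(net, x, params = wrapped)
        fg <- op_channel(probs, 2L)
        op_ftl(fg, tr[[i]]$mask, tp$alpha, tp$beta, tp$gamma, tp$epsilon)
      })
      loss <- op_scale(op_scalar_sum(losses), 1 / length(idx))
      lval <- as.numeric(ag_value(loss))
      if (!is.finite(lval)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; last finite epoch: ", epoch - 1L)
      }
      ag_backward(loss)
      step <- step + 1L
      adam_step(nodes, config$learning_rate, step)
      ep_loss <- ep_loss + lval; n_batches <- n_batches + 1L
    }
    ep_loss <- ep_loss / n_batches

    vd <- NA_real_; vj <- NA_real_
    if (!is.null(va)) {
      cur <- sync_network(net, wrapped)
      ms <- vapply(va, function(p) {
        pr <- decode_targets(predict_probs(cur, p$image))
        c(dice(confusion_counts(pr, p$mask)),
          jaccard(confusion_counts(pr, p$mask)))
      }, numeric(2))
      vd <- mean(ms[1, ]); vj <- mean(ms[2, ])
      sel <- if (config$selection_metric == "dice") vd else vj
      if (sel > best_metric) {
        best_metric <- sel; best_epoch <- epoch
        save_checkpoint(cur, best_path, epoch = epoch, log = log)
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_dice = vd, val_jsi = vj))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.5f  val dice %s\n", epoch, ep_loss,
                  ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
  }

  final <- sync_network(net, wrapped)
  if (is.null(va)) {
    best_epoch <- config$epochs
    save_checkpoint(final, best_path, epoch = best_epoch, log = log)
  }
  list(log = log, checkpoint = best_path, best_epoch = best_epoch,
       net = final)
}

sync_network <- function(net, wrapped) {
  net$params <- unwrap_params(wrapped)
  net
}

#' Save / load a network checkpoint
#'
#' Checkpoints are RDS files holding the architecture spec, the weights and
#' training metadata; loading rebuilds an identical network.
#'
#' @param net an `"asu_network"`.
#' @param path file path (`.rds`).
#' @param ... extra metadata stored alongside (e.g. epoch, log).
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` the
#'   network with a `meta` attribute.
#' @export
save_checkpoint <- function(net, path, ...) {
  saveRDS(list(spec = net$spec, params = net$params, meta = list(...)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- structure(list(spec = ck$spec, params = ck$params),
                   class = "asu_network")
  attr(net, "meta") <- ck$meta
  net
}

#' Predict binary masks
#'
#' Runs inference on a list of images: each image is resized to the network
#' input size, passed through the network, binarized by per-pixel argmax over
#' the two class channels, and the mask is resized back (nearest neighbour) to
#' the image's original size. Images are processed independently, so results
#' do not depend on batch composition.
#'
#' @param net an `"asu_network"` or a checkpoint path.
#' @param images list of `"image_sample"` objects (or bare `H x W x 3`
#'   arrays).
#' @return Named list of binary `H x W` masks at the original image sizes.
#' @export
predict_masks <- function(net, images) {
  if (is.character(net)) net <- load_checkpoint(net)
  stopifnot(inherits(net, "asu_network"))
  if (inherits(images, "image_sample") ||
      (is.array(images) && length(dim(images)) == 3L))
    images <- list(images)
  out <- lapply(images, function(s) {
    if (!inherits(s, "image_sample")) {
      s <- structure(list(id = NA_character_, image = s, mask = NULL,
                          class = NA_character_, provenance = "original",
                          original_size = dim(s)[1:2]),
                     class = "image_sample")
    }
    orig <- s$original_size
    x <- resize_normalize(s, net$spec$input_size)$image
    m <- decode_targets(predict_probs(net, x))
    resize_mask(m, orig)
  })
  ids <- vapply(images, function(s)
    if (inherits(s, "image_sample")) s$id else NA_character_, character(1))
  if (!any(is.na(ids))) names(out) <- ids
  out
}
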