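# Training loop: cross-entropy identity classification with on-the-fly
# augmentation (random rotation + random erasing, training split only) and
# per-epoch validation retrieval.

#' Train the re-identification model
#'
#' Runs mini-batch SGD under the configured schedule. Each training image is,
#' with probability `aug_prob` per transform, randomly rotated and randomly
#' erased before normalisation; the validation split is never augmented.
#' After every epoch the mean training loss and (when a validation set is
#' given) the validation Rank-1 — query = gallery = validation set with
#' self-exclusion — are logged.
#'
#' @param model A [reid_model()]; `n_classes` must cover every label.
#' @param train_set,val_set Lists with `images` (list of `(H, W, 3)` arrays
#'   in `[0, 1]`) and `labels` (integer identities in `1..K`), e.g. from
#'   [dataset_split()]. `val_set` may be `NULL`.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained in place) and `log`, a data.frame with
#'   columns `epoch`, `loss`, `val_rank1`.
#' @export
train_reid <- function(model, train_set, val_set = NULL,
                       cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "reid_model"))
  n <- length(train_set$images)
  if (n == 0L) stop("training set is empty")
  labels <- as.integer(train_set$labels)
  if (any(labels < 1L) || any(labels > model$n_classes)) {
    stop(sprintf("training labels must lie in [1, %d]", model$n_classes))
  }
  if (!is.null(val_set)) {
    if (length(val_set$images) == 0L) stop("validation set is empty")
    vl <- as.integer(val_set$labels)
    if (any(vl < 1L) || any(vl > model$n_classes)) {
      stop("validation labels outside the training label space")
    }
  }
  opt <- make_optimizer(model, cfg)
  log <- data.frame(epoch = integer(0), loss = numeric(0), val_rank1 = numeric(0))
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        imgs <- lapply(train_set$images[idx], augment_image, cfg = cfg)
        x <- normalize_images(imgs, model$norm_mean, model$norm_sd)
        y <- labels[idx]
        zero_model_grads(model)
        fw <- reid_forward(model, x, train = TRUE)
        losses <- c(losses, cross_entropy(fw$probs, y))
        B <- length(y)
        dlogits <- fw$probs
        dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
        reid_backward(model, dlogits / B)
        optimizer_step(opt, epoch)
      }
      r1 <- NA_real_
      if (!is.null(val_set)) {
        desc <- extract_descriptors(model, val_set$images)
        rep_ <- evaluate_descriptors(desc, val_set$labels, max_k = 1L)
        r1 <- rep_$cmc[1L]
      }
      log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                   val_rank1 = r1))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val rank-1 %s", epoch,
                        mean(losses), ifelse(is.na(r1), "-", sprintf("%.3f", r1))))
      }
    }
  })
  list(model = model, log = log)
}

augment_image <- function(img, cfg) {
  if (cfg$aug_prob > 0 && stats::runif(1) < cfg$aug_prob) {
    img <- random_rotation(img, cfg$aug_rotation)
  }
  if (cfg$aug_prob > 0 && stats::runif(1) < cfg$aug_prob) {
    img <- random_erasing(img, cfg$aug_erase)
  }
  img
}

#' Extract retrieval descriptors for a set of images
#'
#' Runs the model in evaluation mode (running normalisation statistics, no
#' augmentation) in mini-batches and returns the configured retrieval
#' feature.
#'
#' @param model A [reid_model()].
#' @param images List of `(H, W, 3)` arrays in `[0, 1]`.
#' @param feature `"concat"`, `"global"` or `"local"`; defaults to the
#'   model's `eval_feature`.
#' @param batch_size Forward batch size.
#' @return `N x D` descriptor matrix.
#' @export
extract_descriptors <- function(model, images, feature = NULL,
                                batch_size = 16L) {
  feature <- feature %||% model$eval_feature
  out <- NULL
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    x <- normalize_images(images[idx], model$norm_mean, model$norm_sd)
    fw <- reid_forward(model, x, train = FALSE)
    f <- switch(feature,
                concat = fw$descriptor,
                global = fw$f_global,
                local = {
                  if (is.null(fw$f_local)) stop("model has no local branch")
                  fw$f_local
                },
                stop("unknown feature type: ", feature))
    out <- rbind(out, f)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
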