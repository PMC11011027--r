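# Full re-identification model: backbone -> inverted pyramid -> local
# attention, concatenated descriptor, linear identity classifier.

#' Assemble the dual-branch re-identification model
#'
#' Builds the serial pipeline backbone -> inverted feature pyramid (global
#' branch) -> local attention enhancement (local branch). The global and
#' local features are concatenated into the descriptor, and a single linear
#' layer maps the descriptor to identity logits. The two ablation switches
#' reproduce the standard architecture ladder: backbone only (descriptor =
#' pooled C4), + pyramid (descriptor = global feature), + pyramid + local
#' branch (concatenated descriptor of twice the width).
#'
#' @param n_classes Number of identity classes K.
#' @param profile Backbone profile, see [build_backbone()].
#' @param use_ifpm Include the global pyramid branch (default `TRUE`).
#' @param use_laem Include the local attention branch (default `TRUE`).
#' @param extra_stem_pool See [build_backbone()].
#' @param laem_pool,laem_shared See [new_laem()].
#' @param merge See [new_ifpm()].
#' @param eval_feature Which feature is used for retrieval:
#'   `"concat"` (default), `"global"` or `"local"`.
#' @param seed Optional integer; when given, weight initialisation is drawn
#'   under this seed in a local RNG scope.
#' @return Object of class `reid_model`.
#' @export
reid_model <- function(n_classes, profile = "desk", use_ifpm = TRUE,
                       use_laem = TRUE, extra_stem_pool = TRUE,
                       laem_pool = "pre", laem_shared = TRUE,
                       merge = "sum", eval_feature = c("concat", "global", "local"),
                       seed = NULL) {
  eval_feature <- match.arg(eval_feature)
  if (!is.numeric(n_classes) || n_classes < 1) {
    stop("n_classes must be a positive integer (is the label space configured?)")
  }
  build <- function() {
    backbone <- build_backbone(profile, pretrained = FALSE,
                               extra_stem_pool = extra_stem_pool)
    w4 <- backbone$widths[4]
    ifpm <- if (use_ifpm) new_ifpm(backbone$widths, merge = merge) else NULL
    laem <- if (use_laem) {
      new_laem(w4, pool_position = laem_pool, shared = laem_shared)
    } else NULL
    desc_dim <- if (use_laem) 2L * w4 else w4
    new_layer("reid_model",
              backbone = backbone, ifpm = ifpm, laem = laem,
              classifier = new_linear(desc_dim, as.integer(n_classes)),
              n_classes = as.integer(n_classes), desc_dim = desc_dim,
              profile = profile, use_ifpm = use_ifpm, use_laem = use_laem,
              eval_feature = eval_feature,
              norm_mean = 0.5, norm_sd = 0.5,
              last_cache = NULL)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @exportS3Method
nn_params.reid_model <- function(layer) {
  out <- nn_params(layer$backbone)
  if (!is.null(layer$ifpm)) out <- c(out, nn_params(layer$ifpm))
  if (!is.null(layer$laem)) out <- c(out, nn_params(layer$laem))
  c(out, nn_params(layer$classifier))
}

#' Forward pass of the re-identification model
#'
#' @param model Model from [reid_model()].
#' @param batch Normalised image batch `(H, W, 3, B)`.
#' @param train Logical; batch-statistics mode, and caches are retained on
#'   the model for the subsequent backward pass.
#' @return List with `f_global`, `f_local` (or `NULL`), `descriptor`
#'   (`B x D` concatenated feature), `logits` and `probs` (`B x K`,
#'   rows summing to 1).
#' @export
reid_forward <- function(model, batch, train = FALSE) {
  stopifnot(inherits(model, "reid_model"))
  stages <- extract_stages(model$backbone, batch, train)
  if (model$use_ifpm) {
    pyr <- ifpm_forward(model$ifpm, stages, train)
    fused <- pyr$fused
    f_global <- pyr$f_global
  } else {
    pyr <- NULL
    fused <- stages$C4
    f_global <- global_avg_pool(fused)
  }
  if (model$use_laem) {
    lb <- local_branch(model$laem, fused, train)
    f_local <- lb$f_local
    descriptor <- cbind(f_global, f_local)
  } else {
    lb <- NULL
    f_local <- NULL
    descriptor <- f_global
  }
  rc <- nn_forward(model$classifier, descriptor, train)
  logits <- rc$out
  probs <- softmax_rows(logits)
  if (train) {
    model$last_cache <- list(
      stages = attr(stages, "cache"), pyr = pyr$cache,
      lb = attr(lb, "cache"), cls = rc$cache,
      fused_dim = dim(fused), dC_dims = lapply(stages[1:4], dim)
    )
  }
  list(f_global = f_global, f_local = f_local, descriptor = descriptor,
       logits = logits, probs = probs)
}

# Backward pass from the logit gradient; accumulates parameter gradients.
reid_backward <- function(model, dlogits) {
  ca <- model$last_cache
  if (is.null(ca)) stop("no cached forward pass; run reid_forward(train = TRUE) first")
  ddesc <- nn_backward(model$classifier, dlogits, ca$cls)
  w4 <- model$backbone$widths[4]
  if (model$use_laem) {
    df_global <- ddesc[, seq_len(w4), drop = FALSE]
    df_local <- ddesc[, w4 + seq_len(ncol(ddesc) - w4), drop = FALSE]
    dfused <- laem_backward(model$laem, df_local, ca$lb)
  } else {
    df_global <- ddesc
    dfused <- array(0, ca$fused_dim)
  }
  dfused <- dfused + global_avg_pool_bwd(df_global, ca$fused_dim)
  if (model$use_ifpm) {
    dC <- ifpm_backward(model$ifpm, dfused, ca$pyr)
  } else {
    dC <- list(C1 = array(0, ca$dC_dims$C1), C2 = array(0, ca$dC_dims$C2),
               C3 = array(0, ca$dC_dims$C3), C4 = dfused)
  }
  backbone_backward(model$backbone, dC, ca$stages)
  model$last_cache <- NULL
  invisible(model)
}

#' Cross-entropy loss
#'
#' `-sum_c y_c log p_c`, with the probability at the true class clamped at
#' 1e-12 so the loss is always finite. Accepts a single probability vector
#' with a one-hot (or index) label, or a `B x K` matrix with a label vector,
#' in which case the mean over the batch is returned.
#'
#' @param probs Probability vector (length K) or `B x K` matrix with rows
#'   summing to 1.
#' @param y One-hot vector / class index, or a length-B vector of class
#'   indices (1-based) for the matrix form.
#' @return Non-negative scalar loss; 0 exactly when the true-class
#'   probability is 1.
#' @export
cross_entropy <- function(probs, y) {
  eps <- 1e-12
  if (is.matrix(probs)) {
    if (length(y) == ncol(probs) && !is.matrix(y) && nrow(probs) == 1L) {
      # single row with one-hot y
      y <- which.max(y)
      return(-log(max(probs[1L, y], eps)))
    }
    stopifnot(length(y) == nrow(probs))
    p <- probs[cbind(seq_len(nrow(probs)), as.integer(y))]
    return(mean(-log(pmax(p, eps))))
  }
  if (length(y) == length(probs)) {
    idx <- which(y == max(y))[1L]
  } else {
    idx <- as.integer(y)
  }
  -log(max(probs[idx], eps))
}

#' Training configuration
#'
#' Defaults follow the published schedule: SGD with momentum 0.9, base
#' learning rate 0.002, classifier learning rate 0.02, weight decay 0.0005,
#' batch size 16, 150 epochs with both rates multiplied by 0.1 from epoch
#' 100 (epochs counted from 0), plus random rotation and random erasing
#' applied to the training split only.
#'
#' @param lr_base,lr_classifier,momentum,weight_decay,batch_size,epochs
#'   Optimisation hyper-parameters.
#' @param lr_decay_epoch,lr_decay_factor Step schedule: from epoch
#'   `lr_decay_epoch` both rates are multiplied by `lr_decay_factor`.
#' @param aug_rotation Rotation bound in degrees for the random-rotation
#'   augmentation.
#' @param aug_erase Area-fraction range for random erasing.
#' @param aug_prob Per-transform application probability.
#' @param seed RNG seed for shuffling and augmentation.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr_base = 0.002, lr_classifier = 0.02,
                         momentum = 0.9, weight_decay = 0.0005,
                         batch_size = 16L, epochs = 150L,
                         lr_decay_epoch = 100L, lr_decay_factor = 0.1,
                         aug_rotation = 15, aug_erase = c(0.02, 0.2),
                         aug_prob = 0.5, seed = 1L) {
  cfg <- list(lr_base = lr_base, lr_classifier = lr_classifier,
              momentum = momentum, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              lr_decay_epoch = as.integer(lr_decay_epoch),
              lr_decay_factor = lr_decay_factor,
              aug_rotation = aug_rotation, aug_erase = aug_erase,
              aug_prob = aug_prob, seed = as.integer(seed))
  with(cfg, stopifnot(lr_base > 0, lr_classifier > 0, momentum >= 0,
                      weight_decay >= 0, batch_size >= 1, epochs >= 1,
                      lr_decay_factor > 0, lr_decay_epoch > 0))
  class(cfg) <- "train_config"
  cfg
}

#' Learning rates at a given epoch
#'
#' @param cfg A [train_config()].
#' @param epoch Epoch index, counted from 0.
#' @return Named numeric vector `c(base = ..., classifier = ...)`; both rates
#'   are multiplied by `lr_decay_factor` from `lr_decay_epoch` on.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  f <- if (epoch >= cfg$lr_decay_epoch) cfg$lr_decay_factor else 1
  c(base = cfg$lr_base * f, classifier = cfg$lr_classifier * f)
}

#' SGD optimiser with two parameter groups
#'
#' Momentum SGD with decoupled-by-group learning rates: the classifier layer
#' trains at `lr_classifier`, everything else at `lr_base`; weight decay is
#' applied to weight matrices only (not biases or normalisation parameters).
#'
#' @param model A [reid_model()].
#' @param cfg A [train_config()].
#' @return Optimiser object; step with [optimizer_step()].
#' @export
make_optimizer <- function(model, cfg) {
  cls_params <- nn_params(model$classifier)
  all_params <- nn_params(model)
  is_cls <- vapply(all_params, function(p) {
    any(vapply(cls_params, function(q) identical(q$layer, p$layer) && q$par == p$par,
               logical(1)))
  }, logical(1))
  entries <- lapply(seq_along(all_params), function(i) {
    p <- all_params[[i]]
    p$group <- if (is_cls[i]) "classifier" else "base"
    p$v <- get(p$par, envir = p$layer) * 0
    p
  })
  opt <- new.env(parent = emptyenv())
  opt$entries <- entries
  opt$cfg <- cfg
  class(opt) <- "reid_optimizer"
  opt
}

#' Apply one SGD step
#'
#' @param opt Optimiser from [make_optimizer()].
#' @param epoch Current epoch (from 0), used for the step schedule.
#' @return The optimiser, invisibly.
#' @export
optimizer_step <- function(opt, epoch = 0L) {
  lrs <- lr_at_epoch(opt$cfg, epoch)
  mom <- opt$cfg$momentum
  wd <- opt$cfg$weight_decay
  for (i in seq_along(opt$entries)) {
    e <- opt$entries[[i]]
    g <- get(e$grad, envir = e$layer)
    if (e$decay && wd > 0) g <- g + wd * get(e$par, envir = e$layer)
    e$v <- mom * e$v + g
    lr <- unname(lrs[if (e$group == "classifier") "classifier" else "base"])
    assign(e$par, get(e$par, envir = e$layer) - lr * e$v, envir = e$layer)
    opt$entries[[i]] <- e
  }
  invisible(opt)
}

zero_model_grads <- function(model) {
  zero_grads(nn_params(model))
  invisible(model)
}

#' Normalise images for the network
#'
#' Maps pixel values in `[0, 1]` to `(x - mean) / sd` per channel. With no
#' pretrained corpus the default is mean 0.5, sd 0.5.
#'
#' @param images List of `(H, W, 3)` arrays or a single array.
#' @param mean,sd Normalisation constants.
#' @return `(H, W, 3, B)` array.
#' @export
normalize_images <- function(images, mean = 0.5, sd = 0.5) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], 3L, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  (x - mean) / sd
}

#' Save / load model weights
#'
#' Serialises all parameter arrays (plus normalisation-layer running
#' statistics) to an RDS file, with the model configuration alongside.
#'
#' @param model A [reid_model()].
#' @param path File path.
#' @return `save_reid_weights` the path invisibly; `load_reid_weights` a
#'   rebuilt model.
#' @export
save_reid_weights <- function(model, path) {
  params <- nn_params(model)
  state <- lapply(params, function(p) get(p$par, envir = p$layer))
  bn_layers <- collect_bn_layers(model)
  bn_state <- lapply(bn_layers, function(l) {
    list(rm = l$running_mean, rv = l$running_var)
  })
  cfg <- list(n_classes = model$n_classes, profile = model$profile,
              use_ifpm = model$use_ifpm, use_laem = model$use_laem,
              eval_feature = model$eval_feature)
  saveRDS(list(state = state, bn = bn_state, cfg = cfg), path)
  invisible(path)
}

#' @rdname save_reid_weights
#' @export
load_reid_weights <- function(path) {
  blob <- readRDS(path)
  cfg <- blob$cfg
  model <- reid_model(cfg$n_classes, profile = cfg$profile,
                      use_ifpm = cfg$use_ifpm, use_laem = cfg$use_laem,
                      eval_feature = cfg$eval_feature, seed = 1L)
  params <- nn_params(model)
  stopifnot(length(params) == length(blob$state))
  for (i in seq_along(params)) {
    assign(params[[i]]$par, blob$state[[i]], envir = params[[i]]$layer)
  }
  bn_layers <- collect_bn_layers(model)
  stopifnot(length(bn_layers) == length(blob$bn))
  for (i in seq_along(bn_layers)) {
    bn_layers[[i]]$running_mean <- blob$bn[[i]]$rm
    bn_layers[[i]]$running_var <- blob$bn[[i]]$rv
  }
  model
}

collect_bn_layers <- function(model) {
  seen <- list()
  walk <- function(x) {
    if (is.environment(x) && inherits(x, "nn_batchnorm2d")) {
      seen[[length(seen) + 1L]] <<- x
    } else if (is.environment(x) && inherits(x, "nn_layer")) {
      for (nm in ls(x)) walk(get(nm, envir = x))
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(model)
  seen
}
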