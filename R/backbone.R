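# Residual backbone exposing the four stage maps C1..C4, with the final
# stage's down-sampling removed so stages 3 and 4 share spatial size.

backbone_profiles <- function() {
  list(
    # 50-layer bottleneck design; stage widths are the classic 4x-expanded
    # (256, 512, 1024, 2048). With the extra stem pool the stage-1 map of a
    # 256x512 input is 32x64, matching the architecture's printed shapes.
    full = list(block = "bottleneck", depths = c(3L, 4L, 6L, 3L),
                widths = c(256L, 512L, 1024L, 2048L),
                inner = c(64L, 128L, 256L, 512L), stem = 64L),
    # Reduced-depth, reduced-width (1/8) variant with the identical stage
    # shape contract; trains in minutes on one CPU core.
    desk = list(block = "basic", depths = c(2L, 2L, 2L, 2L),
                widths = c(32L, 64L, 128L, 256L),
                inner = c(32L, 64L, 128L, 256L), stem = 32L),
    # Tiny variant used for gradient checking and fast structural tests.
    micro = list(block = "basic", depths = c(1L, 1L, 1L, 1L),
                 widths = c(8L, 16L, 32L, 64L),
                 inner = c(8L, 16L, 32L, 64L), stem = 8L)
  )
}

new_basic_block <- function(c_in, c_out, stride) {
  proj <- NULL
  if (c_in != c_out || stride != 1L) {
    proj <- list(conv = new_conv2d(c_in, c_out, 1L, stride = stride, bias = FALSE),
                 bn = new_batchnorm2d(c_out))
  }
  new_layer("nn_basic_block",
            conv1 = new_conv2d(c_in, c_out, 3L, stride = stride, bias = FALSE),
            bn1 = new_batchnorm2d(c_out),
            conv2 = new_conv2d(c_out, c_out, 3L, bias = FALSE),
            bn2 = new_batchnorm2d(c_out),
            proj = proj)
}

#' @exportS3Method
nn_forward.nn_basic_block <- function(layer, x, train = FALSE) {
  r1 <- nn_forward(layer$conv1, x, train)
  r2 <- nn_forward(layer$bn1, r1$out, train)
  a <- r2$out * (r2$out > 0)
  r3 <- nn_forward(layer$conv2, a, train)
  r4 <- nn_forward(layer$bn2, r3$out, train)
  if (is.null(layer$proj)) {
    sc <- x; pc <- NULL
  } else {
    p1 <- nn_forward(layer$proj$conv, x, train)
    p2 <- nn_forward(layer$proj$bn, p1$out, train)
    sc <- p2$out; pc <- list(p1$cache, p2$cache)
  }
  s <- r4$out + sc
  y <- s * (s > 0)
  list(out = y,
       cache = list(c1 = r1$cache, c2 = r2$cache, m1 = r2$out > 0,
                    c3 = r3$cache, c4 = r4$cache, pc = pc, mout = s > 0))
}

#' @exportS3Method
nn_backward.nn_basic_block <- function(layer, dout, cache) {
  ds <- dout * cache$mout
  d4 <- nn_backward(layer$bn2, ds, cache$c4)
  d3 <- nn_backward(layer$conv2, d4, cache$c3)
  d2 <- nn_backward(layer$bn1, d3 * cache$m1, cache$c2)
  dx <- nn_backward(layer$conv1, d2, cache$c1)
  if (is.null(layer$proj)) {
    dx <- dx + ds
  } else {
    dp <- nn_backward(layer$proj$bn, ds, cache$pc[[2]])
    dx <- dx + nn_backward(layer$proj$conv, dp, cache$pc[[1]])
  }
  dx
}

#' @exportS3Method
nn_params.nn_basic_block <- function(layer) {
  out <- c(nn_params(layer$conv1), nn_params(layer$bn1),
           nn_params(layer$conv2), nn_params(layer$bn2))
  if (!is.null(layer$proj)) {
    out <- c(out, nn_params(layer$proj$conv), nn_params(layer$proj$bn))
  }
  out
}

new_bottleneck_block <- function(c_in, c_inner, c_out, stride) {
  proj <- NULL
  if (c_in != c_out || stride != 1L) {
    proj <- list(conv = new_conv2d(c_in, c_out, 1L, stride = stride, bias = FALSE),
                 bn = new_batchnorm2d(c_out))
  }
  new_layer("nn_bottleneck_block",
            conv1 = new_conv2d(c_in, c_inner, 1L, bias = FALSE),
            bn1 = new_batchnorm2d(c_inner),
            conv2 = new_conv2d(c_inner, c_inner, 3L, stride = stride, bias = FALSE),
            bn2 = new_batchnorm2d(c_inner),
            conv3 = new_conv2d(c_inner, c_out, 1L, bias = FALSE),
            bn3 = new_batchnorm2d(c_out),
            proj = proj)
}

#' @exportS3Method
nn_forward.nn_bottleneck_block <- function(layer, x, train = FALSE) {
  r1 <- nn_forward(layer$conv1, x, train)
  b1 <- nn_forward(layer$bn1, r1$out, train)
  a1 <- b1$out * (b1$out > 0)
  r2 <- nn_forward(layer$conv2, a1, train)
  b2 <- nn_forward(layer$bn2, r2$out, train)
  a2 <- b2$out * (b2$out > 0)
  r3 <- nn_forward(layer$conv3, a2, train)
  b3 <- nn_forward(layer$bn3, r3$out, train)
  if (is.null(layer$proj)) {
    sc <- x; pc <- NULL
  } else {
    p1 <- nn_forward(layer$proj$conv, x, train)
    p2 <- nn_forward(layer$proj$bn, p1$out, train)
    sc <- p2$out; pc <- list(p1$cache, p2$cache)
  }
  s <- b3$out + sc
  y <- s * (s > 0)
  list(out = y,
       cache = list(c1 = r1$cache, cb1 = b1$cache, m1 = b1$out > 0,
                    c2 = r2$cache, cb2 = b2$cache, m2 = b2$out > 0,
                    c3 = r3$cache, cb3 = b3$cache, pc = pc, mout = s > 0))
}

#' @exportS3Method
nn_backward.nn_bottleneck_block <- function(layer, dout, cache) {
  ds <- dout * cache$mout
  d <- nn_backward(layer$bn3, ds, cache$cb3)
  d <- nn_backward(layer$conv3, d, cache$c3)
  d <- nn_backward(layer$bn2, d * cache$m2, cache$cb2)
  d <- nn_backward(layer$conv2, d, cache$c2)
  d <- nn_backward(layer$bn1, d * cache$m1, cache$cb1)
  dx <- nn_backward(layer$conv1, d, cache$c1)
  if (is.null(layer$proj)) {
    dx <- dx + ds
  } else {
    dp <- nn_backward(layer$proj$bn, ds, cache$pc[[2]])
    dx <- dx + nn_backward(layer$proj$conv, dp, cache$pc[[1]])
  }
  dx
}

#' @exportS3Method
nn_params.nn_bottleneck_block <- function(layer) {
  out <- c(nn_params(layer$conv1), nn_params(layer$bn1),
           nn_params(layer$conv2), nn_params(layer$bn2),
           nn_params(layer$conv3), nn_params(layer$bn3))
  if (!is.null(layer$proj)) {
    out <- c(out, nn_params(layer$proj$conv), nn_params(layer$proj$bn))
  }
  out
}

make_stage <- function(prof, i, c_in, stride) {
  blocks <- vector("list", prof$depths[i])
  for (j in seq_len(prof$depths[i])) {
    s <- if (j == 1L) stride else 1L
    cin <- if (j == 1L) c_in else prof$widths[i]
    blocks[[j]] <- if (prof$block == "bottleneck") {
      new_bottleneck_block(cin, prof$inner[i], prof$widths[i], s)
    } else {
      new_basic_block(cin, prof$widths[i], s)
    }
  }
  new_sequential(blocks)
}

#' Build the stage-wise residual backbone
#'
#' Constructs a residual feature extractor that exposes its four stage maps
#' `C1..C4`. The entry stride of stage 4 is set to 1 (including its projection
#' shortcut), so stages 3 and 4 share spatial size — the "last down-sampling
#' removed" convention of re-identification backbones. By default the stem
#' applies one extra stride-2 pooling so that a 256x512 input yields a 32x64
#' stage-1 map and the stage maps have channel widths (256, 512, 1024, 2048)
#' in the `"full"` profile.
#'
#' @param profile `"full"` for the 50-layer bottleneck design, `"desk"` for a
#'   reduced-depth, width/8 variant with the identical stage-shape contract
#'   (useful for CPU-scale experiments), or `"micro"` for a tiny variant used
#'   in numerical tests.
#' @param pretrained If `TRUE`, initialise from corpus-pretrained weights.
#'   No pretrained weights ship with the package, so this requires `weights`;
#'   otherwise an explicit error is raised (never a silent random init).
#' @param extra_stem_pool Apply the extra stride-2 stem pooling (default
#'   `TRUE`; total stride 8 before stage 1). Set `FALSE` for the standard
#'   stride-4 stem.
#' @param weights Optional path to a weights file saved with
#'   [save_reid_weights()] (backbone section), used when `pretrained = TRUE`.
#' @return An object of class `reid_backbone`.
#' @seealso [extract_stages()]
#' @export
build_backbone <- function(profile = c("full", "desk", "micro"),
                           pretrained = FALSE, extra_stem_pool = TRUE,
                           weights = NULL) {
  if (!is.character(profile) || !(profile[1] %in% c("full", "desk", "micro"))) {
    stop(sprintf("unknown backbone profile '%s' (expected 'full', 'desk' or 'micro')",
                 as.character(profile[1])))
  }
  profile <- profile[1]
  if (isTRUE(pretrained) && is.null(weights)) {
    stop("pretrained = TRUE requested but no weights file is available in this ",
         "offline installation; pass `weights =` or use pretrained = FALSE")
  }
  prof <- backbone_profiles()[[profile]]
  stem_layers <- list(
    new_conv2d(3L, prof$stem, 7L, stride = 2L, pad = 3L, bias = FALSE),
    new_batchnorm2d(prof$stem),
    new_relu(),
    new_maxpool(3L, stride = 2L, pad = 1L)
  )
  if (isTRUE(extra_stem_pool)) {
    stem_layers <- c(stem_layers, list(new_maxpool(2L, stride = 2L, pad = 0L)))
  }
  bb <- new_layer("reid_backbone",
                  stem = new_sequential(stem_layers),
                  stage1 = make_stage(prof, 1L, prof$stem, 1L),
                  stage2 = make_stage(prof, 2L, prof$widths[1], 2L),
                  stage3 = make_stage(prof, 3L, prof$widths[2], 2L),
                  stage4 = make_stage(prof, 4L, prof$widths[3], 1L),
                  profile = profile, widths = prof$widths,
                  extra_stem_pool = isTRUE(extra_stem_pool),
                  stride = if (isTRUE(extra_stem_pool)) 32L else 16L)
  bb
}

#' Run the backbone and return the four stage feature maps
#'
#' @param model A backbone built with [build_backbone()].
#' @param batch Image batch: numeric array with dim `(H, W, 3, B)`, already
#'   normalised (see [normalize_images()]). `H` and `W` must be multiples of
#'   the backbone's total stride.
#' @param train Use batch statistics in the normalisation layers and record
#'   caches for the backward pass.
#' @return A list of class `stage_features` with maps `C1..C4`
#'   (`(h, w, channels, B)` arrays). When `train = TRUE` the forward caches
#'   are attached for internal use by the trainer.
#' @export
extract_stages <- function(model, batch, train = FALSE) {
  stopifnot(inherits(model, "reid_backbone"))
  d <- dim(batch)
  if (is.null(d) || length(d) != 4L || d[3] != 3L) {
    stop("batch must be an (H, W, 3, B) array")
  }
  if (d[1] %% model$stride != 0L) {
    stop(sprintf("input height %d is not a multiple of the backbone stride %d",
                 d[1], model$stride))
  }
  if (d[2] %% model$stride != 0L) {
    stop(sprintf("input width %d is not a multiple of the backbone stride %d",
                 d[2], model$stride))
  }
  r0 <- nn_forward(model$stem, batch, train)
  r1 <- nn_forward(model$stage1, r0$out, train)
  r2 <- nn_forward(model$stage2, r1$out, train)
  r3 <- nn_forward(model$stage3, r2$out, train)
  r4 <- nn_forward(model$stage4, r3$out, train)
  out <- list(C1 = r1$out, C2 = r2$out, C3 = r3$out, C4 = r4$out)
  class(out) <- "stage_features"
  if (train) {
    attr(out, "cache") <- list(stem = r0$cache, s1 = r1$cache, s2 = r2$cache,
                               s3 = r3$cache, s4 = r4$cache)
  }
  out
}

# Backward through the backbone given gradients for each stage map (the
# pyramid taps C1..C3 in addition to the sequential path, so gradients for
# the inner stages accumulate).
backbone_backward <- function(model, dC, cache) {
  g <- nn_backward(model$stage4, dC$C4, cache$s4)
  g <- nn_backward(model$stage3, g + dC$C3, cache$s3)
  g <- nn_backward(model$stage2, g + dC$C2, cache$s2)
  g <- nn_backward(model$stage1, g + dC$C1, cache$s1)
  invisible(nn_backward(model$stem, g, cache$stem))
}

#' @exportS3Method
nn_params.reid_backbone <- function(layer) {
  c(nn_params(layer$stem), nn_params(layer$stage1), nn_params(layer$stage2),
    nn_params(layer$stage3), nn_params(layer$stage4))
}
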