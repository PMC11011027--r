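# Inverted feature pyramid: bottom-up fusion of the backbone stage maps
# C1..C4 into P1..P3, parallel merge of P3 with C4, and global average
# pooling into the global descriptor.

#' Create an inverted feature pyramid module
#'
#' The module fuses the four backbone stage maps bottom-up: at each level the
#' previous map is projected (stride-2 3x3 convolution + batch norm, or
#' stride 1 at the last level where C3 and C4 already share spatial size) to
#' the next stage's channel width, added to the stage map, passed through a
#' 3x3 fusion convolution and a ReLU. The final map P3 is merged with C4 and
#' average-pooled into the global feature.
#'
#' @param widths Stage channel widths, e.g. `c(256, 512, 1024, 2048)` for the
#'   full profile.
#' @param merge How P3 and C4 are combined before pooling: `"sum"`
#'   (elementwise, keeps the stage-4 width and is the default — the pooled
#'   global feature then has exactly the stage-4 channel count) or
#'   `"concat_reduce"` (channel concatenation followed by a learned 1x1
#'   reduction back to the stage-4 width).
#' @return An object of class `reid_ifpm`.
#' @export
new_ifpm <- function(widths = c(256L, 512L, 1024L, 2048L),
                     merge = c("sum", "concat_reduce")) {
  merge <- match.arg(merge)
  w <- as.integer(widths)
  stopifnot(length(w) == 4L)
  mod <- new_layer("reid_ifpm",
                   down1 = new_conv2d(w[1], w[2], 3L, stride = 2L, bias = FALSE),
                   dbn1 = new_batchnorm2d(w[2]),
                   fuse1 = new_conv2d(w[2], w[2], 3L),
                   down2 = new_conv2d(w[2], w[3], 3L, stride = 2L, bias = FALSE),
                   dbn2 = new_batchnorm2d(w[3]),
                   fuse2 = new_conv2d(w[3], w[3], 3L),
                   down3 = new_conv2d(w[3], w[4], 3L, stride = 1L, bias = FALSE),
                   dbn3 = new_batchnorm2d(w[4]),
                   fuse3 = new_conv2d(w[4], w[4], 3L),
                   reduce = if (merge == "concat_reduce") {
                     new_conv2d(2L * w[4], w[4], 1L)
                   } else NULL,
                   widths = w, merge = merge)
  mod
}

#' @exportS3Method
nn_params.reid_ifpm <- function(layer) {
  out <- c(nn_params(layer$down1), nn_params(layer$dbn1), nn_params(layer$fuse1),
           nn_params(layer$down2), nn_params(layer$dbn2), nn_params(layer$fuse2),
           nn_params(layer$down3), nn_params(layer$dbn3), nn_params(layer$fuse3))
  if (!is.null(layer$reduce)) out <- c(out, nn_params(layer$reduce))
  out
}

#' Project a stage map to the next pyramid level's shape
#'
#' Stride-2 (or stride-1 when the spatial dims already match, as at the
#' C3->C4 level) 3x3 convolution with batch normalisation, mapping to the
#' target channel width. A learned projection is required because the target
#' channel count differs from the input's.
#'
#' @param x Feature map, `(h, w, c, B)` array.
#' @param target_channels Output channel count.
#' @param target_hw Integer pair `(h', w')`; must equal the input spatial
#'   dims or exactly half of them.
#' @param layers Optional list with components `conv` and `bn` (as built by
#'   this function on first use) so weights can be pinned; if `NULL`, freshly
#'   initialised layers are created.
#' @param train Logical; use batch statistics in the normalisation.
#' @return The projected map, with the layers used attached as attribute
#'   `"layers"`.
#' @export
downsample_project <- function(x, target_channels, target_hw, layers = NULL,
                               train = FALSE) {
  d <- dim(x)
  hw <- as.integer(target_hw)
  stopifnot(length(hw) == 2L)
  if (all(hw == d[1:2])) {
    stride <- 1L
  } else if (all(hw * 2L == d[1:2])) {
    stride <- 2L
  } else {
    stop(sprintf("target spatial dims (%d, %d) are neither equal to nor exactly half of (%d, %d)",
                 hw[1], hw[2], d[1], d[2]))
  }
  if (is.null(layers)) {
    layers <- list(conv = new_conv2d(d[3], as.integer(target_channels), 3L,
                                     stride = stride, bias = FALSE),
                   bn = new_batchnorm2d(as.integer(target_channels)))
  }
  r1 <- nn_forward(layers$conv, x, train)
  r2 <- nn_forward(layers$bn, r1$out, train)
  structure(r2$out, layers = layers)
}

#' Fuse a projected pyramid map with the next stage map
#'
#' Adds the two maps (which must have identical shape), applies a 3x3
#' convolution and a ReLU. The output is elementwise non-negative.
#'
#' @param p_prev Projected map from the previous level.
#' @param c_next Backbone stage map at this level.
#' @param conv Optional pinned 3x3 convolution layer; created if `NULL`.
#' @return The fused non-negative map, layers attached as attribute.
#' @export
fuse_level <- function(p_prev, c_next, conv = NULL) {
  if (!identical(dim(p_prev), dim(c_next))) {
    stop("fuse_level: shape mismatch between the projected map and the stage map")
  }
  if (is.null(conv)) conv <- new_conv2d(dim(c_next)[3], dim(c_next)[3], 3L)
  r <- nn_forward(conv, p_prev + c_next, FALSE)
  structure(r$out * (r$out > 0), layers = conv)
}

# Full pyramid forward with caches (internal; used by the model).
ifpm_forward <- function(mod, stages, train = FALSE) {
  ca <- list()
  f <- function(layer, x) {
    r <- nn_forward(layer, x, train)
    ca[[length(ca) + 1L]] <<- r$cache
    r$out
  }
  # level 1: C1 -> C2's shape
  d1 <- f(mod$dbn1, f(mod$down1, stages$C1))
  a1 <- d1 + stages$C2
  f1 <- f(mod$fuse1, a1)
  P1 <- f1 * (f1 > 0)
  # level 2
  d2 <- f(mod$dbn2, f(mod$down2, P1))
  a2 <- d2 + stages$C3
  f2 <- f(mod$fuse2, a2)
  P2 <- f2 * (f2 > 0)
  # level 3 (stride 1: C3 and C4 share spatial size)
  d3 <- f(mod$dbn3, f(mod$down3, P2))
  a3 <- d3 + stages$C4
  f3 <- f(mod$fuse3, a3)
  P3 <- f3 * (f3 > 0)
  if (mod$merge == "sum") {
    fused <- P3 + stages$C4
    rc <- NULL
  } else {
    d <- dim(P3)
    cat_in <- array(0, c(d[1], d[2], 2L * d[3], d[4]))
    cat_in[, , seq_len(d[3]), ] <- P3
    cat_in[, , d[3] + seq_len(d[3]), ] <- stages$C4
    rr <- nn_forward(mod$reduce, cat_in, train)
    fused <- rr$out
    rc <- rr$cache
  }
  f_global <- global_avg_pool(fused)
  list(P1 = P1, P2 = P2, P3 = P3, fused = fused, f_global = f_global,
       cache = list(ops = ca, m1 = f1 > 0, m2 = f2 > 0, m3 = f3 > 0,
                    rc = rc, dC4 = dim(stages$C4)))
}

# Backward through the pyramid. `dfused` is the gradient flowing into the
# merged P3/C4 map (global pooling and local branch both feed it, summed by
# the caller). Returns gradients for C1..C4.
ifpm_backward <- function(mod, dfused, cache) {
  ca <- cache$ops
  i <- length(ca)
  b <- function(layer, d) {
    force(d)  # nested calls must pop their caches before this one
    cc <- ca[[i]]
    i <<- i - 1L
    nn_backward(layer, d, cc)
  }
  if (mod$merge == "sum") {
    dP3 <- dfused
    dC4 <- dfused
  } else {
    dcat <- nn_backward(mod$reduce, dfused, cache$rc)
    C <- cache$dC4[3]
    dP3 <- dcat[, , seq_len(C), , drop = FALSE]
    dC4 <- dcat[, , C + seq_len(C), , drop = FALSE]
    dim(dP3) <- cache$dC4
    dim(dC4) <- cache$dC4
  }
  # level 3
  da3 <- b(mod$fuse3, dP3 * cache$m3)
  dC4 <- dC4 + da3
  dP2 <- b(mod$down3, b(mod$dbn3, da3))
  # level 2
  da2 <- b(mod$fuse2, dP2 * cache$m2)
  dC3 <- da2
  dP1 <- b(mod$down2, b(mod$dbn2, da2))
  # level 1
  da1 <- b(mod$fuse1, dP1 * cache$m1)
  dC2 <- da1
  dC1 <- b(mod$down1, b(mod$dbn1, da1))
  list(C1 = dC1, C2 = dC2, C3 = dC3, C4 = dC4)
}

#' Fuse the stage maps into a feature pyramid
#'
#' Runs the bottom-up fusion path over a set of stage features and returns
#' the pyramid maps together with the merged map and the pooled global
#' feature.
#'
#' @param ifpm Module from [new_ifpm()].
#' @param stages `stage_features` from [extract_stages()].
#' @param train Logical; batch-statistics mode.
#' @return List of class `pyramid_features` with `P1`, `P2`, `P3` (elementwise
#'   non-negative maps whose shapes match `C2`, `C3`, `C4`), `fused`
#'   (the merged P3/C4 map) and `f_global` (`B x channels` matrix).
#' @export
build_pyramid <- function(ifpm, stages, train = FALSE) {
  stopifnot(inherits(ifpm, "reid_ifpm"))
  for (nm in c("C1", "C2", "C3", "C4")) {
    if (is.null(stages[[nm]])) stop("stages must contain maps C1..C4")
  }
  r <- ifpm_forward(ifpm, stages, train)
  out <- r[c("P1", "P2", "P3", "fused", "f_global")]
  class(out) <- "pyramid_features"
  if (train) attr(out, "cache") <- r$cache
  out
}

#' Merge the top pyramid map with the final stage map and pool
#'
#' Connects `P3` and `C4` in parallel by elementwise sum (preserving the
#' stage-4 channel count) and spatially averages the merged map into the
#' global feature vector. The merged map is also what the local branch
#' consumes.
#'
#' @param p3 Top pyramid map, `(h, w, c, B)`.
#' @param c4 Final backbone stage map, same shape.
#' @return List with `f_global` (`B x c` matrix) and `fused` (the merged map).
#' @export
pool_global <- function(p3, c4) {
  if (!identical(dim(p3), dim(c4))) {
    stop("pool_global: P3 and C4 must have identical shapes")
  }
  fused <- p3 + c4
  list(f_global = global_avg_pool(fused), fused = fused)
}
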