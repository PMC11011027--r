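# Local attention enhancement: split the fused global map into horizontal
# part blocks, reduce each to the local width, apply channel + spatial
# (dual-domain) attention, ReLU, and concatenate into the local descriptor.

#' Split a feature map into left-to-right part blocks
#'
#' Partitions the width axis into `n_blocks` contiguous, equally wide blocks.
#' Concatenating the blocks along width restores the input exactly.
#'
#' @param fused_map `(h, w, c, B)` array.
#' @param n_blocks Number of blocks (default 4).
#' @return List of `n_blocks` maps, each `(h, w / n_blocks, c, B)`.
#' @export
split_blocks <- function(fused_map, n_blocks = 4L) {
  d <- dim(fused_map)
  if (is.null(d) || length(d) != 4L) stop("fused_map must be a 4-d array")
  if (d[2] %% n_blocks != 0L) {
    stop(sprintf("width %d is not divisible into %d equal blocks", d[2], n_blocks))
  }
  wb <- d[2] %/% n_blocks
  lapply(seq_len(n_blocks), function(i) {
    fused_map[, (i - 1L) * wb + seq_len(wb), , , drop = FALSE]
  })
}

#' Create a channel + spatial attention unit
#'
#' Holds the layers of one dual-domain attention gate: the shared two-layer
#' channel MLP (hidden width `C / reduction`) applied to the average- and
#' max-pooled channel vectors, and the `k x k` spatial convolution applied to
#' the channelwise mean/max planes. Used by [cbam()] and shared across the
#' local part blocks.
#'
#' @param channels Channel count of the maps the unit will gate.
#' @param reduction Channel MLP bottleneck ratio (default 16); `channels`
#'   must be divisible by it.
#' @param kernel Spatial attention kernel size; must be odd (default 7).
#' @return List of layers (`ca_fc1`, `ca_fc2`, `sa`).
#' @export
new_attention_unit <- function(channels, reduction = 16L, kernel = 7L) {
  if (channels < reduction || channels %% reduction != 0L) {
    stop(sprintf("channel count %d is not divisible by the reduction ratio %d",
                 channels, reduction))
  }
  if (kernel %% 2L == 0L) stop("spatial attention kernel must be odd")
  hidden <- channels %/% reduction
  list(ca_fc1 = new_linear(channels, hidden),
       ca_fc2 = new_linear(hidden, channels),
       sa = new_conv2d(2L, 1L, as.integer(kernel)))
}

attention_unit_params <- function(unit) {
  out <- c(nn_params(unit$ca_fc1), nn_params(unit$ca_fc2), nn_params(unit$sa))
  if (!is.null(unit$reduce)) out <- c(out, nn_params(unit$reduce))
  out
}

# ---- channel attention -----------------------------------------------------

ca_forward <- function(unit, x, train = FALSE) {
  a <- global_avg_pool(x)
  mp <- global_max_pool(x)
  r1a <- nn_forward(unit$ca_fc1, a, train)
  ha <- r1a$out * (r1a$out > 0)
  r2a <- nn_forward(unit$ca_fc2, ha, train)
  r1m <- nn_forward(unit$ca_fc1, mp$out, train)
  hm <- r1m$out * (r1m$out > 0)
  r2m <- nn_forward(unit$ca_fc2, hm, train)
  gate <- sigmoid(r2a$out + r2m$out)
  list(gate = gate,
       cache = list(d = dim(x), mp = mp, gate = gate,
                    c1a = r1a$cache, ma = r1a$out > 0, c2a = r2a$cache,
                    c1m = r1m$cache, mm = r1m$out > 0, c2m = r2m$cache))
}

ca_backward <- function(unit, dgate, cache) {
  ds <- dgate * cache$gate * (1 - cache$gate)
  da <- nn_backward(unit$ca_fc1,
                    nn_backward(unit$ca_fc2, ds, cache$c2a) * cache$ma,
                    cache$c1a)
  dm <- nn_backward(unit$ca_fc1,
                    nn_backward(unit$ca_fc2, ds, cache$c2m) * cache$mm,
                    cache$c1m)
  global_avg_pool_bwd(da, cache$d) + global_max_pool_bwd(dm, cache$mp)
}

#' Channel attention gate
#'
#' Computes `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared
#' two-layer MLP of hidden width `C / reduction`. Every gate value lies
#' strictly in (0, 1).
#'
#' @param x Feature map `(h, w, C, B)`.
#' @param reduction Bottleneck ratio; `C` must be divisible by it.
#' @param unit Optional pinned attention unit from [new_attention_unit()].
#' @return `B x C` gate matrix with the unit attached as attribute `"unit"`.
#' @export
channel_attention <- function(x, reduction = 16L, unit = NULL) {
  d <- dim(x)
  if (is.null(unit)) unit <- new_attention_unit(d[3], reduction = reduction)
  r <- ca_forward(unit, x)
  structure(r$gate, unit = unit)
}

# ---- spatial attention -----------------------------------------------------

sa_forward <- function(unit, x, train = FALSE) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  planes <- array(0, c(d[1], d[2], 2L, B))
  max_idx <- matrix(0L, HW, B)
  for (b in seq_len(B)) {
    m <- matrix(x[, , , b], HW, C)
    planes[, , 1L, b] <- rowMeans(m)
    j <- max.col(m, ties.method = "first")
    max_idx[, b] <- j
    planes[, , 2L, b] <- m[cbind(seq_len(HW), j)]
  }
  r <- nn_forward(unit$sa, planes, train)
  gate <- sigmoid(r$out)
  list(gate = gate,
       cache = list(d = d, conv = r$cache, gate = gate, max_idx = max_idx))
}

sa_backward <- function(unit, dgate, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  dpre <- dgate * cache$gate * (1 - cache$gate)
  dplanes <- nn_backward(unit$sa, dpre, cache$conv)
  dx <- array(0, d)
  for (b in seq_len(B)) {
    dmean <- as.vector(dplanes[, , 1L, b]) / C
    dx[, , , b] <- array(rep(dmean, C), d[1:3])
    dmax <- as.vector(dplanes[, , 2L, b])
    pos <- seq_len(HW) + HW * (cache$max_idx[, b] - 1L) + HW * C * (b - 1L)
    dx[pos] <- dx[pos] + dmax
  }
  dx
}

#' Spatial attention gate
#'
#' Concatenates the channelwise mean and max planes and passes them through a
#' `k x k` convolution and a sigmoid, producing one gate value per spatial
#' position. On a 1x1 map this degenerates to a single scalar gate.
#'
#' @param x Feature map `(h, w, C, B)`.
#' @param kernel Odd kernel size (default 7).
#' @param unit Optional pinned attention unit.
#' @return `(h, w, 1, B)` gate array with the unit attached as attribute.
#' @export
spatial_attention <- function(x, kernel = 7L, unit = NULL) {
  if (kernel %% 2L == 0L) stop("spatial attention kernel must be odd")
  if (is.null(unit)) unit <- new_attention_unit(dim(x)[3], reduction = 1L,
                                                kernel = kernel)
  r <- sa_forward(unit, x)
  structure(r$gate, unit = unit)
}

# ---- composed dual-domain gate --------------------------------------------

expand_channel_gate <- function(gate, d) {
  # gate: B x C -> (H, W, C, B) broadcast
  g <- rep(as.vector(t(gate)), each = d[1] * d[2])
  dim(g) <- d
  g
}

expand_spatial_gate <- function(gate, C) {
  gate[, , rep(1L, C), , drop = FALSE]
}

cbam_forward <- function(unit, x, train = FALSE) {
  d <- dim(x)
  ca <- ca_forward(unit, x, train)
  gc_exp <- expand_channel_gate(ca$gate, d)
  xc <- x * gc_exp
  sa <- sa_forward(unit, xc, train)
  gs_exp <- expand_spatial_gate(sa$gate, d[3])
  out <- xc * gs_exp
  list(out = out,
       cache = list(x = x, xc = xc, gc_exp = gc_exp, gs_exp = gs_exp,
                    ca = ca$cache, sa = sa$cache, d = d))
}

cbam_backward <- function(unit, dout, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  dxc <- dout * cache$gs_exp
  # gradient into the spatial gate: sum over channels of dout * xc
  v <- dout * cache$xc
  dgs <- array(0, c(d[1], d[2], 1L, B))
  for (b in seq_len(B)) {
    dgs[, , 1L, b] <- rowSums(matrix(v[, , , b], HW, C))
  }
  dxc <- dxc + sa_backward(unit, dgs, cache$sa)
  dx <- dxc * cache$gc_exp
  # gradient into the channel gate: sum over space of dxc * x, per (c, b)
  w <- dxc * cache$x
  dgc <- t(matrix(colSums(matrix(w, HW, C * B)), C, B))
  dx + ca_backward(unit, dgc, cache$ca)
}

#' Dual-domain (channel then spatial) attention gating
#'
#' Applies the channel gate first (`F_c = gate_c(F) * F`), then the spatial
#' gate (`F' = gate_s(F_c) * F_c`). Since both gates lie strictly in (0, 1),
#' the output never exceeds the input in magnitude, elementwise.
#'
#' @param x Feature map `(h, w, C, B)`.
#' @param unit Optional pinned attention unit from [new_attention_unit()].
#' @param reduction,kernel Used to build a fresh unit when `unit` is `NULL`.
#' @return The gated map, same shape as `x`, unit attached as attribute.
#' @export
cbam <- function(x, unit = NULL, reduction = 16L, kernel = 7L) {
  if (is.null(unit)) unit <- new_attention_unit(dim(x)[3], reduction, kernel)
  r <- cbam_forward(unit, x)
  structure(r$out, unit = unit)
}

# ---- local branch ----------------------------------------------------------

make_laem_unit <- function(c_in, c_red, reduction, kernel) {
  unit <- new_attention_unit(c_red, reduction = reduction, kernel = kernel)
  unit$reduce <- new_conv2d(c_in, c_red, 1L)
  unit
}

#' Create a local attention enhancement module
#'
#' Builds the local branch applied to the fused global map: a 4-way
#' horizontal block split, per-block reduction (adaptive max pooling to 1x1
#' followed by a 1x1 convolution down to `c_red` channels), a dual-domain
#' attention gate, a ReLU, and concatenation of the enhanced block vectors
#' into the local descriptor of length `n_blocks * c_red`.
#'
#' @param c_in Channel count of the fused map (2048 in the full profile).
#' @param c_red Reduced per-block width (default `c_in / 4`, i.e. 512 in the
#'   full profile, so the local descriptor matches the global width).
#' @param n_blocks Number of horizontal part blocks (default 4).
#' @param reduction Channel-attention bottleneck ratio (default 16).
#' @param kernel Spatial-attention kernel (default 7; degenerate but still
#'   well-defined on the default 1x1 post-pooling maps).
#' @param pool_position `"pre"` (default): pool each block to 1x1 before the
#'   attention gate, as in the printed design; `"post"`: run the gate on the
#'   full-resolution reduced block and pool afterwards (a documented variant,
#'   where spatial attention is non-degenerate).
#' @param shared Share the reduction and attention weights across the four
#'   blocks (default `TRUE`).
#' @return Object of class `reid_laem`.
#' @export
new_laem <- function(c_in, c_red = max(c_in %/% 4L, 1L), n_blocks = 4L,
                     reduction = 16L, kernel = 7L,
                     pool_position = c("pre", "post"), shared = TRUE) {
  pool_position <- match.arg(pool_position)
  n_units <- if (shared) 1L else n_blocks
  units <- lapply(seq_len(n_units), function(i) {
    make_laem_unit(as.integer(c_in), as.integer(c_red), reduction, kernel)
  })
  new_layer("reid_laem", units = units, c_in = as.integer(c_in),
            c_red = as.integer(c_red), n_blocks = as.integer(n_blocks),
            pool_position = pool_position, shared = shared)
}

#' @exportS3Method
nn_params.reid_laem <- function(layer) {
  do.call(c, lapply(layer$units, attention_unit_params))
}

laem_unit <- function(laem, i) {
  if (laem$shared) laem$units[[1L]] else laem$units[[i]]
}

to_1x1_map <- function(vec_bc) {
  # B x C matrix -> (1, 1, C, B) array
  array(as.vector(t(vec_bc)), c(1L, 1L, ncol(vec_bc), nrow(vec_bc)))
}

#' Reduce one part block to the local width
#'
#' Adaptive max pooling to 1x1 followed by a 1x1 convolution from the fused
#' width down to the module's reduced width.
#'
#' @param laem Module from [new_laem()].
#' @param block One part block `(h, w, c_in, B)`.
#' @param train Logical; batch-statistics mode.
#' @return `(1, 1, c_red, B)` map.
#' @export
reduce_block <- function(laem, block, train = FALSE) {
  stopifnot(inherits(laem, "reid_laem"))
  d <- dim(block)
  if (d[3] != laem$c_in) {
    stop(sprintf("block has %d channels, module expects %d", d[3], laem$c_in))
  }
  mp <- global_max_pool(block)
  nn_forward(laem_unit(laem, 1L)$reduce, to_1x1_map(mp$out), train)$out
}

#' Run the local branch on the fused global map
#'
#' @param laem Module from [new_laem()].
#' @param fused_map The merged P3/C4 map from [pool_global()] or
#'   [build_pyramid()].
#' @param train Logical; batch-statistics mode.
#' @return List of class `local_blocks` with `blocks` (the raw split),
#'   `L` (list of enhanced per-block `B x c_red` matrices, non-negative) and
#'   `f_local` (`B x (n_blocks * c_red)` concatenated local descriptor).
#' @export
local_branch <- function(laem, fused_map, train = FALSE) {
  stopifnot(inherits(laem, "reid_laem"))
  blocks <- split_blocks(fused_map, laem$n_blocks)
  caches <- vector("list", laem$n_blocks)
  L <- vector("list", laem$n_blocks)
  for (i in seq_len(laem$n_blocks)) {
    unit <- laem_unit(laem, i)
    if (laem$pool_position == "pre") {
      mp <- global_max_pool(blocks[[i]])
      rr <- nn_forward(unit$reduce, to_1x1_map(mp$out), train)
      cb <- cbam_forward(unit, rr$out, train)
      act <- cb$out * (cb$out > 0)
      L[[i]] <- t(matrix(act, laem$c_red, dim(fused_map)[4]))
      caches[[i]] <- list(mp = mp, red = rr$cache, cb = cb$cache,
                          mask = cb$out > 0, mode = "pre")
    } else {
      rr <- nn_forward(unit$reduce, blocks[[i]], train)
      cb <- cbam_forward(unit, rr$out, train)
      act <- cb$out * (cb$out > 0)
      mp <- global_max_pool(act)
      L[[i]] <- mp$out
      caches[[i]] <- list(mp = mp, red = rr$cache, cb = cb$cache,
                          mask = cb$out > 0, mode = "post")
    }
  }
  out <- list(blocks = blocks, L = L, f_local = do.call(cbind, L))
  class(out) <- "local_blocks"
  attr(out, "cache") <- list(blocks = caches, d = dim(fused_map),
                             wb = dim(fused_map)[2] %/% laem$n_blocks)
  out
}

laem_backward <- function(laem, df_local, cache) {
  d <- cache$d; wb <- cache$wb
  dfused <- array(0, d)
  for (i in seq_len(laem$n_blocks)) {
    unit <- laem_unit(laem, i)
    ci <- cache$blocks[[i]]
    dL <- df_local[, (i - 1L) * laem$c_red + seq_len(laem$c_red), drop = FALSE]
    if (ci$mode == "pre") {
      dact <- array(as.vector(t(dL)), c(1L, 1L, laem$c_red, d[4]))
      dcb <- dact * ci$mask
      dred <- cbam_backward(unit, dcb, ci$cb)
      dpooled <- nn_backward(unit$reduce, dred, ci$red)
      dmp <- t(matrix(dpooled, laem$c_in, d[4]))
      dblock <- global_max_pool_bwd(dmp, ci$mp)
    } else {
      dact <- global_max_pool_bwd(dL, ci$mp) * ci$mask
      dred <- cbam_backward(unit, dact, ci$cb)
      dblock <- nn_backward(unit$reduce, dred, ci$red)
    }
    dfused[, (i - 1L) * wb + seq_len(wb), , ] <- dblock
  }
  dfused
}
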