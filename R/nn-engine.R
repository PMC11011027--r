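#' @useDynLib tigerreid, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft approx
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network engine.
#
# Feature maps are column-major R arrays with dim (H, W, C, B); descriptor
# matrices are B x D. Every layer is an environment carrying its parameters
# and accumulated gradients; `nn_forward()` returns list(out, cache) so a
# layer can be applied several times per step (the local branch shares one
# set of weights across the four part blocks) and `nn_backward()` consumes
# the matching cache and *accumulates* into the gradient slots. Gradients
# are exact (hand-derived); tests check them against finite differences.
# ---------------------------------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

new_layer <- function(class, ...) {
  self <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = self)
  class(self) <- c(class, "nn_layer")
  self
}

#' @keywords internal
nn_forward <- function(layer, x, train = FALSE) UseMethod("nn_forward")
#' @keywords internal
nn_backward <- function(layer, dout, cache) UseMethod("nn_backward")
#' @keywords internal
nn_params <- function(layer) UseMethod("nn_params")

#' @exportS3Method
nn_params.default <- function(layer) list()

param_entry <- function(layer, par, grad, decay = TRUE) {
  list(layer = layer, par = par, grad = grad, decay = decay)
}

zero_grads <- function(params) {
  for (p in params) {
    g <- get(p$grad, envir = p$layer)
    assign(p$grad, g * 0, envir = p$layer)
  }
  invisible(params)
}

# ---- conv2d ----------------------------------------------------------------

new_conv2d <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = TRUE) {
  W <- he_init(c(k, k, c_in, c_out), fan_in = k * k * c_in)
  new_layer("nn_conv2d",
            W = W, b = if (bias) numeric(c_out) else numeric(0),
            gW = W * 0, gb = numeric(if (bias) c_out else 0),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), c_in = c_in, c_out = c_out,
            bias = bias)
}

#' @exportS3Method
nn_forward.nn_conv2d <- function(layer, x, train = FALSE) {
  d <- dim(x)
  if (d[3] != layer$c_in) {
    stop(sprintf("conv2d: channel dimension is %d, expected %d", d[3], layer$c_in))
  }
  y <- conv2d_fwd_cpp(x, as.integer(d), layer$W, dim(layer$W), layer$b,
                      layer$stride, layer$pad)
  list(out = y, cache = list(x = x))
}

#' @exportS3Method
nn_backward.nn_conv2d <- function(layer, dout, cache) {
  g <- conv2d_bwd_cpp(cache$x, as.integer(dim(cache$x)), layer$W, dim(layer$W),
                      dout, layer$stride, layer$pad, layer$bias)
  layer$gW <- layer$gW + g$dW
  if (layer$bias) layer$gb <- layer$gb + g$db
  g$dx
}

#' @exportS3Method
nn_params.nn_conv2d <- function(layer) {
  out <- list(param_entry(layer, "W", "gW", decay = TRUE))
  if (layer$bias) out <- c(out, list(param_entry(layer, "b", "gb", decay = FALSE)))
  out
}

# ---- batch norm ------------------------------------------------------------

# Channel-sum / channel-broadcast helpers for the (H, W, C, B) layout: columns
# of matrix(x, HW, C*B) are ordered with channel cycling fastest within batch.
.chan_sum <- function(v, HW, C, B) {
  cs <- colSums(matrix(v, HW, C * B))
  if (B == 1L) cs else rowSums(matrix(cs, C, B))
}
.chan_expand <- function(s, HW, C, B) {
  rep(rep(s, times = B), each = HW)
}

new_batchnorm2d <- function(c_out, eps = 1e-5, momentum = 0.1) {
  new_layer("nn_batchnorm2d",
            gamma = rep(1, c_out), beta = numeric(c_out),
            ggamma = numeric(c_out), gbeta = numeric(c_out),
            running_mean = numeric(c_out), running_var = rep(1, c_out),
            eps = eps, momentum = momentum, c_out = c_out)
}

#' @exportS3Method
nn_forward.nn_batchnorm2d <- function(layer, x, train = FALSE) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; B <- d[4]; n <- HW * B
  if (train) {
    mu <- .chan_sum(x, HW, C, B) / n
    v <- pmax(.chan_sum(x * x, HW, C, B) / n - mu^2, 0)
    invstd <- 1 / sqrt(v + layer$eps)
    xhat <- (x - .chan_expand(mu, HW, C, B)) * .chan_expand(invstd, HW, C, B)
    m <- layer$momentum
    layer$running_mean <- (1 - m) * layer$running_mean + m * mu
    vu <- if (n > 1) v * n / (n - 1) else v
    layer$running_var <- (1 - m) * layer$running_var + m * vu
  } else {
    invstd <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- (x - .chan_expand(layer$running_mean, HW, C, B)) *
      .chan_expand(invstd, HW, C, B)
  }
  y <- xhat * .chan_expand(layer$gamma, HW, C, B) +
    .chan_expand(layer$beta, HW, C, B)
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, invstd = invstd, d = d, train = train))
}

#' @exportS3Method
nn_backward.nn_batchnorm2d <- function(layer, dout, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; B <- d[4]; n <- HW * B
  xhat <- cache$xhat
  layer$ggamma <- layer$ggamma + .chan_sum(dout * xhat, HW, C, B)
  layer$gbeta <- layer$gbeta + .chan_sum(dout, HW, C, B)
  dxhat <- dout * .chan_expand(layer$gamma, HW, C, B)
  if (cache$train) {
    s1 <- .chan_sum(dxhat, HW, C, B) / n
    s2 <- .chan_sum(dxhat * xhat, HW, C, B) / n
    dx <- .chan_expand(cache$invstd, HW, C, B) *
      (dxhat - .chan_expand(s1, HW, C, B) - xhat * .chan_expand(s2, HW, C, B))
  } else {
    dx <- dxhat * .chan_expand(cache$invstd, HW, C, B)
  }
  dim(dx) <- d
  dx
}

#' @exportS3Method
nn_params.nn_batchnorm2d <- function(layer) {
  list(param_entry(layer, "gamma", "ggamma", decay = FALSE),
       param_entry(layer, "beta", "gbeta", decay = FALSE))
}

# ---- relu ------------------------------------------------------------------

new_relu <- function() new_layer("nn_relu")

#' @exportS3Method
nn_forward.nn_relu <- function(layer, x, train = FALSE) {
  y <- x * (x > 0)
  list(out = y, cache = list(mask = x > 0))
}

#' @exportS3Method
nn_backward.nn_relu <- function(layer, dout, cache) dout * cache$mask

# ---- max pool --------------------------------------------------------------

new_maxpool <- function(k, stride = k, pad = 0L) {
  new_layer("nn_maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

#' @exportS3Method
nn_forward.nn_maxpool <- function(layer, x, train = FALSE) {
  r <- maxpool_fwd_cpp(x, as.integer(dim(x)), layer$k, layer$stride, layer$pad)
  list(out = r$y, cache = list(idx = r$idx, xd = as.integer(dim(x))))
}

#' @exportS3Method
nn_backward.nn_maxpool <- function(layer, dout, cache) {
  maxpool_bwd_cpp(cache$idx, dout, cache$xd)
}

# ---- linear ----------------------------------------------------------------

new_linear <- function(d_in, d_out, bias = TRUE) {
  W <- matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out)
  new_layer("nn_linear",
            W = W, b = if (bias) numeric(d_out) else numeric(0),
            gW = W * 0, gb = numeric(if (bias) d_out else 0),
            d_in = d_in, d_out = d_out, bias = bias)
}

#' @exportS3Method
nn_forward.nn_linear <- function(layer, x, train = FALSE) {
  # x: B x d_in
  y <- x %*% layer$W
  if (layer$bias) y <- sweep(y, 2, layer$b, "+")
  list(out = y, cache = list(x = x))
}

#' @exportS3Method
nn_backward.nn_linear <- function(layer, dout, cache) {
  layer$gW <- layer$gW + crossprod(cache$x, dout)
  if (layer$bias) layer$gb <- layer$gb + colSums(dout)
  dout %*% t(layer$W)
}

#' @exportS3Method
nn_params.nn_linear <- function(layer) {
  out <- list(param_entry(layer, "W", "gW", decay = TRUE))
  if (layer$bias) out <- c(out, list(param_entry(layer, "b", "gb", decay = FALSE)))
  out
}

# ---- sequential container --------------------------------------------------

new_sequential <- function(layers) new_layer("nn_sequential", layers = layers)

#' @exportS3Method
nn_forward.nn_sequential <- function(layer, x, train = FALSE) {
  caches <- vector("list", length(layer$layers))
  for (i in seq_along(layer$layers)) {
    r <- nn_forward(layer$layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, cache = caches)
}

#' @exportS3Method
nn_backward.nn_sequential <- function(layer, dout, cache) {
  for (i in rev(seq_along(layer$layers))) {
    dout <- nn_backward(layer$layers[[i]], dout, cache[[i]])
  }
  dout
}

#' @exportS3Method
nn_params.nn_sequential <- function(layer) {
  do.call(c, lapply(layer$layers, nn_params))
}

# ---- parameter-free pooling helpers ---------------------------------------

# Spatial average of an (H, W, C, B) map -> B x C matrix.
global_avg_pool <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]
  t(matrix(colMeans(matrix(x, HW, d[3] * d[4])), d[3], d[4]))
}

global_avg_pool_bwd <- function(dy, d) {
  HW <- d[1] * d[2]
  dx <- rep(as.vector(t(dy)) / HW, each = HW)
  dim(dx) <- d
  dx
}

# Per-channel spatial max -> list(out = B x C, idx) with argmax cache.
global_max_pool <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; CB <- d[3] * d[4]
  m <- matrix(x, HW, CB)
  idx <- max.col(t(m), ties.method = "first")
  vals <- m[cbind(idx, seq_len(CB))]
  list(out = t(matrix(vals, d[3], d[4])), idx = idx, d = d)
}

global_max_pool_bwd <- function(dy, cache) {
  d <- cache$d; HW <- d[1] * d[2]
  dx <- numeric(prod(d))
  pos <- cache$idx + HW * (seq_along(cache$idx) - 1)
  dx[pos] <- as.vector(t(dy))
  dim(dx) <- d
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Reproducible local RNG scope: evaluates `code` under `seed` and restores the
# caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ks) s <- (s * 1009 + as.double(k) * 61 + 7) %% 2147483647
  as.integer(s)
}
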