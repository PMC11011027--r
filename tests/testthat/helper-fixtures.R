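# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops / closed forms, independent of the package's compiled path.

tr <- asNamespace("tigerreid")

with_seed_test <- function(seed, code) tr$with_seed(seed, code)

# brute-force 2-D convolution over the (H, W, C, B) layout
naive_conv2d <- function(x, W, b = NULL, stride = 1, pad = 0) {
  d <- dim(x); k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, d[4]))
  for (bb in seq_len(d[4])) for (o in seq_len(Cout)) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b) || length(b) == 0) 0 else b[o]
      for (c in seq_len(Cin)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        hh <- (ho - 1) * stride - pad + kh
        ww <- (wo - 1) * stride - pad + kw
        if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2]) {
          acc <- acc + x[hh, ww, c, bb] * W[kh, kw, c, o]
        }
      }
      y[ho, wo, o, bb] <- acc
    }
  }
  y
}

# zero out every parameter of an attention unit (gates then sit at 0.5)
zero_attention_unit <- function(unit) {
  for (l in list(unit$ca_fc1, unit$ca_fc2, unit$sa,
                 if (!is.null(unit$reduce)) unit$reduce)) {
    if (is.null(l)) next
    l$W[] <- 0
    if (length(l$b)) l$b[] <- 0
  }
  unit
}

zero_conv_biases <- function(mod) {
  for (nm in c("fuse1", "fuse2", "fuse3")) {
    if (!is.null(mod[[nm]])) mod[[nm]]$b[] <- 0
  }
  mod
}

rand_map <- function(h, w, c, b = 1, sd = 1) {
  array(stats::rnorm(h * w * c * b, 0, sd), c(h, w, c, b))
}

# independent average-precision oracle: explicit precision-at-rank loop
naive_ap <- function(ranked_labels, query_label) {
  hits <- 0; precs <- c()
  for (r in seq_along(ranked_labels)) {
    if (ranked_labels[r] == query_label) {
      hits <- hits + 1
      precs <- c(precs, hits / r)
    }
  }
  if (length(precs) == 0) return(NA_real_)
  mean(precs)
}

# independent CMC oracle over raw descriptor matrices
naive_cmc_map <- function(desc, labels, k_max) {
  n <- nrow(desc)
  hits <- matrix(FALSE, n, k_max)
  aps <- numeric(n)
  for (q in seq_len(n)) {
    d <- numeric(0); idx <- c()
    for (g in seq_len(n)) {
      if (g == q) next
      s <- 0
      for (j in seq_len(ncol(desc))) s <- s + (desc[q, j] - desc[g, j])^2
      d <- c(d, sqrt(s)); idx <- c(idx, g)
    }
    o <- order(d, seq_along(d))
    rl <- labels[idx[o]]
    for (k in seq_len(k_max)) hits[q, k] <- any(rl[seq_len(min(k, length(rl)))] == labels[q])
    aps[q] <- naive_ap(rl, labels[q])
  }
  list(cmc = colMeans(hits), map = mean(aps, na.rm = TRUE))
}
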