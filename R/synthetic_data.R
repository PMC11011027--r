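# Procedural generator of identity-labelled striped-animal images. Each
# pseudo-animal owns a fixed stripe texture (frequency, phase, angle,
# jaggedness, coat tone); every render varies pose, scale, rotation,
# background and occlusion, so identity is recoverable only from the coat
# pattern. Also provides the training augmentations (random rotation,
# random erasing) and a per-identity 7:3 train/validation split.

# Van der Corput radical-inverse in base 2 over 64 slots: any prefix of the
# identity sequence is spread maximally over the frequency grid, so the
# pairwise frequency separation of the first n identities is at least
# range/2^ceil(log2(n)) (>= range/64 for n <= 64).
vdc64 <- function(i) {
  i <- i %% 64L
  b <- as.integer(intToBits(i))[1:6]
  sum(b * 2^(5:0)) / 64
}

#' Create a reproducible synthetic identity
#'
#' Deterministic in `(id, seed)`. Stripe frequencies are laid out on a
#' 64-slot bit-reversed grid over `freq_range`, which guarantees a minimum
#' pairwise frequency gap of `diff(freq_range)/64` (about 0.16 cycles per
#' body length at the defaults) for up to 64 identities under one seed — and
#' a much larger gap for small identity sets (0.625 cycles for up to 16).
#' Phase, stripe angle, jaggedness and coat tone are drawn per identity.
#'
#' @param id Non-negative integer identity.
#' @param seed Dataset seed; identities from different seeds differ.
#' @param freq_range Stripe frequency range in cycles per body length.
#' @return List of class `synthetic_identity` with fields `id`,
#'   `stripe_frequency`, `stripe_phase`, `stripe_angle` (degrees),
#'   `stripe_jaggedness`, `base_tone` (RGB triple).
#' @export
make_identity <- function(id, seed, freq_range = c(5, 15)) {
  stopifnot(id >= 0)
  span <- diff(freq_range)
  out <- with_seed(derive_seed(seed, 104729L), {
    offset <- stats::runif(1, 0, span / 64)
    offset
  })
  freq <- freq_range[1] + span * vdc64(as.integer(id)) + out
  pars <- with_seed(derive_seed(seed, id, 7919L), {
    list(phase = stats::runif(1, 0, 2 * pi),
         angle = stats::runif(1, -10, 10),
         jag = stats::runif(1, 0.1, 0.5),
         tone = c(stats::runif(1, 0.75, 0.9),
                  stats::runif(1, 0.45, 0.6),
                  stats::runif(1, 0.15, 0.3)))
  })
  structure(list(id = as.integer(id), stripe_frequency = freq,
                 stripe_phase = pars$phase, stripe_angle = pars$angle,
                 stripe_jaggedness = pars$jag, base_tone = pars$tone),
            class = "synthetic_identity")
}

#' Per-render nuisance parameters
#'
#' @param pose_offset `(dx, dy)` pixel offset of the body centre.
#' @param scale Body scale in `[0.8, 1.2]`.
#' @param rotation In-plane rotation in degrees.
#' @param background_seed Integer seed for the procedural background clutter.
#' @param occlusion Optional occlusion box `c(row, col, height, width)`
#'   (1-based, in pixels) or `NULL`.
#' @return List of class `render_spec`.
#' @export
render_spec <- function(pose_offset = c(0, 0), scale = 1, rotation = 0,
                        background_seed = 0L, occlusion = NULL) {
  if (scale < 0.8 || scale > 1.2) stop("scale must lie in [0.8, 1.2]")
  structure(list(pose_offset = pose_offset, scale = scale, rotation = rotation,
                 background_seed = as.integer(background_seed),
                 occlusion = occlusion),
            class = "render_spec")
}

#' Render one synthetic striped-animal image
#'
#' Draws a body-shaped mask (torso ellipse plus head) filled with a
#' sinusoidal-plus-jitter stripe texture at the identity's parameters,
#' composited over seeded procedural background clutter, with optional
#' occlusion. Deterministic for fixed inputs. The body mask is attached as
#' attribute `"mask"` for downstream texture analysis.
#'
#' @param identity A [make_identity()].
#' @param spec A [render_spec()].
#' @param size `(H, W)` in pixels.
#' @return `(H, W, 3)` array in `[0, 1]`.
#' @export
render_image <- function(identity, spec = render_spec(), size = c(64, 128)) {
  stopifnot(inherits(identity, "synthetic_identity"), all(size > 0))
  H <- as.integer(size[1]); W <- as.integer(size[2])
  cy <- H / 2 + spec$pose_offset[2]
  cx <- W / 2 + spec$pose_offset[1]
  th <- spec$rotation * pi / 180
  I <- matrix(seq_len(H), H, W)
  J <- matrix(seq_len(W), H, W, byrow = TRUE)
  xr <- (J - cx); yr <- (I - cy)
  u <- (xr * cos(th) + yr * sin(th)) / spec$scale
  v <- (-xr * sin(th) + yr * cos(th)) / spec$scale
  # body: torso ellipse + head ellipse to the right; sized so the body stays
  # inside the canvas at every admissible scale/offset (no clipping, which
  # would distort mask-normalised texture measurements)
  mask <- (u / (0.26 * W))^2 + (v / (0.26 * H))^2 <= 1 |
    ((u - 0.28 * W) / (0.09 * W))^2 + ((v + 0.05 * H) / (0.13 * H))^2 <= 1
  # stripe coordinate along the body axis, with jagged (wavy) distortion
  ang <- identity$stripe_angle * pi / 180
  uu <- u * cos(ang) + v * sin(ang)
  ww <- -u * sin(ang) + v * cos(ang)
  t <- 2 * pi * identity$stripe_frequency * uu / W + identity$stripe_phase +
    identity$stripe_jaggedness * sin(2 * pi * 2.5 * ww / H + 1.7)
  s <- sin(t)
  wstr <- 1 / (1 + exp(-(s - 0.25) * 8))  # soft stripe indicator
  stripe_col <- c(0.08, 0.07, 0.06)
  img <- with_seed(spec$background_seed, {
    bg <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      fx <- stats::runif(1, 1, 4); fy <- stats::runif(1, 1, 4)
      ph <- stats::runif(1, 0, 2 * pi)
      bg[, , ch] <- 0.45 + 0.22 * sin(2 * pi * (fx * J / W + fy * I / H) + ph) +
        stats::runif(H * W, -0.08, 0.08)
    }
    bg
  })
  for (ch in 1:3) {
    body <- identity$base_tone[ch] * (1 - wstr) + stripe_col[ch] * wstr
    plane <- img[, , ch]
    plane[mask] <- body[mask]
    img[, , ch] <- plane
  }
  if (!is.null(spec$occlusion)) {
    oc <- spec$occlusion
    rows <- oc[1]:min(oc[1] + oc[3] - 1L, H)
    cols <- oc[2]:min(oc[2] + oc[4] - 1L, W)
    img[rows, cols, ] <- 0.5
  }
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- c(H, W, 3L)
  attr(img, "mask") <- mask
  img
}

#' Random rotation augmentation
#'
#' Rotates by an angle drawn uniformly from `[-max_deg, max_deg]` about the
#' image centre, nearest-neighbour resampling, canvas size preserved
#' (out-of-canvas pixels are zero). With `max_deg = 0` the image is returned
#' unchanged.
#'
#' @param image `(H, W, C)` array.
#' @param max_deg Rotation bound in degrees.
#' @param seed Optional seed for a reproducible draw; by default the current
#'   RNG stream is used.
#' @return Rotated image.
#' @export
random_rotation <- function(image, max_deg, seed = NULL) {
  stopifnot(max_deg >= 0)
  if (max_deg == 0) return(image)
  angle <- if (is.null(seed)) {
    stats::runif(1, -max_deg, max_deg)
  } else {
    with_seed(seed, stats::runif(1, -max_deg, max_deg))
  }
  rotate_image(image, angle)
}

#' Rotate an image by a fixed angle
#'
#' @param image `(H, W, C)` array.
#' @param angle Degrees, counter-clockwise in image coordinates.
#' @return Rotated image, same size, nearest-neighbour, zero fill.
#' @export
rotate_image <- function(image, angle) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  I <- matrix(seq_len(H), H, W)
  J <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse mapping: source position of each output pixel
  sj <- round(cx + (J - cx) * cos(th) + (I - cy) * sin(th))
  si <- round(cy - (J - cx) * sin(th) + (I - cy) * cos(th))
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  out <- array(0, d)
  src <- cbind(si[ok], sj[ok])
  dst <- which(ok)
  for (ch in seq_len(d[3])) {
    plane <- matrix(0, H, W)
    plane[dst] <- image[, , ch][src]
    out[, , ch] <- plane
  }
  out
}

#' Random erasing augmentation
#'
#' Replaces one rectangle with uniform noise, simulating occlusion. The
#' rectangle's area fraction is drawn from `area_range` and its aspect ratio
#' from `[0.3, 1/0.3]`; when an integer-sided rectangle of exactly the drawn
#' pixel count fits the canvas, the erased area is exact.
#'
#' @param image `(H, W, C)` array in `[0, 1]`.
#' @param area_range Erased-area fraction range, within (0, 1).
#' @param seed Optional reproducibility seed (default: current RNG stream).
#' @return Image with one noise rectangle.
#' @export
random_erasing <- function(image, area_range = c(0.02, 0.2), seed = NULL) {
  stopifnot(area_range[1] > 0, area_range[2] < 1,
            area_range[1] <= area_range[2])
  run <- function() {
    d <- dim(image)
    H <- d[1]; W <- d[2]
    frac <- stats::runif(1, area_range[1], area_range[2])
    A <- max(1L, round(frac * H * W))
    ratio <- exp(stats::runif(1, log(0.3), log(1 / 0.3)))
    target_h <- sqrt(A * ratio)
    divs <- which(A %% seq_len(min(H, A)) == 0L)
    feas <- divs[A %/% divs <= W]
    if (length(feas) > 0L) {
      rh <- feas[which.min(abs(log(feas / target_h)))]
      rw <- A %/% rh
    } else {
      rh <- max(1L, min(H, round(target_h)))
      rw <- max(1L, min(W, round(A / rh)))
    }
    r0 <- sample.int(H - rh + 1L, 1L)
    c0 <- sample.int(W - rw + 1L, 1L)
    image[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L), ] <-
      stats::runif(rh * rw * d[3])
    image
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a synthetic re-identification dataset
#'
#' Renders `imgs_per_id` images for each of `n_ids` identities with
#' per-image nuisance variation (pose offset, scale, rotation, background
#' clutter, occasional occlusion) and splits each identity's images into
#' train/validation at a 7:3 ratio (train count rounded half-up, so every
#' identity appears in the training split).
#'
#' @param n_ids Number of identities (>= 2).
#' @param imgs_per_id Images per identity (>= 2).
#' @param size `(H, W)` canvas in pixels; `c(64, 128)` suits the desk
#'   profile, `c(256, 512)` the full profile.
#' @param seed Dataset seed; the whole dataset is a pure function of the
#'   arguments.
#' @param dir Optional directory: PNG files plus `manifest.csv` (columns
#'   `path`, `entity_id`, `split`) are written there.
#' @return List of class `reid_dataset` with `manifest` (data.frame),
#'   `images` (named list of `(H, W, 3)` arrays), `identities`, `size`,
#'   `seed`.
#' @export
make_dataset <- function(n_ids, imgs_per_id, size = c(64, 128), seed = 1L,
                         dir = NULL) {
  if (n_ids < 2L) stop("need at least 2 identities")
  if (imgs_per_id < 2L) stop("need at least 2 images per identity to split 7:3")
  H <- size[1]; W <- size[2]
  identities <- lapply(seq_len(n_ids), make_identity, seed = seed)
  rows <- list(); images <- list()
  for (i in seq_len(n_ids)) {
    specs <- with_seed(derive_seed(seed, i, 31L), {
      lapply(seq_len(imgs_per_id), function(k) {
        occ <- NULL
        if (stats::runif(1) < 0.25) {
          oh <- max(2L, round(H * stats::runif(1, 0.2, 0.4)))
          ow <- max(2L, round(W * stats::runif(1, 0.2, 0.4)))
          occ <- c(sample.int(H - oh + 1L, 1L), sample.int(W - ow + 1L, 1L),
                   oh, ow)
        }
        render_spec(
          pose_offset = c(stats::runif(1, -0.05, 0.05) * W,
                          stats::runif(1, -0.05, 0.05) * H),
          scale = stats::runif(1, 0.8, 1.2),
          rotation = stats::runif(1, -8, 8),
          background_seed = sample.int(1000000L, 1L),
          occlusion = occ)
      })
    })
    n_train <- floor(0.7 * imgs_per_id + 0.5)
    if (n_train < 1L) stop("imgs_per_id too small: identity would have no training image")
    tr_idx <- with_seed(derive_seed(seed, i, 57L), sample.int(imgs_per_id, n_train))
    for (k in seq_len(imgs_per_id)) {
      path <- sprintf("id%04d_im%03d.png", i, k)
      images[[path]] <- render_image(identities[[i]], specs[[k]], size)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, entity_id = i,
        split = if (k %in% tr_idx) "train" else "val",
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in names(images)) {
      img <- images[[p]]
      attr(img, "mask") <- NULL
      png::writePNG(img, file.path(dir, p))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(manifest = manifest, images = images,
                 identities = identities, size = size, seed = seed),
            class = "reid_dataset")
}

#' Subset a dataset by split
#'
#' @param dataset A [make_dataset()] result.
#' @param split `"train"` or `"val"`.
#' @return List with `images` (list), `labels` (integer entity ids) and
#'   `ids` (image paths), ready for [train_reid()] / [evaluate_reid()].
#' @export
dataset_split <- function(dataset, split = c("train", "val")) {
  split <- match.arg(split)
  m <- dataset$manifest[dataset$manifest$split == split, ]
  list(images = dataset$images[m$path], labels = m$entity_id, ids = m$path)
}

#' Read a dataset manifest and its images from disk
#'
#' @param dir Directory holding `manifest.csv` (columns `path`, `entity_id`,
#'   `split`) and PNG files.
#' @return `reid_dataset`-like list with `manifest` and `images`.
#' @export
read_manifest <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  req <- c("path", "entity_id", "split")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns path, entity_id, split")
  }
  images <- lapply(manifest$path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  names(images) <- manifest$path
  structure(list(manifest = manifest, images = images),
            class = "reid_dataset")
}

#' Dominant stripe frequency of a rendered image
#'
#' Measures the spectral peak of the body texture in cycles per body length:
#' the grayscale profile across the body (column means within the body
#' mask's bounding box) is resampled to a fixed length, demeaned,
#' zero-padded and Fourier-transformed; the peak magnitude bin is converted
#' back to cycles per body length. Normalising by the mask extent makes the
#' estimate invariant to render scale.
#'
#' @param image Rendered image carrying a `"mask"` attribute (see
#'   [render_image()]), or supply `mask` explicitly.
#' @param mask Optional logical `(H, W)` body mask.
#' @param n_resample,n_fft Resampled profile length and zero-padded FFT size.
#' @return Peak frequency (cycles per body length).
#' @export
stripe_peak_frequency <- function(image, mask = NULL, n_resample = 256L,
                                  n_fft = 2048L) {
  mask <- mask %||% attr(image, "mask")
  if (is.null(mask)) stop("no body mask available")
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  cols <- which(colSums(mask) > 0)
  profile <- vapply(cols, function(j) {
    rows <- mask[, j]
    mean(gray[rows, j])
  }, numeric(1))
  xs <- seq(0, 1, length.out = length(profile))
  rs <- stats::approx(xs, profile, xout = seq(0, 1, length.out = n_resample))$y
  rs <- rs - mean(rs)
  spec <- Mod(stats::fft(c(rs, numeric(n_fft - n_resample))))
  half <- spec[2:(n_fft %/% 2)]
  peak_bin <- which.max(half)  # bin k -> k cycles over the padded window
  peak_bin * n_resample / n_fft
}

#' Spectral stripe feature vector for identity discrimination
#'
#' Normalised magnitude spectrum (low-frequency bins) of the resampled body
#' profile; a nearest-neighbour classifier over these features separates
#' synthetic identities, which is the learnability guarantee behind the
#' training benchmarks.
#'
#' @inheritParams stripe_peak_frequency
#' @param n_bins Number of leading spectrum bins to keep.
#' @return Numeric feature vector of length `n_bins`.
#' @export
stripe_spectrum_feature <- function(image, mask = NULL, n_resample = 256L,
                                    n_fft = 2048L, n_bins = 220L) {
  mask <- mask %||% attr(image, "mask")
  if (is.null(mask)) stop("no body mask available")
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  cols <- which(colSums(mask) > 0)
  profile <- vapply(cols, function(j) mean(gray[mask[, j], j]), numeric(1))
  xs <- seq(0, 1, length.out = length(profile))
  rs <- stats::approx(xs, profile, xout = seq(0, 1, length.out = n_resample))$y
  rs <- rs - mean(rs)
  spec <- Mod(stats::fft(c(rs, numeric(n_fft - n_resample))))
  f <- spec[2:(n_bins + 1L)]
  f / sqrt(sum(f^2) + 1e-12)
}
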