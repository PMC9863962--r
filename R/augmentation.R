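# Random-combination batch augmentation: each tile independently receives a
# randomly sampled composition of the enabled operations, on the fly, so the
# same tile yields different views in different batches and nothing is ever
# written to disk.

AUGMENT_OPS <- c("random_flip", "random_rotation", "horizontal_flip",
                 "vertical_flip", "saturation_jitter", "gaussian_noise",
                 "contour_extract", "smoothing")

#' Augmentation configuration
#'
#' @param enabled_ops subset of the supported operation names (default all):
#'   random flip, random rotation, horizontal/vertical flip, saturation
#'   jitter, Gaussian noise, contour extraction, smoothing.
#' @param probs per-op inclusion probability; either a single value applied
#'   to all ops or a named vector (default 0.5 each).
#' @param rotation_degrees maximum rotation magnitude in degrees, in (0, 180].
#' @param ortho_rotations if TRUE, random rotations are exact multiples of 90
#'   degrees instead of arbitrary angles with reflection padding.
#' @param saturation_range multiplicative saturation factor range.
#' @param noise_sigma Gaussian noise standard deviation (pixel units of the
#'   tile's value range).
#' @param contour_weight blend weight of the edge-magnitude map in \[0, 1\].
#' @param smoothing_sigma Gaussian smoothing scale in pixels.
#' @param seed default seed for [augment_batch()].
#' @return an `augment_config` list.
#' @export
augment_config <- function(enabled_ops = AUGMENT_OPS, probs = 0.5,
                           rotation_degrees = 30, ortho_rotations = FALSE,
                           saturation_range = c(0.7, 1.3),
                           noise_sigma = 0.03, contour_weight = 0.5,
                           smoothing_sigma = 1, seed = 1L) {
  unknown <- setdiff(enabled_ops, AUGMENT_OPS)
  if (length(unknown))
    stop("unknown augmentation op(s): ", paste(unknown, collapse = ", "))
  if (length(probs) == 1L) probs <- stats::setNames(rep(probs,
                                                        length(enabled_ops)),
                                                    enabled_ops)
  if (is.null(names(probs)) || !all(enabled_ops %in% names(probs)))
    stop("probs must be a single value or named for every enabled op")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (rotation_degrees <= 0 || rotation_degrees > 180)
    stop("rotation_degrees must lie in (0, 180]")
  structure(list(enabled_ops = enabled_ops, probs = probs[enabled_ops],
                 rotation_degrees = rotation_degrees,
                 ortho_rotations = ortho_rotations,
                 saturation_range = saturation_range,
                 noise_sigma = noise_sigma,
                 contour_weight = contour_weight,
                 smoothing_sigma = smoothing_sigma, seed = as.integer(seed)),
            class = "augment_config")
}

#' Additive Gaussian pixel noise
#'
#' Adds zero-mean Gaussian noise and clips to the valid pixel range. The
#' range is taken as \[0, 1\] for unit-scaled tiles and \[0, 255\] for 8-bit
#' scaled tiles (or pass `range_max` explicitly).
#'
#' @param tile numeric array.
#' @param sigma noise standard deviation (same units as the tile); `>= 0`.
#' @param range_max clipping ceiling; inferred from the tile when `NULL`.
#' @return noisy tile, same shape, clipped to \[0, range_max\].
#' @export
gaussian_noise <- function(tile, sigma, range_max = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(range_max)) range_max <- if (max(tile) > 1.5) 255 else 1
  if (sigma == 0) return(tile)
  out <- tile + stats::rnorm(length(tile), sd = sigma)
  out[out < 0] <- 0
  out[out > range_max] <- range_max
  out
}

flip_v <- function(tile) tile[rev(seq_len(nrow(tile))), , , drop = FALSE]
flip_h <- function(tile) tile[, rev(seq_len(ncol(tile))), , drop = FALSE]

rotate_ortho <- function(tile, quarters) {
  q <- quarters %% 4L
  if (q == 0L) return(tile)
  out <- tile
  for (i in seq_len(q)) {
    d <- dim(out)
    rot <- array(0, dim = c(d[2L], d[1L], d[3L]))
    for (ch in seq_len(d[3L])) rot[, , ch] <- t(out[rev(seq_len(d[1L])), , ch])
    out <- rot
  }
  out
}

pad_reflect <- function(tile, p) {
  d <- dim(tile)
  ri <- c(rev(seq_len(p) + 1L), seq_len(d[1L]), d[1L] - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(d[2L]), d[2L] - seq_len(p))
  tile[ri, ci, , drop = FALSE]
}

rotate_any <- function(tile, angle) {
  d <- dim(tile)
  p <- ceiling(0.30 * max(d[1:2]))
  padded <- pad_reflect(tile, p)
  img <- EBImage::Image(aperm(padded, c(2L, 1L, 3L)), colormode = "Color")
  rot <- EBImage::rotate(img, angle, output.dim = dim(padded)[2:1])
  arr <- aperm(EBImage::imageData(rot), c(2L, 1L, 3L))
  out <- arr[p + seq_len(d[1L]), p + seq_len(d[2L]), , drop = FALSE]
  pmin(pmax(out, 0), max(1, max(tile)))
}

adjust_saturation <- function(tile, factor) {
  lum <- 0.299 * tile[, , 1L] + 0.587 * tile[, , 2L] + 0.114 * tile[, , 3L]
  out <- tile
  for (ch in 1:3) out[, , ch] <- lum + factor * (tile[, , ch] - lum)
  pmin(pmax(out, 0), max(1, max(tile)))
}

sobel_edges <- function(tile) {
  lum <- 0.299 * tile[, , 1L] + 0.587 * tile[, , 2L] + 0.114 * tile[, , 3L]
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(lum, kx, boundary = "replicate")
  gy <- EBImage::filter2(lum, t(kx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) > 0) mag <- mag / max(mag)
  as.matrix(mag)
}

contour_extract <- function(tile, weight) {
  edges <- sobel_edges(tile)
  out <- tile
  for (ch in 1:3) out[, , ch] <- (1 - weight) * tile[, , ch] + weight * edges
  out
}

smooth_tile <- function(tile, sigma) {
  out <- tile
  for (ch in 1:3)
    out[, , ch] <- as.matrix(EBImage::gblur(tile[, , ch], sigma = sigma,
                                            boundary = "replicate"))
  out
}

apply_one_op <- function(tile, op, cfg) {
  switch(op,
    random_flip = if (stats::runif(1) < 0.5) flip_h(tile) else flip_v(tile),
    random_rotation = if (cfg$ortho_rotations)
      rotate_ortho(tile, sample(1:3, 1)) else
      rotate_any(tile, stats::runif(1, -cfg$rotation_degrees,
                                    cfg$rotation_degrees)),
    horizontal_flip = flip_h(tile),
    vertical_flip = flip_v(tile),
    saturation_jitter = adjust_saturation(
      tile, stats::runif(1, cfg$saturation_range[1], cfg$saturation_range[2])),
    gaussian_noise = gaussian_noise(tile, cfg$noise_sigma),
    contour_extract = contour_extract(tile, cfg$contour_weight),
    smoothing = smooth_tile(tile, cfg$smoothing_sigma),
    stop("unknown op: ", op))
}

#' Augment a batch of RGB tiles with a random composition of operations
#'
#' Each tile independently includes each enabled operation with its
#' configured probability, applied in the fixed listing order. Output shape
#' equals input shape; deterministic given `rng_seed`; labels and masks are
#' never touched.
#'
#' @param batch (H, W, 3, N) array or list of (H, W, 3) arrays.
#' @param cfg an [augment_config()].
#' @param rng_seed seed controlling all sampling (default `cfg$seed`).
#' @return augmented batch in the same container type.
#' @export
augment_batch <- function(batch, cfg, rng_seed = cfg$seed) {
  as_list <- is.list(batch)
  tiles <- if (as_list) batch else
    lapply(seq_len(dim(batch)[4L]), function(i) batch[, , , i, drop = TRUE])
  dims <- lapply(tiles, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L)
    stop("tiles must share one shape")
  out <- with_seed(rng_seed, lapply(tiles, function(tile) {
    d0 <- dim(tile)
    for (op in cfg$enabled_ops) {
      if (stats::runif(1) < cfg$probs[[op]]) tile <- apply_one_op(tile, op, cfg)
    }
    stopifnot(identical(dim(tile), d0))
    tile
  }))
  if (as_list) return(out)
  res <- array(0, dim = dim(batch))
  for (i in seq_along(out)) res[, , , i] <- out[[i]]
  res
}
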