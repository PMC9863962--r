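# Slide tiling: sliding-window enumeration, the strict >3/4 lesion-coverage
# rule, the encoded-size cleaning rule, and train-set normalization.

#' Tiling specification
#'
#' @param patch_size window side in pixels (default 512).
#' @param stride window step in pixels, `0 < stride <= patch_size`
#'   (default 256, i.e. 50% overlap).
#' @param coverage_threshold windows are kept only when the lesion-mask
#'   fraction is strictly greater than this (default 3/4).
#' @param min_encoded_bytes tiles whose encoded size is below this are
#'   discarded (default 330 * 1024). Set 0 to disable. When `patch_size`
#'   differs from 512 the effective threshold scales by `(patch_size/512)^2`.
#' @param codec tile encoding used for the size rule; `"png"` is supported
#'   (`"jpeg-q95"` is part of the interface but not available in this build).
#' @param filter_mode `"encoded_size"` (default) or `"tissue_fraction"`, an
#'   alternative cleaning rule keeping tiles whose non-background fraction is
#'   at least `min_tissue_fraction`.
#' @param min_tissue_fraction used by `filter_mode = "tissue_fraction"`.
#' @return a `patch_spec` list.
#' @export
patch_spec <- function(patch_size = 512L, stride = 256L,
                       coverage_threshold = 3 / 4,
                       min_encoded_bytes = 330L * 1024L,
                       codec = c("png", "jpeg-q95"),
                       filter_mode = c("encoded_size", "tissue_fraction"),
                       min_tissue_fraction = 0.1) {
  codec <- match.arg(codec)
  filter_mode <- match.arg(filter_mode)
  if (stride <= 0 || stride > patch_size)
    stop("require 0 < stride <= patch_size")
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stop("require 0 < coverage_threshold <= 1")
  if (min_encoded_bytes < 0) stop("min_encoded_bytes must be >= 0")
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 coverage_threshold = coverage_threshold,
                 min_encoded_bytes = as.numeric(min_encoded_bytes),
                 codec = codec, filter_mode = filter_mode,
                 min_tissue_fraction = min_tissue_fraction),
            class = "patch_spec")
}

#' Enumerate fully-contained sliding windows
#'
#' Origins are 0-based top-left corners `(i * stride, j * stride)` of
#' half-open windows `[r, r + patch_size) x [c, c + patch_size)` that lie
#' entirely inside the image; incomplete edge windows are dropped, matching a
#' tiling that never pads. Row-major order (rows outer).
#'
#' @param height,width image dimensions in pixels.
#' @param spec a [patch_spec()].
#' @return data.frame with 0-based `row`, `col` origins (possibly 0 rows,
#'   with a warning, when no window fits).
#' @export
enumerate_windows <- function(height, width, spec) {
  ps <- spec$patch_size
  if (height < ps || width < ps) {
    warning(sprintf("image %dx%d smaller than patch size %d: no windows",
                    height, width, ps))
    return(data.frame(row = integer(0), col = integer(0)))
  }
  rows <- seq.int(0L, height - ps, by = spec$stride)
  cols <- seq.int(0L, width - ps, by = spec$stride)
  data.frame(row = rep(rows, each = length(cols)),
             col = rep(cols, times = length(rows)))
}

#' Extract lesion patches from a slide under the strict coverage rule
#'
#' Every enumerated window is scored by its lesion coverage (fraction of
#' mask = 1 pixels); a window is retained only when coverage is strictly
#' greater than `spec$coverage_threshold` ("more than 3/4"), so a window at
#' exactly the threshold is discarded. The patch label is the slide label.
#'
#' @param slide a `wsi_record` (image and mask aligned).
#' @param spec a [patch_spec()].
#' @return list of `patch_record`s (fields `pixels`, `origin` (0-based
#'   row, col), `coverage`, `label`, `slide_id`), with attributes
#'   `n_windows` and `n_discarded_coverage`.
#' @export
extract_patches <- function(slide, spec) {
  if (!identical(dim(slide$mask), dim(slide$image)[1:2]))
    stop("image/mask shape mismatch")
  ps <- spec$patch_size
  wins <- enumerate_windows(nrow(slide$mask), ncol(slide$mask), spec)
  out <- vector("list", nrow(wins))
  kept <- 0L
  for (i in seq_len(nrow(wins))) {
    r <- wins$row[i]; cc <- wins$col[i]
    cov <- mean(slide$mask[(r + 1L):(r + ps), (cc + 1L):(cc + ps)])
    if (cov > spec$coverage_threshold) {
      kept <- kept + 1L
      out[[kept]] <- structure(
        list(pixels = slide$image[(r + 1L):(r + ps), (cc + 1L):(cc + ps), ,
                                  drop = FALSE],
             origin = c(row = r, col = cc), coverage = cov,
             label = slide$label, slide_id = slide$slide_id),
        class = "patch_record")
    }
  }
  out <- out[seq_len(kept)]
  attr(out, "n_windows") <- nrow(wins)
  attr(out, "n_discarded_coverage") <- nrow(wins) - kept
  out
}

effective_min_bytes <- function(spec) {
  spec$min_encoded_bytes * (spec$patch_size / 512)^2
}

#' Encoded-size cleaning rule for one patch
#'
#' Encodes the tile with `spec$codec` and discards it when the encoded byte
#' length falls below the (patch-size-scaled) `min_encoded_bytes`. Tiles with
#' little tissue compress to small files, so this removes near-empty tiles.
#'
#' @param patch a `patch_record`.
#' @param spec a [patch_spec()].
#' @return list with `keep` (logical), `bytes` (encoded length) and
#'   `threshold` (the effective byte threshold applied).
#' @export
size_filter <- function(patch, spec) {
  if (spec$filter_mode == "tissue_fraction") {
    lum <- 0.299 * patch$pixels[, , 1L] + 0.587 * patch$pixels[, , 2L] +
      0.114 * patch$pixels[, , 3L]
    frac <- mean(lum < 0.95)
    return(list(keep = frac >= spec$min_tissue_fraction, bytes = NA_real_,
                threshold = spec$min_tissue_fraction))
  }
  if (spec$codec != "png")
    stop(sprintf("codec '%s' is not available; use 'png'", spec$codec))
  bytes <- tryCatch(length(png::writePNG(patch$pixels, raw())),
                    error = function(e) {
                      warning("codec failure; patch discarded: ",
                              conditionMessage(e))
                      -1
                    })
  if (bytes < 0) return(list(keep = FALSE, bytes = NA_real_,
                             threshold = effective_min_bytes(spec)))
  thr <- effective_min_bytes(spec)
  list(keep = bytes >= thr, bytes = bytes, threshold = thr)
}

#' Fit per-channel normalization statistics on training patches
#'
#' Mean and standard deviation per RGB channel over the training collection
#' only; validation/test data reuse these statistics, so no information leaks
#' across the split.
#'
#' @param train_patches list of `patch_record`s, or a (H, W, 3, N) array.
#' @return `normalization_stats` list: `mean`, `sd` (length-3), `computed_over`.
#' @export
fit_normalization <- function(train_patches) {
  x <- if (is.array(train_patches)) train_patches else
    patches_to_array(train_patches)
  if (length(x) == 0) stop("empty training collection")
  mu <- sd <- numeric(3)
  for (ch in 1:3) {
    v <- as.vector(x[, , ch, , drop = FALSE])
    mu[ch] <- mean(v)
    sd[ch] <- stats::sd(v)
  }
  if (any(sd <= 1e-12))
    stop("zero-variance channel(s): ", paste(which(sd <= 1e-12), collapse = ", "),
         "; cannot standardize")
  ids <- if (is.array(train_patches)) character(0) else
    unique(vapply(train_patches, function(p) p$slide_id, character(1)))
  structure(list(mean = mu, sd = sd, computed_over = ids),
            class = "normalization_stats")
}

#' Apply normalization statistics to an image array
#' @param x (H, W, 3) or (H, W, 3, N) array.
#' @param stats a `normalization_stats`.
#' @return standardized array of the same shape.
#' @export
apply_normalization <- function(x, stats) {
  d <- dim(x)
  v <- rep((stats$mean), each = d[1L] * d[2L])
  s <- rep((stats$sd), each = d[1L] * d[2L])
  (x - v) / s
}

#' Stack a list of patch records into a (H, W, 3, N) array
#' @param patches list of `patch_record`s sharing one size.
#' @return 4-d array.
#' @export
patches_to_array <- function(patches) {
  if (length(patches) == 0) return(array(0, dim = c(0, 0, 3, 0)))
  d <- dim(patches[[1]]$pixels)
  x <- array(0, dim = c(d[1L], d[2L], 3L, length(patches)))
  for (i in seq_along(patches)) x[, , , i] <- patches[[i]]$pixels
  x
}

#' Build a labelled patch dataset from slide records
#'
#' Harvests coverage-filtered patches from each slide. Normal slides
#' (label 0) carry an empty lesion mask, so the strict coverage rule would
#' discard everything; for those slides the whole window counts as tissue of
#' interest and all windows are harvested (documented pipeline choice). Tumor
#' patches inherit the slide label. Optionally balances classes by seeded
#' subsampling.
#'
#' @param records list of `wsi_record`s.
#' @param spec a [patch_spec()].
#' @param n_per_class optional cap per class (seeded subsample).
#' @param apply_size_filter run [size_filter()] on each retained patch.
#' @param seed seed for the subsampling.
#' @return list with `x` (H, W, 3, N array), `y` (0-based labels),
#'   `patches` (the records).
#' @export
build_patch_dataset <- function(records, spec, n_per_class = NULL,
                                apply_size_filter = FALSE, seed = 1L) {
  all <- list()
  for (rec in records) {
    src <- rec
    if (rec$label == 0L) {
      src <- rec
      src$mask <- matrix(1L, nrow(rec$mask), ncol(rec$mask))
      src$label <- 0L
    }
    ps <- extract_patches(src, spec)
    if (rec$label == 0L) for (i in seq_along(ps)) ps[[i]]$coverage <- 0
    if (apply_size_filter)
      ps <- Filter(function(p) size_filter(p, spec)$keep, ps)
    all <- c(all, ps)
  }
  y <- vapply(all, function(p) p$label, integer(1))
  if (!is.null(n_per_class)) {
    keep <- integer(0)
    with_seed(seed, for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      keep <- c(keep, if (length(idx) > n_per_class)
        sample(idx, n_per_class) else idx)
    })
    all <- all[sort(keep)]
    y <- y[sort(keep)]
  }
  list(x = patches_to_array(all), y = y, patches = all)
}
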