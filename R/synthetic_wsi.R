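# Synthetic whole-slide generator: class-conditioned texture fields with
# paired binary lesion masks, standing in for scanned H&E slides so the whole
# pipeline can be exercised at desk scale.

#' Configuration for the synthetic slide generator
#'
#' Slides are filled with a background texture (class 0, normal tissue) and,
#' for tumor classes, a lesion region filled with a class-conditioned texture.
#' Each class texture is a filtered-noise field: an RGB tint plus smoothed
#' Gaussian noise with a class-specific spatial scale, mimicking the fact that
#' tumor types differ in both stain color balance and morphological scale.
#'
#' @param image_size pixels per side of each square slide.
#' @param n_slides_per_class slides generated per class (4 classes).
#' @param lesion_shape `"rectangle"` (exact area, for arithmetic tests) or
#'   `"blob"` (thresholded smoothed noise).
#' @param lesion_fraction_range length-2 numeric in (0, 1], min <= max; the
#'   lesion area fraction is drawn uniformly from this range.
#' @param texture_params data.frame with exactly 4 rows (classes 0-3) and
#'   columns `class`, `r`, `g`, `b` (tint in \[0,1\]), `sigma` (noise
#'   smoothing scale, px), `amplitude` (noise contrast).
#' @param seed integer master seed for dataset-level generation.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(image_size = 1024L,
                             n_slides_per_class = 10L,
                             lesion_shape = c("blob", "rectangle"),
                             lesion_fraction_range = c(0.2, 0.5),
                             texture_params = default_texture_params(),
                             seed = 1L) {
  lesion_shape <- match.arg(lesion_shape)
  stopifnot(image_size >= 16, n_slides_per_class >= 1)
  if (length(lesion_fraction_range) != 2 ||
      any(lesion_fraction_range <= 0) || any(lesion_fraction_range > 1) ||
      lesion_fraction_range[1] > lesion_fraction_range[2])
    stop("lesion_fraction_range must be (min, max) in (0, 1] with min <= max")
  if (nrow(texture_params) != 4L)
    stop("texture_params must have exactly 4 rows (3 tumor classes + normal)")
  structure(list(image_size = as.integer(image_size),
                 n_slides_per_class = as.integer(n_slides_per_class),
                 lesion_shape = lesion_shape,
                 lesion_fraction_range = lesion_fraction_range,
                 texture_params = texture_params,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default per-class texture parameters
#'
#' Tints follow an H&E-like palette: pale eosin pink for normal tissue, a
#' basophilic purple, a lipid-rich ochre and a dark melanotic brown for the
#' three tumor classes; spatial scales differ so classes are separable by
#' texture as well as color.
#'
#' @return data.frame with columns `class`, `r`, `g`, `b`, `sigma`, `amplitude`.
#' @export
default_texture_params <- function() {
  data.frame(class = 0:3,
             r = c(0.91, 0.48, 0.78, 0.38),
             g = c(0.76, 0.32, 0.62, 0.26),
             b = c(0.85, 0.66, 0.34, 0.28),
             sigma = c(1, 2, 4, 8),
             amplitude = c(0.10, 0.14, 0.14, 0.14))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 7919 + (as.numeric(p) %% 104729) + 13) %% 2147483629
  as.integer(h) + 1L
}

smoothed_noise <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma >= 0.5) {
    z <- as.matrix(EBImage::gblur(z, sigma = sigma, boundary = "replicate"))
  }
  s <- stats::sd(z)
  if (s < 1e-12) s <- 1
  (z - mean(z)) / s
}

class_texture <- function(h, w, par) {
  z <- smoothed_noise(h, w, par$sigma)
  img <- array(0, dim = c(h, w, 3L))
  tint <- c(par$r, par$g, par$b)
  for (ch in 1:3) {
    # shared field plus a light independent component per channel
    zc <- 0.8 * z + 0.2 * matrix(stats::rnorm(h * w), h, w)
    img[, , ch] <- pmin(1, pmax(0, tint[ch] + par$amplitude * zc))
  }
  img
}

#' Generate one synthetic slide with its lesion mask
#'
#' Fills the slide with normal-tissue texture; for tumor classes, carves a
#' lesion region whose area fraction is drawn uniformly from
#' `cfg$lesion_fraction_range` and fills it with the class texture. The mask
#' is 1 exactly on lesion pixels. Deterministic given `(cfg, class_id,
#' rng_seed)`; pixels are quantized to 8-bit levels.
#'
#' @param cfg a [synthetic_config()].
#' @param class_id integer in 0:3 (0 = normal: no lesion, empty mask).
#' @param rng_seed integer seed for this slide.
#' @return a `wsi_record`: list with `image` (H x W x 3 array in \[0,1\]),
#'   `mask` (H x W 0/1 matrix), `label`, `slide_id`.
#' @export
generate_slide <- function(cfg, class_id, rng_seed) {
  if (!is.numeric(class_id) || length(class_id) != 1 || !(class_id %in% 0:3))
    stop("class_id must be a single integer in 0:3")
  n <- cfg$image_size
  with_seed(rng_seed, {
    bg <- class_texture(n, n, cfg$texture_params[1L, ])
    mask <- matrix(0L, n, n)
    img <- bg
    if (class_id != 0) {
      f <- stats::runif(1, cfg$lesion_fraction_range[1],
                        cfg$lesion_fraction_range[2])
      mask <- lesion_mask(n, f, cfg$lesion_shape)
      tex <- class_texture(n, n, cfg$texture_params[class_id + 1L, ])
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[mask == 1L] <- tex[, , ch][mask == 1L]
        img[, , ch] <- pl
      }
    }
    img <- round(img * 255) / 255
    wsi_record(image = img, mask = mask, label = as.integer(class_id),
               slide_id = sprintf("synthetic_c%d_s%d", class_id, rng_seed))
  })
}

lesion_mask <- function(n, fraction, shape) {
  mask <- matrix(0L, n, n)
  if (shape == "rectangle") {
    side <- max(1L, round(n * sqrt(fraction)))
    side <- min(side, n)
    r0 <- sample.int(n - side + 1L, 1L)
    c0 <- sample.int(n - side + 1L, 1L)
    mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 1L
  } else {
    field <- smoothed_noise(n, n, sigma = n / 8)
    thr <- stats::quantile(field, 1 - fraction)
    mask[field > thr] <- 1L
  }
  mask
}

#' Construct and validate a WSI record
#'
#' @param image H x W x 3 numeric array in \[0,1\].
#' @param mask H x W matrix with values 0/1; must be all zero when `label = 0`.
#' @param label integer class id in 0:3.
#' @param slide_id character identifier.
#' @return validated `wsi_record` list.
#' @export
wsi_record <- function(image, mask, label, slide_id) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  if (!identical(dim(mask), dim(image)[1:2]))
    stop("mask shape must equal image spatial shape")
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0/1")
  if (label == 0 && any(mask == 1L))
    stop("normal slides (label 0) must have an empty mask")
  structure(list(image = image, mask = mask, label = as.integer(label),
                 slide_id = slide_id),
            class = "wsi_record")
}

#' Generate a stratified synthetic dataset
#'
#' Generates `n_slides_per_class` slides for each of the 4 classes and
#' partitions them into train/val/test with at least one slide per class per
#' partition. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()] with `n_slides_per_class >= 3`.
#' @param proportions train/val/test split proportions (sum 1).
#' @return list with `records` (list of `wsi_record`) and `manifest`
#'   (data.frame: `slide_id`, `label`, `split`).
#' @export
generate_dataset <- function(cfg, proportions = c(train = 0.6, val = 0.2,
                                                  test = 0.2)) {
  if (cfg$n_slides_per_class < 3)
    stop("n_slides_per_class must be >= 3 to stratify train/val/test")
  records <- list()
  manifest <- NULL
  for (cls in 0:3) {
    n <- cfg$n_slides_per_class
    n_val <- max(1L, floor(n * proportions[["val"]]))
    n_test <- max(1L, floor(n * proportions[["test"]]))
    n_train <- n - n_val - n_test
    if (n_train < 1L) stop("split proportions leave no training slides")
    splits <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
    perm <- with_seed(derive_seed(cfg$seed, 999L, cls), sample.int(n))
    splits <- splits[order(perm)]
    for (i in seq_len(n)) {
      rec <- generate_slide(cfg, cls, derive_seed(cfg$seed, cls, i))
      records[[length(records) + 1L]] <- rec
      manifest <- rbind(manifest,
                        data.frame(slide_id = rec$slide_id, label = cls,
                                   split = splits[i],
                                   stringsAsFactors = FALSE))
    }
  }
  list(records = records, manifest = manifest)
}

#' Write a synthetic dataset to disk
#'
#' Images as RGB PNG, masks as single-channel PNG with 255 = lesion, and a
#' `manifest.csv` with slide_id, image/mask paths, label and split.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest data.frame with path columns.
#' @export
write_wsi_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$image_path <- file.path(dir, paste0(man$slide_id, ".png"))
  man$mask_path <- file.path(dir, paste0(man$slide_id, "_mask.png"))
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    png::writePNG(rec$image, man$image_path[i])
    png::writePNG(rec$mask * 1.0, man$mask_path[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a slide image (and optional mask) back as a `wsi_record`
#' @param image_path PNG image path.
#' @param mask_path optional mask PNG (255/1 = lesion); empty mask if absent.
#' @param label class id (default 0 when unknown).
#' @param slide_id identifier; defaults to the file stem.
#' @return a `wsi_record`.
#' @export
read_wsi_record <- function(image_path, mask_path = NULL, label = 0L,
                            slide_id = NULL) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  mask <- if (is.null(mask_path)) matrix(0L, nrow(img), ncol(img)) else {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  }
  wsi_record(img, mask, label,
             slide_id %||% tools::file_path_sans_ext(basename(image_path)))
}
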