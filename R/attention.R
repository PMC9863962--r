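# BACM head: attention maps from the last-stage feature map, min-max
# normalization, threshold binarization, mask-guided crop of the original
# image re-fed to the network, and the averaged two-pass loss.

#' Build the attention head
#'
#' A 1x1 convolution mapping the backbone's last-stage feature map to X
#' attention maps; each map highlights one learned pattern in the image.
#'
#' @param in_channels channels of the backbone feature map.
#' @param n_maps number of attention maps X (>= 1).
#' @return an `nn_module` (1x1 conv).
#' @export
build_attention_head <- function(in_channels, n_maps = 32L) {
  if (n_maps < 1) stop("X must be >= 1")
  nn_conv(in_channels, as.integer(n_maps), 1L, stride = 1L, pad = 0L)
}

#' Compute attention maps and select one per image
#'
#' Applies the attention head to the feature map and selects, uniformly at
#' random (under the caller's RNG state), one map index per image; the crop
#' is driven by the selected map only.
#'
#' @param head module from [build_attention_head()].
#' @param features (H, W, C, N) backbone feature map.
#' @return list with `maps` (H, W, X, N) and `selected` (1-based index per
#'   image).
#' @export
attention_maps <- function(head, features) {
  maps <- head$forward(features, training = FALSE)
  X <- dim(maps)[3L]
  n <- dim(maps)[4L]
  selected <- if (X == 1L) rep(1L, n) else sample.int(X, n, replace = TRUE)
  list(maps = maps, selected = selected)
}

#' Min-max normalization of an attention map
#'
#' \eqn{A^* = (A - \min A) / (\max A - \min A)}, elementwise, so the output
#' spans \[0, 1\] for any non-constant map. A constant map cannot be
#' rescaled; it is flagged degenerate and returned as all zeros (downstream,
#' the crop falls back to the whole image so training never halts).
#'
#' @param map numeric matrix (one spatial attention map).
#' @return list with `map` (normalized matrix) and `degenerate` (logical).
#' @export
normalize_attention <- function(map) {
  if (length(map) == 0) stop("empty attention map")
  lo <- min(map); hi <- max(map)
  if (hi - lo < 1e-12)
    return(list(map = map * 0, degenerate = TRUE))
  list(map = (map - lo) / (hi - lo), degenerate = FALSE)
}

#' Binarize a normalized attention map at threshold theta_c
#'
#' The mask is 1 where the normalized value is strictly greater than
#' `theta_c`, else 0. An empty result (only possible for a degenerate
#' all-zero map, since a normalized map attains 1) falls back to an all-ones
#' mask: the crop becomes the whole image.
#'
#' @param norm_map normalized map in \[0, 1\] (matrix).
#' @param theta_c threshold in \[0, 1).
#' @return binary matrix of the same shape.
#' @export
binarize_attention <- function(norm_map, theta_c = 0.5) {
  if (theta_c < 0 || theta_c >= 1) stop("theta_c must lie in [0, 1)")
  mask <- (norm_map > theta_c) * 1L
  if (!any(mask == 1L)) mask[] <- 1L
  mask
}

#' Upsample a mask to image resolution by nearest neighbor
#' @param mask binary matrix at feature-map resolution.
#' @param out_h,out_w target size.
#' @return binary matrix `out_h x out_w`.
#' @export
upsample_mask <- function(mask, out_h, out_w) {
  ri <- pmin(nrow(mask), floor((seq_len(out_h) - 0.5) * nrow(mask) / out_h) + 1L)
  ci <- pmin(ncol(mask), floor((seq_len(out_w) - 0.5) * ncol(mask) / out_w) + 1L)
  mask[ri, ci, drop = FALSE]
}

#' Crop region (tight bounding box) of a full-resolution mask
#'
#' @param mask binary matrix at image resolution.
#' @return a `crop_region`: list with `box` = c(row_min, row_max, col_min,
#'   col_max), 0-based half-open, and the mask itself.
#' @export
crop_region <- function(mask) {
  pos_r <- which(rowSums(mask) > 0)
  pos_c <- which(colSums(mask) > 0)
  if (length(pos_r) == 0) {
    message("crop_region: empty mask; falling back to the full image")
    pos_r <- seq_len(nrow(mask)); pos_c <- seq_len(ncol(mask))
    mask[] <- 1L
  }
  structure(list(box = c(row_min = min(pos_r) - 1L, row_max = max(pos_r),
                         col_min = min(pos_c) - 1L, col_max = max(pos_c)),
                 mask = mask),
            class = "crop_region")
}

#' Crop the original image to a region and resize bilinearly
#'
#' Extracts the tight bounding box over all mask-1 pixels and upsamples the
#' crop to `out_size x out_size` (bilinear), producing the AttentionPicture
#' that is re-fed to the network.
#'
#' @param image (H, W, 3) array.
#' @param region a `crop_region`.
#' @param out_size output side in pixels.
#' @return (out_size, out_size, 3) array.
#' @export
crop_and_resize <- function(image, region, out_size) {
  b <- region$box
  stopifnot(b["row_max"] > b["row_min"], b["col_max"] > b["col_min"],
            b["row_max"] <= nrow(image), b["col_max"] <= ncol(image))
  crop <- image[(b[["row_min"]] + 1L):b[["row_max"]],
                (b[["col_min"]] + 1L):b[["col_max"]], , drop = FALSE]
  if (nrow(crop) == out_size && ncol(crop) == out_size) return(crop)
  img <- EBImage::Image(aperm(crop, c(2L, 1L, 3L)), colormode = "Color")
  res <- EBImage::resize(img, w = out_size, h = out_size)
  aperm(EBImage::imageData(res), c(2L, 1L, 3L))
}

#' Attention-guided crops for a batch
#'
#' For each image: select an attention map, normalize (min-max), binarize at
#' `theta_c`, upsample the mask to image resolution, take the tight bounding
#' box, crop the ORIGINAL image and resize to `out_size`.
#'
#' @param head attention head module.
#' @param features (H, W, C, N) backbone feature map for the batch.
#' @param images (H, W, 3, N) original (un-normalized or normalized) inputs.
#' @param theta_c binarization threshold.
#' @param out_size crop output side (defaults to the input side).
#' @return list with `crops` (out, out, 3, N array), `regions`, `selected`,
#'   `degenerate` (logical per image).
#' @export
attention_crops <- function(head, features, images, theta_c = 0.5,
                            out_size = dim(images)[1L]) {
  am <- attention_maps(head, features)
  n <- dim(images)[4L]
  crops <- array(0, dim = c(out_size, out_size, 3L, n))
  regions <- vector("list", n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    sel_map <- matrix(am$maps[, , am$selected[i], i],
                      dim(am$maps)[1L], dim(am$maps)[2L])
    nm <- normalize_attention(sel_map)
    degen[i] <- nm$degenerate
    mask <- binarize_attention(nm$map, theta_c)
    full <- upsample_mask(mask, dim(images)[1L], dim(images)[2L])
    regions[[i]] <- crop_region(full)
    crops[, , , i] <- crop_and_resize(images[, , , i, drop = TRUE],
                                      regions[[i]], out_size)
  }
  list(crops = crops, regions = regions, selected = am$selected,
       degenerate = degen)
}

#' Two-pass BACM forward/backward: original + attention crop
#'
#' Runs the model on the batch, computes the loss of the original pass,
#' builds the attention-guided crops from the last-stage feature map, runs
#' the model again on the crops (after the same augmentation/normalization
#' contract as originals, if supplied) and returns the mean of the two pass
#' losses. When `accumulate = TRUE`, gradients of 1/2 x each pass are
#' accumulated into the model parameters.
#'
#' @param model a `macres_backbone`.
#' @param head attention head for the model's feature channels.
#' @param x (H, W, 3, N) normalized input batch.
#' @param raw_images original images used for cropping (defaults to `x`).
#' @param labels 0-based integer labels.
#' @param loss_fn function(logits, labels) -> list(loss, grad); default
#'   focal loss.
#' @param theta_c binarization threshold.
#' @param crop_transform optional function applied to the crop batch before
#'   the second pass (augmentation + normalization contract).
#' @param accumulate backpropagate into the model (TRUE during training).
#' @return list with `loss`, `loss_original`, `loss_crop`, `logits_original`,
#'   `logits_crop`, `crops`.
#' @export
bacm_forward_loss <- function(model, head, x, labels, raw_images = x,
                              loss_fn = focal_loss_logits, theta_c = 0.5,
                              crop_transform = NULL, accumulate = TRUE) {
  f1 <- model$forward(x, training = accumulate)
  l1 <- loss_fn(f1$logits, labels)
  ac <- attention_crops(head, f1$features, raw_images, theta_c,
                        out_size = dim(x)[1L])
  if (accumulate) model$backward(0.5 * l1$grad)
  crops <- if (is.null(crop_transform)) ac$crops else crop_transform(ac$crops)
  f2 <- model$forward(crops, training = accumulate)
  l2 <- loss_fn(f2$logits, labels)
  if (accumulate) model$backward(0.5 * l2$grad)
  list(loss = 0.5 * l1$loss + 0.5 * l2$loss, loss_original = l1$loss,
       loss_crop = l2$loss, logits_original = f1$logits,
       logits_crop = f2$logits, crops = crops)
}
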