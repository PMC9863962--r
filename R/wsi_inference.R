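# Slide-level pipeline: tile, classify every window (no coverage rule at
# inference -- there is no mask), call the slide class, route tumor patches
# to the class-specific U-Net, reassemble an overlap-averaged lesion mask,
# and render attention heatmaps.

#' Classify every window of a slide
#'
#' All enumerated windows are classified; the lesion-coverage rule does not
#' apply at inference because no mask exists yet.
#'
#' @param slide_image (H, W, 3) array in \[0, 1\].
#' @param fit a `macres_fit` (classifier + normalization stats).
#' @param spec a [patch_spec()].
#' @param batch_size forward batch size.
#' @return list with `probs` (windows x K matrix, rows sum to 1), `origins`
#'   (data.frame of 0-based row/col), `calls` (0-based argmax class per
#'   window).
#' @export
classify_patches <- function(slide_image, fit, spec, batch_size = 32L) {
  wins <- enumerate_windows(nrow(slide_image), ncol(slide_image), spec)
  ps <- spec$patch_size
  x <- array(0, dim = c(ps, ps, 3L, nrow(wins)))
  for (i in seq_len(nrow(wins))) {
    r <- wins$row[i]; cc <- wins$col[i]
    x[, , , i] <- slide_image[(r + 1L):(r + ps), (cc + 1L):(cc + ps), ]
  }
  if (!is.null(fit$stats)) x <- apply_normalization(x, fit$stats)
  probs <- predict_proba(fit$model, x, batch_size)
  list(probs = probs, origins = wins, calls = max.col(probs) - 1L)
}

#' Slide-level class call from per-patch probabilities
#'
#' Majority vote over the non-normal patch calls; a slide with only normal
#' calls is called normal. Ties break toward the class with the higher mean
#' probability over its voting patches.
#'
#' @param probs windows x K probability matrix.
#' @return 0-based class id.
#' @export
call_slide_class <- function(probs) {
  stopifnot(nrow(probs) >= 1)
  calls <- max.col(probs) - 1L
  tumor <- calls[calls != 0L]
  if (length(tumor) == 0L) return(0L)
  tab <- table(tumor)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1L) return(top)
  means <- vapply(top, function(k) mean(probs[calls == k, k + 1L]), numeric(1))
  top[which.max(means)]
}

#' Segment tumor patches and reassemble the slide-level lesion mask
#'
#' Each window whose patch-level call is a tumor class is segmented by the
#' U-Net for the slide's called class; normal-called windows contribute
#' zeros. Overlapping window probabilities are averaged per pixel
#' (accumulate/count), then thresholded. Pixels covered by no window (edge
#' remainder) stay 0 and are flagged in the `uncovered` attribute.
#'
#' @param slide_image (H, W, 3) array.
#' @param class_id slide-level class (1-3); the matching entry of `unets`
#'   must exist.
#' @param unets named list of trained U-Nets, e.g.
#'   `list("1" = ..., "2" = ..., "3" = ...)`.
#' @param patches result of [classify_patches()] on the same slide/spec.
#' @param spec a [patch_spec()].
#' @param threshold probability threshold on the averaged map (default 0.5).
#' @return binary H x W mask with attributes `prob` (averaged probability
#'   map) and `uncovered` (logical matrix).
#' @export
segment_and_reassemble <- function(slide_image, class_id, unets, patches,
                                   spec, threshold = 0.5) {
  key <- as.character(class_id)
  if (is.null(unets[[key]]))
    stop("no segmentation network available for class ", class_id)
  unet <- unets[[key]]
  ps <- spec$patch_size
  h <- nrow(slide_image); w <- ncol(slide_image)
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  wins <- patches$origins
  tumor_idx <- which(patches$calls != 0L)
  if (length(tumor_idx)) {
    x <- array(0, dim = c(ps, ps, 3L, length(tumor_idx)))
    for (j in seq_along(tumor_idx)) {
      i <- tumor_idx[j]
      r <- wins$row[i]; cc <- wins$col[i]
      x[, , , j] <- slide_image[(r + 1L):(r + ps), (cc + 1L):(cc + ps), ]
    }
    pr <- unet_predict(unet, x)
    if (length(dim(pr)) == 2L) pr <- array(pr, dim = c(ps, ps, 1L))
  }
  j <- 0L
  for (i in seq_len(nrow(wins))) {
    r <- wins$row[i]; cc <- wins$col[i]
    rows <- (r + 1L):(r + ps); cols <- (cc + 1L):(cc + ps)
    cnt[rows, cols] <- cnt[rows, cols] + 1
    if (patches$calls[i] != 0L) {
      j <- j + 1L
      acc[rows, cols] <- acc[rows, cols] + pr[, , j]
    }
  }
  prob <- matrix(0, h, w)
  covered <- cnt > 0
  prob[covered] <- acc[covered] / cnt[covered]
  mask <- matrix(as.integer(prob > threshold), h, w)
  attr(mask, "prob") <- prob
  attr(mask, "uncovered") <- !covered
  mask
}

#' Slide-level attention heatmap
#'
#' For every window: run the backbone, compute attention maps, min-max
#' normalize the selected map, upsample to window resolution and place it at
#' the window origin; overlapping placements are averaged. Returns the
#' heatmap in \[0, 1\] plus a red-tinted overlay image.
#'
#' @param slide_image (H, W, 3) array.
#' @param fit a `macres_fit` with an attention `head`.
#' @param spec a [patch_spec()].
#' @param alpha overlay blend weight.
#' @return list with `heatmap` (H x W in \[0,1\]) and `overlay` (H, W, 3).
#' @export
attention_heatmap <- function(slide_image, fit, spec, alpha = 0.45) {
  if (is.null(fit$head)) stop("fit has no attention head")
  wins <- enumerate_windows(nrow(slide_image), ncol(slide_image), spec)
  ps <- spec$patch_size
  h <- nrow(slide_image); w <- ncol(slide_image)
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (i in seq_len(nrow(wins))) {
    r <- wins$row[i]; cc <- wins$col[i]
    tile <- slide_image[(r + 1L):(r + ps), (cc + 1L):(cc + ps), ,
                        drop = FALSE]
    xt <- array(tile, dim = c(ps, ps, 3L, 1L))
    if (!is.null(fit$stats)) xt <- apply_normalization(xt, fit$stats)
    f <- fit$model$forward(xt, training = FALSE)
    am <- attention_maps(fit$head, f$features)
    nm <- normalize_attention(am$maps[, , am$selected[1L], 1L])
    up <- upsample_mask_num(nm$map, ps, ps)
    rows <- (r + 1L):(r + ps); cols <- (cc + 1L):(cc + ps)
    acc[rows, cols] <- acc[rows, cols] + up
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  heat <- matrix(0, h, w)
  heat[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  overlay <- slide_image
  overlay[, , 1L] <- (1 - alpha) * slide_image[, , 1L] + alpha * heat
  overlay[, , 2L] <- (1 - alpha) * slide_image[, , 2L]
  overlay[, , 3L] <- (1 - alpha) * slide_image[, , 3L]
  list(heatmap = heat, overlay = overlay)
}

# numeric (non-binary) nearest-neighbor upsample
upsample_mask_num <- function(m, out_h, out_w) {
  ri <- pmin(nrow(m), floor((seq_len(out_h) - 0.5) * nrow(m) / out_h) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(out_w) - 0.5) * ncol(m) / out_w) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Full slide-level inference
#'
#' Tiles the slide, classifies all windows, calls the slide class, segments
#' and reassembles the lesion mask with the class-specific U-Net, and
#' renders the attention heatmap.
#'
#' @param slide_image (H, W, 3) array in \[0, 1\].
#' @param fit classifier `macres_fit`.
#' @param unets named list of per-class U-Nets (`"1"`, `"2"`, `"3"`).
#' @param spec a [patch_spec()].
#' @param threshold segmentation threshold.
#' @param heatmap also compute the attention heatmap (needs `fit$head`).
#' @return a `slide_prediction`: list with `probs`, `origins`, `calls`,
#'   `slide_class`, `mask`, and optionally `heatmap`/`overlay`.
#' @export
run_wsi_pipeline <- function(slide_image, fit, unets, spec, threshold = 0.5,
                             heatmap = FALSE) {
  patches <- classify_patches(slide_image, fit, spec)
  cls <- call_slide_class(patches$probs)
  mask <- if (cls == 0L) {
    m <- matrix(0L, nrow(slide_image), ncol(slide_image))
    attr(m, "prob") <- matrix(0, nrow(slide_image), ncol(slide_image))
    m
  } else {
    segment_and_reassemble(slide_image, cls, unets, patches, spec, threshold)
  }
  out <- list(probs = patches$probs, origins = patches$origins,
              calls = patches$calls, slide_class = cls, mask = mask)
  if (heatmap) {
    hm <- attention_heatmap(slide_image, fit, spec)
    out$heatmap <- hm$heatmap
    out$overlay <- hm$overlay
  }
  structure(out, class = "slide_prediction")
}
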