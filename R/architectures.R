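# Backbone family: SampleInput stem (three 3x3 convs replacing the 7x7),
# bottleneck stages optionally wrapped in the double-nested DARes residual,
# an SPP head for size-independent descriptors, and a plain U-Net for the
# per-class lesion segmentation stage.

#' Model configuration
#'
#' @param n_classes number of output classes (default 4: normal + 3 tumors).
#' @param dares_layers subset of `c("layer2", "layer3", "layer4")` whose
#'   stages use the DARes double-nested residual (default layer2 + layer4,
#'   the best-performing placement).
#' @param use_sample_input replace the single 7x7 stride-2 stem conv with
#'   three stacked 3x3 convs of identical overall stride and receptive field.
#' @param use_spp use the spatial-pyramid-pooling head (fixed-length features
#'   from any input size) instead of global average pooling.
#' @param spp_levels pyramid grid sizes (default 1, 2, 4 -> 21 bins).
#' @param n_attention_maps number of attention maps X produced by the
#'   attention head (default 32).
#' @param width_multiplier channel-count scale in (0, 1]; miniature desk-scale
#'   models use <= 0.125.
#' @param input_size nominal square input side in pixels.
#' @param blocks_per_stage bottleneck blocks in layers 1-4 (default ResNet50's
#'   3, 4, 6, 3; miniature presets use 2, 2, 2, 2).
#' @return a `model_config` list.
#' @export
model_config <- function(n_classes = 4L,
                         dares_layers = c("layer2", "layer4"),
                         use_sample_input = TRUE, use_spp = TRUE,
                         spp_levels = c(1L, 2L, 4L),
                         n_attention_maps = 32L, width_multiplier = 1,
                         input_size = 224L,
                         blocks_per_stage = c(3L, 4L, 6L, 3L)) {
  if (!all(dares_layers %in% c("layer2", "layer3", "layer4")))
    stop("dares_layers must be a subset of layer2/layer3/layer4")
  stopifnot(n_attention_maps >= 1, width_multiplier > 0, width_multiplier <= 1,
            n_classes >= 2, length(blocks_per_stage) == 4,
            all(blocks_per_stage >= 1))
  structure(list(n_classes = as.integer(n_classes),
                 dares_layers = dares_layers,
                 use_sample_input = isTRUE(use_sample_input),
                 use_spp = isTRUE(use_spp),
                 spp_levels = as.integer(spp_levels),
                 n_attention_maps = as.integer(n_attention_maps),
                 width_multiplier = width_multiplier,
                 input_size = as.integer(input_size),
                 blocks_per_stage = as.integer(blocks_per_stage)),
            class = "model_config")
}

#' Miniature desk-scale configuration
#'
#' A narrow, shallow variant of the default configuration for CPU-scale
#' experiments: width multiplier 1/8, two blocks per stage, 64-px inputs and
#' a 2-level pyramid (the final feature map of a 64-px input is 2x2).
#'
#' @param ... overrides forwarded to [model_config()].
#' @return a `model_config`.
#' @export
miniature_config <- function(...) {
  args <- list(...)
  defaults <- list(n_classes = 4L, dares_layers = c("layer2", "layer4"),
                   use_sample_input = TRUE, use_spp = TRUE,
                   spp_levels = c(1L, 2L), n_attention_maps = 4L,
                   width_multiplier = 0.125, input_size = 64L,
                   blocks_per_stage = c(2L, 2L, 2L, 2L))
  do.call(model_config, utils::modifyList(defaults, args))
}

#' Plain-student configuration derived from a teacher configuration
#'
#' The student keeps the teacher's class count, width and depth but drops the
#' architectural additions: single 7x7 stem, no DARes stages, global average
#' pooling instead of SPP.
#'
#' @param teacher_cfg the teacher's `model_config`.
#' @return a `model_config` for the plain backbone.
#' @export
student_config <- function(teacher_cfg) {
  cfg <- teacher_cfg
  cfg$dares_layers <- character(0)
  cfg$use_sample_input <- FALSE
  cfg$use_spp <- FALSE
  cfg
}

base_width <- function(cfg) max(4L, as.integer(round(64 * cfg$width_multiplier)))

#' Build the input stem
#'
#' With `use_sample_input` on: three stacked 3x3 convolutions (stride 2 on
#' the last) whose composite receptive field is exactly 7x7 and whose overall
#' downsampling equals the single 7x7 stride-2 convolution they replace.
#' With the flag off: the plain 7x7 stride-2 stem, same output shape.
#'
#' @param cfg a [model_config()].
#' @return an `nn_module` mapping (H, W, 3, N) to (H/2, W/2, C, N).
#' @export
build_sample_input <- function(cfg) {
  c0 <- base_width(cfg)
  if (cfg$use_sample_input) {
    nn_sequential(nn_conv(3L, c0, 3L, stride = 1L, pad = 1L), nn_bn(c0),
                  nn_relu(),
                  nn_conv(c0, c0, 3L, stride = 1L, pad = 1L), nn_bn(c0),
                  nn_relu(),
                  nn_conv(c0, c0, 3L, stride = 2L, pad = 1L), nn_bn(c0),
                  nn_relu())
  } else {
    nn_sequential(nn_conv(3L, c0, 7L, stride = 2L, pad = 3L), nn_bn(c0),
                  nn_relu())
  }
}

bottleneck <- function(in_c, mid_c, out_c, stride = 1L) {
  body <- nn_sequential(
    nn_conv(in_c, mid_c, 1L, stride = 1L, pad = 0L), nn_bn(mid_c), nn_relu(),
    nn_conv(mid_c, mid_c, 3L, stride = stride, pad = 1L), nn_bn(mid_c),
    nn_relu(),
    nn_conv(mid_c, out_c, 1L, stride = 1L, pad = 0L), nn_bn(out_c))
  shortcut <- if (in_c != out_c || stride != 1L)
    nn_sequential(nn_conv(in_c, out_c, 1L, stride = stride, pad = 0L),
                  nn_bn(out_c)) else NULL
  nn_residual(body, shortcut)
}

# DARes stage: the stage's bottleneck stack wrapped in an OUTER residual that
# adds (a) the projected stage input (shallow) and (b) the projected output of
# the middle block, to the stage output (deep), before a final ReLU.
nn_dares_stage <- function(blocks, in_c, out_c, stride) {
  self <- new_module("dares_stage")
  self$blocks <- blocks
  self$mid <- as.integer(ceiling(length(blocks) / 2))
  self$proj_in <- nn_sequential(nn_conv(in_c, out_c, 1L, stride = stride,
                                        pad = 0L), nn_bn(out_c))
  self$proj_mid <- nn_sequential(nn_conv(out_c, out_c, 1L, stride = 1L,
                                         pad = 0L), nn_bn(out_c))
  self$children <- c(blocks, list(self$proj_in, self$proj_mid))
  self$forward <- function(x, training = TRUE) {
    a <- x
    a_mid <- NULL
    for (i in seq_along(self$blocks)) {
      a <- self$blocks[[i]]$forward(a, training)
      if (i == self$mid) a_mid <- a
    }
    y <- a + self$proj_in$forward(x, training) +
      self$proj_mid$forward(a_mid, training)
    self$cache <- y > 0
    y * self$cache
  }
  self$backward <- function(dy) {
    dz <- dy * self$cache
    dx_extra <- self$proj_in$backward(dz)
    dmid_extra <- self$proj_mid$backward(dz)
    d <- dz
    for (i in rev(seq_along(self$blocks))) {
      if (i == self$mid) d <- d + dmid_extra
      d <- self$blocks[[i]]$backward(d)
    }
    d + dx_extra
  }
  self
}

#' Build one backbone stage, plain or DARes-wrapped
#'
#' @param stage one of `"layer1"`..`"layer4"` (layer1 is never DARes-wrapped;
#'   only layers 2-4 are valid DARes placements).
#' @param cfg a [model_config()].
#' @param dares force DARes wiring regardless of `cfg$dares_layers`
#'   (`NULL` = follow the config).
#' @return an `nn_module`.
#' @export
build_dares_block <- function(stage, cfg, dares = NULL) {
  stages <- c("layer1", "layer2", "layer3", "layer4")
  if (!stage %in% stages) stop("invalid stage name: ", stage)
  i <- match(stage, stages)
  bw <- base_width(cfg)
  mid <- bw * 2L^(i - 1L)
  out_c <- mid * 4L
  in_c <- if (i == 1L) bw else mid * 2L
  stride <- if (i == 1L) 1L else 2L
  n_blocks <- cfg$blocks_per_stage[i]
  blocks <- vector("list", n_blocks)
  blocks[[1L]] <- bottleneck(in_c, mid, out_c, stride)
  for (b in seq_len(n_blocks - 1L) + 1L)
    blocks[[b]] <- bottleneck(out_c, mid, out_c, 1L)
  use_dares <- if (is.null(dares)) stage %in% cfg$dares_layers else dares
  if (use_dares) nn_dares_stage(blocks, in_c, out_c, stride)
  else nn_sequential(blocks)
}

#' Build the spatial-pyramid-pooling head
#'
#' Average-pools the feature map over each `l x l` grid of every pyramid
#' level and concatenates the results, yielding a fixed-length descriptor of
#' `channels * sum(levels^2)` for any input spatial size at least
#' `max(levels)`.
#'
#' @param cfg a [model_config()]; uses `cfg$spp_levels`.
#' @return an `nn_spp` module.
#' @export
build_spp <- function(cfg) {
  if (length(cfg$spp_levels) == 0) stop("spp_levels must be nonempty")
  nn_spp(cfg$spp_levels)
}

#' Assemble the classifier backbone
#'
#' ResNet50-skeleton network honoring all configuration switches: SampleInput
#' or plain stem, DARes placement per stage, SPP or global-average head,
#' channel widths scaled by the width multiplier. The returned model exposes
#' both the last-stage feature map (for the attention head) and the class
#' logits.
#'
#' @param cfg a [model_config()].
#' @return a `macres_backbone` module whose `$forward(x, training)` returns
#'   `list(features, logits)` with `logits` an N x K matrix.
#' @export
build_backbone <- function(cfg) {
  self <- new_module("backbone")
  class(self) <- c("macres_backbone", class(self))
  self$cfg <- cfg
  self$stem <- build_sample_input(cfg)
  self$pool <- nn_maxpool(2L, 2L)
  self$stages <- lapply(paste0("layer", 1:4), build_dares_block, cfg = cfg)
  bw <- base_width(cfg)
  self$out_channels <- bw * 8L * 4L
  if (cfg$use_spp) {
    self$head_pool <- build_spp(cfg)
    feat_len <- self$out_channels * sum(cfg$spp_levels^2)
  } else {
    self$head_pool <- nn_spp(1L)  # global average pooling
    feat_len <- self$out_channels
  }
  self$fc <- nn_linear(feat_len, cfg$n_classes)
  self$children <- c(list(self$stem, self$pool), self$stages,
                     list(self$head_pool, self$fc))
  self$forward <- function(x, training = TRUE) {
    h <- self$stem$forward(x, training)
    h <- self$pool$forward(h, training)
    for (st in self$stages) h <- st$forward(h, training)
    features <- h
    z <- self$head_pool$forward(h, training)
    logits <- t(self$fc$forward(z, training))
    list(features = features, logits = logits)
  }
  self$backward <- function(dlogits) {
    d <- self$fc$backward(t(dlogits))
    d <- self$head_pool$backward(d)
    for (st in rev(self$stages)) d <- st$backward(d)
    d <- self$pool$backward(d)
    self$stem$backward(d)
  }
  self
}

#' Class probabilities from a backbone in evaluation mode
#'
#' @param model a `macres_backbone`.
#' @param x (H, W, 3, N) input array (already normalized).
#' @param batch_size forward batch size.
#' @return N x K matrix of probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, x, batch_size = 32L) {
  n <- dim(x)[4L]
  out <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    f <- model$forward(x[, , , s:e, drop = FALSE], training = FALSE)
    out <- rbind(out, softmax_rows(f$logits))
  }
  out
}

# ---------------------------------------------------------------------------
# U-Net for per-class lesion segmentation
# ---------------------------------------------------------------------------

conv_block <- function(in_c, out_c) {
  nn_sequential(nn_conv(in_c, out_c, 3L, pad = 1L), nn_bn(out_c), nn_relu(),
                nn_conv(out_c, out_c, 3L, pad = 1L), nn_bn(out_c), nn_relu())
}

#' Build a U-Net for binary lesion segmentation
#'
#' Standard encoder-decoder with skip connections: `depth` 2x downsamplings,
#' nearest-neighbor upsampling in the decoder, channel concatenation with the
#' matching encoder map, and a final 1x1 convolution producing a per-pixel
#' lesion logit at the input resolution. Input sides must be divisible by
#' `2^depth`.
#'
#' @param n_channels input channels (3 for RGB tiles).
#' @param width_base channels of the first encoder block (doubles per level).
#' @param depth number of pooling steps (default 3).
#' @return a `macres_unet` module; `$forward(x, training)` returns an
#'   (H, W, 1, N) logit array.
#' @export
build_unet <- function(n_channels = 3L, width_base = 8L, depth = 3L) {
  self <- new_module("unet")
  class(self) <- c("macres_unet", class(self))
  self$depth <- as.integer(depth)
  w <- width_base * 2L^(seq_len(depth + 1L) - 1L)
  self$enc <- vector("list", depth)
  in_c <- n_channels
  for (i in seq_len(depth)) {
    self$enc[[i]] <- conv_block(in_c, w[i])
    in_c <- w[i]
  }
  self$pools <- lapply(seq_len(depth), function(i) nn_maxpool(2L, 2L))
  self$bottom <- conv_block(w[depth], w[depth + 1L])
  self$ups <- vector("list", depth)
  self$upconv <- vector("list", depth)
  self$dec <- vector("list", depth)
  for (i in seq_len(depth)) {
    lev <- depth + 1L - i          # decoder level, deepest first
    self$ups[[i]] <- nn_upsample2()
    self$upconv[[i]] <- nn_conv(w[lev + 1L], w[lev], 3L, pad = 1L)
    self$dec[[i]] <- conv_block(2L * w[lev], w[lev])
  }
  self$final <- nn_conv(w[1L], 1L, 1L, pad = 0L)
  self$children <- c(self$enc, self$pools, list(self$bottom), self$ups,
                     self$upconv, self$dec, list(self$final))
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (d[1L] %% 2L^self$depth != 0L || d[2L] %% 2L^self$depth != 0L)
      stop(sprintf("input %dx%d not divisible by 2^%d", d[1L], d[2L],
                   self$depth))
    skips <- vector("list", self$depth)
    h <- x
    for (i in seq_len(self$depth)) {
      h <- self$enc[[i]]$forward(h, training)
      skips[[i]] <- h
      h <- self$pools[[i]]$forward(h, training)
    }
    h <- self$bottom$forward(h, training)
    self$skip_channels <- vapply(skips, function(s) dim(s)[3L], numeric(1))
    for (i in seq_len(self$depth)) {
      lev <- self$depth + 1L - i
      h <- self$ups[[i]]$forward(h, training)
      h <- self$upconv[[i]]$forward(h, training)
      h <- self$dec[[i]]$forward(concat_c(skips[[lev]], h), training)
    }
    self$final$forward(h, training)
  }
  self$backward <- function(dy) {
    d <- self$final$backward(dy)
    dskips <- vector("list", self$depth)
    for (i in rev(seq_len(self$depth))) {
      lev <- self$depth + 1L - i
      dcat <- self$dec[[i]]$backward(d)
      nsk <- self$skip_channels[lev]
      dskips[[lev]] <- dcat[, , seq_len(nsk), , drop = FALSE]
      d <- dcat[, , nsk + seq_len(dim(dcat)[3L] - nsk), , drop = FALSE]
      d <- self$upconv[[i]]$backward(d)
      d <- self$ups[[i]]$backward(d)
    }
    d <- self$bottom$backward(d)
    for (i in rev(seq_len(self$depth))) {
      d <- self$pools[[i]]$backward(d)
      d <- d + dskips[[i]]
      d <- self$enc[[i]]$backward(d)
    }
    d
  }
  self
}

#' Gradient footprint of one stem output unit (receptive-field audit)
#'
#' Runs the stem on a probe input in evaluation mode with linearized ReLUs,
#' backpropagates a one-hot gradient from a single interior output unit, and
#' returns the bounding-box size of the nonzero input-gradient region — the
#' effective receptive field.
#'
#' @param stem module from [build_sample_input()].
#' @param input_size probe input side (default 32).
#' @return list with `height`, `width` of the footprint and the footprint
#'   mask itself.
#' @export
stem_receptive_field <- function(stem, input_size = 32L) {
  relus <- collect_relus(stem)
  for (r in relus) r$linear_mode <- TRUE
  on.exit(for (r in relus) r$linear_mode <- FALSE)
  x <- array(stats::rnorm(input_size^2 * 3), c(input_size, input_size, 3L, 1L))
  y <- stem$forward(x, training = FALSE)
  d <- dim(y)
  dy <- array(0, dim = d)
  ctr <- c(d[1L] %/% 2L, d[2L] %/% 2L)
  dy[ctr[1L], ctr[2L], 1L, 1L] <- 1
  dx <- stem$backward(dy)
  fp <- apply(abs(dx) > 1e-12, c(1L, 2L), any)
  rows <- range(which(rowSums(fp) > 0))
  cols <- range(which(colSums(fp) > 0))
  list(height = diff(rows) + 1L, width = diff(cols) + 1L, footprint = fp)
}

collect_relus <- function(mod) {
  out <- if (identical(mod$type, "relu")) list(mod) else list()
  for (ch in mod$children) out <- c(out, collect_relus(ch))
  out
}
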