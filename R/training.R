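# Training loops: teacher (backbone + BACM two-pass focal loss), student
# (knowledge distillation with temperature-softened teacher targets), plain
# supervised baseline, and the U-Net segmentation fit. All loops are fully
# seeded and log per-epoch histories.

#' Cosine-annealing learning rate with restarts
#'
#' \deqn{\eta(s) = \eta_{min} + \tfrac12(\eta_{base} - \eta_{min})
#'   (1 + \cos(\pi \phi / T_{max}))}
#' where \eqn{\phi = s \bmod T_{max}}, except that at exact multiples of
#' `T_max` (the minimum point) the schedule returns `eta_min` and the NEXT
#' step restarts near `base_lr`, beginning a new decay round.
#'
#' @param step 0-based global step.
#' @param base_lr maximum (initial) learning rate.
#' @param t_max steps per annealing period (>= 1).
#' @param eta_min floor learning rate (default 0).
#' @return learning rate at `step`.
#' @export
cosine_lr <- function(step, base_lr, t_max, eta_min = 0) {
  stopifnot(step >= 0, t_max >= 1)
  phase <- step %% t_max
  if (step > 0 && phase == 0) phase <- t_max
  eta_min + 0.5 * (base_lr - eta_min) * (1 + cos(pi * phase / t_max))
}

#' Training configuration
#'
#' Defaults mirror the study protocol (50 epochs, batch size 8, learning
#' rate 1e-5, cosine-annealed); miniature desk-scale runs override them.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size samples per step (>= 1).
#' @param base_lr initial learning rate (> 0).
#' @param schedule `"cosine_annealing"` or `"constant"`.
#' @param t_max annealing period in steps; `NULL` = one period spanning the
#'   whole run (steps-per-epoch x epochs).
#' @param eta_min cosine floor.
#' @param seed RNG seed for init, shuffling, augmentation and map selection.
#' @param theta_c attention binarization threshold for the BACM pass.
#' @param use_bacm train the teacher with the two-pass attention-crop loss.
#' @param loss `"focal"`, `"cross_entropy"` or `"label_smoothing"`.
#' @param alpha,gamma focal parameters; `smoothing` for label smoothing.
#' @param augment optional [augment_config()] applied to training batches.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, base_lr = 1e-5,
                         schedule = c("cosine_annealing", "constant"),
                         t_max = NULL, eta_min = 0, seed = 1L,
                         theta_c = 0.5, use_bacm = TRUE,
                         loss = c("focal", "cross_entropy", "label_smoothing"),
                         alpha = 0.25, gamma = 2, smoothing = 0.1,
                         augment = NULL) {
  schedule <- match.arg(schedule)
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, batch_size >= 1, base_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 schedule = schedule, t_max = t_max, eta_min = eta_min,
                 seed = as.integer(seed), theta_c = theta_c,
                 use_bacm = isTRUE(use_bacm), loss = loss, alpha = alpha,
                 gamma = gamma, smoothing = smoothing, augment = augment),
            class = "train_config")
}

make_loss_fn <- function(tc) {
  switch(tc$loss,
         focal = function(z, y) focal_loss_logits(z, y, tc$alpha, tc$gamma),
         cross_entropy = function(z, y) focal_loss_logits(z, y, alpha = 1,
                                                          gamma = 0),
         label_smoothing = function(z, y)
           label_smoothing_loss(z, y, tc$smoothing))
}

step_lr <- function(tc, step, t_max) {
  if (tc$schedule == "constant") tc$base_lr
  else cosine_lr(step, tc$base_lr, t_max, tc$eta_min)
}

eval_accuracy <- function(model, x, y, batch_size = 32L) {
  p <- predict_proba(model, x, batch_size)
  mean(max.col(p) - 1L == y)
}

#' Train the teacher network
#'
#' Builds the backbone and attention head from `model_cfg`, then optimizes
#' the two-pass BACM loss (mean of original-pass and attention-crop-pass
#' losses) with Adam under a cosine-annealed learning rate. Validation
#' metrics use evaluation mode, no augmentation; the best-validation-accuracy
#' weights are retained (ties favor the earlier epoch).
#'
#' @param model_cfg a [model_config()].
#' @param data list with `train` and `val`, each `list(x, y)` where `x` is an
#'   (H, W, 3, N) array in \[0, 1\] and `y` 0-based labels.
#' @param tc a [train_config()].
#' @param normalize fit per-channel standardization on the training split and
#'   apply it to both splits (default TRUE).
#' @return a `macres_fit`: list with `model`, `head`, `history` (data.frame),
#'   `best_state`, `best_epoch`, `stats`, `model_cfg`, `train_cfg`.
#' @export
train_teacher <- function(model_cfg, data, tc, normalize = TRUE) {
  if (length(data$train$y) == 0 || length(data$val$y) == 0)
    stop("empty train or val split")
  set.seed(tc$seed)
  stats <- NULL
  xtr_raw <- data$train$x
  if (normalize) {
    stats <- fit_normalization(data$train$x)
    data$train$x <- apply_normalization(data$train$x, stats)
    data$val$x <- apply_normalization(data$val$x, stats)
  }
  model <- build_backbone(model_cfg)
  head <- build_attention_head(model$out_channels, model_cfg$n_attention_maps)
  opt <- optim_adam(model, lr = tc$base_lr)
  loss_fn <- make_loss_fn(tc)
  n <- length(data$train$y)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  t_max <- tc$t_max %||% (steps_per_epoch * tc$epochs)
  history <- NULL
  best <- list(acc = -Inf, epoch = NA_integer_, state = NULL)
  gstep <- 0L
  lr_trace <- numeric(0)
  for (ep in seq_len(tc$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = tc$batch_size)) {
      b <- idx[s:min(n, s + tc$batch_size - 1L)]
      xb_raw <- xtr_raw[, , , b, drop = FALSE]
      xb <- data$train$x[, , , b, drop = FALSE]
      yb <- data$train$y[b]
      if (!is.null(tc$augment)) {
        aug_seed <- derive_seed(tc$seed, ep, s)
        xb_aug <- augment_batch(xb_raw, tc$augment, aug_seed)
        xb <- if (normalize) apply_normalization(xb_aug, stats) else xb_aug
      }
      zero_grads(model)
      if (tc$use_bacm) {
        ct <- if (normalize)
          function(cr) apply_normalization(cr, stats) else NULL
        r <- bacm_forward_loss(model, head, xb, yb, raw_images = xb_raw,
                               loss_fn = loss_fn, theta_c = tc$theta_c,
                               crop_transform = ct)
        loss_val <- r$loss
      } else {
        f <- model$forward(xb, training = TRUE)
        l <- loss_fn(f$logits, yb)
        model$backward(l$grad)
        loss_val <- l$loss
      }
      lr <- step_lr(tc, gstep, t_max)
      lr_trace <- c(lr_trace, lr)
      opt$step(lr)
      gstep <- gstep + 1L
      ep_loss <- ep_loss + loss_val * length(b)
    }
    val_acc <- eval_accuracy(model, data$val$x, data$val$y)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / n,
                                val_acc = val_acc,
                                lr = step_lr(tc, gstep - 1L, t_max)))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = ep, state = state_dict(model))
    }
  }
  structure(list(model = model, head = head, history = history,
                 best_state = best$state, best_epoch = best$epoch,
                 stats = stats, model_cfg = model_cfg, train_cfg = tc,
                 lr_trace = lr_trace, t_max = t_max),
            class = "macres_fit")
}

#' Save / load a fit checkpoint
#'
#' Weights go to an RDS container with a JSON sidecar describing the model
#' configuration.
#'
#' @param fit a `macres_fit`.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(state = state_dict(fit$model),
              head_state = state_dict(fit$head),
              best_state = fit$best_state, history = fit$history,
              stats = fit$stats, model_cfg = fit$model_cfg,
              train_cfg = fit$train_cfg)
  saveRDS(obj, path)
  jsonlite::write_json(unclass(fit$model_cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param use_best load the best-validation weights instead of the final ones.
#' @return `load_checkpoint` returns a reconstructed `macres_fit`.
#' @export
load_checkpoint <- function(path, use_best = FALSE) {
  obj <- readRDS(path)
  model <- build_backbone(obj$model_cfg)
  load_state_dict(model, if (use_best && !is.null(obj$best_state))
    obj$best_state else obj$state)
  head <- build_attention_head(model$out_channels,
                               obj$model_cfg$n_attention_maps)
  load_state_dict(head, obj$head_state)
  structure(list(model = model, head = head, history = obj$history,
                 best_state = obj$best_state, stats = obj$stats,
                 model_cfg = obj$model_cfg, train_cfg = obj$train_cfg),
            class = "macres_fit")
}

#' Distillation parameters
#' @param a soft/hard mix weight in \[0, 1\] (default 0.7).
#' @param temperature softening temperature T > 0 (default 4).
#' @param literal_attention_term if TRUE, the attention-pass term of the
#'   total loss uses the frozen teacher's prediction on the AttentionPicture
#'   (the literal printed form, which passes no gradient to the student);
#'   default FALSE: the student's own prediction on the teacher's crop.
#' @return a `distill_params` list.
#' @export
distill_params <- function(a = 0.7, temperature = 4,
                           literal_attention_term = FALSE) {
  stopifnot(a >= 0, a <= 1, temperature > 0)
  structure(list(a = a, temperature = temperature,
                 literal_attention_term = isTRUE(literal_attention_term)),
            class = "distill_params")
}

#' Distill a student network from a trained teacher
#'
#' The frozen teacher supplies temperature-softened soft labels on the
#' originals and the attention-guided crop (AttentionPicture). The student
#' minimizes the total loss
#' \eqn{\tfrac12 L_{KD} + \tfrac12 L_f(\text{attention pass})}, where
#' \eqn{L_{KD}} mixes the focal hard-label term and the \eqn{T^2}-scaled KL
#' term against the teacher's soft labels.
#'
#' @param teacher a `macres_fit` (teacher network; left untouched).
#' @param student_cfg a [model_config()] for the student (same class count).
#' @param data as in [train_teacher()].
#' @param dp a [distill_params()].
#' @param tc a [train_config()] for the student run.
#' @return a `macres_fit` for the student, whose history records the KD and
#'   attention-pass loss components.
#' @export
distill_student <- function(teacher, student_cfg, data, dp, tc) {
  if (student_cfg$n_classes != teacher$model_cfg$n_classes)
    stop("teacher/student class-count mismatch")
  set.seed(tc$seed)
  stats <- teacher$stats
  xtr_raw <- data$train$x
  if (!is.null(stats)) {
    data$train$x <- apply_normalization(data$train$x, stats)
    data$val$x <- apply_normalization(data$val$x, stats)
  }
  student <- build_backbone(student_cfg)
  opt <- optim_adam(student, lr = tc$base_lr)
  n <- length(data$train$y)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  t_max <- tc$t_max %||% (steps_per_epoch * tc$epochs)
  history <- NULL
  best <- list(acc = -Inf, epoch = NA_integer_, state = NULL)
  gstep <- 0L
  lr_trace <- numeric(0)
  for (ep in seq_len(tc$epochs)) {
    idx <- sample.int(n)
    ep_kd <- 0; ep_att <- 0; ep_tot <- 0
    for (s in seq(1L, n, by = tc$batch_size)) {
      b <- idx[s:min(n, s + tc$batch_size - 1L)]
      xb <- data$train$x[, , , b, drop = FALSE]
      xb_raw <- xtr_raw[, , , b, drop = FALSE]
      yb <- data$train$y[b]
      # frozen teacher: soft labels on originals + attention crop
      ft <- teacher$model$forward(xb, training = FALSE)
      tsl <- soft_targets(ft$logits, dp$temperature)
      ac <- attention_crops(teacher$head, ft$features, xb_raw, tc$theta_c,
                            out_size = dim(xb)[1L])
      crops <- if (is.null(stats)) ac$crops else
        apply_normalization(ac$crops, stats)
      zero_grads(student)
      fs <- student$forward(xb, training = TRUE)
      kd <- kd_loss_grad(fs$logits, tsl, yb, a = dp$a,
                         temperature = dp$temperature, alpha = tc$alpha,
                         gamma = tc$gamma)
      student$backward(0.5 * kd$grad)
      if (dp$literal_attention_term) {
        ftc <- teacher$model$forward(crops, training = FALSE)
        att <- focal_loss_logits(ftc$logits, yb, tc$alpha, tc$gamma)
        # no student gradient from the literal (teacher-side) term
      } else {
        fsc <- student$forward(crops, training = TRUE)
        att <- focal_loss_logits(fsc$logits, yb, tc$alpha, tc$gamma)
        student$backward(0.5 * att$grad)
      }
      lr <- step_lr(tc, gstep, t_max)
      lr_trace <- c(lr_trace, lr)
      opt$step(lr)
      gstep <- gstep + 1L
      nb <- length(b)
      ep_kd <- ep_kd + kd$loss * nb
      ep_att <- ep_att + att$loss * nb
      ep_tot <- ep_tot + total_loss(kd$loss, att$loss) * nb
    }
    val_acc <- eval_accuracy(student, data$val$x, data$val$y)
    history <- rbind(history,
                     data.frame(epoch = ep, kd_loss = ep_kd / n,
                                attention_loss = ep_att / n,
                                total_loss = ep_tot / n, val_acc = val_acc,
                                lr = step_lr(tc, gstep - 1L, t_max)))
    if (val_acc > best$acc)
      best <- list(acc = val_acc, epoch = ep, state = state_dict(student))
  }
  structure(list(model = student, head = NULL, history = history,
                 best_state = best$state, best_epoch = best$epoch,
                 stats = stats, model_cfg = student_cfg, train_cfg = tc,
                 distill = dp, lr_trace = lr_trace, t_max = t_max),
            class = "macres_fit")
}

#' Train a plain supervised student (no distillation), same budget
#'
#' Baseline arm for distillation comparisons: identical architecture, data,
#' seeding and schedule, but the loss is the focal hard-label term only.
#'
#' @inheritParams distill_student
#' @return a `macres_fit`.
#' @export
train_plain_student <- function(student_cfg, data, tc, stats = NULL) {
  tc$use_bacm <- FALSE
  if (!is.null(stats)) {
    data$train$x <- apply_normalization(data$train$x, stats)
    data$val$x <- apply_normalization(data$val$x, stats)
    fit <- train_teacher(student_cfg, data, tc, normalize = FALSE)
    fit$stats <- stats
    fit
  } else {
    train_teacher(student_cfg, data, tc)
  }
}

#' Train a U-Net on lesion tiles
#'
#' Binary cross-entropy on per-pixel logits, Adam, cosine-annealed learning
#' rate.
#'
#' @param unet a `macres_unet` from [build_unet()] (modified in place).
#' @param x (H, W, 3, N) tile array in \[0, 1\].
#' @param masks (H, W, N) binary array of lesion masks.
#' @param tc a [train_config()] (`use_bacm` ignored).
#' @return list with `unet` and `history` (per-epoch mean loss).
#' @export
train_unet <- function(unet, x, masks, tc) {
  set.seed(tc$seed)
  n <- dim(x)[4L]
  opt <- optim_adam(unet, lr = tc$base_lr)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  t_max <- tc$t_max %||% (steps_per_epoch * tc$epochs)
  history <- NULL
  gstep <- 0L
  for (ep in seq_len(tc$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = tc$batch_size)) {
      b <- idx[s:min(n, s + tc$batch_size - 1L)]
      xb <- x[, , , b, drop = FALSE]
      yb <- array(masks[, , b], dim = c(dim(x)[1L], dim(x)[2L], 1L, length(b)))
      zero_grads(unet)
      z <- unet$forward(xb, training = TRUE)
      l <- bce_logits(z, yb)
      unet$backward(l$grad)
      opt$step(step_lr(tc, gstep, t_max))
      gstep <- gstep + 1L
      ep_loss <- ep_loss + l$loss * length(b)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / n))
  }
  list(unet = unet, history = history)
}

#' Predict lesion probabilities with a U-Net
#' @param unet trained `macres_unet`.
#' @param x (H, W, 3, N) tiles.
#' @param batch_size forward batch size.
#' @return (H, W, N) array of sigmoid probabilities.
#' @export
unet_predict <- function(unet, x, batch_size = 16L) {
  n <- dim(x)[4L]
  out <- array(0, dim = c(dim(x)[1L], dim(x)[2L], n))
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    z <- unet$forward(x[, , , s:e, drop = FALSE], training = FALSE)
    out[, , s:e] <- 1 / (1 + exp(-z[, , 1L, , drop = TRUE]))
  }
  out
}
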