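# Loss family and evaluation metrics: focal loss, temperature softmax,
# knowledge-distillation losses, label smoothing, confusion-matrix metrics
# and binary-mask overlap metrics.

#' Focal loss from true-class probabilities
#'
#' Computes the mean focal loss \eqn{-\alpha_t (1-p_t)^\gamma \log p_t} over a
#' vector of true-class probabilities. With `gamma = 0` and `alpha = 1` this
#' reduces to the ordinary cross-entropy \eqn{-\log p_t}. The focusing term
#' down-weights well-classified samples, which matters when tumor classes are
#' heavily imbalanced.
#'
#' @param pt numeric vector of predicted probabilities of the true class,
#'   each in (0, 1].
#' @param alpha per-class weighting factor \eqn{\alpha_t} (default 0.25).
#' @param gamma focusing exponent \eqn{\gamma \ge 0} (default 2).
#' @param eps clamp applied to `pt` before the log to guard `pt = 0`.
#' @return scalar mean focal loss.
#' @export
focal_loss <- function(pt, alpha = 0.25, gamma = 2, eps = 1e-12) {
  stopifnot(gamma >= 0, alpha > 0)
  if (any(pt < 0 | pt > 1)) stop("pt must lie in [0, 1]")
  if (any(pt <= 0)) {
    warning("focal_loss: pt = 0 clamped to eps")
    pt <- pmax(pt, eps)
  }
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Focal loss on logits, with gradient
#'
#' Training-time form: applies softmax to each row of `logits`, evaluates the
#' focal loss on the true-class probabilities and returns the analytic
#' gradient with respect to the logits (mean reduction over rows).
#'
#' @param logits numeric matrix, samples in rows, classes in columns.
#' @param labels integer class ids in `0:(K-1)`, one per row.
#' @param alpha,gamma focal-loss parameters, see [focal_loss()].
#' @return list with `loss` (scalar) and `grad` (matrix like `logits`).
#' @export
focal_loss_logits <- function(logits, labels, alpha = 0.25, gamma = 2) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels + 1L)
  pt <- pmax(p[idx], 1e-12)
  loss <- mean(-alpha * (1 - pt)^gamma * log(pt))
  # dL/dpt, then chain through softmax: dpt/dz_j = pt * (1[j = t] - p_j)
  dl_dpt <- if (gamma == 0) -alpha / pt else
    -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
  onehot <- p * 0
  onehot[idx] <- 1
  # dpt/dz_j = pt * (1[j = t] - p_j), so dL/dz_j = dL/dpt * pt * (1[j=t] - p_j)
  grad <- (onehot - p) * (dl_dpt * pt)
  list(loss = loss, grad = grad / n)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Temperature-scaled softmax (soft targets)
#'
#' \eqn{\mathrm{Softmax}(T)_i = \exp(z_i/T) / \sum_j \exp(z_j/T)}. At `T = 1`
#' this is the ordinary softmax used for hard labels; larger temperatures make
#' the output distribution more uniform, exposing the teacher's dark
#' knowledge about class similarity.
#'
#' @param logits numeric vector, or matrix with samples in rows.
#' @param temperature positive temperature `T`.
#' @return probability vector/matrix matching `logits`; rows sum to 1.
#' @export
soft_targets <- function(logits, temperature = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (is.matrix(logits)) return(softmax_rows(logits / temperature))
  e <- exp(logits / temperature - max(logits / temperature))
  e / sum(e)
}

#' Kullback-Leibler divergence KL(p || q)
#'
#' @param p,q probability vectors, or matrices with distributions in rows
#'   (mean over rows is returned for matrices).
#' @return scalar divergence in nats.
#' @export
kl_divergence <- function(p, q) {
  eps <- 1e-12
  if (is.matrix(p)) {
    mean(rowSums(p * (log(pmax(p, eps)) - log(pmax(q, eps)))))
  } else {
    sum(p * (log(pmax(p, eps)) - log(pmax(q, eps))))
  }
}

check_prob_rows <- function(x, name) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (any(x < -1e-9) || any(abs(rowSums(x) - 1) > 1e-6))
    stop(sprintf("%s must be rows of probabilities summing to 1", name))
  x
}

#' Knowledge-distillation loss
#'
#' \deqn{L_{KD} = (1-a)\, L_f(\mathrm{SHP}, \mathrm{label}) +
#'   a T^2 \, \mathrm{KL}(\mathrm{TSL} \,\|\, \mathrm{SSP})}
#' where SHP is the student's ordinary (T = 1) softmax output, SSP its
#' temperature-softened output, and TSL the teacher's soft labels at the same
#' temperature. The \eqn{T^2} factor keeps the soft-target gradients on the
#' same scale as the hard-label term.
#'
#' @param student_hard_pred student probabilities at T = 1 (rows = samples).
#' @param student_soft_pred student probabilities at temperature `T`.
#' @param teacher_soft_labels teacher probabilities at temperature `T`.
#' @param label integer class ids in `0:(K-1)`.
#' @param a mix weight in \[0, 1\]; `a = 0` is pure hard-label training.
#' @param temperature distillation temperature `T > 0`.
#' @param alpha,gamma focal parameters for the hard-label term.
#' @return scalar loss.
#' @export
kd_loss <- function(student_hard_pred, student_soft_pred, teacher_soft_labels,
                    label, a = 0.7, temperature = 4, alpha = 0.25, gamma = 2) {
  stopifnot(a >= 0, a <= 1, temperature > 0)
  shp <- check_prob_rows(student_hard_pred, "student_hard_pred")
  ssp <- check_prob_rows(student_soft_pred, "student_soft_pred")
  tsl <- check_prob_rows(teacher_soft_labels, "teacher_soft_labels")
  pt <- shp[cbind(seq_len(nrow(shp)), label + 1L)]
  (1 - a) * focal_loss(pt, alpha, gamma) +
    a * temperature^2 * kl_divergence(tsl, ssp)
}

#' Total distillation loss
#'
#' \deqn{T_{loss} = \tfrac12 L_{KD} + \tfrac12 L_f(\textrm{attention pass})}
#' The second term is the focal loss of the prediction made on the
#' AttentionPicture (the attention-guided crop re-fed to the network).
#' Weights are configurable; `(1, 0)` degenerates to the KD loss alone.
#'
#' @param l_kd knowledge-distillation loss term.
#' @param attention_pass_loss focal loss of the attention-crop pass.
#' @param w_kd,w_att the two mixing weights (default 1/2, 1/2).
#' @return scalar total loss.
#' @export
total_loss <- function(l_kd, attention_pass_loss, w_kd = 0.5, w_att = 0.5) {
  stopifnot(is.finite(l_kd), is.finite(attention_pass_loss))
  w_kd * l_kd + w_att * attention_pass_loss
}

#' Label-smoothing cross-entropy
#'
#' Cross-entropy against the smoothed target that puts `1 - s` on the true
#' class and `s / (K - 1)` on each other class.
#'
#' @param logits numeric matrix (samples x classes) or vector.
#' @param label integer class ids in `0:(K-1)`.
#' @param smoothing smoothing factor `s` in \[0, 1) (default 0.1).
#' @return list with `loss` and `grad` with respect to the logits.
#' @export
label_smoothing_loss <- function(logits, label, smoothing = 0.1) {
  stopifnot(smoothing >= 0, smoothing < 1)
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  k <- ncol(logits)
  p <- softmax_rows(logits)
  n <- nrow(logits)
  q <- matrix(smoothing / (k - 1), n, k)
  q[cbind(seq_len(n), label + 1L)] <- 1 - smoothing
  logp <- log(pmax(p, 1e-12))
  list(loss = -mean(rowSums(q * logp)), grad = (p - q) / n)
}

#' Gradient of the KD loss with respect to the student logits
#'
#' @param student_logits matrix (samples x classes), raw student outputs.
#' @param teacher_soft_labels teacher probabilities at temperature `T`.
#' @param label integer class ids.
#' @inheritParams kd_loss
#' @return list with `loss` and `grad` (matrix like `student_logits`).
#' @keywords internal
kd_loss_grad <- function(student_logits, teacher_soft_labels, label,
                         a = 0.7, temperature = 4, alpha = 0.25, gamma = 2) {
  hard <- focal_loss_logits(student_logits, label, alpha, gamma)
  ssp <- softmax_rows(student_logits / temperature)
  tsl <- check_prob_rows(teacher_soft_labels, "teacher_soft_labels")
  n <- nrow(ssp)
  klv <- kl_divergence(tsl, ssp)
  # d/dz of T^2 * KL(t || softmax(z/T)) = T * (s - t); mean over rows
  gkl <- temperature * (ssp - tsl) / n
  list(loss = (1 - a) * hard$loss + a * temperature^2 * klv,
       grad = (1 - a) * hard$grad + a * temperature * (ssp - tsl) / n)
}

#' One-vs-rest confusion counts
#'
#' @param labels true integer class ids.
#' @param preds predicted integer class ids.
#' @param n_classes number of classes `K`.
#' @return data.frame with one row per class: `class`, `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, preds, n_classes) {
  stopifnot(length(labels) == length(preds))
  out <- lapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(labels == k & preds == k)
    fp <- sum(labels != k & preds == k)
    fn <- sum(labels == k & preds != k)
    tn <- sum(labels != k & preds != k)
    data.frame(class = k, TP = tp, FP = fp, TN = tn, FN = fn)
  })
  do.call(rbind, out)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP),
#' Accuracy = (TP+TN)/(TP+TN+FP+FN). A zero denominator yields `NA` with
#' `undefined = TRUE` rather than NaN propagation.
#'
#' @param counts a one-row data.frame or list with `TP`, `FP`, `TN`, `FN`.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `undefined`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  acc <- safe(tp + tn, tp + tn + fp + fn)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       undefined = any(is.na(c(sens, spec, acc))))
}

#' IoU and Dice overlap of two binary masks
#'
#' IoU = TP/(FN+TP+FP) and Dice = 2 TP/(FN+2 TP+FP) over pixels. When both
#' masks are empty there is nothing to miss, and both metrics are defined as
#' 1 (logged convention).
#'
#' @param pred,truth binary matrices of identical shape (values 0/1).
#' @return list with `iou`, `dice`, `TP`, `FP`, `FN`.
#' @export
segmentation_metrics <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (0/1)")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (tp + fp + fn == 0) {
    message("segmentation_metrics: both masks empty; IoU = Dice = 1 by convention")
    return(list(iou = 1, dice = 1, TP = 0L, FP = 0L, FN = 0L))
  }
  list(iou = tp / (fn + tp + fp), dice = 2 * tp / (fn + 2 * tp + fp),
       TP = tp, FP = fp, FN = fn)
}

# binary cross-entropy on logits, for the U-Net ------------------------------

bce_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  grad <- (1 / (1 + exp(-z)) - y) / length(z)
  list(loss = loss, grad = grad)
}
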