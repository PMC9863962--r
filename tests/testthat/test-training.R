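# Cosine schedule closed form, deterministic histories, checkpointing, and
# the frozen-teacher contract during distillation.

test_that("cosine annealing hits the endpoints and restarts", {
  expect_equal(cosine_lr(0, 1e-3, 100), 1e-3)
  expect_equal(cosine_lr(100, 1e-3, 100, eta_min = 1e-6), 1e-6)
  expect_equal(cosine_lr(50, 1e-3, 100), (1e-3) / 2, tolerance = 1e-9)
  # the step after the minimum restarts toward base_lr
  after <- cosine_lr(101, 1e-3, 100, eta_min = 1e-6)
  expect_gt(after, 0.9e-3)
  expect_equal(cosine_lr(200, 1e-3, 100, eta_min = 1e-6), 1e-6)
  # closed-form trace over two periods
  for (s in 0:250) {
    phase <- s %% 100
    if (s > 0 && phase == 0) phase <- 100
    expect_equal(cosine_lr(s, 2e-3, 100, 1e-5),
                 1e-5 + 0.5 * (2e-3 - 1e-5) * (1 + cos(pi * phase / 100)))
  }
})

tiny_data <- function(n_per_class = 8, size = 32L, seed = 123) {
  # directly separable micro-dataset: class-tinted noise tiles
  set.seed(seed)
  tint <- rbind(c(0.9, 0.7, 0.8), c(0.4, 0.3, 0.6),
                c(0.7, 0.6, 0.3), c(0.3, 0.2, 0.2))
  mk <- function(n) {
    x <- array(0, c(size, size, 3, n * 4))
    y <- integer(n * 4)
    k <- 0
    for (cl in 0:3) for (i in seq_len(n)) {
      k <- k + 1
      for (ch in 1:3)
        x[, , ch, k] <- pmin(1, pmax(0, tint[cl + 1, ch] +
                                       0.1 * matrix(rnorm(size^2), size)))
      y[k] <- cl
    }
    list(x = x, y = y)
  }
  list(train = mk(n_per_class), val = mk(3))
}

tiny_cfg <- function() miniature_config(width_multiplier = 0.0625,
                                        input_size = 32L, spp_levels = 1L,
                                        blocks_per_stage = c(1L, 1L, 1L, 1L))

test_that("teacher training is deterministic and logs a closed-form lr trace", {
  data <- tiny_data()
  tc <- train_config(epochs = 2, batch_size = 8, base_lr = 1e-3, seed = 5,
                     use_bacm = TRUE, t_max = 4, eta_min = 1e-6)
  f1 <- train_teacher(tiny_cfg(), data, tc)
  f2 <- train_teacher(tiny_cfg(), data, tc)
  expect_identical(f1$history, f2$history)
  expect_equal(param_checksum(f1$model), param_checksum(f2$model))
  # the logged lr trace equals the closed form at every step, restart included
  steps <- seq_along(f1$lr_trace) - 1L
  expect_equal(f1$lr_trace,
               vapply(steps, cosine_lr, numeric(1), base_lr = 1e-3,
                      t_max = 4, eta_min = 1e-6))
  expect_lt(min(f1$lr_trace), 1e-5)        # reaches the floor mid-run
  expect_gt(f1$lr_trace[6], f1$lr_trace[4])  # and restarts afterwards
})

test_that("training reduces the loss and tracks the best validation epoch", {
  data <- tiny_data(n_per_class = 10)
  tc <- train_config(epochs = 3, batch_size = 8, base_lr = 2e-3, seed = 6,
                     use_bacm = FALSE)
  fit <- train_teacher(tiny_cfg(), data, tc)
  expect_equal(nrow(fit$history), 3)
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
  expect_equal(fit$best_epoch,
               which.max(fit$history$val_acc))   # ties resolve earlier anyway
  expect_error(train_teacher(tiny_cfg(),
                             list(train = data$train,
                                  val = list(x = data$val$x[, , , 0,
                                                            drop = FALSE],
                                             y = integer(0))), tc),
               "empty")
})

test_that("checkpoints round-trip weights, stats and config", {
  data <- tiny_data()
  tc <- train_config(epochs = 1, batch_size = 8, base_lr = 1e-3, seed = 7)
  fit <- train_teacher(tiny_cfg(), data, tc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  xv <- apply_normalization(data$val$x, fit$stats)
  expect_equal(predict_proba(back$model, xv), predict_proba(fit$model, xv),
               tolerance = 1e-12)
  expect_equal(back$stats$mean, fit$stats$mean)
})

test_that("the teacher is frozen during distillation", {
  data <- tiny_data()
  teacher <- train_teacher(tiny_cfg(), data,
                           train_config(epochs = 1, batch_size = 8,
                                        base_lr = 1e-3, seed = 8))
  before <- param_checksum(teacher$model)
  kd <- distill_student(teacher, student_config(tiny_cfg()), data,
                        distill_params(a = 0.7, temperature = 4),
                        train_config(epochs = 1, batch_size = 8,
                                     base_lr = 1e-3, seed = 9))
  expect_equal(param_checksum(teacher$model), before)
  expect_true(all(c("kd_loss", "attention_loss", "total_loss") %in%
                    names(kd$history)))
  expect_true(all(is.finite(kd$history$total_loss)))
  # class-count mismatch is rejected
  bad_cfg <- student_config(miniature_config(n_classes = 3,
                                             width_multiplier = 0.0625,
                                             input_size = 32L,
                                             blocks_per_stage = rep(1L, 4)))
  expect_error(distill_student(teacher, bad_cfg, data, distill_params(),
                               train_config(epochs = 1, seed = 1)),
               "mismatch")
})

test_that("distillation from an uninformative teacher still trains", {
  data <- tiny_data(n_per_class = 6)
  # untrained teacher: near-uniform soft labels; KL term finite, run completes
  set.seed(10)
  mdl <- build_backbone(tiny_cfg())
  teacher <- list(model = mdl,
                  head = build_attention_head(mdl$out_channels, 4),
                  stats = fit_normalization(data$train$x),
                  model_cfg = tiny_cfg())
  class(teacher) <- "macres_fit"
  kd <- distill_student(teacher, student_config(tiny_cfg()), data,
                        distill_params(a = 0.7, temperature = 4),
                        train_config(epochs = 1, batch_size = 8,
                                     base_lr = 1e-3, seed = 11))
  expect_true(all(is.finite(kd$history$kd_loss)))
})

test_that("a = 0 with zero attention weight reduces to plain supervision", {
  # degenerate mixing: the KD gradient contribution equals the pure focal one
  set.seed(12)
  z <- matrix(rnorm(12), 3, 4)
  tsl <- macresnet:::softmax_rows(matrix(rnorm(12), 3, 4))
  y <- c(0L, 1L, 3L)
  kd <- macresnet:::kd_loss_grad(z, tsl, y, a = 0, temperature = 4)
  pf <- focal_loss_logits(z, y)
  expect_equal(kd$loss, pf$loss)
  expect_equal(kd$grad, pf$grad)
})

test_that("U-Net training reduces the segmentation loss", {
  set.seed(13)
  n <- 24
  x <- array(0, c(16, 16, 3, n)); m <- array(0, c(16, 16, n))
  for (i in seq_len(n)) {
    r <- sample(4:10, 1)
    x[, , , i] <- array(runif(16 * 16 * 3, 0.6, 0.9), c(16, 16, 3))
    x[r:(r + 4), 3:10, 1, i] <- 0.1          # dark lesion in channel 1
    m[r:(r + 4), 3:10, i] <- 1
  }
  u <- build_unet(3, 4, depth = 2)
  fit <- train_unet(u, x, m, train_config(epochs = 4, batch_size = 8,
                                          base_lr = 2e-3, seed = 14))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  pr <- unet_predict(fit$unet, x[, , , 1:2, drop = FALSE])
  expect_equal(dim(pr), c(16, 16, 2))
  expect_true(all(pr >= 0 & pr <= 1))
})
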