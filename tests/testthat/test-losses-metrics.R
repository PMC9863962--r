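# Loss family and metric formulas, each checked against independent scalar
# arithmetic and (for the training forms) finite-difference gradients.

test_that("focal loss matches closed-form values and reduces to cross-entropy", {
  expect_equal(focal_loss(1, alpha = 0.25, gamma = 2), 0)
  expect_equal(focal_loss(0.5, alpha = 0.25, gamma = 2),
               0.25 * 0.25 * (-log(0.5)))
  pt <- c(0.2, 0.5, 0.9)
  expect_equal(focal_loss(pt, alpha = 1, gamma = 0), mean(-log(pt)))
  # focusing down-weights: focal <= cross-entropy for gamma > 0, alpha = 1
  set.seed(1)
  for (i in 1:20) {
    p <- runif(5, 0.01, 1)
    expect_lte(focal_loss(p, alpha = 1, gamma = 2),
               focal_loss(p, alpha = 1, gamma = 0))
  }
  expect_error(focal_loss(1.2), "pt")
  expect_warning(focal_loss(c(0, 0.5)), "clamped")
})

test_that("focal loss on logits agrees with the scalar form and its gradient", {
  set.seed(2)
  for (i in 1:10) {
    z <- matrix(rnorm(3 * 4, sd = 2), 3, 4)
    y <- sample(0:3, 3, replace = TRUE)
    r <- focal_loss_logits(z, y, alpha = 0.25, gamma = 2)
    p <- macresnet:::softmax_rows(z)
    pt <- p[cbind(1:3, y + 1)]
    expect_equal(r$loss, mean(-0.25 * (1 - pt)^2 * log(pt)), tolerance = 1e-12)
    idx <- sample(length(z), 4)
    g <- num_grad(function(v) { z0 <- z; z0[] <- v
      focal_loss_logits(z0, y, 0.25, 2)$loss }, as.vector(z), idx)
    expect_equal(as.vector(r$grad)[idx], g, tolerance = 1e-6)
  }
})

test_that("temperature softmax: uniformity, T = 1 case, closed form", {
  expect_equal(soft_targets(c(3, 3, 3), 5), rep(1 / 3, 3))
  z <- c(0.3, -1, 2)
  expect_equal(soft_targets(z, 1), exp(z) / sum(exp(z)))
  expect_equal(soft_targets(c(1, 2), 2),
               c(exp(0.5), exp(1)) / (exp(0.5) + exp(1)))
  expect_equal(soft_targets(c(1, 2), 2)[1], 0.37754067, tolerance = 1e-7)
  # larger T flattens the distribution
  s1 <- soft_targets(z, 1); s8 <- soft_targets(z, 8)
  expect_lt(max(s8) - min(s8), max(s1) - min(s1))
  expect_error(soft_targets(z, 0), "temperature")
  m <- soft_targets(matrix(rnorm(12), 3, 4), 3)
  expect_equal(rowSums(m), rep(1, 3))
})

test_that("KD loss combines focal and T^2-scaled KL as stated", {
  set.seed(3)
  shp <- macresnet:::softmax_rows(matrix(rnorm(8), 2, 4))
  ssp <- macresnet:::softmax_rows(matrix(rnorm(8), 2, 4))
  tsl <- macresnet:::softmax_rows(matrix(rnorm(8), 2, 4))
  y <- c(1L, 3L)
  a <- 0.7; temp <- 4
  got <- kd_loss(shp, ssp, tsl, y, a = a, temperature = temp)
  pt <- shp[cbind(1:2, y + 1)]
  want <- (1 - a) * mean(-0.25 * (1 - pt)^2 * log(pt)) +
    a * temp^2 * mean(rowSums(tsl * (log(tsl) - log(ssp))))
  expect_equal(got, want, tolerance = 1e-9)
  # a = 0: pure hard-label focal term
  expect_equal(kd_loss(shp, ssp, tsl, y, a = 0, temperature = temp),
               focal_loss(pt))
  # matched distributions: KL term vanishes
  expect_equal(kd_loss(shp, tsl, tsl, y, a = a, temperature = temp),
               (1 - a) * focal_loss(pt), tolerance = 1e-9)
  expect_error(kd_loss(shp * 2, ssp, tsl, y), "probabilities")
})

test_that("KD gradient matches finite differences", {
  set.seed(4)
  z <- matrix(rnorm(12), 3, 4)
  tsl <- macresnet:::softmax_rows(matrix(rnorm(12), 3, 4))
  y <- c(0L, 2L, 1L)
  r <- macresnet:::kd_loss_grad(z, tsl, y, a = 0.7, temperature = 4)
  idx <- sample(length(z), 6)
  g <- num_grad(function(v) { z0 <- z; z0[] <- v
    macresnet:::kd_loss_grad(z0, tsl, y, 0.7, 4)$loss }, as.vector(z), idx)
  expect_equal(as.vector(r$grad)[idx], g, tolerance = 1e-6)
  # consistency with the probability-space form
  shp <- macresnet:::softmax_rows(z)
  ssp <- macresnet:::softmax_rows(z / 4)
  expect_equal(r$loss, kd_loss(shp, ssp, tsl, y, 0.7, 4), tolerance = 1e-9)
})

test_that("total loss is the stated mean and degenerates correctly", {
  expect_equal(total_loss(0.8, 0.6), 0.7)
  expect_equal(total_loss(0.8, 0), 0.4)
  expect_equal(total_loss(0.8, 0.6, w_kd = 1, w_att = 0), 0.8)
})

test_that("label smoothing: s = 0 is cross-entropy, uniform logits give log K", {
  set.seed(5)
  z <- matrix(rnorm(8), 2, 4)
  y <- c(2L, 0L)
  r0 <- label_smoothing_loss(z, y, smoothing = 0)
  p <- macresnet:::softmax_rows(z)
  expect_equal(r0$loss, mean(-log(p[cbind(1:2, y + 1)])), tolerance = 1e-9)
  for (s in c(0, 0.1, 0.4))
    expect_equal(label_smoothing_loss(matrix(0, 1, 4), 1L, s)$loss, log(4))
  # confident logits: the smoothed target keeps a positive floor on the loss
  zc <- matrix(c(30, 0, 0, 0), 1, 4)
  r <- label_smoothing_loss(zc, 0L, smoothing = 0.1)
  expect_gt(r$loss, 0.9)  # ~ (s/(K-1)) * sum of non-true logit gaps = 0.1*30/3
  idx <- 1:8
  g <- num_grad(function(v) { z0 <- z; z0[] <- v
    label_smoothing_loss(z0, y, 0.1)$loss }, as.vector(z), idx)
  expect_equal(as.vector(label_smoothing_loss(z, y, 0.1)$grad), g,
               tolerance = 1e-6)
})

test_that("classification metrics match the printed formulas and a recount", {
  m <- classification_metrics(list(TP = 8, FN = 2, TN = 90, FP = 0))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.98)
  expect_false(m$undefined)
  m2 <- classification_metrics(list(TP = 5, FN = 0, TN = 20, FP = 0))
  expect_equal(c(m2$sensitivity, m2$specificity, m2$accuracy), c(1, 1, 1))
  m3 <- classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(m3$sensitivity) && m3$undefined)
  set.seed(6)
  for (i in 1:10) {
    y <- sample(0:3, 50, replace = TRUE)
    p <- sample(0:3, 50, replace = TRUE)
    cc <- confusion_counts(y, p, 4)
    for (k in 0:3) {
      row <- cc[cc$class == k, ]
      expect_equal(row$TP, sum(y == k & p == k))
      expect_equal(row$FN, sum(y == k & p != k))
      expect_equal(row$FP, sum(y != k & p == k))
      expect_equal(row$TN + row$TP + row$FP + row$FN, 50)
      mm <- classification_metrics(row)
      if (!mm$undefined) {
        expect_equal(mm$sensitivity, row$TP / (row$TP + row$FN))
        expect_equal(mm$accuracy, mean((y == k) == (p == k)))
      }
    }
  }
})

test_that("IoU and Dice match formulas and the Dice-IoU identity", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(segmentation_metrics(a, a)$iou, 1)
  expect_equal(segmentation_metrics(a, 1 - a)$iou, 0)
  expect_equal(segmentation_metrics(a, 1 - a)$dice, 0)
  # TP=6, FP=2, FN=2
  pred <- matrix(0, 4, 4); truth <- matrix(0, 4, 4)
  pred[1:2, 1:4] <- 1          # 8 predicted
  truth[1:2, 1:3] <- 1; truth[3, 1:2] <- 1  # 8 true, 6 overlap
  sm <- segmentation_metrics(pred, truth)
  expect_equal(c(sm$TP, sm$FP, sm$FN), c(6, 2, 2))
  expect_equal(sm$iou, 0.6)
  expect_equal(sm$dice, 0.75)
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    t <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    sm <- segmentation_metrics(p, t)
    expect_equal(sm$dice, 2 * sm$iou / (1 + sm$iou), tolerance = 1e-12)
  }
  expect_message(z <- segmentation_metrics(matrix(0, 2, 2), matrix(0, 2, 2)),
                 "convention")
  expect_equal(c(z$iou, z$dice), c(1, 1))
  expect_error(segmentation_metrics(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
})

test_that("losses are non-negative and KL vanishes only at equality", {
  set.seed(8)
  for (i in 1:20) {
    p <- soft_targets(rnorm(4), 2)
    q <- soft_targets(rnorm(4), 2)
    expect_gte(kl_divergence(p, q), -1e-12)
  }
  p <- soft_targets(rnorm(4), 1)
  expect_equal(kl_divergence(p, p), 0, tolerance = 1e-12)
})
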