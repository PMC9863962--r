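# Tiling arithmetic, the strict coverage rule, the encoded-size filter and
# normalization statistics.

test_that("window enumeration matches brute-force containment", {
  spec <- patch_spec(512, 256, min_encoded_bytes = 0)
  w <- enumerate_windows(1024, 1024, spec)
  expect_equal(nrow(w), 9)
  expect_equal(sort(unique(w$row)), c(0, 256, 512))
  expect_equal(sort(unique(w$col)), c(0, 256, 512))
  expect_equal(nrow(enumerate_windows(512, 512, spec)), 1)
  expect_warning(e <- enumerate_windows(511, 1024, spec), "smaller")
  expect_equal(nrow(e), 0)
  # brute force: every (r, c) with r,c multiples of stride and window inside
  for (hw in list(c(700, 900), c(512, 768))) {
    w <- enumerate_windows(hw[1], hw[2], spec)
    brute <- expand.grid(row = 0:(hw[1]), col = 0:(hw[2]))
    brute <- brute[brute$row %% 256 == 0 & brute$col %% 256 == 0 &
                     brute$row + 512 <= hw[1] & brute$col + 512 <= hw[2], ]
    expect_equal(nrow(w), nrow(brute))
    expect_setequal(paste(w$row, w$col), paste(brute$row, brute$col))
  }
  # row-major order: origins sorted by row then col
  w <- enumerate_windows(1024, 1024, spec)
  expect_equal(order(w$row, w$col), seq_len(nrow(w)))
})

make_slide <- function(mask, label = 1L, id = "s") {
  img <- array(runif(length(mask) * 3), dim = c(dim(mask), 3))
  wsi_record(img, mask, label, id)
}

test_that("coverage rule is strict: exactly 3/4 is discarded", {
  spec <- patch_spec(64, 64, 3 / 4, min_encoded_bytes = 0)
  mask <- matrix(0L, 64, 64)
  mask[1:48, ] <- 1L                  # exactly 0.75 coverage
  set.seed(1)
  expect_length(extract_patches(make_slide(mask), spec), 0)
  mask[49, 1] <- 1L                   # one pixel above the threshold
  got <- extract_patches(make_slide(mask), spec)
  expect_length(got, 1)
  expect_gt(got[[1]]$coverage, 0.75)
})

test_that("full-coverage slide keeps all 9 windows with slide labels", {
  set.seed(2)
  spec <- patch_spec(512, 256, min_encoded_bytes = 0)
  slide <- make_slide(matrix(1L, 1024, 1024), label = 2L, id = "full")
  got <- extract_patches(slide, spec)
  expect_length(got, 9)
  expect_true(all(vapply(got, function(p) p$coverage, numeric(1)) == 1))
  expect_true(all(vapply(got, function(p) p$label, integer(1)) == 2L))
  expect_equal(attr(got, "n_windows"), 9)
  expect_equal(attr(got, "n_discarded_coverage"), 0)
})

test_that("retained windows equal a per-window pixel-count oracle", {
  spec <- patch_spec(64, 32, 3 / 4, min_encoded_bytes = 0)
  set.seed(3)
  for (trial in 1:20) {
    mask <- matrix(rbinom(256 * 256, 1, runif(1, 0.5, 0.95)), 256, 256)
    slide <- make_slide(mask)
    got <- extract_patches(slide, spec)
    # oracle: recount every window by explicit pixel loops
    wins <- enumerate_windows(256, 256, spec)
    oracle_keep <- c()
    for (i in seq_len(nrow(wins))) {
      cnt <- 0
      for (r in (wins$row[i] + 1):(wins$row[i] + 64))
        cnt <- cnt + sum(mask[r, (wins$col[i] + 1):(wins$col[i] + 64)])
      if (cnt / (64 * 64) > 3 / 4)
        oracle_keep <- c(oracle_keep, paste(wins$row[i], wins$col[i]))
    }
    got_keys <- vapply(got, function(p) paste(p$origin[1], p$origin[2]),
                       character(1))
    if (is.null(oracle_keep)) oracle_keep <- character(0)
    expect_setequal(got_keys, oracle_keep)
    # conservation
    expect_equal(length(got) + attr(got, "n_discarded_coverage"), nrow(wins))
  }
})

test_that("pasting retained patches back reproduces the source", {
  set.seed(4)
  spec <- patch_spec(64, 32, 0.5, min_encoded_bytes = 0)
  mask <- matrix(rbinom(128 * 128, 1, 0.8), 128, 128)
  slide <- make_slide(mask)
  got <- extract_patches(slide, spec)
  expect_gt(length(got), 0)
  recon <- array(NA_real_, dim = dim(slide$image))
  for (p in got) {
    r <- p$origin[1]; cc <- p$origin[2]
    recon[(r + 1):(r + 64), (cc + 1):(cc + 64), ] <- p$pixels
  }
  covered <- !is.na(recon)
  expect_equal(recon[covered], slide$image[covered])
})

test_that("encoded-size filter discards flat tiles and honors the threshold", {
  set.seed(5)
  spec <- patch_spec(64, 64)  # default 330 kb scaled by (64/512)^2
  flat <- structure(list(pixels = array(0.5, c(64, 64, 3)),
                         origin = c(row = 0, col = 0), coverage = 1,
                         label = 1L, slide_id = "flat"),
                    class = "patch_record")
  noise <- flat
  noise$pixels <- array(runif(64 * 64 * 3), c(64, 64, 3))
  r_flat <- size_filter(flat, spec)
  r_noise <- size_filter(noise, spec)
  expect_false(r_flat$keep)
  expect_true(r_noise$keep)
  expect_lt(r_flat$bytes, r_noise$bytes)
  expect_equal(r_flat$threshold, 330 * 1024 * (64 / 512)^2)
  # threshold 0 disables the rule
  spec0 <- patch_spec(64, 64, min_encoded_bytes = 0)
  expect_true(size_filter(flat, spec0)$keep)
  # the unavailable codec fails loudly rather than silently
  specj <- patch_spec(64, 64, codec = "jpeg-q95")
  expect_error(size_filter(flat, specj), "codec")
})

test_that("tissue-fraction filter mode distinguishes empty from busy tiles", {
  spec <- patch_spec(64, 64, filter_mode = "tissue_fraction",
                     min_tissue_fraction = 0.1)
  white <- structure(list(pixels = array(1, c(64, 64, 3))),
                     class = "patch_record")
  busy <- structure(list(pixels = array(0.4, c(64, 64, 3))),
                    class = "patch_record")
  expect_false(size_filter(white, spec)$keep)
  expect_true(size_filter(busy, spec)$keep)
})

test_that("normalization is fit on train only and standardizes exactly", {
  set.seed(6)
  x <- array(rnorm(16 * 16 * 3 * 40, mean = rep(c(1, 2, 3), each = 256)),
             c(16, 16, 3, 40))
  st <- fit_normalization(x)
  expect_equal(st$mean, apply(x, 3, mean))
  z <- apply_normalization(x, st)
  for (ch in 1:3) {
    expect_equal(mean(z[, , ch, ]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(as.vector(z[, , ch, ])), 1, tolerance = 1e-10)
  }
  # known moments recovered
  x2 <- array(0, c(4, 4, 3, 10))
  x2[, , 1, ] <- 5; x2[, , 2, ] <- rnorm(160, 1, 2); x2[, , 3, ] <- rnorm(160)
  expect_error(fit_normalization(x2), "zero-variance")
  # val data normalized with TRAIN stats need not be centered
  val <- x + 1
  zv <- apply_normalization(val, st)
  expect_gt(abs(mean(zv)), 0.5)
  # degenerate: all-identical patches
  expect_error(fit_normalization(array(0.3, c(8, 8, 3, 5))), "zero-variance")
})

test_that("patch dataset builder harvests all four classes", {
  set.seed(7)
  cfg <- synthetic_config(image_size = 128, n_slides_per_class = 3,
                          lesion_shape = "rectangle",
                          lesion_fraction_range = c(0.4, 0.6), seed = 5)
  recs <- lapply(0:3, function(cl) generate_slide(cfg, cl, 100 + cl))
  spec <- patch_spec(64, 32, 3 / 4, min_encoded_bytes = 0)
  ds <- build_patch_dataset(recs, spec, n_per_class = 4, seed = 9)
  expect_setequal(unique(ds$y), 0:3)
  expect_equal(dim(ds$x)[4], length(ds$y))
  expect_lte(max(table(ds$y)), 4)
})
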