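# Shared fixtures. Heavy artifacts (synthetic dataset, trained miniature
# networks) are built once per session and memoized, so the training tests
# and the end-to-end checks share one set of study-condition runs.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# study conditions for the miniature experiments: 256-px slides, rectangular
# lesions covering 35-65% of the slide, 64-px patches at stride 16,
# 200 training patches per class (800 total), width-1/16 networks
mini_synth_cfg <- function(seed = 42L) {
  synthetic_config(image_size = 256L, n_slides_per_class = 10L,
                   lesion_shape = "rectangle",
                   lesion_fraction_range = c(0.35, 0.65), seed = seed)
}

mini_patch_spec <- function() {
  patch_spec(patch_size = 64L, stride = 16L, coverage_threshold = 3 / 4,
             min_encoded_bytes = 0)
}

mini_model_cfg <- function() miniature_config(width_multiplier = 0.0625)

mini_dataset <- function() {
  memo("mini_dataset", function() {
    ds <- generate_dataset(mini_synth_cfg())
    spec <- mini_patch_spec()
    tr <- build_patch_dataset(ds$records[ds$manifest$split == "train"], spec,
                              n_per_class = 200L, seed = 7L)
    va <- build_patch_dataset(ds$records[ds$manifest$split == "val"], spec,
                              n_per_class = 60L, seed = 8L)
    list(slides = ds, data = list(train = list(x = tr$x, y = tr$y),
                                  val = list(x = va$x, y = va$y)))
  })
}

# the reference miniature teacher: 5 epochs of BACM training (criterion run)
trained_teacher <- function() {
  memo("teacher", function() {
    d <- mini_dataset()
    tc <- train_config(epochs = 5L, batch_size = 8L, base_lr = 1e-3,
                       seed = 11L, use_bacm = TRUE)
    train_teacher(mini_model_cfg(), d$data, tc)
  })
}

# per-class U-Nets trained on lesion tiles from the training slides
trained_unets <- function() {
  memo("unets", function() {
    d <- mini_dataset()
    man <- d$slides$manifest
    spec <- patch_spec(64L, 32L, coverage_threshold = 0.05,
                      min_encoded_bytes = 0)
    unets <- list()
    for (cls in 1:3) {
      recs <- d$slides$records[man$split == "train" & man$label == cls]
      tiles <- list(); masks <- list()
      for (rec in recs) {
        wins <- enumerate_windows(nrow(rec$mask), ncol(rec$mask), spec)
        for (i in seq_len(nrow(wins))) {
          r <- wins$row[i]; cc <- wins$col[i]
          tiles[[length(tiles) + 1L]] <-
            rec$image[(r + 1):(r + 64), (cc + 1):(cc + 64), , drop = FALSE]
          masks[[length(masks) + 1L]] <-
            rec$mask[(r + 1):(r + 64), (cc + 1):(cc + 64)]
        }
      }
      keep <- with_seed_local(100 + cls,
                              sample(length(tiles), min(200L, length(tiles))))
      x <- array(0, dim = c(64, 64, 3, length(keep)))
      m <- array(0, dim = c(64, 64, length(keep)))
      for (j in seq_along(keep)) {
        x[, , , j] <- tiles[[keep[j]]]
        m[, , j] <- masks[[keep[j]]]
      }
      un <- with_seed_local(200 + cls, build_unet(3L, 4L, depth = 2L))
      fit <- train_unet(un, x, m, train_config(epochs = 3L, batch_size = 8L,
                                               base_lr = 2e-3,
                                               seed = 300 + cls))
      unets[[as.character(cls)]] <- fit$unet
    }
    unets
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# independent finite-difference gradient of f at x (scalar-valued f)
num_grad <- function(f, x, idx, h = 1e-5) {
  vapply(idx, function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

rand_tile <- function(h = 16L, w = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(h * w * 3), dim = c(h, w, 3L))
}
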