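#' @useDynLib macresnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal define-and-run CNN engine.
#
# Tensors are numeric arrays with dim (H, W, C, N). Each module is an
# environment carrying forward()/backward() closures, leaf parameters and a
# list of child modules. backward() accumulates parameter gradients and
# returns the gradient with respect to the module input. All randomness goes
# through R's RNG so runs are reproducible under set.seed().
# ---------------------------------------------------------------------------

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- value * 0   # matches shape and attributes of the value
  p$m <- p$g
  p$s <- p$g
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_module <- function(type) {
  self <- new.env()
  self$type <- type
  self$params <- list()
  self$children <- list()
  class(self) <- c(paste0("nn_", type), "nn_module")
  self
}

#' Collect all leaf parameters of a module tree
#' @param mod an `nn_module`
#' @return flat list of parameter environments
#' @keywords internal
collect_params <- function(mod) {
  out <- mod$params
  for (ch in mod$children) out <- c(out, collect_params(ch))
  out
}

#' Total number of trainable scalars in a module tree
#' @param mod an `nn_module`
#' @return integer count
#' @export
n_parameters <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(p$v), numeric(1)))
}

zero_grads <- function(mod) {
  for (p in collect_params(mod)) p$g[] <- 0
  invisible(mod)
}

# channel-wise helpers for (H, W, C, N) arrays ------------------------------

channel_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, d[1L] * d[2L])), d[3L]))
}

channel_bcast <- function(v, d) {
  # length(v) == C; recycles over N because the array is (H, W, C, N)
  rep(v, each = d[1L] * d[2L])
}

# conv ----------------------------------------------------------------------

nn_conv <- function(in_c, out_c, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    bias = TRUE) {
  self <- new_module("conv")
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad); self$in_c <- in_c; self$out_c <- out_c
  fan_in <- k * k * in_c
  self$W <- new_param(matrix(stats::rnorm(out_c * fan_in, sd = sqrt(2 / fan_in)),
                             out_c, fan_in))
  self$params <- list(self$W)
  if (bias) {
    self$b <- new_param(numeric(out_c))
    self$params <- c(self$params, list(self$b))
  } else self$b <- NULL

  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    cols <- cpp_im2col(x, self$k, self$k, self$stride, self$pad)
    y <- self$W$v %*% cols
    if (!is.null(self$b)) y <- y + self$b$v
    ho <- (d[1L] + 2L * self$pad - self$k) %/% self$stride + 1L
    wo <- (d[2L] + 2L * self$pad - self$k) %/% self$stride + 1L
    self$cache <- list(cols = cols, dimx = d, ho = ho, wo = wo)
    dim(y) <- c(self$out_c, ho, wo, d[4L])
    aperm(y, c(2L, 3L, 1L, 4L))
  }
  self$backward <- function(dy) {
    ca <- self$cache
    dY <- aperm(dy, c(3L, 1L, 2L, 4L))
    dim(dY) <- c(self$out_c, ca$ho * ca$wo * ca$dimx[4L])
    self$W$g <- self$W$g + dY %*% t(ca$cols)
    if (!is.null(self$b)) self$b$g <- self$b$g + rowSums(dY)
    dcols <- crossprod(self$W$v, dY)
    cpp_col2im(dcols, ca$dimx[1L], ca$dimx[2L], ca$dimx[3L], ca$dimx[4L],
               self$k, self$k, self$stride, self$pad)
  }
  self
}

# batch norm ----------------------------------------------------------------

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  self <- new_module("bn")
  self$gamma <- new_param(rep(1, c))
  self$beta <- new_param(numeric(c))
  self$params <- list(self$gamma, self$beta)
  self$rmean <- numeric(c); self$rvar <- rep(1, c)
  self$momentum <- momentum; self$eps <- eps

  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    m <- d[1L] * d[2L] * d[4L]
    if (training) {
      mu <- channel_sum(x) / m
      xc <- x - channel_bcast(mu, d)
      var <- channel_sum(xc * xc) / m
      ivar <- 1 / sqrt(var + self$eps)
      xhat <- xc * channel_bcast(ivar, d)
      self$rmean <- (1 - self$momentum) * self$rmean + self$momentum * mu
      self$rvar <- (1 - self$momentum) * self$rvar + self$momentum * var
      self$cache <- list(xhat = xhat, ivar = ivar, m = m, training = TRUE)
      xhat * channel_bcast(self$gamma$v, d) + channel_bcast(self$beta$v, d)
    } else {
      ivar <- 1 / sqrt(self$rvar + self$eps)
      xhat <- (x - channel_bcast(self$rmean, d)) * channel_bcast(ivar, d)
      self$cache <- list(ivar = ivar, xhat = xhat, training = FALSE)
      xhat * channel_bcast(self$gamma$v, d) + channel_bcast(self$beta$v, d)
    }
  }
  self$backward <- function(dy) {
    ca <- self$cache
    d <- dim(dy)
    self$gamma$g <- self$gamma$g + channel_sum(dy * ca$xhat)
    self$beta$g <- self$beta$g + channel_sum(dy)
    if (!ca$training) {
      return(dy * channel_bcast(self$gamma$v * ca$ivar, d))
    }
    m <- ca$m
    dxhat <- dy * channel_bcast(self$gamma$v, d)
    s1 <- channel_sum(dxhat)
    s2 <- channel_sum(dxhat * ca$xhat)
    (dxhat - channel_bcast(s1 / m, d) - ca$xhat * channel_bcast(s2 / m, d)) *
      channel_bcast(ca$ivar, d)
  }
  self
}

# activations & pooling ------------------------------------------------------

nn_relu <- function() {
  self <- new_module("relu")
  self$linear_mode <- FALSE  # receptive-field probes route gradients as if linear
  self$forward <- function(x, training = TRUE) {
    self$cache <- x > 0
    x * self$cache
  }
  self$backward <- function(dy) {
    if (self$linear_mode) dy else dy * self$cache
  }
  self
}

nn_maxpool <- function(k = 2L, stride = k) {
  self <- new_module("maxpool")
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$forward <- function(x, training = TRUE) {
    r <- cpp_maxpool_fwd(x, self$k, self$stride)
    self$cache <- list(argmax = r$argmax, dimx = dim(x))
    r$y
  }
  self$backward <- function(dy) {
    ca <- self$cache
    cpp_maxpool_bwd(dy, ca$argmax, ca$dimx[1L], ca$dimx[2L], ca$dimx[3L],
                    ca$dimx[4L])
  }
  self
}

# spatial pyramid pooling: fixed-length descriptor from any spatial size -----

nn_spp <- function(levels = c(1L, 2L, 4L)) {
  self <- new_module("spp")
  self$levels <- as.integer(levels)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (d[1L] < max(self$levels) || d[2L] < max(self$levels))
      stop(sprintf("SPP input %dx%d smaller than largest pyramid grid %d",
                   d[1L], d[2L], max(self$levels)))
    C <- d[3L]; N <- d[4L]
    pieces <- list(); bins <- list()
    for (l in self$levels) {
      hb <- floor(seq(0, d[1L], length.out = l + 1))
      wb <- floor(seq(0, d[2L], length.out = l + 1))
      for (j in seq_len(l)) for (i in seq_len(l)) {
        hs <- (hb[i] + 1):hb[i + 1]; ws <- (wb[j] + 1):wb[j + 1]
        blk <- x[hs, ws, , , drop = FALSE]
        pieces[[length(pieces) + 1L]] <-
          colMeans(matrix(blk, length(hs) * length(ws), C * N))
        bins[[length(bins) + 1L]] <- list(hs = hs, ws = ws)
      }
    }
    self$cache <- list(dimx = d, bins = bins)
    # (n_bins * C) x N, bin-major within channel blocks: stack bins then C
    y <- do.call(rbind, lapply(pieces, function(p) matrix(p, ncol = N)))
    # each piece is a C x N block stacked vertically -> (C * n_bins) rows
    y
  }
  self$backward <- function(dy) {
    ca <- self$cache
    d <- ca$dimx; C <- d[3L]; N <- d[4L]
    dx <- array(0, dim = d)
    for (b in seq_along(ca$bins)) {
      hs <- ca$bins[[b]]$hs; ws <- ca$bins[[b]]$ws
      rows <- ((b - 1L) * C + 1L):(b * C)
      g <- dy[rows, , drop = FALSE] / (length(hs) * length(ws))
      add <- array(rep(as.vector(g), each = length(hs) * length(ws)),
                   dim = c(length(hs), length(ws), C, N))
      dx[hs, ws, , ] <- dx[hs, ws, , , drop = FALSE] + add
    }
    dx
  }
  self$out_len <- function(channels) channels * sum(self$levels^2)
  self
}

nn_flatten <- function() {
  self <- new_module("flatten")
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    self$cache <- d
    matrix(x, prod(d[1:3]), d[4L])
  }
  self$backward <- function(dy) array(dy, dim = self$cache)
  self
}

nn_linear <- function(in_d, out_d) {
  self <- new_module("linear")
  self$W <- new_param(matrix(stats::rnorm(out_d * in_d, sd = sqrt(2 / in_d)),
                             out_d, in_d))
  self$b <- new_param(numeric(out_d))
  self$params <- list(self$W, self$b)
  self$forward <- function(x, training = TRUE) {
    self$cache <- x
    self$W$v %*% x + self$b$v
  }
  self$backward <- function(dy) {
    self$W$g <- self$W$g + dy %*% t(self$cache)
    self$b$g <- self$b$g + rowSums(dy)
    crossprod(self$W$v, dy)
  }
  self
}

nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  self <- new_module("sequential")
  self$children <- mods
  self$forward <- function(x, training = TRUE) {
    for (m in self$children) x <- m$forward(x, training)
    x
  }
  self$backward <- function(dy) {
    for (m in rev(self$children)) dy <- m$backward(dy)
    dy
  }
  self
}

# residual wrapper: y = relu(body(x) + shortcut(x)) --------------------------

nn_residual <- function(body, shortcut = NULL) {
  self <- new_module("residual")
  self$children <- if (is.null(shortcut)) list(body) else list(body, shortcut)
  self$body <- body; self$shortcut <- shortcut
  self$forward <- function(x, training = TRUE) {
    yb <- self$body$forward(x, training)
    ys <- if (is.null(self$shortcut)) x else self$shortcut$forward(x, training)
    y <- yb + ys
    self$cache <- y > 0
    y * self$cache
  }
  self$backward <- function(dy) {
    dz <- dy * self$cache
    dx <- self$body$backward(dz)
    dx + if (is.null(self$shortcut)) dz else self$shortcut$backward(dz)
  }
  self
}

# upsample (nearest, factor 2) and channel concat for the U-Net --------------

nn_upsample2 <- function() {
  self <- new_module("upsample2")
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    self$cache <- d
    x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
      drop = FALSE]
  }
  self$backward <- function(dy) {
    d <- self$cache
    oi <- seq(1L, 2L * d[1L], by = 2L); oj <- seq(1L, 2L * d[2L], by = 2L)
    dy[oi, oj, , , drop = FALSE] + dy[oi + 1L, oj, , , drop = FALSE] +
      dy[oi, oj + 1L, , , drop = FALSE] + dy[oi + 1L, oj + 1L, , , drop = FALSE]
  }
  self
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# Adam ------------------------------------------------------------------------

#' Adam optimizer state over a module's parameters
#' @param mod module whose parameters to optimize
#' @param lr learning rate
#' @param beta1,beta2 moment decay rates
#' @param eps numerical stabilizer
#' @return an optimizer object with a `$step(lr)` method
#' @export
optim_adam <- function(mod, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env()
  opt$params <- collect_params(mod)
  opt$lr <- lr; opt$b1 <- beta1; opt$b2 <- beta2; opt$eps <- eps; opt$t <- 0L
  opt$step <- function(lr = opt$lr) {
    opt$t <- opt$t + 1L
    bc1 <- 1 - opt$b1^opt$t
    bc2 <- 1 - opt$b2^opt$t
    for (p in opt$params) {
      p$m <- opt$b1 * p$m + (1 - opt$b1) * p$g
      p$s <- opt$b2 * p$s + (1 - opt$b2) * p$g * p$g
      p$v <- p$v - lr * (p$m / bc1) / (sqrt(p$s / bc2) + opt$eps)
    }
    invisible(NULL)
  }
  opt
}

# weight (de)serialization -----------------------------------------------------

#' Extract all parameter values (and batch-norm running stats) of a module tree
#' @param mod an `nn_module`
#' @return a list of numeric arrays
#' @export
state_dict <- function(mod) {
  vals <- lapply(collect_params(mod), function(p) p$v)
  bn <- collect_bn(mod)
  list(params = vals,
       bn_stats = lapply(bn, function(b) list(rmean = b$rmean, rvar = b$rvar)))
}

collect_bn <- function(mod) {
  out <- if (identical(mod$type, "bn")) list(mod) else list()
  for (ch in mod$children) out <- c(out, collect_bn(ch))
  out
}

#' Load parameter values produced by [state_dict()] into a compatible module
#' @param mod target module
#' @param state list from [state_dict()]
#' @export
load_state_dict <- function(mod, state) {
  ps <- collect_params(mod)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$v) == length(state$params[[i]]))
    ps[[i]]$v[] <- state$params[[i]]
  }
  bn <- collect_bn(mod)
  for (i in seq_along(bn)) {
    bn[[i]]$rmean <- state$bn_stats[[i]]$rmean
    bn[[i]]$rvar <- state$bn_stats[[i]]$rvar
  }
  invisible(mod)
}

#' Checksum of a module's parameters (for frozen-teacher audits)
#' @param mod an `nn_module`
#' @return a single numeric hash-like sum
#' @export
param_checksum <- function(mod) {
  sum(vapply(collect_params(mod), function(p) sum(p$v) + sum(abs(p$v)),
             numeric(1)))
}
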