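# Reverse-mode autodiff over plain R arrays.
#
# A tape records every differentiable op in execution order; backward walks
# it in reverse. Tensor nodes are small environments holding the value `v`
# (a numeric array), the accumulated gradient `g`, a `req` flag and the tape.
# Heavy kernels (convolutions, upsampling) live in C++; everything
# elementwise relies on R's vectorized arithmetic, which is C-speed for the
# array sizes this package trains at.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_tensor <- function(v, req = FALSE, tape = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$req <- req
  e$tape <- tape
  class(e) <- "ag_tensor"
  e
}

ag_const <- function(v) ag_tensor(v, req = FALSE, tape = NULL)
ag_param <- function(v, tape) ag_tensor(v, req = TRUE, tape = tape)

is_tensor <- function(x) inherits(x, "ag_tensor")

# Wrap an op result; `backward` maps the output gradient to a list of input
# gradients (NULL entries for inputs that need none).
ag_op <- function(val, inputs, backward) {
  req <- FALSE
  tape <- NULL
  for (x in inputs) {
    if (x$req) req <- TRUE
    if (is.null(tape) && !is.null(x$tape)) tape <- x$tape
  }
  out <- ag_tensor(val, req = req && !is.null(tape), tape = tape)
  if (out$req) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[n]] <- list(out = out, inputs = inputs, backward = backward)
    tape$n <- n
  }
  out
}

ag_accum <- function(x, g) {
  if (!x$req) return(invisible(NULL))
  x$g <- if (is.null(x$g)) g else x$g + g
  invisible(NULL)
}

# Backpropagate from a scalar loss tensor through its tape.
ag_backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$v) == 1L, !is.null(loss$tape))
  loss$g <- 1
  tape <- loss$tape
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    go <- node$out$g
    if (is.null(go)) next
    grads <- node$backward(go)
    for (j in seq_along(node$inputs)) {
      if (!is.null(grads[[j]])) ag_accum(node$inputs[[j]], grads[[j]])
    }
  }
  invisible(NULL)
}

# When one operand is a scalar the elementwise gradient must be summed for it.
reduce_like <- function(g, v) if (length(v) == 1L) sum(g) else g

ag_add <- function(a, b) {
  ag_op(a$v + b$v, list(a, b), function(g) {
    list(reduce_like(g, a$v), reduce_like(g, b$v))
  })
}

ag_sub <- function(a, b) {
  ag_op(a$v - b$v, list(a, b), function(g) {
    list(reduce_like(g, a$v), reduce_like(-g, b$v))
  })
}

ag_mul <- function(a, b) {
  ag_op(a$v * b$v, list(a, b), function(g) {
    list(reduce_like(g * b$v, a$v), reduce_like(g * a$v, b$v))
  })
}

ag_div <- function(a, b) {
  ag_op(a$v / b$v, list(a, b), function(g) {
    list(reduce_like(g / b$v, a$v), reduce_like(-g * a$v / (b$v^2), b$v))
  })
}

ag_smul <- function(a, k) ag_op(a$v * k, list(a), function(g) list(g * k))

ag_square <- function(a) ag_op(a$v^2, list(a), function(g) list(2 * g * a$v))

ag_exp <- function(a) {
  v <- exp(a$v)
  ag_op(v, list(a), function(g) list(g * v))
}

# log with an epsilon floor; gradient is zero where the floor binds.
ag_logc <- function(a, eps = 1e-7) {
  ok <- a$v > eps
  ag_op(log(pmax(a$v, eps)), list(a), function(g) {
    gx <- g / pmax(a$v, eps)
    gx[!ok] <- 0
    list(gx)
  })
}

ag_sum <- function(a) {
  d <- dim(a$v)
  n <- length(a$v)
  ag_op(sum(a$v), list(a), function(g) {
    out <- rep(as.numeric(g), n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

ag_lrelu <- function(a, slope = 0.01) {
  pos <- a$v > 0
  ag_op(ifelse(pos, a$v, slope * a$v), list(a), function(g) {
    list(ifelse(pos, g, slope * g))
  })
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$v))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

# ---- structured ops on feature maps, dim (X, Y, Z, C) -----------------------

nvox_of <- function(d) prod(d[1:3])

# softmax over the channel axis
ag_softmax_ch <- function(a) {
  d <- dim(a$v)
  C <- d[4]
  m <- matrix(a$v, ncol = C)
  mx <- m[, 1]
  if (C > 1) for (j in 2:C) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  v <- array(p, dim = d)
  ag_op(v, list(a), function(g) {
    gm <- matrix(g, ncol = C)
    dot <- rowSums(gm * p)
    list(array(p * (gm - dot), dim = d))
  })
}

# instance normalization: per-channel mean/variance over the spatial axes
ag_instnorm <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a$v)
  C <- d[4]
  nv <- nvox_of(d)
  m <- matrix(a$v, ncol = C)
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = nv)) * rep(istd, each = nv)
  y <- xhat * rep(gamma$v, each = nv) + rep(beta$v, each = nv)
  ag_op(array(y, dim = d), list(a, gamma, beta), function(g) {
    gm <- matrix(g, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- gm * rep(gamma$v, each = nv)
    mean_dxh <- colMeans(dxh)
    mean_dxh_xh <- colMeans(dxh * xhat)
    dx <- (dxh - rep(mean_dxh, each = nv) - xhat * rep(mean_dxh_xh, each = nv)) *
      rep(istd, each = nv)
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

# global average pool over space -> length-C vector
ag_gap <- function(a) {
  d <- dim(a$v)
  nv <- nvox_of(d)
  ag_op(colMeans(matrix(a$v, ncol = d[4])), list(a), function(g) {
    list(array(rep(g / nv, each = nv), dim = d))
  })
}

# global max pool over space -> length-C vector
ag_gmp <- function(a) {
  d <- dim(a$v)
  C <- d[4]
  m <- matrix(a$v, ncol = C)
  idx <- apply(m, 2, which.max)
  ag_op(m[cbind(idx, seq_len(C))], list(a), function(g) {
    gx <- array(0, dim = d)
    gm <- matrix(gx, ncol = C)
    gm[cbind(idx, seq_len(C))] <- g
    list(array(gm, dim = d))
  })
}

# dense layer on a plain vector (CBAM channel MLP)
ag_linear <- function(v, W, b) {
  ag_op(as.vector(W$v %*% v$v) + b$v, list(v, W, b), function(g) {
    list(as.vector(crossprod(W$v, g)), outer(g, v$v), g)
  })
}

# multiply each channel by a scalar gate (length-C vector)
ag_scale_channels <- function(a, gate) {
  d <- dim(a$v)
  nv <- nvox_of(d)
  gb <- rep(gate$v, each = nv)
  ag_op(a$v * array(gb, dim = d), list(a, gate), function(g) {
    list(g * array(gb, dim = d), colSums(matrix(g * a$v, ncol = d[4])))
  })
}

# multiply every channel by a single-channel spatial map, dim (X, Y, Z, 1)
ag_scale_spatial <- function(a, m) {
  d <- dim(a$v)
  nv <- nvox_of(d)
  mb <- rep(as.vector(m$v), d[4])
  ag_op(a$v * array(mb, dim = d), list(a, m), function(g) {
    gm <- rowSums(matrix(g * a$v, ncol = d[4]))
    dim(gm) <- c(d[1:3], 1L)
    list(g * array(mb, dim = d), gm)
  })
}

# mean over the channel axis -> (X, Y, Z, 1)
ag_cmean <- function(a) {
  d <- dim(a$v)
  C <- d[4]
  v <- rowMeans(matrix(a$v, ncol = C))
  dim(v) <- c(d[1:3], 1L)
  ag_op(v, list(a), function(g) {
    list(array(rep(as.vector(g) / C, C), dim = d))
  })
}

# max over the channel axis -> (X, Y, Z, 1)
ag_cmax <- function(a) {
  d <- dim(a$v)
  C <- d[4]
  m <- matrix(a$v, ncol = C)
  idx <- max.col(m, ties.method = "first")
  nv <- nvox_of(d)
  v <- m[cbind(seq_len(nv), idx)]
  dim(v) <- c(d[1:3], 1L)
  ag_op(v, list(a), function(g) {
    gm <- matrix(0, nrow = nv, ncol = C)
    gm[cbind(seq_len(nv), idx)] <- as.vector(g)
    list(array(gm, dim = d))
  })
}

# sum over the channel axis -> (X, Y, Z, 1)
ag_csum <- function(a) {
  d <- dim(a$v)
  C <- d[4]
  v <- rowSums(matrix(a$v, ncol = C))
  dim(v) <- c(d[1:3], 1L)
  ag_op(v, list(a), function(g) {
    list(array(rep(as.vector(g), C), dim = d))
  })
}

ag_concat_ch <- function(a, b) {
  da <- dim(a$v)
  db <- dim(b$v)
  v <- array(c(a$v, b$v), dim = c(da[1:3], da[4] + db[4]))
  ag_op(v, list(a, b), function(g) {
    na <- prod(da)
    list(array(g[seq_len(na)], dim = da),
         array(g[-seq_len(na)], dim = db))
  })
}

# ---- C++-backed ops ---------------------------------------------------------

ag_conv3d <- function(x, w, b, stride = 1L, pad = 0L) {
  xd <- dim(x$v)
  wd <- dim(w$v)
  v <- cpp_conv3d_fwd(x$v, xd, w$v, wd, b$v, stride, pad)
  ag_op(v, list(x, w, b), function(g) {
    r <- cpp_conv3d_bwd(x$v, xd, w$v, wd, g, stride, pad, x$req)
    list(if (x$req) r$gx else NULL, r$gw, r$gb)
  })
}

# transposed convolution, kernel 2 stride 2 (learned x2 upsampling)
ag_convt2 <- function(x, w, b) {
  xd <- dim(x$v)
  v <- cpp_convt3d_fwd(x$v, xd, w$v, b$v)
  ag_op(v, list(x, w, b), function(g) {
    r <- cpp_convt3d_bwd(x$v, xd, w$v, g)
    list(if (x$req) r$gx else NULL, r$gw, r$gb)
  })
}

ag_upsample <- function(x, f) {
  if (f == 1L) return(x)
  xd <- dim(x$v)
  ag_op(cpp_upsample3d(x$v, xd, as.integer(f)), list(x), function(g) {
    list(cpp_upsample3d_bwd(g, xd, as.integer(f)))
  })
}
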