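# Independent scalar-loop oracles, deliberately written as naive loops so
# they share no code with the vectorized implementations they check.

oracle_wce <- function(p, y, w, eps = 1e-7) {
  # p: (..., C) probability array with class axis; y, w: flat-compatible
  C <- dim(p)[length(dim(p))]
  pm <- matrix(p, ncol = C)
  yv <- as.vector(y)
  wv <- as.vector(w)
  acc <- 0
  for (i in seq_along(yv)) {
    acc <- acc + wv[i] * (-log(max(pm[i, yv[i] + 1], eps)))
  }
  acc / sum(wv)
}

oracle_wdice <- function(pfg, y, w) {
  pv <- as.vector(pfg)
  yv <- as.numeric(as.vector(y) != 0)
  wv <- as.vector(w)
  num <- 0
  den <- 0
  for (i in seq_along(yv)) {
    num <- num + wv[i] * yv[i] * pv[i]
    den <- den + wv[i] * (pv[i]^2 + yv[i]^2)
  }
  1 - 2 * num / den
}

oracle_kl_maps <- function(p_scales, p_avg, eps = 1e-7) {
  C <- dim(p_avg)[4]
  nv <- prod(dim(p_avg)[1:3])
  lapply(p_scales, function(ps) {
    pm <- matrix(ps, ncol = C)
    cm <- matrix(p_avg, ncol = C)
    out <- numeric(nv)
    for (v in seq_len(nv)) {
      acc <- 0
      for (j in seq_len(C))
        acc <- acc + pm[v, j] * log(max(pm[v, j], eps) / max(cm[v, j], eps))
      out[v] <- max(acc, 0)
    }
    array(out, dim = dim(p_avg)[1:3])
  })
}

oracle_unsup <- function(p_scales, eps = 1e-7) {
  S <- length(p_scales)
  C <- dim(p_scales[[1]])[4]
  nv <- prod(dim(p_scales[[1]])[1:3])
  p_avg <- Reduce(`+`, p_scales) / S
  D <- oracle_kl_maps(p_scales, p_avg, eps)
  total <- 0
  for (s in seq_len(S)) {
    pm <- matrix(p_scales[[s]], ncol = C)
    cm <- matrix(p_avg, ncol = C)
    dv <- as.vector(D[[s]])
    num <- 0; den <- 0; mag <- 0
    for (v in seq_len(nv)) {
      sq <- 0
      for (j in seq_len(C)) sq <- sq + (pm[v, j] - cm[v, j])^2
      wv <- exp(-dv[v])
      num <- num + sq * wv
      den <- den + wv
      mag <- mag + dv[v]^2
    }
    total <- total + num / den + mag / nv
  }
  total / S
}

# all-pairs surface distances (the distance-transform check)
oracle_surface_dists <- function(pred, gt, spacing) {
  surf <- function(mask) {
    d <- dim(mask)
    out <- matrix(0, nrow = 0, ncol = 3)
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      if (!mask[x, y, z]) next
      nb_bg <- FALSE
      for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
        xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3] ||
            !mask[xx, yy, zz]) { nb_bg <- TRUE; break }
      }
      if (nb_bg) out <- rbind(out, c(x, y, z))
    }
    out
  }
  sp <- surf(pred)
  sg <- surf(gt)
  one_way <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      min(sqrt(colSums(((t(b) - a[i, ]) * spacing)^2)))
    }, numeric(1))
  }
  c(one_way(sp, sg), one_way(sg, sp))
}

# dense accumulate-and-divide recomposition
oracle_recompose <- function(patches, grid, out_shape) {
  acc <- array(0, dim = out_shape)
  cnt <- array(0, dim = out_shape)
  p <- grid$patch_shape
  for (i in seq_along(patches)) {
    o <- grid$offsets[i, ]
    for (dz in 0:(p[3] - 1)) for (dy in 0:(p[2] - 1)) for (dx in 0:(p[1] - 1)) {
      acc[o[1] + dx, o[2] + dy, o[3] + dz] <-
        acc[o[1] + dx, o[2] + dy, o[3] + dz] + patches[[i]][dx + 1, dy + 1, dz + 1]
      cnt[o[1] + dx, o[2] + dy, o[3] + dz] <-
        cnt[o[1] + dx, o[2] + dy, o[3] + dz] + 1
    }
  }
  acc / cnt
}

# random probability pyramid for loss tests
random_pyramid <- function(shape = c(2, 2, 2), C = 2, S = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_scales <- lapply(seq_len(S), function(s) {
    a <- array(runif(prod(shape) * C, 0.05, 1), dim = c(shape, C))
    sw <- array(rep(apply(a, 1:3, sum), C), dim = c(shape, C))
    a / sw
  })
  structure(list(p_scales = p_scales,
                 p_avg = Reduce(`+`, p_scales) / S),
            class = "tpssan_pyramid")
}

tiny_phantom_spec <- function(seed = 3L, noise = 0, bias = 0) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), chamber_semi_axes = c(9, 7, 6),
               n_appendages = 2L, appendage_radius = 2, noise_sigma = noise,
               bias_field_strength = bias, seed = seed)
}
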