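# The loss system: weighted cross-entropy and weighted Dice (shared by the
# supervised and pseudo-label terms), KL uncertainty maps over the
# multi-scale prediction pyramid, the uncertainty-rectified consistency
# loss with uncertainty minimization, and the ramped total loss.

as_label_array <- function(y) {
  if (inherits(y, "tpssan_labelmap")) y$data else y
}

# true-class probability per voxel; p either carries a class axis (one more
# dim than y) or is the foreground-class probability of a binary problem
true_class_prob <- function(p, y) {
  dy <- if (is.null(dim(y))) length(y) else dim(y)
  if (!is.null(dim(p)) && length(dim(p)) == length(dy) + 1L) {
    C <- dim(p)[length(dim(p))]
    pm <- matrix(p, ncol = C)
    pm[cbind(seq_along(y), as.vector(y) + 1L)]
  } else {
    as.vector(y) * as.vector(p) + (1 - as.vector(y)) * (1 - as.vector(p))
  }
}

fg_prob <- function(p) {
  if (!is.null(dim(p)) && length(dim(p)) == 4L) as.vector(p[, , , 2L])
  else as.vector(p)
}

#' Weighted cross-entropy loss
#'
#' `-sum_i w_i log p_i[y_i] / sum_i w_i`, with probabilities floored at
#' `eps`. Uniform weights reduce it to the standard mean cross-entropy.
#'
#' @param p Class-probability grid with a trailing class axis, or the
#'   foreground-class probability grid of a binary problem.
#' @param y Label map (`tpssan_labelmap` or integer array/vector).
#' @param w Non-negative confidence weights, same shape as `y`, with a
#'   positive total.
#' @param eps Probability floor.
#' @return Non-negative scalar; 0 iff the true class has probability 1
#'   wherever `w > 0`.
#' @export
weighted_cross_entropy <- function(p, y, w, eps = 1e-7) {
  y <- as_label_array(y)
  sw <- sum(w)
  if (sw <= 0) stop("weight map must have a positive total")
  pt <- true_class_prob(p, y)
  -sum(as.vector(w) * log(pmax(pt, eps))) / sw
}

#' Weighted Dice loss
#'
#' `1 - 2 sum(w y p) / sum(w (p^2 + y^2))` on the foreground class.
#' A zero denominator (empty foreground and zero prediction) is defined as
#' 0 with a warning.
#'
#' @inheritParams weighted_cross_entropy
#' @return Value in [0, 1]; 0 iff `p = y` wherever `w > 0`.
#' @export
weighted_dice <- function(p, y, w) {
  y <- as.numeric(as.vector(as_label_array(y)) != 0L)
  if (sum(w) <= 0) stop("weight map must have a positive total")
  pf <- fg_prob(p)
  wv <- as.vector(w)
  den <- sum(wv * (pf^2 + y^2))
  if (den == 0) {
    warning("weighted_dice: empty foreground and zero prediction; defined as 0")
    return(0)
  }
  1 - 2 * sum(wv * y * pf) / den
}

#' Combined supervised segmentation loss
#'
#' The convex combination `ratio * CE + (1 - ratio) * Dice` (default equal
#' halves) evaluated on the full-resolution prediction of the pyramid.
#'
#' @param pyramid A `tpssan_pyramid` (see [network_forward()]) or a bare
#'   class-probability grid.
#' @inheritParams weighted_cross_entropy
#' @param ce_dice_ratio Weight of the cross-entropy part, in [0, 1].
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(pyramid, y, w, ce_dice_ratio = 0.5, eps = 1e-7) {
  p <- if (inherits(pyramid, "tpssan_pyramid")) pyramid$p_scales[[1]] else pyramid
  ce_dice_ratio * weighted_cross_entropy(p, y, w, eps) +
    (1 - ce_dice_ratio) * weighted_dice(p, y, w)
}

#' Per-scale KL uncertainty maps
#'
#' `D_s[v] = sum_j p_s^j[v] log(p_s^j[v] / p_c^j[v])` — the KL divergence
#' at each voxel between the scale-s prediction and the scale-average
#' prediction, with `eps`-floored probabilities. Non-negative; exactly 0
#' where `p_s = p_c`.
#'
#' @param pyramid A `tpssan_pyramid`.
#' @param eps Probability floor inside the logarithms.
#' @return List of S non-negative 3D arrays.
#' @export
uncertainty_maps <- function(pyramid, eps = 1e-7) {
  pc <- pyramid$p_avg
  lapply(pyramid$p_scales, function(ps) {
    d <- dim(ps)
    kl <- rowSums(matrix(ps * (log(pmax(ps, eps)) - log(pmax(pc, eps))),
                         ncol = d[4]))
    dim(kl) <- d[1:3]
    pmax(kl, 0)
  })
}

#' Uncertainty-rectified multi-scale consistency loss
#'
#' Mean over scales of the rectified squared deviation from the average
#' prediction plus an uncertainty-minimization penalty:
#' `(1/S) sum_s [ sum_v ||p_s - p_c||^2_v w_s^v / sum_v w_s^v ]
#'  + (1/S) sum_s ||D_s||^2 / V`, with rectification weights
#' `w_s^v = exp(-D_s^v)`. Zero exactly when all scales agree.
#'
#' @inheritParams uncertainty_maps
#' @return Non-negative scalar.
#' @export
unsup_loss <- function(pyramid, eps = 1e-7) {
  S <- length(pyramid$p_scales)
  pc <- pyramid$p_avg
  D <- uncertainty_maps(pyramid, eps)
  V <- prod(dim(pyramid$p_scales[[1]])[1:3])
  term1 <- 0
  term2 <- 0
  for (s in seq_len(S)) {
    ps <- pyramid$p_scales[[s]]
    sq <- rowSums(matrix((ps - pc)^2, ncol = dim(ps)[4]))
    ws <- exp(-as.vector(D[[s]]))
    term1 <- term1 + sum(sq * ws) / sum(ws)
    term2 <- term2 + sum(D[[s]]^2) / V
  }
  (term1 + term2) / S
}

#' Consistency-weight schedule and total loss
#'
#' `loss_weights()` bundles the peak unsupervised weight with its ramp-up;
#' `lambda_schedule()` evaluates the ramped weight at iteration `t`
#' (0-based): 0 at t = 0, `lambda_unsup * exp(-5 (1 - t/T)^2)` during the
#' Gaussian ramp, and the full `lambda_unsup` from t = T on. Linear and
#' constant ramps are available.
#'
#' @param lambda_unsup Peak weight of the consistency loss (>= 0).
#' @param rampup_length Ramp duration T in iterations.
#' @param rampup_shape `"gaussian"`, `"linear"` or `"constant"`.
#' @return `loss_weights()`: a `tpssan_lossweights` list.
#' @export
loss_weights <- function(lambda_unsup = 0.1, rampup_length = 40L,
                         rampup_shape = c("gaussian", "linear", "constant")) {
  stopifnot(lambda_unsup >= 0, rampup_length >= 0)
  structure(list(lambda_unsup = lambda_unsup,
                 rampup_length = as.integer(rampup_length),
                 rampup_shape = match.arg(rampup_shape)),
            class = "tpssan_lossweights")
}

#' @rdname loss_weights
#' @param t Iteration counter (0-based).
#' @param lw A `tpssan_lossweights`.
#' @export
lambda_schedule <- function(t, lw) {
  T <- lw$rampup_length
  if (lw$rampup_shape == "constant" || T == 0L || t >= T)
    return(lw$lambda_unsup)
  switch(lw$rampup_shape,
         gaussian = if (t <= 0) 0 else lw$lambda_unsup * exp(-5 * (1 - t / T)^2),
         linear = lw$lambda_unsup * max(0, t) / T)
}

#' @rdname loss_weights
#' @param sup,semi,unsup The three loss components at iteration `t`.
#' @return `total_loss()`: `sup + semi + lambda(t) * unsup`.
#' @export
total_loss <- function(sup, semi, unsup, t, lw) {
  stopifnot(is.finite(sup), is.finite(semi), is.finite(unsup))
  sup + semi + lambda_schedule(t, lw) * unsup
}

# ---- differentiable (tape) versions used by the trainer ---------------------

# CE + Dice on a probability tensor against constant targets
ag_seg_loss <- function(p, y, w, ce_dice_ratio = 0.5, eps = 1e-7) {
  d <- dim(p$v)
  C <- d[4]
  nv <- prod(d[1:3])
  yv <- as.vector(as_label_array(y))
  wv <- as.vector(w)
  onehot <- matrix(0, nrow = nv, ncol = C)
  onehot[cbind(seq_len(nv), yv + 1L)] <- 1
  ce_w <- array(onehot * wv / sum(wv), dim = d)
  ce <- ag_smul(ag_sum(ag_mul(ag_logc(p, eps), ag_const(ce_w))), -1)
  fg_sel <- array(0, dim = d)
  fg_sel[, , , 2L] <- 1
  pf <- ag_csum(ag_mul(p, ag_const(fg_sel)))
  yfg <- array(as.numeric(yv != 0L), dim = c(d[1:3], 1L))
  wc <- array(wv, dim = c(d[1:3], 1L))
  num <- ag_smul(ag_sum(ag_mul(ag_const(wc * yfg), pf)), 2)
  den <- ag_sum(ag_mul(ag_const(wc), ag_add(ag_square(pf), ag_const(yfg^2))))
  dice <- ag_sub(ag_const(1), ag_div(num, den))
  ag_add(ag_smul(ce, ce_dice_ratio), ag_smul(dice, 1 - ce_dice_ratio))
}

# uncertainty-rectified consistency on a list of probability tensors
ag_unsup_loss <- function(p_scales, eps = 1e-7) {
  S <- length(p_scales)
  pc <- p_scales[[1]]
  for (s in 2:S) pc <- ag_add(pc, p_scales[[s]])
  pc <- ag_smul(pc, 1 / S)
  V <- prod(dim(pc$v)[1:3])
  total <- NULL
  lpc <- ag_logc(pc, eps)
  for (s in seq_len(S)) {
    ps <- p_scales[[s]]
    Ds <- ag_csum(ag_mul(ps, ag_sub(ag_logc(ps, eps), lpc)))
    ws <- ag_exp(ag_smul(Ds, -1))
    sq <- ag_csum(ag_square(ag_sub(ps, pc)))
    t1 <- ag_div(ag_sum(ag_mul(sq, ws)), ag_sum(ws))
    t2 <- ag_smul(ag_sum(ag_square(Ds)), 1 / V)
    term <- ag_add(t1, t2)
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  ag_smul(total, 1 / S)
}
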