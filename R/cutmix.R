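# Volumetric CutMix: replace an axis-aligned box of sample A with the
# corresponding box of sample B, mixing the label maps with the same binary
# mask. The 2D area-fraction convention generalizes to a volume fraction,
# so box side lengths scale with the cube root of (1 - lambda).

#' Sample the CutMix mixing ratio
#'
#' Draws lambda from Beta(alpha, alpha); with alpha = 1 this is the uniform
#' distribution on (0, 1). Uses the current RNG state, so seed once per run.
#'
#' @param alpha Positive concentration parameter.
#' @return A scalar in [0, 1].
#' @export
sample_lambda <- function(alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  rbeta(1, alpha, alpha)
}

#' Sample a CutMix box mask
#'
#' The mask is 1 outside a single axis-aligned box and 0 inside it. Box
#' side lengths are `shape * (1 - lam)^(1/3)` rounded to integers and the
#' box lies fully inside the grid, so the realized ones-fraction matches
#' `lam` up to the rounding of the three sides.
#'
#' @param shape Three positive integers.
#' @param lam Target ones-fraction in [0, 1].
#' @return Integer 0/1 array of dim `shape`.
#' @export
sample_box_mask <- function(shape, lam) {
  shape <- as.integer(shape)
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  side <- pmin(shape, as.integer(round(shape * (1 - lam)^(1 / 3))))
  mask <- array(1L, dim = shape)
  if (all(side > 0L)) {
    corner <- vapply(seq_len(3L), function(ax)
      sample.int(shape[ax] - side[ax] + 1L, 1L), integer(1))
    mask[corner[1]:(corner[1] + side[1] - 1L),
         corner[2]:(corner[2] + side[2] - 1L),
         corner[3]:(corner[3] + side[3] - 1L)] <- 0L
  }
  mask
}

#' CutMix two (volume, label) pairs
#'
#' Computes `x_mix = M * x_A + (1 - M) * x_B` and the same for the label
#' maps, with a box mask M drawn for a Beta(alpha, alpha) ratio. Labels are
#' mixed as hard integer maps, never softened.
#'
#' @param a,b Lists with elements `volume` and `label`
#'   (`tpssan_volume`/`tpssan_labelmap` or bare arrays), sharing one shape.
#' @param alpha Beta concentration for the ratio draw.
#' @param lam,mask Optional: fix the ratio and/or the mask instead of
#'   drawing them.
#' @return A `tpssan_mixsample`: `x_mix`, `y_mix`, `mask`, and `lam` (the
#'   realized ones-fraction of the mask, not the drawn ratio).
#' @export
cutmix <- function(a, b, alpha = 1, lam = NULL, mask = NULL) {
  xa <- vol_data(a$volume); ya <- vol_data(a$label)
  xb <- vol_data(b$volume); yb <- vol_data(b$label)
  if (!identical(dim(xa), dim(xb)))
    stop("cutmix requires equal shapes: ", paste(dim(xa), collapse = "x"),
         " vs ", paste(dim(xb), collapse = "x"))
  if (is.null(lam)) lam <- sample_lambda(alpha)
  if (is.null(mask)) mask <- sample_box_mask(dim(xa), lam)
  x_mix <- mask * xa + (1L - mask) * xb
  y_mix <- mask * ya + (1L - mask) * yb
  storage.mode(y_mix) <- "integer"
  structure(list(x_mix = x_mix, y_mix = y_mix, mask = mask,
                 lam = mean(mask)),
            class = "tpssan_mixsample")
}
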