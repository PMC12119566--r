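# Multi-view slice-confidence supervision: every slice gets a confidence
# that decays exponentially with its distance to a designated source slice
# (the middle transverse and middle coronal slices by default); the
# per-view maps are fused into one voxelwise weight map that multiplies the
# supervised and pseudo-label losses.

#' Confidence of a slice at distance d from the source slice
#'
#' Returns 1 for the source slice itself and `decay_weight^d` otherwise
#' (an exponential decay in slice distance, measured in slice indices).
#'
#' @param d Non-negative integer distance(s).
#' @param decay_weight Per-slice decay factor in (0, 1].
#' @return Numeric vector of confidences in (0, 1].
#' @export
slice_confidence <- function(d, decay_weight) {
  if (any(d < 0)) stop("slice distance d must be >= 0")
  if (decay_weight <= 0 || decay_weight > 1)
    stop("decay_weight must lie in (0, 1]")
  decay_weight^d
}

view_axis <- function(view) {
  switch(view,
         transverse = 3L,  # xy-planes stacked along z
         coronal = 2L,     # xz-planes stacked along y
         stop("invalid view '", view, "' (expected 'transverse' or 'coronal')"))
}

#' Build the per-view slice weight map
#'
#' Every voxel in slice i along the view axis holds
#' `slice_confidence(|i - source|, decay_weight)`; the map is constant
#' within each slice. A band of `band_width` slices centered on the source
#' carries confidence 1, with the decay measured from the band edge
#' (band_width = 1 is the single-source-slice case).
#'
#' @param shape Three integers, the volume shape.
#' @param view `"transverse"` or `"coronal"`.
#' @param source_index Slice index (1-based), or `"middle"`.
#' @param decay_weight Decay factor in (0, 1].
#' @param band_width Odd width of the full-confidence band.
#' @return Numeric 3D weight array with values in (0, 1].
#' @export
build_view_weightmap <- function(shape, view, source_index = "middle",
                                 decay_weight = 0.95, band_width = 1L) {
  shape <- as.integer(shape)
  ax <- view_axis(view)
  n <- shape[ax]
  src <- if (identical(source_index, "middle")) (n + 1L) %/% 2L
         else as.integer(source_index)
  if (src < 1L || src > n)
    stop("source_index ", src, " outside the ", n, "-slice extent of the ",
         view, " view")
  half_band <- (as.integer(band_width) - 1L) %/% 2L
  d <- pmax(0L, abs(seq_len(n) - src) - half_band)
  p <- slice_confidence(d, decay_weight)
  w <- switch(ax,
              NULL,
              array(rep(rep(p, each = shape[1]), times = shape[3]), dim = shape),
              array(rep(p, each = shape[1] * shape[2]), dim = shape))
  w
}

#' Fuse the transverse and coronal weight maps
#'
#' @param w_transverse,w_coronal Equal-shaped weight arrays in [0, 1].
#' @param rule `"product"` (a voxel is confident only if both views are),
#'   `"max"` or `"mean"`.
#' @return The fused weight array in [0, 1].
#' @export
combine_views <- function(w_transverse, w_coronal,
                          rule = c("product", "max", "mean")) {
  rule <- match.arg(rule)
  if (!identical(dim(w_transverse), dim(w_coronal)))
    stop("weight maps have mismatched shapes")
  switch(rule,
         product = w_transverse * w_coronal,
         max = pmax(w_transverse, w_coronal),
         mean = (w_transverse + w_coronal) / 2)
}

# Weight map per the `supervision:` config section; `enabled = FALSE` or
# decay_weight = 1 yields the unweighted (all-ones) map.
make_weightmap <- function(shape, sup) {
  if (!isTRUE(sup$enabled)) return(array(1, dim = shape))
  wt <- build_view_weightmap(shape, "transverse", sup$source_index,
                             sup$decay_weight, sup$band_width)
  wc <- build_view_weightmap(shape, "coronal", sup$source_index,
                             sup$decay_weight, sup$band_width)
  combine_views(wt, wc, sup$combine_rule)
}
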