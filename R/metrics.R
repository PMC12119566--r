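# Evaluation metrics: voxel-overlap (Dice, Jaccard, as percentages) and
# spacing-aware surface distances (95th-percentile Hausdorff, average
# surface distance) via a separable Euclidean distance transform.

#' Dice and Jaccard overlap (percent)
#'
#' `dice = 200 |P∩G| / (|P|+|G|)`, `jaccard = 100 |P∩G| / |P∪G|` on the
#' binary foregrounds; two empty masks score 100.
#'
#' @param pred,gt Label maps (`tpssan_labelmap` or arrays); foreground is
#'   any nonzero voxel.
#' @return Named numeric `c(dice, jaccard)`.
#' @export
overlap_metrics <- function(pred, gt) {
  p <- as_label_array(pred) != 0L
  g <- as_label_array(gt) != 0L
  if (!identical(dim(p), dim(g)))
    stop("pred and gt have mismatched shapes")
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(c(dice = 100, jaccard = 100))
  inter <- sum(p & g)
  c(dice = 200 * inter / (np + ng),
    jaccard = 100 * inter / (np + ng - inter))
}

# border voxels: foreground with at least one face-adjacent background
# neighbor (voxels beyond the grid border count as background)
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(FALSE, dim = d)
  if (all(d >= 3L)) {
    cx <- 2:(d[1] - 1); cy <- 2:(d[2] - 1); cz <- 2:(d[3] - 1)
    interior[cx, cy, cz] <-
      mask[cx, cy, cz] &
      mask[cx - 1, cy, cz] & mask[cx + 1, cy, cz] &
      mask[cx, cy - 1, cz] & mask[cx, cy + 1, cz] &
      mask[cx, cy, cz - 1] & mask[cx, cy, cz + 1]
  }
  mask & !interior
}

#' 95% Hausdorff and average surface distance
#'
#' Surfaces are the border voxels of each mask; all nearest
#' surface-to-opposite-surface distances are pooled over both directions.
#' `asd` is their mean and `hd95` their 95th percentile (linear
#' interpolation between order statistics). Distances honor the voxel
#' spacing, so the default unit spacing reports voxel units.
#'
#' @param pred,gt Nonempty binary label maps of one shape.
#' @param spacing Three positive voxel spacings.
#' @return Named numeric `c(hd95, asd)`.
#' @export
surface_metrics <- function(pred, gt, spacing = c(1, 1, 1)) {
  p <- as_label_array(pred) != 0L
  g <- as_label_array(gt) != 0L
  if (!identical(dim(p), dim(g)))
    stop("pred and gt have mismatched shapes")
  if (sum(p) == 0 || sum(g) == 0)
    stop("undefined surface distance: at least one mask is empty")
  sp <- surface_voxels(p)
  sg <- surface_voxels(g)
  d <- dim(p)
  dt_g <- cpp_edt3d(array(as.integer(sg), dim = d), d, as.numeric(spacing))
  dt_p <- cpp_edt3d(array(as.integer(sp), dim = d), d, as.numeric(spacing))
  pooled <- c(dt_g[sp], dt_p[sg])
  c(hd95 = unname(quantile(pooled, 0.95)), asd = mean(pooled))
}

#' Evaluate predicted segmentations against ground truth
#'
#' Matches prediction and ground-truth volumes by file name, computes all
#' four metrics per case plus a mean row, and optionally writes the report
#' as CSV.
#'
#' @param pred_dir,gt_dir Directories of NIfTI/NRRD label volumes with
#'   matching file names.
#' @param out_csv Optional path for the CSV report.
#' @param spacing Voxel spacing used for the surface distances; `NULL`
#'   takes each ground-truth header's spacing.
#' @return A data frame with columns `case, dice, jaccard, hd95, asd`
#'   (the final row is the mean).
#' @export
evaluate_cases <- function(pred_dir, gt_dir, out_csv = NULL, spacing = NULL) {
  files <- sort(list.files(gt_dir, pattern = "\\.(nii(\\.gz)?|nrrd)$"))
  if (length(files) == 0) stop("no ground-truth volumes found in ", gt_dir)
  rows <- lapply(files, function(f) {
    pf <- file.path(pred_dir, f)
    if (!file.exists(pf)) stop("missing prediction for case ", f)
    gt <- read_volume(file.path(gt_dir, f))
    pred <- read_volume(pf)
    sp <- if (is.null(spacing)) gt$spacing else spacing
    ov <- overlap_metrics(pred$data != 0, gt$data != 0)
    # an empty prediction has well-defined overlap but undefined surface
    # distances; report NA for the latter instead of aborting the batch
    su <- tryCatch(surface_metrics(pred$data != 0, gt$data != 0, sp),
                   error = function(e) c(hd95 = NA_real_, asd = NA_real_))
    data.frame(case = f, dice = ov[["dice"]], jaccard = ov[["jaccard"]],
               hd95 = su[["hd95"]], asd = su[["asd"]],
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rbind(rep, data.frame(case = "mean", dice = mean(rep$dice),
                               jaccard = mean(rep$jaccard),
                               hd95 = mean(rep$hd95, na.rm = TRUE),
                               asd = mean(rep$asd, na.rm = TRUE),
                               stringsAsFactors = FALSE))
  if (!is.null(out_csv)) write.csv(rep, out_csv, row.names = FALSE)
  rep
}
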