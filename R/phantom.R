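# Cardiac phantom simulator: one bright, randomly oriented ellipsoidal
# chamber with tubular appendages protruding from its surface (mimicking an
# atrial body with vessel stumps), multiplicative low-order bias field and
# additive Gaussian noise. Gives the rest of the pipeline a learnable
# segmentation task without any external dataset.

#' Specification of a cardiac phantom
#'
#' @param grid_shape Three positive integers, the voxel grid (x, y, z).
#' @param chamber_semi_axes Three positive semi-axis lengths in voxels.
#' @param n_appendages Number of tubular appendages attached to the chamber
#'   surface.
#' @param appendage_radius Tube radius in voxels.
#' @param noise_sigma Standard deviation of the additive Gaussian intensity
#'   noise (>= 0).
#' @param bias_field_strength Amplitude of the smooth multiplicative bias
#'   field (0 disables it).
#' @param contrast Length-2 numeric, mean intensity of background and
#'   foreground.
#' @param seed Non-negative integer; identical (spec, seed) pairs produce
#'   bit-identical phantoms.
#' @param random_orientation Rotate the chamber randomly? Disable to obtain
#'   an axis-aligned ellipsoid (useful for analytic volume checks).
#' @return A `tpssan_phantomspec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 48L),
                         chamber_semi_axes = c(14, 11, 9),
                         n_appendages = 3L, appendage_radius = 2.5,
                         noise_sigma = 0.05, bias_field_strength = 0.2,
                         contrast = c(background = 0.2, foreground = 1),
                         seed = 1L, random_orientation = TRUE) {
  spec <- list(grid_shape = as.integer(grid_shape),
               chamber_semi_axes = as.numeric(chamber_semi_axes),
               n_appendages = as.integer(n_appendages),
               appendage_radius = as.numeric(appendage_radius),
               noise_sigma = as.numeric(noise_sigma),
               bias_field_strength = as.numeric(bias_field_strength),
               contrast = as.numeric(contrast),
               seed = as.integer(seed),
               random_orientation = isTRUE(random_orientation))
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 1L),
            length(spec$chamber_semi_axes) == 3L,
            all(spec$chamber_semi_axes > 0),
            spec$n_appendages >= 0L, spec$appendage_radius > 0,
            spec$noise_sigma >= 0, spec$bias_field_strength >= 0,
            length(spec$contrast) == 2L, spec$seed >= 0L)
  # chamber must fit inside the grid with a >= 2 voxel margin regardless of
  # orientation, so bound by the largest semi-axis
  a_max <- max(spec$chamber_semi_axes)
  half <- (spec$grid_shape - 1) / 2
  if (any(a_max + 2 > half))
    stop("grid too small for chamber: largest semi-axis ", a_max,
         " + 2 voxel margin exceeds half-extent (", paste(half, collapse = ", "),
         ") of grid (", paste(spec$grid_shape, collapse = "x"), ")")
  structure(spec, class = "tpssan_phantomspec")
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  d <- diag(qr.R(qr_d))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Generate one phantom volume and its label map
#'
#' The label is 1 inside a (randomly oriented) ellipsoid plus
#' `n_appendages` cylindrical tubes rooted on its surface, 0 elsewhere. The
#' intensity is the class mean, modulated by a smooth multiplicative
#' polynomial bias field and additive Gaussian noise. The foreground must
#' occupy 2--40% of the grid, else generation aborts.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (a `tpssan_volume`) and `label`
#'   (a `tpssan_labelmap`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "tpssan_phantomspec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  ctr <- (gs + 1) / 2
  R <- if (spec$random_orientation) random_rotation() else diag(3)
  co <- cbind(rep(seq_len(gs[1]), times = gs[2] * gs[3]) - ctr[1],
              rep(rep(seq_len(gs[2]), each = gs[1]), times = gs[3]) - ctr[2],
              rep(seq_len(gs[3]), each = gs[1] * gs[2]) - ctr[3])
  q <- co %*% R  # body-frame coordinates
  ax <- spec$chamber_semi_axes
  inside <- (q[, 1] / ax[1])^2 + (q[, 2] / ax[2])^2 + (q[, 3] / ax[3])^2 <= 1
  if (spec$n_appendages > 0L) {
    A <- R %*% diag(1 / ax^2) %*% t(R)  # world-frame ellipsoid quadratic
    tube_len <- max(3, 0.7 * min(ax))
    for (i in seq_len(spec$n_appendages)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      r_surf <- 1 / sqrt(drop(t(u) %*% A %*% u))
      # inset the tube root below the surface so it stays face-connected
      p0 <- (r_surf - 1.5 * spec$appendage_radius) * u
      p1 <- (r_surf + tube_len) * u
      seg <- p1 - p0
      seg2 <- sum(seg^2)
      rel <- sweep(co, 2, p0)
      tt <- pmin(1, pmax(0, (rel %*% seg) / seg2))
      dvec <- rel - tt %*% t(seg)
      inside <- inside | (rowSums(dvec^2) <= spec$appendage_radius^2)
    }
  }
  lab <- array(as.integer(inside), dim = gs)
  frac <- mean(inside)
  if (frac < 0.02 || frac > 0.40)
    stop(sprintf("foreground fraction %.3f outside the required 2%%-40%% band;
 adjust chamber_semi_axes relative to grid_shape", frac))
  mu <- ifelse(inside, spec$contrast[2], spec$contrast[1])
  bias <- 1
  if (spec$bias_field_strength > 0) {
    tn <- sweep(co, 2, (gs - 1) / 2, "/")  # normalized to [-1, 1]
    cf <- rnorm(9)
    poly <- cf[1] * tn[, 1] + cf[2] * tn[, 2] + cf[3] * tn[, 3] +
      cf[4] * tn[, 1] * tn[, 2] + cf[5] * tn[, 1] * tn[, 3] +
      cf[6] * tn[, 2] * tn[, 3] +
      cf[7] * (tn[, 1]^2 - 1 / 3) + cf[8] * (tn[, 2]^2 - 1 / 3) +
      cf[9] * (tn[, 3]^2 - 1 / 3)
    bias <- 1 + spec$bias_field_strength * poly / max(abs(poly))
  }
  vox <- mu * bias
  if (spec$noise_sigma > 0) vox <- vox + rnorm(length(vox), sd = spec$noise_sigma)
  list(volume = new_volume(array(vox, dim = gs)),
       label = new_labelmap(lab, num_classes = 2L))
}

#' Write a labeled/unlabeled phantom dataset to disk
#'
#' Generates `n_labeled + n_unlabeled` phantoms (each with its own derived
#' seed), writes the volumes as NIfTI, writes label maps only for the
#' labeled subset, and records the split in `manifest.csv` with columns
#' `id, volume_path, label_path, split` (empty `label_path` for unlabeled
#' cases). Two runs with the same seed produce byte-identical manifests.
#'
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param n_labeled Number of labeled volumes (>= 1).
#' @param n_unlabeled Number of unlabeled volumes.
#' @param spec Base [phantom_spec()]; each case reuses it with a derived seed.
#' @param seed Integer master seed for the dataset.
#' @param overwrite Allow writing into an existing non-empty directory?
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(out_dir, n_labeled, n_unlabeled, spec,
                             seed = 1L, overwrite = FALSE) {
  if (n_labeled < 1L) stop("n_labeled must be >= 1")
  stopifnot(n_unlabeled >= 0L, inherits(spec, "tpssan_phantomspec"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir,
         " exists and is not empty; pass overwrite = TRUE to replace it")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_labeled + n_unlabeled
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_spec <- spec
    case_spec$seed <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483629)
    ph <- generate_phantom(case_spec)
    id <- sprintf("case_%03d", i)
    vp <- paste0(id, "_vol.nii.gz")
    labeled <- i <= n_labeled
    lp <- if (labeled) paste0(id, "_lab.nii.gz") else ""
    write_volume(ph$volume, file.path(out_dir, vp))
    if (labeled) write_volume(ph$label, file.path(out_dir, lp))
    rows[[i]] <- data.frame(id = id, volume_path = vp, label_path = lp,
                            split = if (labeled) "labeled" else "unlabeled",
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Is the foreground one single 26-connected component? (used by tests and
# as a phantom sanity helper)
single_component_26 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  arr_ind <- arrayInd(idx[1], d)
  frontier <- idx[1]
  visited[frontier] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(frontier) > 0) {
    fi <- arrayInd(frontier, d)
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
      cbind(fi[, 1] + offs[k, 1], fi[, 2] + offs[k, 2], fi[, 3] + offs[k, 3])))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    lin <- unique(lin[mask[lin] & !visited[lin]])
    visited[lin] <- TRUE
    frontier <- lin
  }
  sum(visited) == length(idx)
}
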