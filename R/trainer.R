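# Mean-teacher semi-supervised training: the student is updated by SGD on
# the total loss (supervised + pseudo-label + ramped consistency), the
# teacher by an exponential moving average of the student; the teacher sees
# noised unlabeled inputs and supplies the pseudo-labels.

#' Training configuration
#'
#' @param max_iterations Number of SGD iterations.
#' @param batch_size Items per batch (one labeled + one unlabeled).
#' @param lr Base learning rate (polynomial decay, exponent 0.9).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty added to the gradients.
#' @param ema_decay Teacher EMA decay in [0, 1).
#' @param noise_sigma Std. dev. of the Gaussian noise added to the
#'   teacher's unlabeled inputs (after z-score normalization).
#' @param patch_shape Training patch shape; each axis must be divisible by
#'   `2^num_levels` of the network.
#' @param seed Master seed; every stochastic choice of a run flows from it.
#' @param semi_enabled Disable to train on the supervised loss only (the
#'   ablation baseline).
#' @return A `tpssan_trainconfig` list.
#' @export
train_config <- function(max_iterations = 200L, batch_size = 2L, lr = 0.01,
                         momentum = 0.9, weight_decay = 1e-4,
                         ema_decay = 0.99, noise_sigma = 0.1,
                         patch_shape = c(32L, 32L, 32L), seed = 1L,
                         semi_enabled = TRUE) {
  stopifnot(max_iterations >= 1, lr > 0, ema_decay >= 0, ema_decay < 1,
            noise_sigma >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 ema_decay = ema_decay, noise_sigma = noise_sigma,
                 patch_shape = as.integer(patch_shape),
                 seed = as.integer(seed), semi_enabled = isTRUE(semi_enabled)),
            class = "tpssan_trainconfig")
}

#' EMA parameter transfer
#'
#' `theta_teacher <- decay * theta_teacher + (1 - decay) * theta_student`,
#' elementwise over matching named parameter lists. decay = 0 copies the
#' student; decay = 1 leaves the teacher untouched.
#'
#' @param teacher,student Named lists of numeric arrays with equal shapes.
#' @param decay EMA decay in [0, 1].
#' @return The updated teacher parameter list.
#' @export
ema_update <- function(teacher, student, decay) {
  stopifnot(identical(names(teacher), names(student)),
            decay >= 0, decay <= 1)
  for (n in names(teacher)) {
    if (!identical(dim(teacher[[n]]), dim(student[[n]])) ||
        length(teacher[[n]]) != length(student[[n]]))
      stop("parameter shape mismatch at '", n, "'")
    teacher[[n]] <- decay * teacher[[n]] + (1 - decay) * student[[n]]
  }
  teacher
}

#' Initialize a mean-teacher training state
#'
#' Builds the student network, copies it into the teacher, and zeroes the
#' optimizer buffers.
#'
#' @param net_config A [network_config()].
#' @param cfg A [train_config()].
#' @param lw A [loss_weights()].
#' @return A `tpssan_trainstate`.
#' @export
init_train_state <- function(net_config, cfg, lw = loss_weights()) {
  net <- make_network(net_config, seed = cfg$seed)
  structure(list(config = net_config, train_config = cfg, loss_weights = lw,
                 student = net$params, teacher = net$params,
                 momentum_buf = lapply(net$params, function(p) p * 0),
                 iter = 0L, history = list()),
            class = "tpssan_trainstate")
}

as_input4d <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

teacher_pseudo <- function(state, x) {
  P <- wrap_params(state$teacher)
  out <- net_forward_t(P, state$config, ag_const(as_input4d(x)))
  p <- out$p_scales[[1]]$v
  d <- dim(p)
  array(max.col(matrix(p, ncol = d[4]), ties.method = "first") - 1L,
        dim = d[1:3])
}

#' One SGD + EMA training step
#'
#' Computes the supervised loss on the labeled patch, the pseudo-label loss
#' (teacher targets, optionally through CutMix) and the
#' uncertainty-rectified pyramid consistency on the unlabeled patch, takes
#' one SGD step on the student and one EMA step on the teacher.
#'
#' @param batch List with `labeled = list(x, y, w)` and, unless the state
#'   was configured supervised-only, `unlabeled = list(x, w)` plus optional
#'   `x2` in `unlabeled` to CutMix the two unlabeled patches.
#' @param state A `tpssan_trainstate`.
#' @param cfg The `tpssan_trainconfig` (defaults to the one in `state`).
#' @return The advanced `tpssan_trainstate`.
#' @export
training_step <- function(batch, state, cfg = state$train_config) {
  tape <- ag_tape()
  SP <- wrap_params(state$student, tape)
  lb <- batch$labeled
  out_l <- net_forward_t(SP, state$config, ag_const(as_input4d(lb$x)))
  l_sup <- ag_seg_loss(out_l$p_scales[[1]], lb$y, lb$w)
  lam <- lambda_schedule(state$iter, state$loss_weights)
  if (cfg$semi_enabled && !is.null(batch$unlabeled)) {
    ub <- batch$unlabeled
    noise <- function(x) {
      if (cfg$noise_sigma > 0) x + array(rnorm(length(x), sd = cfg$noise_sigma),
                                         dim = dim(x)) else x
    }
    if (!is.null(ub$x2)) {
      mix_lam <- sample_lambda(batch$cutmix_alpha %||% 1)
      mask <- sample_box_mask(dim(ub$x), mix_lam)
      pl1 <- teacher_pseudo(state, noise(ub$x))
      pl2 <- teacher_pseudo(state, noise(ub$x2))
      x_in <- mask * ub$x + (1L - mask) * ub$x2
      pseudo <- mask * pl1 + (1L - mask) * pl2
    } else {
      x_in <- ub$x
      pseudo <- teacher_pseudo(state, noise(ub$x))
    }
    out_u <- net_forward_t(SP, state$config, ag_const(as_input4d(x_in)))
    l_semi <- ag_seg_loss(out_u$p_scales[[1]], pseudo, ub$w)
    l_unsup <- ag_unsup_loss(out_u$p_scales)
    total <- ag_add(ag_add(l_sup, l_semi), ag_smul(l_unsup, lam))
  } else {
    l_semi <- NULL
    l_unsup <- NULL
    total <- l_sup
  }
  vals <- c(l_sup = l_sup$v,
            l_semi = if (is.null(l_semi)) 0 else l_semi$v,
            l_unsup = if (is.null(l_unsup)) 0 else l_unsup$v)
  if (any(!is.finite(vals)))
    stop("non-finite loss at iteration ", state$iter, ": ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  ag_backward(total)
  lr_t <- cfg$lr * (1 - state$iter / cfg$max_iterations)^0.9
  for (n in names(state$student)) {
    g <- SP[[n]]$g
    if (is.null(g)) g <- 0
    g <- g + cfg$weight_decay * state$student[[n]]
    state$momentum_buf[[n]] <- cfg$momentum * state$momentum_buf[[n]] + g
    state$student[[n]] <- state$student[[n]] - lr_t * state$momentum_buf[[n]]
  }
  state$teacher <- ema_update(state$teacher, state$student, cfg$ema_decay)
  state$iter <- state$iter + 1L
  state$history[[length(state$history) + 1L]] <-
    data.frame(iteration = state$iter, l_sup = vals[["l_sup"]],
               l_semi = vals[["l_semi"]], l_unsup = vals[["l_unsup"]],
               lambda = lam, total = total$v)
  state
}

zscore <- function(x) {
  s <- sd(as.vector(x))
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}

random_patch_corner <- function(vol_shape, patch_shape) {
  vapply(1:3, function(ax)
    if (vol_shape[ax] > patch_shape[ax])
      sample.int(vol_shape[ax] - patch_shape[ax] + 1L, 1L) else 1L,
    integer(1))
}

crop_patch <- function(data, corner, p) {
  data[corner[1]:(corner[1] + p[1] - 1L), corner[2]:(corner[2] + p[2] - 1L),
       corner[3]:(corner[3] + p[3] - 1L), drop = FALSE]
}

#' Train the mean-teacher model on a phantom dataset
#'
#' Loads the manifest written by [generate_dataset()], z-score-normalizes
#' every volume, builds the multi-view weight maps, and runs
#' [training_step()] for `cfg$max_iterations` iterations (sampling one
#' labeled and one unlabeled patch per batch at random corners, applying
#' CutMix to the unlabeled pair with the configured probability). Label
#' files of unlabeled cases are never read. Runs are bit-reproducible for
#' a fixed seed.
#'
#' @param data_dir Directory holding `manifest.csv` and the volumes.
#' @param net_config A [network_config()].
#' @param cfg A [train_config()].
#' @param lw A [loss_weights()].
#' @param supervision List: `enabled`, `decay_weight`, `combine_rule`,
#'   `source_index`, `band_width` (see [build_view_weightmap()]).
#' @param augment List: `cutmix = list(enabled, alpha, prob)`.
#' @param checkpoint Path for the checkpoint (RDS + JSON sidecar).
#' @param log_csv Path for the per-iteration loss log.
#' @param resume_from Optional checkpoint to continue from; losses resume at
#'   the next iteration row.
#' @return The final `tpssan_trainstate`, invisibly.
#' @export
train_semisup <- function(data_dir, net_config, cfg, lw = loss_weights(),
                          supervision = list(enabled = TRUE,
                                             decay_weight = 0.95,
                                             combine_rule = "product",
                                             source_index = "middle",
                                             band_width = 1L),
                          augment = list(cutmix = list(enabled = TRUE,
                                                       alpha = 1,
                                                       prob = 0.5)),
                          checkpoint = file.path(data_dir, "checkpoint.rds"),
                          log_csv = file.path(data_dir, "train_log.csv"),
                          resume_from = NULL) {
  manifest_path <- file.path(data_dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("no manifest.csv found in ", data_dir)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  lab_rows <- manifest[manifest$split == "labeled", , drop = FALSE]
  unl_rows <- manifest[manifest$split == "unlabeled", , drop = FALSE]
  if (nrow(lab_rows) == 0) stop("empty labeled pool in ", data_dir)
  if (cfg$semi_enabled && nrow(unl_rows) == 0)
    stop("semi-supervised training needs at least one unlabeled volume")
  load_case <- function(row, with_label) {
    v <- read_volume(file.path(data_dir, row$volume_path))
    out <- list(x = zscore(v$data))
    if (with_label)
      out$y <- read_labelmap(file.path(data_dir, row$label_path),
                             net_config$num_classes)$data
    out
  }
  labeled <- lapply(seq_len(nrow(lab_rows)), function(i)
    load_case(lab_rows[i, ], TRUE))
  unlabeled <- lapply(seq_len(nrow(unl_rows)), function(i)
    load_case(unl_rows[i, ], FALSE))
  wmap_cache <- list()
  wmap_for <- function(shape) {
    key <- paste(shape, collapse = "x")
    if (is.null(wmap_cache[[key]]))
      wmap_cache[[key]] <<- make_weightmap(shape, supervision)
    wmap_cache[[key]]
  }
  if (!is.null(resume_from)) {
    state <- load_checkpoint(resume_from)
    stopifnot(inherits(state, "tpssan_trainstate"))
  } else {
    state <- init_train_state(net_config, cfg, lw)
    set.seed(cfg$seed)
  }
  p <- cfg$patch_shape
  use_cutmix <- isTRUE(augment$cutmix$enabled) && length(unlabeled) >= 2L
  while (state$iter < cfg$max_iterations) {
    li <- labeled[[sample.int(length(labeled), 1L)]]
    lc <- random_patch_corner(dim(li$x), p)
    batch <- list(labeled = list(x = crop_patch(li$x, lc, p),
                                 y = crop_patch(li$y, lc, p),
                                 w = crop_patch(wmap_for(dim(li$x)), lc, p)))
    if (cfg$semi_enabled) {
      ui <- unlabeled[[sample.int(length(unlabeled), 1L)]]
      uc <- random_patch_corner(dim(ui$x), p)
      batch$unlabeled <- list(x = crop_patch(ui$x, uc, p),
                              w = crop_patch(wmap_for(dim(ui$x)), uc, p))
      if (use_cutmix && runif(1) < (augment$cutmix$prob %||% 0.5)) {
        u2 <- unlabeled[[sample.int(length(unlabeled), 1L)]]
        c2 <- random_patch_corner(dim(u2$x), p)
        batch$unlabeled$x2 <- crop_patch(u2$x, c2, p)
        batch$cutmix_alpha <- augment$cutmix$alpha %||% 1
      }
    }
    state <- training_step(batch, state, cfg)
  }
  log_df <- do.call(rbind, state$history)
  write.csv(log_df, log_csv, row.names = FALSE)
  save_checkpoint(state, checkpoint)
  invisible(state)
}

#' Sliding-window prediction with a trained checkpoint
#'
#' Z-score-normalizes the volume, extracts the fixed-stride patch grid,
#' runs the teacher network (or the student with `use = "student"`),
#' mean-recomposes the full-resolution probability head and takes the
#' voxelwise argmax.
#'
#' @param v A `tpssan_volume` (or 3D array).
#' @param checkpoint A `tpssan_trainstate` or a path to a saved one.
#' @param patch_shape Patch shape; defaults to the training patch.
#' @param stride Sliding-window stride; defaults to half the patch.
#' @param use `"teacher"` (default) or `"student"`.
#' @return A `tpssan_labelmap`.
#' @export
predict_volume <- function(v, checkpoint, patch_shape = NULL, stride = NULL,
                           use = c("teacher", "student")) {
  use <- match.arg(use)
  state <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  data <- zscore(vol_data(v))
  p <- as.integer(patch_shape %||% state$train_config$patch_shape)
  if (any(p > dim(data)))
    stop("patch shape exceeds the volume extent")
  grid <- patch_grid(dim(data), p,
                     as.integer(stride %||% pmax(1L, p %/% 2L)))
  params <- if (use == "teacher") state$teacher else state$student
  P <- wrap_params(params)
  probs <- lapply(extract_patches(data, grid), function(pa) {
    out <- net_forward_t(P, state$config, ag_const(as_input4d(pa)))
    out$p_scales[[1]]$v
  })
  fused <- recompose(probs, grid, dim(data))
  C <- dim(fused)[4]
  lab <- max.col(matrix(fused, ncol = C), ties.method = "first") - 1L
  new_labelmap(array(lab, dim = dim(data)), num_classes = C)
}
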