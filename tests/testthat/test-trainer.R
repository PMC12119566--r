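tiny_net_cfg <- function() make_variant(5L, base_channels = 2L,
                                        num_levels = 2L, pyramid_scales = 2L)

tiny_train_cfg <- function(iters = 5L, semi = TRUE, seed = 1L)
  train_config(max_iterations = iters, patch_shape = c(8L, 8L, 8L),
               seed = seed, semi_enabled = semi, ema_decay = 0.9)

tiny_batch <- function(seed = 1, semi = TRUE) {
  set.seed(seed)
  b <- list(labeled = list(x = array(rnorm(8^3), c(8, 8, 8)),
                           y = array(sample(0:1, 8^3, TRUE), c(8, 8, 8)),
                           w = array(1, c(8, 8, 8))))
  if (semi) b$unlabeled <- list(x = array(rnorm(8^3), c(8, 8, 8)),
                                w = array(1, c(8, 8, 8)))
  b
}

test_that("EMA transfer follows its closed-form geometric recursion", {
  set.seed(1)
  t0 <- list(a = array(rnorm(8), c(2, 2, 2)), b = rnorm(3))
  s <- list(a = array(rnorm(8), c(2, 2, 2)), b = rnorm(3))
  expect_identical(ema_update(t0, s, 0), s)
  expect_identical(ema_update(t0, s, 1), t0)
  decay <- 0.9
  th <- t0
  for (k in 1:7) th <- ema_update(th, s, decay)
  for (n in names(t0))
    expect_equal(th[[n]], decay^7 * t0[[n]] + (1 - decay^7) * s[[n]],
                 tolerance = 1e-12)
  bad <- s; bad$a <- array(0, c(2, 2))
  expect_error(ema_update(t0, bad, 0.5), "shape mismatch")
})

test_that("after each step the teacher lies between its past self and the student", {
  st <- init_train_state(tiny_net_cfg(), tiny_train_cfg())
  set.seed(2)
  teacher_before <- st$teacher
  st1 <- training_step(tiny_batch(), st)
  for (n in names(st1$teacher)) {
    lo <- pmin(teacher_before[[n]], st1$student[[n]])
    hi <- pmax(teacher_before[[n]], st1$student[[n]])
    expect_true(all(st1$teacher[[n]] >= lo - 1e-12 &
                      st1$teacher[[n]] <= hi + 1e-12))
  }
})

test_that("identical seeded steps produce bit-identical losses", {
  run_once <- function() {
    st <- init_train_state(tiny_net_cfg(), tiny_train_cfg())
    set.seed(7)
    st <- training_step(tiny_batch(3), st)
    st <- training_step(tiny_batch(4), st)
    st
  }
  a <- run_once()
  b <- run_once()
  expect_identical(do.call(rbind, a$history), do.call(rbind, b$history))
  expect_identical(a$student, b$student)
})

test_that("with zero noise and teacher == student, pseudo-labels are the student argmax", {
  cfg <- tiny_net_cfg()
  tc <- tiny_train_cfg()
  tc$noise_sigma <- 0
  st <- init_train_state(cfg, tc)   # teacher initialized as a student copy
  expect_identical(st$teacher, st$student)
  x <- array(rnorm(8^3), c(8, 8, 8))
  pseudo <- tpssan:::teacher_pseudo(st, x)
  pyr <- network_forward(structure(list(config = cfg, params = st$student),
                                   class = "tpssan_network"), x)
  own <- apply(pyr$p_scales[[1]], 1:3, which.max) - 1L
  expect_identical(pseudo, own)
})

test_that("supervised loss decreases over 50 steps on one noiseless phantom", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                      chamber_semi_axes = c(5, 4, 3),
                                      n_appendages = 0L, noise_sigma = 0,
                                      bias_field_strength = 0, seed = 2))
  cfg <- tiny_net_cfg()
  tc <- train_config(max_iterations = 50L, patch_shape = c(16L, 16L, 16L),
                     seed = 1L, semi_enabled = FALSE)
  st <- init_train_state(cfg, tc)
  batch <- list(labeled = list(x = tpssan:::zscore(ph$volume$data),
                               y = ph$label$data,
                               w = array(1, c(16, 16, 16))))
  set.seed(1)
  for (i in 1:50) st <- training_step(batch, st, tc)
  expect_lt(st$history[[50]]$l_sup, st$history[[1]]$l_sup)
  expect_equal(length(st$history), 50L)
})

test_that("full training runs are reproducible, resumable and leak-proof", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), chamber_semi_axes = c(5, 4, 3),
                       n_appendages = 0L, noise_sigma = 0.05,
                       bias_field_strength = 0.1, seed = 1)
  dd <- file.path(tempdir(), "trainds")
  unlink(dd, recursive = TRUE)
  generate_dataset(dd, n_labeled = 1, n_unlabeled = 2, spec, seed = 3)
  cfg <- tiny_net_cfg()
  tc <- train_config(max_iterations = 6L, patch_shape = c(16L, 16L, 16L),
                     seed = 5L, ema_decay = 0.9)
  ck1 <- tempfile(fileext = ".rds"); lg1 <- tempfile(fileext = ".csv")
  ck2 <- tempfile(fileext = ".rds"); lg2 <- tempfile(fileext = ".csv")
  s1 <- train_semisup(dd, cfg, tc, checkpoint = ck1, log_csv = lg1)
  s2 <- train_semisup(dd, cfg, tc, checkpoint = ck2, log_csv = lg2)
  expect_identical(s1$teacher, s2$teacher)
  log1 <- read.csv(lg1)
  expect_equal(nrow(log1), 6L)
  expect_equal(log1$iteration, 1:6)

  # poisoning the unlabeled label file must not change training at all
  manifest <- read.csv(file.path(dd, "manifest.csv"), stringsAsFactors = FALSE)
  unl <- manifest$volume_path[manifest$split == "unlabeled"][1]
  poison <- new_labelmap(array(1L, c(16, 16, 16)))
  write_volume(poison, file.path(dd, sub("_vol", "_lab", unl)))
  s3 <- train_semisup(dd, cfg, tc, checkpoint = tempfile(fileext = ".rds"),
                      log_csv = tempfile(fileext = ".csv"))
  expect_identical(s3$teacher, s1$teacher)

  # resuming at iteration k continues the log at k + 1
  tc2 <- tc
  tc2$max_iterations <- 9L
  s4 <- train_semisup(dd, cfg, tc2, checkpoint = tempfile(fileext = ".rds"),
                      log_csv = lg2, resume_from = ck1)
  log2 <- read.csv(lg2)
  expect_equal(nrow(log2), 9L)
  expect_equal(log2$iteration, 1:9)
  expect_equal(s4$iter, 9L)
  expect_error(train_semisup(file.path(tempdir(), "nowhere"), cfg, tc),
               "no manifest")
  unlink(dd, recursive = TRUE)
})

test_that("sliding-window prediction reduces to one forward pass on a single patch", {
  cfg <- tiny_net_cfg()
  tc <- tiny_train_cfg(iters = 3L, semi = FALSE)
  st <- init_train_state(cfg, tc)
  set.seed(6)
  v <- new_volume(array(rnorm(8^3), c(8, 8, 8)))
  pred <- predict_volume(v, st, patch_shape = c(8, 8, 8))
  P <- tpssan:::wrap_params(st$teacher)
  out <- tpssan:::net_forward_t(P, cfg, tpssan:::ag_const(
    tpssan:::as_input4d(tpssan:::zscore(v$data))))
  direct <- apply(out$p_scales[[1]]$v, 1:3, which.max) - 1L
  expect_identical(pred$data, direct)
  expect_s3_class(pred, "tpssan_labelmap")
})
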