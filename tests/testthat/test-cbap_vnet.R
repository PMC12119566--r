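test_that("adaptive channel attention gates by the pooled sigmoid", {
  z <- array(0, c(4, 4, 4, 3))
  expect_equal(adaptive_channel_attention(z), z)
  # constant single-channel input c -> c * sigmoid(c)
  for (cc in c(-1.3, 0.4, 2)) {
    x <- array(cc, c(3, 3, 3, 1))
    expect_equal(adaptive_channel_attention(x),
                 array(cc * plogis(cc), c(3, 3, 3, 1)), tolerance = 1e-12)
  }
  set.seed(1)
  x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  out <- adaptive_channel_attention(x)
  expect_true(all(abs(out) <= abs(x)))
  expect_equal(dim(out), dim(x))
})

test_that("CBAM preserves shape, kills zeros and reduces to identity at gate 1", {
  set.seed(2)
  x <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  out <- cbam_block(x, seed = 1)
  expect_equal(dim(out), dim(x))
  expect_equal(cbam_block(array(0, dim(x)), seed = 1), array(0, dim(x)))
  # freeze both sigmoid pre-activations at a large constant => gate ~ 1
  big <- 50
  k <- 7
  params <- list(ca.w1 = matrix(0, 2, 4), ca.b1 = rep(0, 2),
                 ca.w2 = matrix(0, 4, 2), ca.b2 = rep(big, 4),
                 sa.w = array(0, c(k, k, k, 2, 1)), sa.b = big)
  expect_equal(cbam_block(x, params = params), x, tolerance = 1e-10)
  expect_error(cbam_block(array(0, c(4, 4, 4, 6)),
                          config = network_config(base_channels = 4,
                                                  num_levels = 2,
                                                  pyramid_scales = 2,
                                                  cbam_positions = character(),
                                                  reduction_ratio = 4,
                                                  input_attention = FALSE)),
               "configuration error")
})

test_that("forward yields valid class distributions at every scale", {
  cfg <- make_variant(3L, base_channels = 2L, num_levels = 2L,
                      pyramid_scales = 3L)
  net <- make_network(cfg, seed = 1)
  set.seed(3)
  x <- array(rnorm(8^3), c(8, 8, 8))
  pyr <- network_forward(net, x)
  expect_length(pyr$p_scales, 3L)
  for (p in pyr$p_scales) {
    expect_equal(dim(p), c(8, 8, 8, 2))
    expect_equal(apply(p, 1:3, sum), array(1, c(8, 8, 8)), tolerance = 1e-5)
    expect_true(all(p >= 0))
  }
  expect_equal(pyr$p_avg, Reduce(`+`, pyr$p_scales) / 3, tolerance = 1e-12)
  # repeated evaluation is deterministic (no train/eval stochasticity)
  expect_identical(network_forward(net, x)$p_scales, pyr$p_scales)
  expect_error(network_forward(net, array(0, c(8, 8, 6))), "axis z")
})

test_that("the ablation selector reproduces the five placement variants", {
  v1 <- make_variant(1)
  expect_setequal(v1$cbam_positions, paste0("down", 1:4))
  expect_false(v1$input_attention)
  v2 <- make_variant(2)
  expect_setequal(v2$cbam_positions, paste0("down", 1:3))
  expect_true(v2$input_attention)
  v3 <- make_variant(3)
  expect_setequal(v3$cbam_positions, paste0("down", 1:4))
  expect_true(v3$input_attention)
  v4 <- make_variant(4)
  expect_setequal(v4$cbam_positions, paste0("up", 1:4))
  expect_true(v4$input_attention)
  v5 <- make_variant(5)
  expect_length(v5$cbam_positions, 0L)
  expect_false(v5$input_attention)
  expect_error(make_variant(6), "1..5")
})

test_that("parameter count matches a layer-by-layer tally for a tiny network", {
  cfg <- network_config(base_channels = 2L, num_levels = 2L,
                        pyramid_scales = 2L, cbam_positions = "down1",
                        input_attention = TRUE, reduction_ratio = 2L,
                        spatial_kernel = 3L)
  net <- make_network(cfg, seed = 1)
  conv <- function(k, cin, cout, norm = TRUE)
    k^3 * cin * cout + cout + if (norm) 2 * cout else 0
  ch <- c(2, 4, 8)  # widths double per level from base 2
  h <- ch[2] / 2    # CBAM channel-MLP bottleneck width at reduction 2
  tally <-
    conv(3, 1, ch[1]) +                      # stem (input attention: no params)
    conv(2, ch[1], ch[2]) + conv(3, ch[2], ch[2]) +            # enc1 + down
    (h * ch[2] + h) + (ch[2] * h + ch[2]) +                    # CBAM MLP
    3^3 * 2 * 1 + 1 +                                          # CBAM spatial
    conv(2, ch[2], ch[3]) + 2 * conv(3, ch[3], ch[3]) +        # enc2 + down
    (8 * ch[3] * ch[2] + ch[2] + 2 * ch[2]) + conv(3, 2 * ch[2], ch[2]) + # dec2
    (8 * ch[2] * ch[1] + ch[1] + 2 * ch[1]) + conv(3, 2 * ch[1], ch[1]) + # dec1
    conv(1, ch[1], 2, norm = FALSE) + conv(1, ch[2], 2, norm = FALSE)     # heads
  expect_equal(network_num_params(net), tally)
})

test_that("every parameter of every variant receives gradient", {
  set.seed(4)
  x <- array(rnorm(32^3), c(32, 32, 32, 1))
  y <- array(sample(0:1, 32^3, TRUE), c(32, 32, 32))
  w <- array(1, c(32, 32, 32))
  for (m in 1:5) {
    cfg <- make_variant(m, base_channels = 2L)
    net <- make_network(cfg, seed = m)
    tape <- tpssan:::ag_tape()
    P <- tpssan:::wrap_params(net$params, tape)
    out <- tpssan:::net_forward_t(P, cfg, tpssan:::ag_const(x))
    loss <- NULL
    for (s in seq_along(out$p_scales)) {
      l <- tpssan:::ag_seg_loss(out$p_scales[[s]], y, w)
      loss <- if (is.null(loss)) l else tpssan:::ag_add(loss, l)
    }
    tpssan:::ag_backward(loss)
    dead <- names(net$params)[vapply(names(net$params), function(n)
      is.null(P[[n]]$g) || all(P[[n]]$g == 0), logical(1))]
    expect_length(dead, 0L)
  }
})

test_that("coarse features translate with the input (periodic shift)", {
  # a compact blob on a constant background shifted by one downsampling
  # period translates the pre-upsampling features by one coarse voxel,
  # up to border effects
  cfg <- make_variant(5L, base_channels = 2L, num_levels = 1L,
                      pyramid_scales = 2L)
  net <- make_network(cfg, seed = 5)
  n <- 24L
  blob <- function(cx) {
    x <- array(0, c(n, n, n, 1))
    for (i in -2:2) for (j in -2:2) for (k in -2:2)
      x[cx + i, 12 + j, 12 + k, 1] <- exp(-(i^2 + j^2 + k^2) / 4)
    x
  }
  P <- tpssan:::wrap_params(net$params)
  f0 <- tpssan:::net_forward_t(P, cfg, tpssan:::ag_const(blob(10L)),
                               internals = TRUE)$encoder_features[[1]]$v
  f1 <- tpssan:::net_forward_t(P, cfg, tpssan:::ag_const(blob(12L)),
                               internals = TRUE)$encoder_features[[1]]$v
  margin <- 4L
  idx <- (margin + 1):(n / 2 - margin)
  expect_equal(f1[idx, , , , drop = FALSE],
               f0[idx - 1L, , , , drop = FALSE], tolerance = 1e-8)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  cfg <- make_variant(5L, base_channels = 2L, num_levels = 2L,
                      pyramid_scales = 2L)
  st <- init_train_state(cfg, train_config(max_iterations = 5,
                                           patch_shape = c(8, 8, 8)))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  st2 <- load_checkpoint(path)
  expect_identical(st2$student, st$student)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$base_channels, 2L)
  expect_error(load_checkpoint(tempfile()), "not found")
})
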