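test_that("weighted cross-entropy matches hand-evaluated toys and reductions", {
  # 2-voxel toy: w = (1,3), true-class probabilities (0.5, 0.25)
  expect_equal(weighted_cross_entropy(c(0.5, 0.25), c(1, 1), c(1, 3)),
               (1 * log(2) + 3 * log(4)) / 4, tolerance = 1e-12)
  set.seed(1)
  p <- array(runif(2 * 2 * 2 * 2, 0.1, 1), c(2, 2, 2, 2))
  p <- p / array(rep(apply(p, 1:3, sum), 2), dim(p))
  y <- array(sample(0:1, 8, TRUE), c(2, 2, 2))
  expect_equal(weighted_cross_entropy(p, y, array(1, c(2, 2, 2))),
               oracle_wce(p, y, array(1, c(2, 2, 2))), tolerance = 1e-12)
  # perfect prediction scores zero
  ph <- array(0, c(2, 2, 2, 2))
  ph[, , , 1] <- (y == 0); ph[, , , 2] <- (y == 1)
  expect_equal(weighted_cross_entropy(ph, y, array(1, c(2, 2, 2))), 0,
               tolerance = 1e-6)
  expect_error(weighted_cross_entropy(p, y, array(0, c(2, 2, 2))), "positive")
})

test_that("weighted Dice matches hand-evaluated toys and edge conventions", {
  expect_equal(weighted_dice(c(0.5, 0.5), c(1, 0), c(1, 1)), 1 / 3,
               tolerance = 1e-12)
  y <- array(c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L), c(2, 2, 2))
  pperf <- array(0, c(2, 2, 2, 2))
  pperf[, , , 2] <- y; pperf[, , , 1] <- 1 - y
  expect_equal(weighted_dice(pperf, y, array(runif(8) + 0.1, c(2, 2, 2))), 0)
  pz <- array(0, c(2, 2, 2, 2)); pz[, , , 1] <- 1
  expect_equal(weighted_dice(pz, y, array(1, c(2, 2, 2))), 1)
  expect_warning(
    v <- weighted_dice(pz, array(0L, c(2, 2, 2)), array(1, c(2, 2, 2))),
    "empty")
  expect_equal(v, 0)
})

test_that("supervised loss averages CE and Dice and ignores weight rescaling", {
  set.seed(2)
  p <- array(runif(16, 0.1, 1), c(2, 2, 2, 2))
  p <- p / array(rep(apply(p, 1:3, sum), 2), dim(p))
  y <- array(sample(0:1, 8, TRUE), c(2, 2, 2))
  w <- array(runif(8, 0.2, 1), c(2, 2, 2))
  expect_equal(supervised_loss(p, y, w),
               0.5 * weighted_cross_entropy(p, y, w) +
                 0.5 * weighted_dice(p, y, w))
  expect_equal(supervised_loss(p, y, w), supervised_loss(p, y, 7.3 * w),
               tolerance = 1e-12)
})

test_that("KL uncertainty maps match the two-term hand evaluation", {
  # one voxel, p_s = (1, 0), p_c = (0.5, 0.5): D = 1 * log(1/0.5) = log 2
  pyr <- structure(list(
    p_scales = list(array(c(1, 0), c(1, 1, 1, 2)),
                    array(c(0, 1), c(1, 1, 1, 2))),
    p_avg = array(c(0.5, 0.5), c(1, 1, 1, 2))), class = "tpssan_pyramid")
  D <- uncertainty_maps(pyr)
  expect_equal(as.vector(D[[1]]), log(2), tolerance = 1e-5)
  expect_equal(as.vector(D[[2]]), log(2), tolerance = 1e-5)

  pyr2 <- random_pyramid(c(2, 2, 2), C = 3, S = 3, seed = 3)
  D2 <- uncertainty_maps(pyr2)
  expect_true(all(unlist(D2) >= 0))
  same <- structure(list(p_scales = list(pyr2$p_scales[[1]], pyr2$p_scales[[1]]),
                         p_avg = pyr2$p_scales[[1]]), class = "tpssan_pyramid")
  expect_true(all(unlist(uncertainty_maps(same)) == 0))
})

test_that("consistency loss is zero at agreement and positive otherwise", {
  pyr <- random_pyramid(c(2, 2, 2), C = 2, S = 2, seed = 4)
  same <- structure(list(p_scales = list(pyr$p_scales[[1]], pyr$p_scales[[1]]),
                         p_avg = pyr$p_scales[[1]]), class = "tpssan_pyramid")
  expect_equal(unsup_loss(same), 0)
  expect_gt(unsup_loss(pyr), 0)
  expect_equal(unsup_loss(pyr), oracle_unsup(pyr$p_scales), tolerance = 1e-12)
})

test_that("the consistency ramp matches its closed form", {
  lw <- loss_weights(lambda_unsup = 0.2, rampup_length = 50)
  expect_equal(lambda_schedule(0, lw), 0)
  expect_equal(lambda_schedule(50, lw), 0.2)
  expect_equal(lambda_schedule(200, lw), 0.2)
  expect_equal(lambda_schedule(25, lw), 0.2 * exp(-5 * (1 - 25 / 50)^2))
  expect_equal(total_loss(1, 2, 3, 0, lw), 3)
  expect_equal(total_loss(1, 2, 3, 100, lw), 3 + 0.2 * 3)
  lin <- loss_weights(0.2, 50, "linear")
  expect_equal(lambda_schedule(25, lin), 0.1)
})

test_that("tape losses agree with the array losses and their gradients check out", {
  set.seed(5)
  d <- c(2, 2, 2, 2)
  logits <- array(rnorm(prod(d)), d)
  y <- array(sample(0:1, 8, TRUE), c(2, 2, 2))
  w <- array(runif(8, 0.2, 1), c(2, 2, 2))
  softmax4 <- function(a) {
    e <- exp(a - array(rep(apply(a, 1:3, max), d[4]), d))
    e / array(rep(apply(e, 1:3, sum), d[4]), d)
  }
  # value consistency, tape vs plain
  p <- softmax4(logits)
  tape <- tpssan:::ag_tape()
  pt <- tpssan:::ag_param(p, tape)
  l1 <- tpssan:::ag_seg_loss(pt, y, w)
  expect_equal(l1$v, supervised_loss(p, y, w), tolerance = 1e-12)

  pyr_t <- lapply(1:3, function(i) tpssan:::ag_param(softmax4(
    array(rnorm(prod(d)), d)), tape))
  l2 <- tpssan:::ag_unsup_loss(pyr_t)
  plain <- structure(list(p_scales = lapply(pyr_t, function(t) t$v),
                          p_avg = Reduce(`+`, lapply(pyr_t, function(t) t$v)) / 3),
                     class = "tpssan_pyramid")
  expect_equal(l2$v, unsup_loss(plain), tolerance = 1e-12)

  # finite-difference gradient check through softmax on 2^3 toys
  fd_one <- function(make_loss, x0) {
    tape <- tpssan:::ag_tape()
    xt <- tpssan:::ag_param(x0, tape)
    loss <- make_loss(xt)
    tpssan:::ag_backward(loss)
    g <- xt$g
    eps <- 1e-5
    for (i in sample(length(x0), 6)) {
      xp <- x0; xp[i] <- xp[i] + eps
      xm <- x0; xm[i] <- xm[i] - eps
      num <- (make_loss(tpssan:::ag_const(xp))$v -
                make_loss(tpssan:::ag_const(xm))$v) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  fd_one(function(xt) tpssan:::ag_seg_loss(tpssan:::ag_softmax_ch(xt), y, w),
         logits)
  p2_fixed <- softmax4(array(rnorm(prod(d)), d))
  fd_one(function(xt) {
    tpssan:::ag_unsup_loss(list(tpssan:::ag_softmax_ch(xt),
                                tpssan:::ag_const(p2_fixed)))
  }, logits)
})
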