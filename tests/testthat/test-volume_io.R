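test_that("NIfTI write/read round-trips data and spacing", {
  set.seed(1)
  v <- new_volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(0.5, 0.5, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-12)
  expect_equal(r$spacing, v$spacing)
})

test_that("missing files and unknown formats are rejected", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  p <- tempfile(fileext = ".h5")
  writeLines("x", p)
  expect_error(read_volume(p), "unrecognized volume format")
  expect_error(write_volume(array(0, c(2, 2, 2)), tempfile(fileext = ".xyz")),
               "unrecognized volume format")
})

test_that("NRRD write/read round-trips data, spacing and origin", {
  set.seed(2)
  v <- new_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)), spacing = c(1, 2, 3),
                  origin = c(-1, 0, 2.5))
  path <- tempfile(fileext = ".nrrd")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-15)
  expect_equal(r$spacing, v$spacing)
  expect_equal(r$origin, v$origin)
})

test_that("NRRD written by SimpleITK reads back with normalized axes", {
  # SimpleITK arrays are indexed (z, y, x); the file's fastest axis must
  # land on our x axis, verified through voxel sums and marginal profiles
  path <- tempfile(fileext = ".nrrd")
  script <- sprintf(paste(
    "import SimpleITK as sitk, numpy as np",
    "a = np.arange(3*4*5, dtype=np.float64).reshape(3, 4, 5)  # (z, y, x)",
    "img = sitk.GetImageFromArray(a)",
    "img.SetSpacing((0.5, 1.5, 2.0))",
    "sitk.WriteImage(img, %s)", sep = "\n"), shQuote(path))
  status <- system2("python", "-", input = script)
  expect_equal(status, 0L)
  v <- read_volume(path)
  expect_equal(dim(v$data), c(5L, 4L, 3L))
  expect_equal(v$spacing, c(0.5, 1.5, 2.0))
  ref <- aperm(array(0:(3 * 4 * 5 - 1), dim = c(5, 4, 3)), c(1, 2, 3))
  expect_equal(sum(v$data), sum(ref))
  # marginal profile along x (fastest axis on disk)
  expect_equal(apply(v$data, 1, sum), apply(ref, 1, sum))
  expect_equal(apply(v$data, 3, sum), apply(ref, 3, sum))
})

test_that("patch grids cover every voxel and honor patch shape", {
  g <- patch_grid(c(8, 8, 8), c(8, 8, 8))
  expect_equal(nrow(g$offsets), 1L)
  v <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(extract_patches(v, g)[[1]], v)

  g2 <- patch_grid(c(10, 8, 8), c(8, 8, 8), stride = 2)
  pats <- extract_patches(v2 <- array(rnorm(10 * 8 * 8), c(10, 8, 8)), g2)
  expect_equal(length(pats), nrow(g2$offsets))
  covered <- array(FALSE, c(10, 8, 8))
  for (i in seq_len(nrow(g2$offsets))) {
    o <- g2$offsets[i, ]
    covered[o[1]:(o[1] + 7), o[2]:(o[2] + 7), o[3]:(o[3] + 7)] <- TRUE
  }
  expect_true(all(covered))
  expect_error(patch_grid(c(8, 8, 8), c(8, 8, 8), stride = 0), "stride")
  expect_error(patch_grid(c(4, 4, 4), c(8, 8, 8)), "patch larger than volume")
})

test_that("recomposition averages overlaps and matches the dense oracle", {
  v <- array(rnorm(8^3), c(8, 8, 8))
  g <- patch_grid(c(8, 8, 8), c(8, 8, 8))
  expect_equal(recompose(list(v), g, c(8, 8, 8)), v)

  # two half-overlapping constant patches: overlap must hold the mean
  g2 <- patch_grid(c(12, 8, 8), c(8, 8, 8), stride = 4)
  r <- recompose(list(array(0, c(8, 8, 8)), array(1, c(8, 8, 8))), g2,
                 c(12, 8, 8))
  expect_equal(unique(as.vector(r[1:4, , ])), 0)
  expect_equal(unique(as.vector(r[5:8, , ])), 0.5)
  expect_equal(unique(as.vector(r[9:12, , ])), 1)

  set.seed(3)
  g3 <- patch_grid(c(9, 7, 6), c(4, 4, 4), stride = c(3, 2, 2))
  pats <- lapply(seq_len(nrow(g3$offsets)),
                 function(i) array(rnorm(64), c(4, 4, 4)))
  expect_equal(recompose(pats, g3, c(9, 7, 6)),
               oracle_recompose(pats, g3, c(9, 7, 6)), tolerance = 1e-12)
})

test_that("one-hot extract/recompose preserves labels away from ties", {
  set.seed(4)
  lab <- array(sample(0:1, 10 * 8 * 8, TRUE), c(10, 8, 8))
  g <- patch_grid(c(10, 8, 8), c(8, 8, 8), stride = 2)
  onehot <- function(patch) {
    o <- array(0, c(dim(patch), 2))
    o[, , , 1] <- patch == 0
    o[, , , 2] <- patch == 1
    o
  }
  pats <- lapply(extract_patches(lab, g), onehot)
  fused <- recompose(pats, g, c(10, 8, 8))
  rec <- (fused[, , , 2] > fused[, , , 1]) * 1L
  expect_identical(rec, lab)
})
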