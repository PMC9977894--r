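test_that("Hounsfield windowing clips and rescales linearly", {
  expect_equal(window_normalize(c(-5, 0, 45, 90, 120)),
               c(0, 0, 0.5, 1, 1))
  # idempotent when rescaled back to HU
  v <- array(runif(24, -100, 200), c(2, 3, 4))
  w <- window_normalize(v)
  expect_equal(window_normalize(w * 90), w)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("slicing yields one aligned sample per z index with binary masks", {
  set.seed(41)
  vol <- window_normalize(array(runif(32 * 32 * 5, 0, 90), c(32, 32, 5)),
                          0, 90)
  masks <- array(0L, c(32, 32, 5))
  masks[10:14, 10:14, 2] <- 1L
  out <- slice_volume(vol, masks, size = 32, id = "scan01")
  expect_length(out, 5)
  expect_equal(sum(out[[2]]$mask), 25)
  expect_equal(sum(out[[1]]$mask), 0)
  expect_equal(vapply(out, `[[`, 0L, "z"), 1:5)
  expect_error(slice_volume(vol, masks[, , 1:4]), "masks")
})

test_that("resized checkerboard masks stay binary under nearest-neighbour", {
  skip_if_not_installed("EBImage")
  vol <- array(0.5, c(64, 64, 1))
  masks <- array(as.integer((row(matrix(0, 64, 64)) +
                               col(matrix(0, 64, 64))) %% 2L), c(64, 64, 1))
  out <- slice_volume(vol, masks, size = 32, id = "cb")
  expect_true(all(out[[1]]$mask %in% c(0L, 1L)))
})

test_that("augmentation is deterministic, preserves alignment and foreground count", {
  s <- generate_phantom(phantom_config(size = 64), seed = 2)
  a1 <- augment_slice(s, seed = 7)
  a2 <- augment_slice(s, seed = 7)
  expect_identical(a1, a2)
  # flips and right-angle rotations are bijections of the pixel grid
  expect_equal(sum(a1$mask), sum(s$mask))
  expect_true(all(a1$image >= 0 & a1$image <= 1))
})

test_that("augmentation noise has the configured variance", {
  flat <- structure(list(image = matrix(0.5, 100, 100),
                         mask = matrix(0L, 100, 100), id = "f", z = 1L),
                    class = "slice_sample")
  # variance 0.01 means standard deviation 0.1 on the intensity scale
  devs <- unlist(lapply(1:3, function(sd_) {
    a <- augment_slice(flat, seed = sd_, noise_var = 0.01)
    as.vector(a$image - 0.5)
  }))
  expect_lt(abs(stats::sd(devs) - 0.1), 0.01)
})

test_that("slice datasets survive a write/read round trip bit-exactly", {
  dir <- withr::local_tempdir()
  ds <- generate_phantom_dataset(4, phantom_config(size = 64), seed = 11,
                                 dir = dir, k_folds = 2)
  back <- read_slice_dataset(dir)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(back[[i]]$image, ds$samples[[i]]$image, tolerance = 1e-12)
    expect_identical(back[[i]]$mask, ds$samples[[i]]$mask)
    expect_equal(back[[i]]$fold, ds$samples[[i]]$fold)
  }
})

test_that("NIfTI volumes round trip through read_ct_volume", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  vol <- array(round(runif(16 * 16 * 3, -50, 150)), c(16, 16, 3))
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  got <- read_ct_volume(f)
  expect_equal(as.vector(got), as.vector(vol))
  expect_equal(dim(got), c(16, 16, 3))
})
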