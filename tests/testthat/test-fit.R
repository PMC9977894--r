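# training loop, cross-validation and ensembling at desk scale

small_spec <- function(nl = "modified")
  gcn_spec(g = 2, input_size = 32, enc_dim_base = 2, dec_dim_base = 2,
           depth = c(1, 1, 1, 1), nonlinearity = nl)

test_that("training reduces the BCE loss on easy phantoms within five epochs", {
  samples <- easy_phantoms(24, size = 32, seed = 61)
  fit <- gcn_fit(samples, small_spec(),
                 gcn_control(epochs = 5, batch_size = 4), seed = 3)
  expect_lt(fit$history$loss[5], fit$history$loss[1])
  expect_equal(nrow(fit$history), 5)
})

test_that("fitting is reproducible: same seed gives identical history and predictions", {
  samples <- easy_phantoms(12, size = 32, seed = 62)
  ctrl <- gcn_control(epochs = 2, batch_size = 4)
  f1 <- gcn_fit(samples, small_spec(), ctrl, seed = 17)
  f2 <- gcn_fit(samples, small_spec(), ctrl, seed = 17)
  expect_identical(f1$history[c("epoch", "loss", "dice")],
                   f2$history[c("epoch", "loss", "dice")])
  x <- samples[[1]]$image
  expect_identical(predict(f1, x, type = "length"),
                   predict(f2, x, type = "length"))
  f3 <- gcn_fit(samples, small_spec(), ctrl, seed = 18)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("fold plans split volumes, never slices, and balance fold sizes", {
  plan <- fold_plan(sprintf("scan%03d", 1:210), k = 5, seed = 1)
  expect_equal(unname(tabulate(plan$assignment, 5)), rep(42L, 5))
  # no volume in two folds by construction; the per-fold train/test split
  # of slices must respect volume boundaries
  ids <- rep(sprintf("scan%03d", 1:10), each = 3)
  plan2 <- fold_plan(ids, k = 5, seed = 2)
  for (f in 1:5) {
    test_vols <- names(plan2$assignment)[plan2$assignment == f]
    train_vols <- names(plan2$assignment)[plan2$assignment != f]
    expect_length(intersect(test_vols, train_vols), 0)
  }
})

test_that("cross validation produces per-fold and pooled metrics with hygiene", {
  samples <- easy_phantoms(10, size = 32, seed = 63)
  cv <- gcn_cv(samples, k = 5, small_spec(),
               gcn_control(epochs = 1, batch_size = 4), seed = 4)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(sum(cv$per_fold$n_test), 10)
  expect_true(all(cv$per_fold$n_train + cv$per_fold$n_test == 10))
  expect_true(all(cv$pooled >= 0 & cv$pooled <= 1))
})

test_that("metric CSVs from cross validation are written and reproducible", {
  samples <- easy_phantoms(10, size = 32, seed = 64)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ctrl <- gcn_control(epochs = 1, batch_size = 4)
  gcn_cv(samples, k = 5, small_spec(), ctrl, seed = 9, out_dir = d1)
  gcn_cv(samples, k = 5, small_spec(), ctrl, seed = 9, out_dir = d2)
  for (f in c("metrics_per_fold.csv", "metrics_pooled.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("ensembles average capsule lengths pixelwise before thresholding", {
  samples <- easy_phantoms(6, size = 32, seed = 65)
  ctrl <- gcn_control(epochs = 1, batch_size = 4)
  fits <- lapply(1:3, function(s) gcn_fit(samples, small_spec(), ctrl, seed = s))
  ens <- gcn_ensemble(fits)
  x <- samples[[1]]$image
  lens <- lapply(fits, predict, newdata = x, type = "length")
  expect_equal(predict(ens, x, type = "length"),
               (lens[[1]] + lens[[2]] + lens[[3]]) / 3, tolerance = 1e-12)
  # identical members reproduce the single-model output
  ens_same <- gcn_ensemble(list(fits[[1]], fits[[1]], fits[[1]]))
  expect_equal(predict(ens_same, x, type = "length"), lens[[1]],
               tolerance = 1e-12)
  # strict thresholding: a pixel at exactly the threshold is background
  expect_equal(sum((matrix(0.5, 2, 2) > 0.5)), 0)
  expect_error(gcn_ensemble(fits[1]), "2")
  bad <- gcn_fit(samples, small_spec("squash"), ctrl, seed = 1)
  expect_error(gcn_ensemble(list(fits[[1]], bad)), "same spec")
})

test_that("run_fold trains on out-of-fold volumes and errors on empty folds", {
  samples <- easy_phantoms(10, size = 32, seed = 66)
  plan <- fold_plan(vapply(samples, `[[`, "", "id"), k = 5, seed = 1)
  r <- run_fold(samples, plan, 1, small_spec(),
                gcn_control(epochs = 1, batch_size = 4), seed = 2)
  expect_equal(r$n_train + r$n_test, 10)
  expect_true(all(r$metrics >= 0 & r$metrics <= 1))
})
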