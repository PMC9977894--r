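test_that("spec validation enforces the stem reinterpretation and divisibility", {
  expect_s3_class(gcn_spec(g = 2), "gcn_spec")
  expect_error(gcn_spec(g = 3), "divisible")
  expect_error(gcn_spec(g = 2, input_size = 60), "divisible by 16")
  expect_error(gcn_spec(threshold = 1.5), "threshold")
})

test_that("forward pass propagates shapes: four halvings to the bottleneck and back", {
  spec <- tiny_spec(g = 2, size = 32)
  set.seed(51)
  model <- gcn_build(spec)
  x <- array(runif(32 * 32), c(32, 32))
  fwd <- groupcapsnet:::gcn_forward(model, x, keep = TRUE)
  expect_equal(dim(fwd$lengths), c(32, 32, 1))
  # bottleneck field spatial extent is input/16
  bneck <- fwd$skips   # encoder outputs retained for skips
  expect_equal(dim(fwd$caches$dec1_deconv$slabs[[1]])[2] - 1L, 2 * 2)
  # all capsule lengths lie in [0, 1)
  expect_true(all(fwd$lengths >= 0 & fwd$lengths < 1))
})

test_that("every variant's analytic weight count matches the instantiated model", {
  for (g in c(1, 2, 4)) {
    spec <- gcn_spec(g = g, input_size = 64, enc_dim_base = 2,
                     dec_dim_base = 2, depth = c(1, 1, 2, 2))
    set.seed(g)
    model <- gcn_build(spec)
    walked <- length(unlist(model$stem[c("W1", "b1", "W2", "b2")])) +
      sum(vapply(model$layers, function(l)
        sum(vapply(unlist(l$W, recursive = FALSE), length, 0)), 0))
    expect_equal(count_parameters(spec), walked)
  }
})

test_that("full-architecture weight counts are deterministic and ordered by group count", {
  counts <- vapply(c(1, 2, 4, 8), function(g)
    count_parameters(gcn_spec(g = g)), 0)
  expect_true(all(diff(counts) > 0))
  expect_identical(counts, vapply(c(1, 2, 4, 8), function(g)
    count_parameters(gcn_spec(g = g)), 0))
  # a single 1x1 capsule layer: 2 in-types dim 8 -> 1 out-type dim 8, no bias
  l <- gcn_layer(2, 8, 1, 8, g = 1, mode = "head")
  expect_equal(sum(vapply(unlist(l$W, recursive = FALSE), length, 0)), 128)
})

test_that("prediction thresholds behave as documented at the extremes", {
  spec <- tiny_spec(g = 1, size = 16)
  set.seed(52)
  model <- gcn_build(spec)
  fit <- structure(list(model = model, spec = spec), class = "gcn")
  x <- matrix(runif(256), 16, 16)
  lens <- predict(fit, x, type = "length")
  expect_true(all(lens >= 0 & lens < 1))
  expect_equal(sum(predict(fit, x, threshold = 0.999999)), 0)
  expect_equal(sum(predict(fit, x, threshold = 1e-12)), 256)
  expect_error(predict(fit, matrix(0.5, 20, 20)), "divisible")
})

test_that("an untrained network is deterministic given the build seed", {
  spec <- tiny_spec(g = 2, size = 16)
  x <- matrix(runif(256), 16, 16)
  l1 <- predict(structure(list(
    model = groupcapsnet:::.with_seed(5, gcn_build(spec)), spec = spec),
    class = "gcn"), x, type = "length")
  l2 <- predict(structure(list(
    model = groupcapsnet:::.with_seed(5, gcn_build(spec)), spec = spec),
    class = "gcn"), x, type = "length")
  expect_identical(l1, l2)
})
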