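# grouped layer semantics: block structure, degenerate partitions, deconv

test_that("a grouped layer equals independently computed per-group sub-layers", {
  set.seed(21)
  for (T_ in c(4, 8, 16)) for (g in c(1, 2, 4)) {
    d <- 4
    l <- gcn_layer(T_, d, T_, d, g = g, mode = "conv")
    x <- rand_field(d, T_, 6, 6, seed = T_ * 10 + g)
    full <- layer_forward(l, x)
    Tg <- T_ / g
    for (i in seq_len(g)) {
      sub <- gcn_layer(Tg, d, Tg, d, g = 1, mode = "conv")
      # transplant the group's weight bank into the non-grouped sub-layer
      sub$W[[1]] <- l$W[[i]]
      xs <- x[, (i - 1) * Tg + 1:Tg, , , drop = FALSE]
      got <- layer_forward(sub, xs)
      expect_lt(max(abs(got - full[, (i - 1) * Tg + 1:Tg, , , drop = FALSE])),
                1e-6)
    }
  }
})

test_that("g = 1 grouped layer is identical to the non-grouped layer", {
  set.seed(22)
  l1 <- gcn_layer(4, 3, 4, 3, g = 1, mode = "conv")
  x <- rand_field(3, 4, 8, 8, seed = 9)
  # same weights reused through the grouped code path with g = 1 is the
  # same object; instead check a g = 2 layer against g = 1 with
  # block-diagonal weights equal across paths
  l2 <- gcn_layer(4, 3, 4, 3, g = 2, mode = "conv")
  # build l1 weights from l2 blocks is not possible (missing cross-group
  # pairs); the meaningful degenerate check: a one-group partition routes
  # all types together, matching the plain layer definition
  out <- layer_forward(l1, x)
  expect_equal(dim(out), c(3, 4, 8, 8))
  votes <- capsule_votes(l1, x)
  expect_length(votes, 1)
  expect_equal(dim(votes[[1]])[4], 4 * 9)   # all types x kernel offsets
})

test_that("vote arrays of a grouped layer are exactly 1/g the size of non-grouped", {
  set.seed(23)
  x <- rand_field(4, 8, 6, 6, seed = 3)
  n_votes <- function(g) {
    l <- gcn_layer(8, 4, 8, 4, g = g, mode = "conv")
    sum(vapply(capsule_votes(l, x), function(u) prod(dim(u)) / dim(u)[1],
               0))
  }
  expect_equal(n_votes(2) * 2, n_votes(1))
  expect_equal(n_votes(4) * 4, n_votes(1))
})

test_that("deconvolution doubles the spatial extent and matches a scatter oracle", {
  set.seed(24)
  l <- gcn_layer(2, 3, 2, 3, g = 1, mode = "deconv", routing_iters = 2)
  x <- rand_field(3, 2, 4, 4, seed = 14)
  out <- layer_forward(l, x)
  expect_equal(dim(out), c(3, 2, 8, 8))

  # scatter oracle: output (2i-1+a, 2j-1+b) routes the votes
  # W_(a,b) v_t(i, j) over input types only
  nt <- 2
  for (i in 1:4) for (j in 1:4) for (a in 0:1) for (b in 0:1) {
    k <- a + 2 * b + 1   # offset enumeration (a fastest), matches 2x2 grid
    U <- array(0, c(3, 2, 1, nt))
    for (t in seq_len(nt)) {
      ci <- (k - 1) * nt + t
      U[, , 1, t] <- matrix(l$W[[1]][[ci]] %*% x[, t, i, j], 3, 2)
    }
    want <- capsule_route(U, 2, "modified")$output[, , 1]
    expect_equal(out[, , 2 * i - 1 + a, 2 * j - 1 + b], want,
                 tolerance = 1e-10)
  }
})

test_that("constant input with shared weights gives a spatially constant deconv output", {
  set.seed(25)
  l <- gcn_layer(2, 2, 2, 2, g = 1, mode = "deconv")
  x <- array(rep(c(0.2, -0.1, 0.05, 0.3), each = 1), c(2, 2, 1, 1))
  x <- array(rep(x, 16), c(2, 2, 4, 4))
  out <- layer_forward(l, x)
  # all positions produced by the same kernel offset must be identical
  for (a in 0:1) for (b in 0:1) {
    sl <- out[, , seq(1 + a, 8, by = 2), seq(1 + b, 8, by = 2)]
    expect_lt(max(abs(sweep(sl, 1:2, sl[, , 1, 1]))), 1e-12)
  }
})

test_that("capsule outputs of a layer always have length below one", {
  set.seed(26)
  for (mode in c("conv", "down", "deconv", "head")) {
    l <- gcn_layer(4, 4, if (mode == "head") 1 else 4, 4,
                   g = if (mode == "head") 1 else 2, mode = mode)
    x <- rand_field(4, 4, 4, 4, seed = 31, scale = 3)
    out <- layer_forward(l, x)
    expect_true(all(capsule_lengths(out) < 1))
  }
})

test_that("permuting types within one group (with weights) leaves output unchanged", {
  set.seed(27)
  l <- gcn_layer(4, 3, 4, 3, g = 2, mode = "conv")
  x <- rand_field(3, 4, 5, 5, seed = 8)
  out <- layer_forward(l, x)
  # swap input types 1 and 2 (both in group 1) and the matching weight
  # matrices in every contributor slot of group 1
  l2 <- l
  nt <- l$groups[[1]]$n_in
  for (k in seq_len(l$K)) {
    c1 <- (k - 1) * nt + 1; c2 <- (k - 1) * nt + 2
    l2$W[[1]][c(c1, c2)] <- l$W[[1]][c(c2, c1)]
  }
  x2 <- x[, c(2, 1, 3, 4), , , drop = FALSE]
  expect_equal(layer_forward(l2, x2), out, tolerance = 1e-12)
})
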