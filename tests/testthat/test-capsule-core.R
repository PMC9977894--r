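# voting, routing and counting primitives

test_that("votes are the per-pair matrix transformations of input capsules", {
  # identity and scalar transformations
  l <- gcn_layer(1, 2, 1, 2, g = 1, mode = "head")
  l$W[[1]][[1]] <- diag(2)
  x <- array(c(1, 0), c(2, 1, 1, 1))
  expect_equal(as.vector(capsule_votes(l, x)[[1]]), c(1, 0))
  l$W[[1]][[1]] <- 2 * diag(2)
  x[] <- c(0.3, -0.4)
  expect_equal(as.vector(capsule_votes(l, x)[[1]]), c(0.6, -0.8))

  # random weights against an independent dense matrix-vector oracle
  set.seed(11)
  l2 <- gcn_layer(2, 2, 1, 3, g = 1, mode = "head")
  x2 <- array(stats::rnorm(4), c(2, 2, 1, 1))
  u <- capsule_votes(l2, x2)[[1]]   # (3, 1, 1, 2)
  for (t in 1:2) {
    expected <- l2$W[[1]][[t]] %*% x2[, t, 1, 1]
    expect_equal(as.vector(u[, 1, 1, t]), as.vector(expected),
                 tolerance = 1e-6)
  }
})

test_that("vote shape errors name the mismatch", {
  l <- gcn_layer(2, 4, 2, 4, g = 1, mode = "conv")
  bad <- array(0, c(3, 2, 8, 8))
  expect_error(layer_forward(l, bad), "expects")
  expect_error(gcn_layer(3, 4, 2, 4, g = 2), "divisible")
  expect_error(gcn_layer(2, 4, 3, 4, g = 2), "divisible")
})

# independent scalar-loop transcript of the routing recurrence
route_oracle <- function(U, iters, nonlin) {
  d <- dim(U)[1]; Tg <- dim(U)[2]; P <- dim(U)[3]; C <- dim(U)[4]
  nl <- function(s) {
    r <- sqrt(sum(s^2))
    if (nonlin == "modified") s / (1 + r) else s * r / (1 + r^2)
  }
  S <- array(0, c(d, Tg, P)); Cw <- array(0, c(Tg, P, C))
  for (p in seq_len(P)) {
    b <- matrix(0, Tg, C)
    for (it in seq_len(iters)) {
      cw <- apply(b, 2, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
      cw <- matrix(cw, Tg, C)
      for (t in seq_len(Tg)) {
        s <- numeric(d)
        for (cc in seq_len(C)) s <- s + cw[t, cc] * U[, t, p, cc]
        S[, t, p] <- s
      }
      if (it < iters) {
        for (t in seq_len(Tg)) {
          v <- nl(S[, t, p])
          for (cc in seq_len(C)) b[t, cc] <- b[t, cc] + sum(U[, t, p, cc] * v)
        }
      }
    }
    Cw[, p, ] <- cw
  }
  V <- array(0, dim(S))
  for (p in seq_len(P)) for (t in seq_len(Tg)) V[, t, p] <- nl(S[, t, p])
  list(dominant = S, output = V, couplings = Cw)
}

test_that("routing matches a step-by-step transcript of the recurrence", {
  set.seed(3)
  U <- array(stats::rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  for (nl in c("modified", "squash")) for (iters in c(1, 3)) {
    got <- capsule_route(U, iters, nl)
    want <- route_oracle(U, iters, nl)
    expect_equal(got$dominant, want$dominant, tolerance = 1e-10)
    expect_equal(got$output, want$output, tolerance = 1e-10)
    expect_equal(got$couplings, want$couplings, tolerance = 1e-10)
  }
})

test_that("a single vote routes to its own direction", {
  u <- c(0.3, -0.2, 0.5)
  U <- array(u, c(3, 1, 1, 1))
  for (iters in c(1, 3)) {
    out <- capsule_route(U, iters, "modified")$output[, 1, 1]
    expect_equal(out / sqrt(sum(out^2)), u / sqrt(sum(u^2)), tolerance = 1e-12)
  }
})

test_that("identical votes with uniform couplings sum to k times the initial coupling", {
  u <- c(0.1, 0.2)
  k <- 4
  U <- array(rep(u, k), c(2, 1, 1, k))
  # one output type: softmax gives coupling 1 per contributor
  dom <- capsule_route(U, 1, "modified")$dominant[, 1, 1]
  expect_equal(dom, k * 1 * u, tolerance = 1e-12)
})

test_that("couplings are nonnegative and sum to one across output types", {
  set.seed(5)
  U <- array(stats::rnorm(3 * 4 * 5 * 6), c(3, 4, 5, 6))
  cw <- capsule_route(U, 3, "squash")$couplings
  expect_true(all(cw >= 0))
  sums <- apply(cw, c(2, 3), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("routing rejects invalid configuration and non-finite votes", {
  U <- array(1, c(2, 1, 1, 1))
  expect_error(capsule_route(U, 0), "iteration")
  U[1] <- NaN
  expect_error(capsule_route(U, 3), "finite")
})

test_that("vote counting follows the exact 1/g law on a grid of configurations", {
  for (T_ in c(4, 8, 16)) for (K in c(1, 4, 9)) for (P in c(1, 16)) {
    base <- count_votes(T_, T_, K, P, g = 1)
    for (g in c(1, 2, 4)) {
      expect_equal(count_votes(T_, T_, K, P, g = g) * g, base)
    }
  }
  expect_equal(count_votes(4, 4, 1), 16)
  expect_equal(count_votes(4, 4, 1, g = 2), 8)
  expect_equal(count_votes(4, 4, 1, g = 4), 4)
})

test_that("group partitions are disjoint, equal-size, covering and contiguous", {
  for (n in c(4, 8, 16)) for (g in c(1, 2, 4)) {
    p <- group_partition(n, g)
    expect_length(p, g)
    expect_equal(sort(unlist(p)), 1:n)
    expect_true(all(lengths(p) == n / g))
  }
  expect_error(group_partition(6, 4), "divisible")
})
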