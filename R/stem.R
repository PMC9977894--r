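# Plain convolutional stem: two 3x3, stride-1, 16-channel convolutions with
# biases and a ReLU between them. The 16-channel output is reinterpreted as
# g types x 16/g dims capsules and passed through the capsule nonlinearity
# to form the initial capsule field.

.stem_init <- function(in_ch = 1L, ch = 16L, gain = 1) {
  sd1 <- gain / sqrt(in_ch * 9)
  sd2 <- gain / sqrt(ch * 9)
  list(W1 = array(stats::rnorm(ch * in_ch * 9, sd = sd1), c(ch, in_ch, 9L)),
       b1 = numeric(ch),
       W2 = array(stats::rnorm(ch * ch * 9, sd = sd2), c(ch, ch, 9L)),
       b2 = numeric(ch))
}

# x: (ch_in, H, W, B) -> padded slab (ch_in, H*W+1, B)
.slab <- function(x) {
  d <- dim(x)
  a <- array(0, c(d[1L], d[2L] * d[3L] + 1L, d[4L]))
  a[, seq_len(d[2L] * d[3L]), ] <- x
  a
}

.conv3_forward <- function(A, W, b, H, Wd, B) {
  geom <- .gcn_geom(H, Wd, "conv")
  ch_out <- dim(W)[1L]; ch_in <- dim(W)[2L]
  Z <- gcn_conv_forward(A, geom$idx, W, b, ch_in, ch_out, B, H * Wd, H * Wd)
  matrix(Z, ch_out, H * Wd * B)
}

.conv3_backward <- function(A, W, gZ, H, Wd, B) {
  geom <- .gcn_geom(H, Wd, "conv")
  ch_out <- dim(W)[1L]; ch_in <- dim(W)[2L]
  r <- gcn_conv_backward(A, geom$idx, W, gZ, ch_in, ch_out, B, H * Wd, H * Wd)
  list(gA = array(r$gA, dim(A)), gW = array(r$gW, dim(W)), gb = r$gb)
}

# image batch (H, W, B) -> initial capsule field (d0, g, H, W, B)
.stem_forward <- function(stem, x, g, nonlin, keep = FALSE) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; B <- d[3L]
  ch <- length(stem$b1)
  A0 <- .slab(array(x, c(1L, H, Wd, B)))
  Z1 <- .conv3_forward(A0, stem$W1, stem$b1, H, Wd, B)
  R1 <- Z1 * (Z1 > 0)
  A1 <- .slab(array(R1, c(ch, H, Wd, B)))
  Z2 <- .conv3_forward(A1, stem$W2, stem$b2, H, Wd, B)
  # reinterpret channels as g types x ch/g dims: channel = (type-1)*d0 + j
  d0 <- ch %/% g
  S <- array(Z2, c(d0, g, H * Wd, B))
  V <- .nonlin_forward(S, nonlin)
  out <- array(V, c(d0, g, H, Wd, B))
  if (keep)
    attr(out, "cache") <- list(A0 = A0, Z1 = Z1, A1 = A1, S = S,
                               H = H, W = Wd, B = B)
  out
}

.stem_backward <- function(stem, cache, gout, g, nonlin) {
  H <- cache$H; Wd <- cache$W; B <- cache$B
  ch <- length(stem$b1)
  d0 <- ch %/% g
  gV <- array(gout, c(d0, g * H * Wd * B))
  gS <- .nonlin_backward(cache$S, gV, nonlin)
  gZ2 <- matrix(gS, ch, H * Wd * B)
  bk2 <- .conv3_backward(cache$A1, stem$W2, gZ2, H, Wd, B)
  gR1 <- bk2$gA[, seq_len(H * Wd), , drop = FALSE]
  dim(gR1) <- c(ch, H * Wd * B)
  gZ1 <- gR1 * (cache$Z1 > 0)
  bk1 <- .conv3_backward(cache$A0, stem$W1, gZ1, H, Wd, B)
  list(gW1 = bk1$gW, gb1 = bk1$gb, gW2 = bk2$gW, gb2 = bk2$gb)
}

# capsule nonlinearity and its vector-Jacobian product, capsule dim first
.nonlin_forward <- function(S, nonlin) {
  d <- dim(S)
  m <- matrix(S, nrow = d[1L])
  r <- sqrt(.colSums(m * m, d[1L], ncol(m)))
  sc <- if (nonlin == "modified") 1 / (1 + r) else r / (1 + r * r)
  array(m * rep(sc, each = d[1L]), dim = d)
}

.nonlin_backward <- function(S, gV, nonlin) {
  d <- dim(S)
  n <- d[1L]
  m <- matrix(S, nrow = n)
  gm <- matrix(gV, nrow = n)
  r2 <- .colSums(m * m, n, ncol(m))
  r <- sqrt(r2)
  dot <- .colSums(m * gm, n, ncol(m))
  if (nonlin == "modified") {     # f = s/(1+r): J = I/(1+r) - s s^T / (r (1+r)^2)
    a <- 1 / (1 + r)
    b <- ifelse(r > 1e-12, -dot / (r * (1 + r)^2), 0)
  } else {                        # f = s r/(1+r^2): J = a I + a'(r) s s^T / r
    a <- r / (1 + r2)
    b <- ifelse(r > 1e-12, (1 - r2) / (1 + r2)^2 * dot / r, 0)
  }
  array(gm * rep(a, each = n) + m * rep(b, each = n), dim = d)
}
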