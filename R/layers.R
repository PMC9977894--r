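# Grouped convolutional capsule layers: vote generation, routing-based
# clustering and the squashing nonlinearities. Votes are generated by one
# BLAS multiply per contributor (in-group type x kernel offset), shared
# across spatial positions; gather/scatter and routing run in compiled code.

.geom_cache <- new.env(parent = emptyenv())

# kernel geometry for a layer mode at input extent H x W.
# idx: (P0, K) matrix mapping output position -> input slot (pad = H*W+1);
# for deconv, votes are generated at input resolution (idx = identity) and
# out[[k]] maps input positions to the output positions of kernel offset k.
.gcn_geom <- function(H, W, mode) {
  key <- paste(H, W, mode, sep = ":")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  pad <- H * W + 1L
  lin <- function(i, j, nr) i + (j - 1L) * nr
  if (mode == "conv") {
    off <- expand.grid(dy = -1:1, dx = -1:1)
    ij <- expand.grid(i = seq_len(H), j = seq_len(W))
    idx <- vapply(seq_len(9L), function(k) {
      ii <- ij$i + off$dy[k]; jj <- ij$j + off$dx[k]
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      out <- rep(pad, H * W)
      out[ok] <- lin(ii[ok], jj[ok], H)
      out
    }, integer(H * W))
    g <- list(K = 9L, Hout = H, Wout = W, idx = matrix(idx, ncol = 9L))
  } else if (mode == "down") {
    if (H %% 2L || W %% 2L) stop("stride-2 downsampling needs even spatial extent")
    Hout <- H %/% 2L; Wout <- W %/% 2L
    off <- expand.grid(a = 0:1, b = 0:1)
    ij <- expand.grid(i = seq_len(Hout), j = seq_len(Wout))
    idx <- vapply(seq_len(4L), function(k)
      lin(2L * ij$i - 1L + off$a[k], 2L * ij$j - 1L + off$b[k], H),
      integer(Hout * Wout))
    g <- list(K = 4L, Hout = Hout, Wout = Wout,
              idx = matrix(idx, ncol = 4L))
  } else if (mode == "deconv") {
    Hout <- 2L * H; Wout <- 2L * W
    off <- expand.grid(a = 0:1, b = 0:1)
    ij <- expand.grid(i = seq_len(H), j = seq_len(W))
    out <- lapply(seq_len(4L), function(k)
      lin(2L * ij$i - 1L + off$a[k], 2L * ij$j - 1L + off$b[k], Hout))
    idx <- matrix(rep(seq_len(H * W), 4L), ncol = 4L)
    g <- list(K = 4L, Hout = Hout, Wout = Wout, idx = idx, out = out)
  } else if (mode == "head") {
    g <- list(K = 1L, Hout = H, Wout = W,
              idx = matrix(seq_len(H * W), ncol = 1L))
  } else stop("unknown layer mode: ", mode)
  .geom_cache[[key]] <- g
  g
}

#' Construct a grouped capsule layer
#'
#' Creates a (possibly grouped) convolutional capsule layer with its trainable
#' weight bank. Within each of the `g` groups every output type receives one
#' vote per in-group input type and kernel offset; transformation matrices are
#' shared across spatial positions and drawn from a zero-mean Gaussian whose
#' variance is scaled by fan-in (`in_dim * kernel area`).
#'
#' Modes: `"conv"` is a 3x3, stride-1, extent-preserving layer; `"down"` a
#' 2x2, stride-2 downsampling layer; `"deconv"` a 2x2, stride-2 transposed
#' layer that doubles the spatial extent; `"head"` a 1x1 layer (used
#' non-grouped for the segmentation capsule).
#'
#' `in_types`/`in_dim` may be vectors describing several concatenated input
#' blocks (as after a skip connection); each block's types are partitioned
#' into `g` groups and group `i` of the layer consumes block-wise group `i`.
#'
#' @param in_types,in_dim Input capsule type count(s) and dimension(s).
#' @param out_types,out_dim Output capsule type count and dimension.
#' @param g Group count; all type counts must be divisible by `g`.
#' @param mode One of `"conv"`, `"down"`, `"deconv"`, `"head"`.
#' @param nonlinearity `"modified"` (default) or `"squash"`.
#' @param routing_iters Routing iterations (default 3).
#' @param gain Multiplier on the initialisation standard deviation.
#' @return An object of class `"gcn_layer"`.
#' @export
gcn_layer <- function(in_types, in_dim, out_types, out_dim, g = 1L,
                      mode = c("conv", "down", "deconv", "head"),
                      nonlinearity = c("modified", "squash"),
                      routing_iters = 3L, gain = 1) {
  mode <- match.arg(mode)
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(length(in_types) == length(in_dim), all(in_types >= 1),
            all(in_dim >= 1), out_types >= 1, out_dim >= 1, g >= 1)
  if (routing_iters < 1) stop("routing_iters must be >= 1")
  if (any(in_types %% g != 0L))
    stop("every input block's type count must be divisible by g = ", g,
         " (got ", paste(in_types, collapse = ", "), ")")
  if (out_types %% g != 0L)
    stop("output type count ", out_types, " must be divisible by g = ", g)
  K <- switch(mode, conv = 9L, down = 4L, deconv = 4L, head = 1L)
  nb <- length(in_types)
  Tg_out <- out_types %/% g
  out_part <- group_partition(out_types, g)
  groups <- vector("list", g)
  W <- vector("list", g)
  for (i in seq_len(g)) {
    blk <- integer(0); tl <- integer(0)
    for (b in seq_len(nb)) {
      sz <- in_types[b] %/% g
      blk <- c(blk, rep.int(b, sz))
      tl <- c(tl, seq.int((i - 1L) * sz + 1L, i * sz))
    }
    nt <- length(blk)
    dvec <- in_dim[blk]
    # contributor c = (k - 1) * nt + t : offset-major so deconv can route
    # each kernel offset's votes separately
    groups[[i]] <- list(out_idx = out_part[[i]], n_in = nt,
                        block = blk, type = tl, dims = dvec,
                        doff = c(0L, cumsum(dvec)))
    W[[i]] <- lapply(seq_len(K * nt), function(ci) {
      din <- dvec[(ci - 1L) %% nt + 1L]
      sd <- gain / sqrt(din * K)
      matrix(stats::rnorm(out_dim * Tg_out * din, sd = sd),
             nrow = out_dim * Tg_out, ncol = din)
    })
  }
  structure(list(in_types = in_types, in_dim = in_dim, out_types = out_types,
                 out_dim = out_dim, g = g, mode = mode, K = K,
                 nonlinearity = nonlinearity, iters = as.integer(routing_iters),
                 groups = groups, W = W),
            class = "gcn_layer")
}

.nonlin_id <- function(x) if (identical(x, "modified")) 1L else 0L

# normalise input to a list of (d, T, H, W, B) blocks
.as_blocks <- function(x) {
  if (!is.list(x)) x <- list(x)
  lapply(x, function(b) {
    d <- dim(b)
    if (length(d) == 4L) { dim(b) <- c(d, 1L); d <- dim(b) }
    if (length(d) != 5L) stop("capsule input must be a 4-d or 5-d array")
    b
  })
}

.check_blocks <- function(layer, blocks) {
  if (length(blocks) != length(layer$in_types))
    stop("layer expects ", length(layer$in_types), " input block(s), got ",
         length(blocks))
  for (b in seq_along(blocks)) {
    d <- dim(blocks[[b]])
    if (d[1L] != layer$in_dim[b] || d[2L] != layer$in_types[b])
      stop(sprintf(
        "input block %d is %d types x %d dims but the layer expects %d x %d",
        b, d[2L], d[1L], layer$in_types[b], layer$in_dim[b]))
  }
  invisible(TRUE)
}

# stack one group's in-group types into a (Dg, HW+1, B) slab with a zero pad
.group_slab <- function(grp, blocks, HW, B) {
  Dg <- grp$doff[length(grp$doff)]
  slab <- array(0, c(Dg, HW + 1L, B))
  for (t in seq_along(grp$block)) {
    rows <- (grp$doff[t] + 1L):grp$doff[t + 1L]
    v <- blocks[[grp$block[t]]][, grp$type[t], , , , drop = FALSE]
    dim(v) <- c(length(rows), HW, B)
    slab[rows, seq_len(HW), ] <- v
  }
  slab
}

#' Vote capsules of a grouped layer
#'
#' Computes the intermediate vote capsules `u_{t'|t} = W_{t'|t} v_t` a layer
#' materialises for an input field, without routing them. Mainly useful for
#' inspection and testing; [layer_forward()] fuses voting and routing.
#'
#' @param layer A [gcn_layer()].
#' @param x Input array `(dim, n_types, H, W[, batch])` or a list of such
#'   blocks for concatenated inputs.
#' @return A list with one element per group: a vote array of dimensions
#'   `(out_dim, out_types_per_group, positions, contributors)`, contributors
#'   ordered offset-major (all in-group types of kernel offset 1 first).
#' @export
capsule_votes <- function(layer, x) {
  blocks <- .as_blocks(x)
  .check_blocks(layer, blocks)
  d <- dim(blocks[[1L]])
  H <- d[3L]; W <- d[4L]; B <- d[5L]
  geom <- .gcn_geom(H, W, layer$mode)
  Pq <- if (layer$mode == "deconv") H * W else geom$Hout * geom$Wout
  m <- layer$out_dim * (layer$out_types %/% layer$g)
  lapply(seq_len(layer$g), function(i) {
    grp <- layer$groups[[i]]
    slab <- .group_slab(grp, blocks, H * W, B)
    U <- gcn_layer_votes(slab, grp$doff, geom$idx, layer$W[[i]],
                         m, B, H * W, Pq)
    array(U, c(layer$out_dim, layer$out_types %/% layer$g, Pq * B,
               layer$K * grp$n_in))
  })
}

#' Route a vote set into dominant capsules
#'
#' Runs agreement-based iterative routing over a vote array: coupling logits
#' start at zero, couplings are obtained by softmax across the group's output
#' types for each contributor and position, dominant capsules are the
#' coupling-weighted vote sums, and logits are updated with the scalar product
#' of each vote and the nonlinearity-mapped dominant capsule.
#'
#' @param votes Array `(out_dim, out_types, positions, contributors)`, e.g.
#'   one element of [capsule_votes()].
#' @param routing_iters Number of iterations (>= 1).
#' @param nonlinearity `"modified"` or `"squash"`.
#' @return A list with `dominant` (pre-nonlinearity weighted sums,
#'   `(out_dim, out_types, positions)`), `output` (after the nonlinearity)
#'   and `couplings` (`(out_types, positions, contributors)`).
#' @export
capsule_route <- function(votes, routing_iters = 3L,
                          nonlinearity = c("modified", "squash")) {
  nonlinearity <- match.arg(nonlinearity)
  d <- dim(votes)
  if (length(d) != 4L) stop("votes must be a 4-d array")
  if (!all(is.finite(votes))) stop("votes contain non-finite values")
  r <- gcn_route_forward(votes, d[1L], d[2L], d[3L], d[4L],
                         as.integer(routing_iters), .nonlin_id(nonlinearity))
  list(dominant = array(r$S, d[1:3]),
       output = array(r$V, d[1:3]),
       couplings = array(r$Cw, c(d[2L], d[3L], d[4L])))
}

#' Forward pass through a grouped capsule layer
#'
#' Votes, routes and squashes. Each output group is computed from its input
#' group only; outputs are concatenated in group order, so a `g = 1` layer is
#' structurally identical to a non-grouped layer.
#'
#' @inheritParams capsule_votes
#' @param keep Keep the quantities needed for a backward pass.
#' @return Output capsule field array `(out_dim, out_types, H', W'[, batch])`;
#'   with `keep = TRUE`, attribute `"cache"` holds backward state.
#' @export
layer_forward <- function(layer, x, keep = FALSE) {
  blocks <- .as_blocks(x)
  .check_blocks(layer, blocks)
  had_batch <- length(dim(if (is.list(x)) x[[1L]] else x)) == 5L
  d <- dim(blocks[[1L]])
  H <- d[3L]; W <- d[4L]; B <- d[5L]
  HW <- H * W
  geom <- .gcn_geom(H, W, layer$mode)
  do <- layer$out_dim; Tg <- layer$out_types %/% layer$g
  P0 <- geom$Hout * geom$Wout
  out <- array(0, c(do, layer$out_types, P0, B))
  nl <- .nonlin_id(layer$nonlinearity)
  deconv <- layer$mode == "deconv"
  Pq <- if (deconv) HW else P0
  m <- do * Tg
  gcache <- if (keep) vector("list", layer$g)
  slabs <- if (keep) vector("list", layer$g)
  for (i in seq_len(layer$g)) {
    grp <- layer$groups[[i]]
    slab <- .group_slab(grp, blocks, HW, B)
    U <- gcn_layer_votes(slab, grp$doff, geom$idx, layer$W[[i]],
                         m, B, HW, Pq)
    if (keep) slabs[[i]] <- slab
    oi <- grp$out_idx
    nt <- grp$n_in
    if (deconv) {
      dim(U) <- c(m * Pq * B, 4L * nt)
      kc <- if (keep) vector("list", 4L)
      for (k in seq_len(4L)) {
        Uk <- U[, ((k - 1L) * nt + 1L):(k * nt), drop = FALSE]
        r <- gcn_route_forward(Uk, do, Tg, Pq * B, nt, layer$iters, nl)
        out[, oi, geom$out[[k]], ] <- array(r$V, c(do, Tg, Pq, B))
        if (keep) kc[[k]] <- list(S = r$S, Cw = r$Cw)
      }
      if (keep) gcache[[i]] <- kc
    } else {
      r <- gcn_route_forward(U, do, Tg, Pq * B, layer$K * nt, layer$iters, nl)
      out[, oi, , ] <- array(r$V, c(do, Tg, P0, B))
      if (keep) gcache[[i]] <- list(S = r$S, Cw = r$Cw)
    }
  }
  dim(out) <- c(do, layer$out_types, geom$Hout, geom$Wout, B)
  if (!had_batch) dim(out) <- dim(out)[1:4]
  if (keep)
    attr(out, "cache") <- list(slabs = slabs, geom = geom, H = H, W = W, B = B,
                               groups = gcache)
  out
}

# Backward pass. gout: gradient wrt the layer output (same shape).
# Returns list(gx = list of block gradients, gW = weight gradients
# nested as (group, contributor)).
layer_backward <- function(layer, cache, gout) {
  geom <- cache$geom; B <- cache$B; H <- cache$H; W <- cache$W
  do <- layer$out_dim; Tg <- layer$out_types %/% layer$g
  P0 <- geom$Hout * geom$Wout
  HW <- H * W
  dim(gout) <- c(do, layer$out_types, P0, B)
  nl <- .nonlin_id(layer$nonlinearity)
  nb <- length(layer$in_types)
  deconv <- layer$mode == "deconv"
  Pq <- if (deconv) HW else P0
  m <- do * Tg
  gx <- lapply(seq_len(nb), function(b)
    array(0, c(layer$in_dim[b], layer$in_types[b], H, W, B)))
  gW <- vector("list", layer$g)
  for (i in seq_len(layer$g)) {
    grp <- layer$groups[[i]]
    oi <- grp$out_idx
    nt <- grp$n_in
    if (deconv) {
      gU <- array(0, c(m, Pq * B, 4L * nt))
      for (k in seq_len(4L)) {
        gV <- gout[, oi, geom$out[[k]], , drop = FALSE]
        dim(gV) <- c(do, Tg, Pq * B)
        kc <- cache$groups[[i]][[k]]
        gU[, , ((k - 1L) * nt + 1L):(k * nt)] <-
          gcn_route_backward(kc$Cw, kc$S, gV, do, Tg, Pq * B, nt, nl)
      }
    } else {
      gV <- gout[, oi, , , drop = FALSE]
      dim(gV) <- c(do, Tg, P0 * B)
      kc <- cache$groups[[i]]
      gU <- gcn_route_backward(kc$Cw, kc$S, gV, do, Tg, P0 * B,
                               layer$K * nt, nl)
    }
    bk <- gcn_layer_votes_backward(gU, cache$slabs[[i]], grp$doff, geom$idx,
                                   layer$W[[i]], m, B, HW, Pq)
    gW[[i]] <- bk$gW
    gX <- array(bk$gX, c(grp$doff[nt + 1L], HW + 1L, B))
    for (t in seq_len(nt)) {
      rows <- (grp$doff[t] + 1L):grp$doff[t + 1L]
      cur <- gx[[grp$block[t]]][, grp$type[t], , , , drop = FALSE]
      dim(cur) <- c(length(rows), HW, B)
      gx[[grp$block[t]]][, grp$type[t], , , ] <-
        cur + gX[rows, seq_len(HW), , drop = FALSE]
    }
  }
  list(gx = gx, gW = gW)
}
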