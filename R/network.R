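#' Declarative specification of a GroupCapsNet variant
#'
#' Describes a U-shaped grouped capsule network. The stem's
#' `stem_channels`-channel output is reinterpreted as `g` initial capsule
#' types of `stem_channels / g` dimensions. Encoder stage `s` has
#' `g * 2^(s-1)` types of `enc_dim_base * 2^(s-1)` dimensions and
#' `depth[s]` grouped capsule layers, the first of which downsamples by a
#' 2x2 stride-2 kernel; a 256x256 input therefore reaches a 16x16
#' bottleneck. Decoder stages mirror the encoder with layer counts
#' `rev(depth)`: a 2x2 deconvolutional capsule doubles the spatial extent,
#' the matching encoder stage's capsules (the initial capsules for the last
#' stage) are concatenated along the type axis group-by-group, and the
#' stage's grouped layers follow. A non-grouped 1x1 segmentation head
#' produces the final 1-type, `head_dim`-dimension capsule whose length is
#' the foreground probability map.
#'
#' The default dimension bases (6 for the encoder, 10 for the decoder) are
#' the calibrated resolution of the architecture's free dimensions; see the
#' methods vignette for how they were fixed against the published
#' per-variant weight counts.
#'
#' @param g Group count (1, 2, 4 or 8).
#' @param input_size Spatial extent of (square) input slices; must be
#'   divisible by 16.
#' @param enc_dim_base,dec_dim_base Capsule dimension of the first encoder
#'   stage / the two shallowest decoder stages; deeper stages double them.
#' @param depth Encoder layers per stage (default `c(1, 2, 4, 8)`, doubling
#'   stage to stage; the decoder uses the reverse).
#' @param stem_channels Channels of the two stem convolutions; must be
#'   divisible by `g`.
#' @param nonlinearity `"modified"` (default) or `"squash"`, used
#'   network-wide.
#' @param routing_iters Routing iterations (default 3).
#' @param threshold Default segmentation threshold on capsule length.
#' @param head_dim Dimension of the segmentation capsule (default 8).
#' @param init_gain Multiplier on weight-initialisation standard deviations.
#' @return An object of class `"gcn_spec"`.
#' @export
#' @examples
#' spec <- gcn_spec(g = 2, input_size = 64)
#' count_parameters(spec)
gcn_spec <- function(g = 2L, input_size = 256L, enc_dim_base = 6L,
                     dec_dim_base = 10L, depth = c(1L, 2L, 4L, 8L),
                     stem_channels = 16L,
                     nonlinearity = c("modified", "squash"),
                     routing_iters = 3L, threshold = 0.5, head_dim = 8L,
                     init_gain = 1) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(g >= 1, length(depth) == 4L, all(depth >= 1),
            stem_channels >= 1, input_size >= 16)
  if (stem_channels %% g != 0L)
    stop("stem_channels (", stem_channels, ") must be divisible by g (", g, ")")
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16 (four stride-2 stages)")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  spec <- list(g = as.integer(g), input_size = as.integer(input_size),
               enc_dim_base = as.integer(enc_dim_base),
               dec_dim_base = as.integer(dec_dim_base),
               depth = as.integer(depth),
               stem_channels = as.integer(stem_channels),
               nonlinearity = nonlinearity,
               routing_iters = as.integer(routing_iters),
               threshold = threshold, head_dim = as.integer(head_dim),
               init_gain = init_gain)
  class(spec) <- "gcn_spec"
  spec
}

#' @export
print.gcn_spec <- function(x, ...) {
  cat(sprintf("<gcn_spec> GroupCapsNet-G%d, %dx%d input, %s squashing\n",
              x$g, x$input_size, x$input_size,
              if (x$nonlinearity == "modified") "modified" else "classic"))
  cat(sprintf("  encoder: types %s, dims %s, layers %s\n",
              paste(x$g * 2^(0:3), collapse = "/"),
              paste(x$enc_dim_base * 2^(0:3), collapse = "/"),
              paste(x$depth, collapse = "/")))
  cat(sprintf("  trainable weights: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ordered capsule-layer configurations (without weights)
.gcn_layer_plan <- function(spec) {
  g <- spec$g
  T0 <- g; d0 <- spec$stem_channels %/% g
  Te <- g * 2^(0:3); de <- spec$enc_dim_base * 2^(0:3)
  Td <- Te[c(3L, 2L, 1L, 1L)]; dd <- spec$dec_dim_base * c(4L, 2L, 1L, 1L)
  skipT <- c(Te[3L], Te[2L], Te[1L], T0)
  skipD <- c(de[3L], de[2L], de[1L], d0)
  dl <- rev(spec$depth)
  plan <- list()
  pT <- T0; pD <- d0
  for (s in 1:4) {
    plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d_down", s),
      mode = "down", in_types = pT, in_dim = pD,
      out_types = Te[s], out_dim = de[s], g = g)
    if (spec$depth[s] > 1L) for (l in 2:spec$depth[s])
      plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d_conv%d", s, l),
        mode = "conv", in_types = Te[s], in_dim = de[s],
        out_types = Te[s], out_dim = de[s], g = g)
    pT <- Te[s]; pD <- de[s]
  }
  for (m in 1:4) {
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_deconv", m),
      mode = "deconv", in_types = pT, in_dim = pD,
      out_types = Td[m], out_dim = dd[m], g = g)
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_conv1", m),
      mode = "conv", in_types = c(Td[m], skipT[m]),
      in_dim = c(dd[m], skipD[m]),
      out_types = Td[m], out_dim = dd[m], g = g, skip = m)
    if (dl[m] > 1L) for (l in 2:dl[m])
      plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_conv%d", m, l),
        mode = "conv", in_types = Td[m], in_dim = dd[m],
        out_types = Td[m], out_dim = dd[m], g = g)
    pT <- Td[m]; pD <- dd[m]
  }
  plan[[length(plan) + 1L]] <- list(name = "head", mode = "head",
    in_types = pT, in_dim = pD, out_types = 1L, out_dim = spec$head_dim,
    g = 1L)
  plan
}

#' Count the trainable weights of a network variant
#'
#' Exact number of trainable scalars of the network a spec describes: the
#' stem convolution weights and biases plus every capsule transformation
#' matrix (capsule layers carry no biases). Purely analytic and deterministic
#' in the spec; agrees with enumerating the weights of an instantiated model.
#'
#' @param spec A [gcn_spec()].
#' @return The weight count as a double.
#' @export
#' @examples
#' sapply(c(1, 2, 4, 8), function(g) count_parameters(gcn_spec(g = g)))
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "gcn_spec"))
  ch <- spec$stem_channels
  n <- 9 * 1 * ch + ch + 9 * ch * ch + ch
  for (cfg in .gcn_layer_plan(spec)) {
    K <- switch(cfg$mode, conv = 9, down = 4, deconv = 4, head = 1)
    n <- n + sum(K * cfg$out_types * (cfg$in_types / cfg$g) *
                   cfg$out_dim * cfg$in_dim)
  }
  n
}

#' Instantiate a GroupCapsNet
#'
#' Builds stem and capsule layers with freshly initialised weights. Weights
#' are drawn from the current RNG state; call `set.seed()` first for
#' reproducible models.
#'
#' @param spec A [gcn_spec()].
#' @return An object of class `"gcn_model"`.
#' @export
gcn_build <- function(spec) {
  stopifnot(inherits(spec, "gcn_spec"))
  layers <- list()
  for (cfg in .gcn_layer_plan(spec))
    layers[[cfg$name]] <- gcn_layer(cfg$in_types, cfg$in_dim, cfg$out_types,
                                    cfg$out_dim, g = cfg$g, mode = cfg$mode,
                                    nonlinearity = spec$nonlinearity,
                                    routing_iters = spec$routing_iters,
                                    gain = spec$init_gain)
  structure(list(spec = spec, stem = .stem_init(1L, spec$stem_channels,
                                                spec$init_gain),
                 layers = layers, plan = .gcn_layer_plan(spec)),
            class = "gcn_model")
}

# forward pass; x: (H, W, B) image batch in [0,1].
# Returns list(lengths (H,W,B), head (d,1,H,W,B), caches if keep).
gcn_forward <- function(model, x, keep = FALSE) {
  spec <- model$spec
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) { dim(x) <- c(dim(x) %||% length(x), 1L); d <- dim(x) }
  if (d[1L] %% 16L != 0L || d[2L] %% 16L != 0L)
    stop("input extent ", d[1L], "x", d[2L], " is not divisible by 16")
  F0 <- .stem_forward(model$stem, x, spec$g, spec$nonlinearity, keep)
  caches <- if (keep) list(stem = attr(F0, "cache"))
  attr(F0, "cache") <- NULL
  skips <- list(`4` = F0)   # skip source for decoder stage m: enc stage 4-m, 0 -> F0
  cur <- F0
  for (cfg in model$plan) {
    nm <- cfg$name
    input <- if (!is.null(cfg$skip)) {
      src <- skips[[c("e3", "e2", "e1", "4")[cfg$skip]]]
      list(cur, src)
    } else cur
    out <- layer_forward(model$layers[[nm]], input, keep = keep)
    if (keep) { caches[[nm]] <- attr(out, "cache"); attr(out, "cache") <- NULL }
    if (grepl("^enc([123])_", nm)) {
      s <- substr(nm, 4L, 4L)
      # keep the latest output of encoder stages 1..3 as skip sources
      skips[[paste0("e", s)]] <- out
    }
    cur <- out
  }
  lengths <- capsule_lengths(cur)
  dim(lengths) <- dim(cur)[3:5]
  res <- list(lengths = lengths, head = cur)
  if (keep) { res$caches <- caches; res$skips <- skips }
  res
}

# backward from dL/dlengths; returns gradient tree (stem + per-layer gW)
gcn_backward <- function(model, fwd, glengths) {
  spec <- model$spec
  head <- fwd$head
  dh <- dim(head)
  r <- fwd$lengths
  gl <- array(glengths, dim(r))
  # d|v|/dv = v / |v|
  scale <- ifelse(r > 1e-12, gl / pmax(r, 1e-12), 0)
  gcur <- head * rep(scale, each = dh[1L])
  dim(gcur) <- dh
  grads <- list()
  gskips <- list()
  plan <- model$plan
  # name of the final layer of each encoder stage (the skip fork point)
  fork <- character(0)
  for (cfg in plan) if (grepl("^enc[123]_", cfg$name))
    fork[paste0("e", substr(cfg$name, 4L, 4L))] <- cfg$name
  for (li in rev(seq_along(plan))) {
    cfg <- plan[[li]]
    nm <- cfg$name
    # a skip branch forks off this layer's OUTPUT: merge its gradient first
    hit <- names(fork)[fork == nm]
    if (length(hit) && !is.null(gskips[[hit]])) {
      gcur <- gcur + gskips[[hit]]
      gskips[[hit]] <- NULL
    }
    bk <- layer_backward(model$layers[[nm]], fwd$caches[[nm]], gcur)
    grads[[nm]] <- bk$gW
    if (!is.null(cfg$skip)) {
      key <- c("e3", "e2", "e1", "f0")[cfg$skip]
      gskips[[key]] <- if (is.null(gskips[[key]])) bk$gx[[2L]] else
        gskips[[key]] + bk$gx[[2L]]
    }
    gcur <- bk$gx[[1L]]
  }
  if (!is.null(gskips$f0)) gcur <- gcur + gskips$f0
  grads$stem <- .stem_backward(model$stem, fwd$caches$stem, gcur,
                               spec$g, spec$nonlinearity)
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a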