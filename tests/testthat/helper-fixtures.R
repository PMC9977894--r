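# shared tiny fixtures built in code

# random capsule field (dim, types, H, W[, B]) with lengths well below 1
rand_field <- function(d, types, H, W, B = NULL, seed = 1, scale = 0.3) {
  set.seed(seed)
  dims <- c(d, types, H, W, if (!is.null(B)) B)
  array(stats::rnorm(prod(dims), sd = scale / sqrt(d)), dims)
}

# brute-force dense oracle for votes of a 1x1-kernel ("head") layer:
# independent per-pair matrix-vector products
dense_vote_oracle <- function(W_list, x, out_dim, out_types) {
  d <- dim(x)   # (din, tin, H, W)
  votes <- array(0, c(out_dim, out_types, d[3] * d[4], length(W_list) / out_types))
  # W_list: contributor-major list of (out_dim*out_types x din) stacked mats
  for (ci in seq_along(W_list)) {
    for (p in seq_len(d[3] * d[4])) {
      ij <- arrayInd(p, d[3:4])
      v <- x[, ci, ij[1], ij[2]]
      u <- W_list[[ci]] %*% v
      votes[, , p, ci] <- matrix(u, out_dim, out_types)
    }
  }
  votes
}

tiny_spec <- function(g = 2, size = 16, nonlinearity = "modified") {
  gcn_spec(g = g, input_size = size, enc_dim_base = 2, dec_dim_base = 2,
           depth = c(1, 1, 1, 1), stem_channels = if (g == 1) 16 else 16,
           nonlinearity = nonlinearity, head_dim = 4)
}

easy_phantoms <- function(n, size = 64, seed = 1) {
  generate_phantom_dataset(n, phantom_config(size = size, preset = "easy"),
                           seed = seed)$samples
}
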