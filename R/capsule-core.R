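#' Squashing nonlinearity
#'
#' Maps a dominant capsule `v` to an output capsule of the same direction
#' whose Euclidean length is `||v||^2 / (1 + ||v||^2)`, strictly inside
#' `[0, 1)`. A capsule's length encodes the probability that the entity it
#' represents is present; squashing turns an unbounded weighted vote sum into
#' such a probability-scaled vector. The zero vector maps exactly to zero.
#'
#' @param v A numeric vector (one capsule) or an array whose **first**
#'   dimension is the capsule dimension; the map is applied capsule-wise.
#' @return An object of the same shape as `v`.
#' @seealso [modified_squash()] for the cheaper variant.
#' @export
#' @examples
#' squash(c(1, 0))        # length 1 -> length 1/2
#' squash(c(3, 4))        # length 5 -> length 25/26, direction (0.6, 0.8)
squash <- function(v) {
  .capsulewise(v, function(x, r) x * (r / (1 + r * r)))
}

#' Modified squashing nonlinearity
#'
#' Maps a dominant capsule `v` to `v / (1 + ||v||)`: same direction, length
#' `||v|| / (1 + ||v||)` in `[0, 1)`. It agrees with [squash()] exactly at
#' lengths 0 and 1 but needs fewer elementary floating-point operations (no
#' squared-norm ratio), which makes it cheaper in both the forward and the
#' backward pass; see [squash_op_count()].
#'
#' @inheritParams squash
#' @return An object of the same shape as `v`.
#' @export
#' @examples
#' modified_squash(c(0, 1))   # (0, 0.5), identical to squash at unit length
#' modified_squash(c(3, 4))   # v / 6
modified_squash <- function(v) {
  .capsulewise(v, function(x, r) x / (1 + r))
}

# apply f(x, r) capsule-wise, capsules along the first dimension
.capsulewise <- function(v, f) {
  if (is.null(dim(v))) {
    stopifnot(is.numeric(v), all(is.finite(v)))
    return(f(v, sqrt(sum(v * v))))
  }
  d <- dim(v)
  m <- matrix(v, nrow = d[1L])
  r <- sqrt(.colSums(m * m, d[1L], ncol(m)))
  out <- f(m, rep(r, each = d[1L]))
  array(out, dim = d, dimnames = dimnames(v))
}

#' Elementary operation counts of the squashing variants
#'
#' Counts the elementary floating-point operations (multiplies, additions,
#' divisions, square roots) each nonlinearity spends on one capsule of
#' dimension `dim`. Both share the squared-norm accumulation and one square
#' root; the classic squash additionally forms the ratio
#' `||v||^2 / (1 + ||v||^2)` before rescaling, so its total is strictly
#' larger for every `dim`.
#'
#' @param dim Capsule dimension (positive integer).
#' @return A data frame with one row per variant and columns `mul`, `add`,
#'   `div`, `sqrt` and `total`.
#' @export
squash_op_count <- function(dim) {
  stopifnot(dim >= 1)
  # shared: squared norm = dim mul + (dim-1) add; norm = 1 sqrt
  # squash:   1 add (1+r^2), 1 div (r^2/(1+r^2)), 1 div (/r), dim mul (scale v)
  # modified: 1 add (1+r),   dim div (v/(1+r))
  sq  <- c(mul = dim + dim, add = dim - 1 + 1, div = 2, sqrt = 1)
  mod <- c(mul = dim,       add = dim - 1 + 1, div = dim, sqrt = 1)
  out <- rbind(squash = sq, modified_squash = mod)
  out <- as.data.frame(out)
  out$total <- rowSums(out)
  out
}

#' Equal contiguous partition of capsule types into groups
#'
#' Splits type indices `1..n_types` into `g` disjoint, equal-size,
#' contiguous blocks. Grouped layers confine voting and routing within each
#' block, which is what cuts vote and weight counts by a factor of `g`.
#'
#' @param n_types Total number of capsule types; must be divisible by `g`.
#' @param g Number of groups.
#' @return A list of `g` integer vectors (class `"group_partition"`).
#' @export
#' @examples
#' group_partition(8, 2)
group_partition <- function(n_types, g) {
  stopifnot(n_types >= 1, g >= 1)
  if (n_types %% g != 0L)
    stop("n_types (", n_types, ") must be divisible by g (", g, ")")
  size <- n_types %/% g
  blocks <- lapply(seq_len(g), function(i) seq.int((i - 1L) * size + 1L, i * size))
  structure(blocks, class = "group_partition", n_types = n_types, g = g)
}

#' Number of intermediate vote capsules of a capsule layer
#'
#' Returns the exact number of vote capsules materialised by one forward
#' pass of a (possibly grouped) convolutional capsule layer. Each output
#' position of each output type receives one vote from every in-group input
#' type at every kernel offset, so the grouped count is exactly `1/g` of the
#' non-grouped count: `count_votes(..., g) * g == count_votes(..., 1)`.
#'
#' @param in_types,out_types Capsule type counts of the input and output
#'   layer; both must be divisible by `g`.
#' @param kernel_area Number of kernel offsets (e.g. 9 for a 3x3 kernel).
#' @param positions Number of output spatial positions (default 1).
#' @param g Group count.
#' @return Integer-valued double: the vote count.
#' @export
#' @examples
#' count_votes(4, 4, 1)          # 16 all-pairs votes
#' count_votes(4, 4, 1, g = 2)   # 8: two 2x2 blocks
count_votes <- function(in_types, out_types, kernel_area, positions = 1, g = 1) {
  stopifnot(in_types >= 1, out_types >= 1, kernel_area >= 1, positions >= 1, g >= 1)
  if (in_types %% g != 0L || out_types %% g != 0L)
    stop("type counts must be divisible by g")
  out_types * (in_types / g) * kernel_area * positions
}

#' Spatial grid of typed capsule vectors
#'
#' Constructs the activation container used throughout the network: at every
#' spatial position there are `n_types` capsules of dimension `dim`. Values
#' are stored as an array `(dim, n_types, height, width[, batch])`.
#'
#' @param values Numeric array of 4 (single image) or 5 (batched) dimensions
#'   ordered `(dim, n_types, height, width[, batch])`.
#' @return The validated array with class `"capsule_field"`.
#' @export
capsule_field <- function(values) {
  d <- dim(values)
  if (is.null(d) || !(length(d) %in% c(4L, 5L)))
    stop("values must be a (dim, n_types, height, width[, batch]) array")
  if (any(d < 1L)) stop("all extents of a capsule field must be >= 1")
  if (!all(is.finite(values))) stop("capsule field contains non-finite values")
  structure(values, class = "capsule_field")
}

#' @export
print.capsule_field <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<capsule_field> %d types x %d dims, %d x %d spatial%s\n",
              d[2L], d[1L], d[3L], d[4L],
              if (length(d) == 5L) sprintf(", batch %d", d[5L]) else ""))
  invisible(x)
}

#' Capsule lengths of a field
#'
#' @param x A `capsule_field` or a bare `(dim, n_types, ...)` array.
#' @return An array of Euclidean lengths with the capsule dimension dropped.
#' @export
capsule_lengths <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1L])
  array(sqrt(.colSums(m * m, d[1L], ncol(m))), dim = d[-1L])
}
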