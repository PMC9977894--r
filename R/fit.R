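#' Training control parameters
#'
#' Defaults follow the comparison protocol the networks are trained under:
#' binary cross-entropy on the segmentation capsule length, Adam with
#' learning rate 0.001 decayed by a factor of 0.9 every 60 epochs, at most
#' 250 epochs.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Slices per mini-batch.
#' @param lr Initial Adam learning rate.
#' @param lr_decay,decay_every Multiply `lr` by `lr_decay` every
#'   `decay_every` epochs.
#' @param augment Apply random flip/rotation and Gaussian noise
#'   (variance `noise_var`) to training slices each epoch.
#' @param noise_var Variance of augmentation noise (see [augment_slice()]).
#' @param stop_dice If non-`NULL`, stop early once the running training Dice
#'   of an epoch reaches this value.
#' @param verbose Print a line per epoch.
#' @return A list of class `"gcn_control"`.
#' @export
gcn_control <- function(epochs = 250L, batch_size = 8L, lr = 1e-3,
                        lr_decay = 0.9, decay_every = 60L, augment = TRUE,
                        noise_var = 0.01, stop_dice = NULL, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, lr_decay > 0,
            decay_every >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 augment = isTRUE(augment), noise_var = noise_var,
                 stop_dice = stop_dice, verbose = isTRUE(verbose)),
            class = "gcn_control")
}

# parameter / gradient trees ------------------------------------------------

.param_tree <- function(model) {
  list(stem = model$stem[c("W1", "b1", "W2", "b2")],
       layers = lapply(model$layers, `[[`, "W"))
}

.set_params <- function(model, tree) {
  model$stem[c("W1", "b1", "W2", "b2")] <- tree$stem
  for (nm in names(model$layers)) model$layers[[nm]]$W <- tree$layers[[nm]]
  model
}

.grad_tree <- function(model, grads) {
  st <- grads$stem
  list(stem = list(W1 = st$gW1, b1 = st$gb1, W2 = st$gW2, b2 = st$gb2),
       layers = lapply(names(model$layers), function(nm) grads[[nm]]) |>
         stats::setNames(names(model$layers)))
}

# zero-initialised copy of a parameter tree (Adam moment state)
.zero_tree <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, .zero_tree)
}

# Adam step over a parameter tree; updates p and the moment trees in place
# (the caller owns all leaves).
.adam_rec <- function(p, g, m, v, lr, b1, b2, eps, c1, c2) {
  if (is.numeric(p)) {
    if (!is.null(g)) gcn_adam_inplace(p, g, m, v, lr, b1, b2, eps, c1, c2)
    return(invisible(NULL))
  }
  for (i in seq_along(p))
    .adam_rec(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, eps, c1, c2)
  invisible(NULL)
}

# ---------------------------------------------------------------------------

#' Fit a GroupCapsNet to labelled slices
#'
#' Trains a grouped capsule segmentation network with Adam on binary
#' cross-entropy over the segmentation capsule lengths. Fully deterministic
#' given `seed` (single-threaded BLAS assumed for bit reproducibility).
#'
#' @param samples List of `slice_sample` objects (from [slice_volume()],
#'   [generate_phantom_dataset()] or [read_slice_dataset()]); all images
#'   must share the spec's `input_size`.
#' @param spec A [gcn_spec()]; its `input_size` must match the slices.
#' @param control A [gcn_control()].
#' @param seed Integer seed governing initialisation, shuffling and
#'   augmentation.
#' @return An object of class `"gcn"`: the fitted model plus a per-epoch
#'   `history` data frame (`epoch`, `loss`, `dice`, `lr`).
#' @export
#' @examples
#' \donttest{
#' ds <- generate_phantom_dataset(8, phantom_config(64, preset = "easy"), 1)
#' spec <- gcn_spec(g = 2, input_size = 64, enc_dim_base = 2,
#'                  dec_dim_base = 2, depth = c(1, 1, 1, 1))
#' fit <- gcn_fit(ds$samples, spec, gcn_control(epochs = 1, batch_size = 4))
#' print(fit)
#' }
gcn_fit <- function(samples, spec = gcn_spec(), control = gcn_control(),
                    seed = 1L) {
  stopifnot(length(samples) >= 1, inherits(spec, "gcn_spec"),
            inherits(control, "gcn_control"))
  n <- length(samples)
  sz <- dim(samples[[1L]]$image)
  if (any(sz != spec$input_size))
    stop("slices are ", sz[1L], "x", sz[2L], " but the spec expects ",
         spec$input_size)
  model <- .with_seed(seed, gcn_build(spec))
  ptree <- .param_tree(model)
  state <- list(m = .zero_tree(ptree), v = .zero_tree(ptree))
  t0 <- proc.time()[["elapsed"]]
  hist <- list()
  step <- 0L
  for (epoch in seq_len(control$epochs)) {
    lr <- control$lr * control$lr_decay^((epoch - 1L) %/% control$decay_every)
    ord <- .with_seed(seed * 131 + epoch, sample.int(n))
    ep_loss <- 0; ep_n <- 0L
    cc <- confusion_counts(logical(0), logical(0))
    for (b0 in seq(1L, n, by = control$batch_size)) {
      idx <- ord[b0:min(b0 + control$batch_size - 1L, n)]
      B <- length(idx)
      x <- array(0, c(sz[1L], sz[2L], B))
      y <- array(0, c(sz[1L], sz[2L], B))
      for (j in seq_len(B)) {
        s <- samples[[idx[j]]]
        if (control$augment)
          s <- augment_slice(s, seed = (seed * 7919 + epoch * 1009 +
                                          idx[j]) %% 2147483647,
                             noise_var = control$noise_var)
        x[, , j] <- s$image
        y[, , j] <- s$mask
      }
      fwd <- gcn_forward(model, x, keep = TRUE)
      loss <- bce_loss(fwd$lengths, y)
      gl <- .bce_grad(fwd$lengths, y)
      grads <- gcn_backward(model, fwd, gl)
      step <- step + 1L
      gtree <- .grad_tree(model, grads)
      .adam_rec(ptree, gtree, state$m, state$v, lr, 0.9, 0.999, 1e-8,
                1 - 0.9^step, 1 - 0.999^step)
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
      cc <- cc + confusion_counts(fwd$lengths > spec$threshold, y > 0.5)
    }
    dice <- segmentation_metrics(cc)[["dice"]]
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / ep_n,
                                dice = dice, lr = lr)
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f  train dice %.3f", epoch,
                      ep_loss / ep_n, dice))
    if (!is.null(control$stop_dice) && dice >= control$stop_dice) break
  }
  structure(list(model = model, spec = spec, control = control, seed = seed,
                 history = do.call(rbind, hist),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "gcn")
}

#' @export
print.gcn <- function(x, ...) {
  h <- x$history
  cat(sprintf("GroupCapsNet-G%d fit: %d epochs, final loss %.4f, train dice %.3f\n",
              x$spec$g, nrow(h), h$loss[nrow(h)], h$dice[nrow(h)]))
  cat(sprintf("  %s squashing, %s trainable weights, %.1fs elapsed\n",
              if (x$spec$nonlinearity == "modified") "modified" else "classic",
              format(count_parameters(x$spec), big.mark = ","), x$elapsed))
  invisible(x)
}

#' @export
summary.gcn <- function(object, ...) {
  print(object)
  print(object$spec)
  cat("training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.gcn <- function(object, ...) {
  .param_tree(object$model)
}

#' Segment slices with a fitted network
#'
#' @param object A fitted `"gcn"` (or a `"gcn_ensemble"`).
#' @param newdata A matrix (one slice), a `(H, W, B)` array, a
#'   `slice_sample`, or a list of `slice_sample`s.
#' @param type `"mask"` (default) returns thresholded binary masks,
#'   `"length"` the capsule-length probability maps.
#' @param threshold Length threshold; defaults to the spec's. A pixel is
#'   foreground when its length is strictly greater than the threshold.
#' @param batch_size Slices per forward pass.
#' @param ... Unused.
#' @return `(H, W)` matrix or `(H, W, B)` array of masks or lengths.
#' @export
predict.gcn <- function(object, newdata, type = c("mask", "length"),
                        threshold = NULL, batch_size = 16L, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$spec$threshold
  x <- .as_image_batch(newdata)
  d <- dim(x)
  out <- array(0, d)
  for (b0 in seq(1L, d[3L], by = batch_size)) {
    sel <- b0:min(b0 + batch_size - 1L, d[3L])
    fwd <- gcn_forward(object$model, x[, , sel, drop = FALSE], keep = FALSE)
    out[, , sel] <- fwd$lengths
  }
  if (type == "mask") out <- (out > threshold) + 0L
  if (d[3L] == 1L && !(length(dim(newdata)) == 3L)) dim(out) <- d[1:2]
  out
}

.as_image_batch <- function(newdata) {
  if (inherits(newdata, "slice_sample")) newdata <- list(newdata)
  if (is.list(newdata)) {
    sz <- dim(newdata[[1L]]$image)
    x <- array(0, c(sz, length(newdata)))
    for (i in seq_along(newdata)) x[, , i] <- newdata[[i]]$image
    return(x)
  }
  x <- as.array(newdata)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

#' @export
plot.gcn <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "BCE loss", main = "training loss", ...)
  plot(h$epoch, h$dice, type = "b", pch = 16, xlab = "epoch",
       ylab = "Dice", ylim = c(0, 1), main = "training Dice", ...)
  invisible(x)
}

#' Evaluate a fitted network on labelled slices
#'
#' Pools pixel confusion counts over all slices (micro-averaging; set
#' `macro = TRUE` for the per-slice mean instead) and computes Dice, IoU,
#' sensitivity and specificity.
#'
#' @param object A fitted `"gcn"` or `"gcn_ensemble"`.
#' @param samples List of `slice_sample`s with reference masks.
#' @param threshold Length threshold (default: the spec's).
#' @param macro Average metrics per slice instead of pooling counts.
#' @param batch_size Slices per forward pass.
#' @return A list with `metrics` (named vector) and `counts`.
#' @export
evaluate_model <- function(object, samples, threshold = NULL, macro = FALSE,
                           batch_size = 16L) {
  lengths <- predict(object, samples, type = "length",
                     batch_size = batch_size)
  threshold <- threshold %||%
    (if (inherits(object, "gcn_ensemble")) object$fits[[1L]]$spec$threshold
     else object$spec$threshold)
  if (length(dim(lengths)) == 2L) dim(lengths) <- c(dim(lengths), 1L)
  if (macro) {
    ms <- vapply(seq_along(samples), function(i)
      segmentation_metrics(confusion_counts(lengths[, , i] > threshold,
                                            samples[[i]]$mask > 0.5)),
      numeric(4L))
    return(list(metrics = rowMeans(ms), counts = NULL))
  }
  cc <- confusion_counts(logical(0), logical(0))
  for (i in seq_along(samples))
    cc <- cc + confusion_counts(lengths[, , i] > threshold,
                                samples[[i]]$mask > 0.5)
  list(metrics = segmentation_metrics(cc), counts = cc)
}
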