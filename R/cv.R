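# Patient-level k-fold cross validation and model ensembling.

#' Assign volumes to cross-validation folds
#'
#' Folds partition the set of volume (patient) identifiers, never individual
#' slices, so correlated slices from one scan can never appear on both sides
#' of a split.
#'
#' @param ids Character vector of volume identifiers (one per slice is fine;
#'   duplicates are collapsed).
#' @param k Number of folds (default 5).
#' @param seed Seed for the assignment permutation.
#' @return A list of class `"fold_plan"`: `k`, and `assignment` (named
#'   integer vector, fold per volume).
#' @export
#' @examples
#' fold_plan(sprintf("scan%03d", 1:210), k = 5, seed = 1)$k
fold_plan <- function(ids, k = 5L, seed = 1L) {
  vols <- unique(as.character(ids))
  if (length(vols) < k)
    stop("cannot make ", k, " folds from ", length(vols), " volumes")
  perm <- .with_seed(seed, sample(vols))
  # round-robin over a seeded permutation: fold sizes differ by at most one
  assignment <- stats::setNames(rep_len(seq_len(k), length(vols)), perm)[vols]
  structure(list(k = as.integer(k), assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d volumes in %d folds (sizes: %s)\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Train and evaluate one cross-validation fold
#'
#' Trains on all slices whose volume is outside the fold and evaluates
#' (micro-averaged) on the fold's slices.
#'
#' @param samples List of `slice_sample`s.
#' @param plan A [fold_plan()] built from the samples' volume ids.
#' @param fold Fold index in `1..k`.
#' @param spec,control,seed Passed to [gcn_fit()].
#' @return A list with the fitted model (`fit`), `metrics` and `counts`.
#' @export
run_fold <- function(samples, plan, fold, spec = gcn_spec(),
                     control = gcn_control(), seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1, fold <= plan$k)
  ids <- vapply(samples, `[[`, "", "id")
  test <- plan$assignment[ids] == fold
  if (!any(test) || all(test))
    stop("fold ", fold, " has an empty train or test side")
  fit <- gcn_fit(samples[!test], spec, control, seed = seed + fold)
  ev <- evaluate_model(fit, samples[test])
  list(fit = fit, metrics = ev$metrics, counts = ev$counts,
       n_train = sum(!test), n_test = sum(test))
}

#' k-fold cross validation of a GroupCapsNet
#'
#' @inheritParams run_fold
#' @param k Number of folds.
#' @param out_dir If non-`NULL`, write per-fold and pooled metric CSVs there.
#' @return A list of class `"gcn_cv"`: `folds` (per-fold results),
#'   `per_fold` (metric data frame) and `pooled` (metrics from counts pooled
#'   over all folds).
#' @export
gcn_cv <- function(samples, k = 5L, spec = gcn_spec(),
                   control = gcn_control(), seed = 1L, out_dir = NULL) {
  plan <- fold_plan(vapply(samples, `[[`, "", "id"), k, seed)
  folds <- lapply(seq_len(k), function(f)
    run_fold(samples, plan, f, spec, control, seed))
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f)
    data.frame(fold = f, t(folds[[f]]$metrics),
               n_train = folds[[f]]$n_train, n_test = folds[[f]]$n_test)))
  pooled_counts <- Reduce(`+`, lapply(folds, `[[`, "counts"))
  pooled <- segmentation_metrics(pooled_counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_fold, file.path(out_dir, "metrics_per_fold.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(t(pooled)),
                     file.path(out_dir, "metrics_pooled.csv"),
                     row.names = FALSE)
  }
  structure(list(folds = folds, per_fold = per_fold, pooled = pooled,
                 plan = plan), class = "gcn_cv")
}

#' @export
print.gcn_cv <- function(x, ...) {
  cat(sprintf("<gcn_cv> %d folds; pooled dice %.4f, iou %.4f\n",
              x$plan$k, x$pooled[["dice"]], x$pooled[["iou"]]))
  print(x$per_fold, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Ensemble of fitted networks
#'
#' Combines two or more fits of the same spec; predictions average the
#' per-pixel capsule lengths across members before thresholding.
#'
#' @param fits List of `"gcn"` objects with identical specs.
#' @return An object of class `"gcn_ensemble"`.
#' @export
gcn_ensemble <- function(fits) {
  stopifnot(length(fits) >= 2)
  ref <- fits[[1L]]$spec
  for (f in fits[-1L]) {
    s <- f$spec
    same <- identical(s[setdiff(names(s), "init_gain")],
                      ref[setdiff(names(ref), "init_gain")])
    if (!same) stop("all ensemble members must share the same spec")
  }
  structure(list(fits = fits), class = "gcn_ensemble")
}

#' @rdname gcn_ensemble
#' @inheritParams predict.gcn
#' @export
predict.gcn_ensemble <- function(object, newdata, type = c("mask", "length"),
                                 threshold = NULL, batch_size = 16L, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$fits[[1L]]$spec$threshold
  preds <- lapply(object$fits, predict, newdata = newdata, type = "length",
                  batch_size = batch_size)
  out <- Reduce(`+`, preds) / length(preds)
  if (type == "mask") out <- (out > threshold) + 0L
  out
}

#' @export
print.gcn_ensemble <- function(x, ...) {
  cat(sprintf("<gcn_ensemble> %d GroupCapsNet-G%d models\n",
              length(x$fits), x$fits[[1L]]$spec$g))
  invisible(x)
}
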