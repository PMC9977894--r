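# CT volume reading, Hounsfield windowing, z-axis slicing with resizing,
# augmentation, and the PNG + CSV slice-dataset layout shared with the
# phantom generator.

#' Read a CT volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file with Hounsfield-unit voxels.
#' @return A 3-d array `(H, W, Z)` with attribute `"pixdim"` carrying voxel
#'   spacing (not used by the model, carried for provenance).
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  if (length(dim(v)) != 3L)
    stop("expected a 3-d CT volume, got ", length(dim(v)), " dimensions")
  if (!all(is.finite(v))) stop("CT volume contains non-finite values")
  attr(v, "pixdim") <- RNifti::pixdim(img)
  v
}

#' Window and normalise Hounsfield units
#'
#' Clips CT values to `[lower, upper]` (default 0--90 HU, the soft-tissue
#' range containing brain parenchyma and acute hemorrhage) and rescales
#' linearly to `[0, 1]`.
#'
#' @param volume Numeric array of Hounsfield units.
#' @param lower,upper Window bounds in HU.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
#' @examples
#' window_normalize(c(-5, 45, 120))   # 0, 0.5, 1
window_normalize <- function(volume, lower = 0, upper = 90) {
  stopifnot(upper > lower, all(is.finite(volume)))
  out <- (pmin(pmax(volume, lower), upper) - lower) / (upper - lower)
  attributes(out) <- attributes(volume)
  out
}

.resize2d <- function(m, size, nearest = FALSE) {
  if (all(dim(m) == size)) return(m)
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("resizing slices requires the EBImage package")
  out <- EBImage::resize(m, w = size, h = size,
                         filter = if (nearest) "none" else "bilinear")
  as.matrix(out)
}

#' Slice a CT volume into training samples
#'
#' Splits a windowed volume and its mask volume along the z axis into
#' per-slice samples, resizing images by bilinear and masks by
#' nearest-neighbour interpolation (so masks stay binary).
#'
#' @param volume Normalised CT array `(H, W, Z)` with values in `[0, 1]`.
#' @param masks Binary mask array of identical shape.
#' @param size Output extent (default 256).
#' @param id Volume identifier recorded in each sample.
#' @param keep_empty Keep slices whose mask is empty (default `TRUE`).
#' @return A list of `slice_sample` objects.
#' @export
slice_volume <- function(volume, masks, size = 256L, id = "volume",
                         keep_empty = TRUE) {
  dv <- dim(volume); dm <- dim(masks)
  if (!identical(dv, dm))
    stop("volume is ", paste(dv, collapse = "x"), " but masks are ",
         paste(dm, collapse = "x"))
  if (min(volume) < 0 || max(volume) > 1)
    stop("volume must be windowed to [0, 1] first; see window_normalize()")
  out <- list()
  for (z in seq_len(dv[3L])) {
    mk <- masks[, , z]
    if (!keep_empty && !any(mk > 0)) next
    s <- structure(list(
      image = .resize2d(volume[, , z], size),
      mask = matrix(as.integer(.resize2d(mk, size, nearest = TRUE) > 0.5),
                    size, size),
      id = id, z = z), class = "slice_sample")
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Augment a slice sample
#'
#' Applies a random horizontal/vertical flip and rotation identically to
#' image and mask, then adds zero-mean Gaussian noise to the image only and
#' re-clips it to `[0, 1]`. Deterministic given `seed`.
#'
#' @param sample A `slice_sample`.
#' @param seed Integer seed.
#' @param noise_var Variance of the additive Gaussian noise (default 0.01,
#'   i.e. standard deviation 0.1 on the `[0, 1]` intensity scale; pass the
#'   variance, not the standard deviation).
#' @param rotation `"right-angle"` (lossless multiples of 90 degrees,
#'   default) or `"any"` (arbitrary angle, resampled; requires EBImage).
#' @return The augmented `slice_sample`.
#' @export
augment_slice <- function(sample, seed, noise_var = 0.01,
                          rotation = c("right-angle", "any")) {
  rotation <- match.arg(rotation)
  stopifnot(inherits(sample, "slice_sample"), noise_var >= 0)
  .with_seed(seed, {
    img <- sample$image; mk <- sample$mask
    if (stats::runif(1) < 0.5) { img <- img[nrow(img):1, ]; mk <- mk[nrow(mk):1, ] }
    if (stats::runif(1) < 0.5) { img <- img[, ncol(img):1]; mk <- mk[, ncol(mk):1] }
    if (rotation == "right-angle") {
      k <- sample.int(4L, 1L) - 1L
      rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
      if (k > 0L) for (i in seq_len(k)) { img <- rot90(img); mk <- rot90(mk) }
    } else {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("arbitrary-angle rotation requires the EBImage package")
      ang <- stats::runif(1, 0, 360)
      dm <- dim(img)
      img <- as.matrix(EBImage::rotate(img, ang, output.dim = dm, bg.col = 0))
      mk <- as.matrix(EBImage::rotate(mk, ang, output.dim = dm, filter = "none",
                                      bg.col = 0))
      mk <- matrix(as.integer(mk > 0.5), dm[1L], dm[2L])
    }
    if (noise_var > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = sqrt(noise_var)),
                          nrow(img))
      img <- pmin(pmax(img, 0), 1)
    }
    out <- sample
    out$image <- img
    out$mask <- mk
    out
  })
}

#' @export
print.slice_sample <- function(x, ...) {
  cat(sprintf("<slice_sample> %s z=%d, %dx%d, %.1f%% foreground\n",
              x$id, x$z, nrow(x$image), ncol(x$image), 100 * mean(x$mask)))
  invisible(x)
}

.sample_stub <- function(s) sprintf("%s_z%03d", s$id, s$z)

#' Write a slice dataset as PNGs with a CSV manifest
#'
#' Each sample becomes `<id>_z<z>_img.png` (8-bit grayscale) and
#' `<id>_z<z>_mask.png`; `manifest.csv` records id, z and fold. The layout
#' is shared by real CT slices and phantoms.
#'
#' @param samples List of `slice_sample` objects.
#' @param dir Output directory (created if needed).
#' @param manifest Optional manifest data frame; built from the samples if
#'   omitted.
#' @return Invisibly, the manifest.
#' @export
write_slice_dataset <- function(samples, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(manifest))
    manifest <- data.frame(id = vapply(samples, `[[`, "", "id"),
                           z = vapply(samples, `[[`, 0L, "z"),
                           fold = vapply(samples, function(s)
                             s$fold %||% NA_integer_, NA_integer_))
  for (s in samples) {
    stub <- .sample_stub(s)
    png::writePNG(s$image, file.path(dir, paste0(stub, "_img.png")))
    png::writePNG(s$mask + 0, file.path(dir, paste0(stub, "_mask.png")))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a slice dataset written by [write_slice_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return List of `slice_sample` objects (with `fold` where recorded).
#' @export
read_slice_dataset <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(mf)), function(i) {
    stub <- sprintf("%s_z%03d", mf$id[i], mf$z[i])
    img <- png::readPNG(file.path(dir, paste0(stub, "_img.png")))
    mk <- png::readPNG(file.path(dir, paste0(stub, "_mask.png")))
    structure(list(image = img, mask = matrix(as.integer(mk > 0.5), nrow(mk)),
                   id = mf$id[i], z = mf$z[i],
                   fold = if ("fold" %in% names(mf)) mf$fold[i] else NA_integer_),
              class = "slice_sample")
  })
}
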