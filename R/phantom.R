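# Synthetic head-CT phantoms: an elliptical skull ring, textured parenchyma,
# and hyperdense lesions with irregular (radially perturbed ellipse)
# boundaries. Masks are the exact lesion support, so there is no label noise.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Configuration of the CT phantom generator
#'
#' Intensities are in windowed units: the 0--90 HU window maps acute
#' hemorrhage (roughly 60--90 HU) to 0.65--1.0 and brain parenchyma
#' (roughly 25--40 HU) to 0.28--0.45, which is what the default bands
#' emulate; the skull (far above 90 HU) clips to ~1.
#'
#' @param size Image extent in pixels (square).
#' @param n_lesions Integer range `c(min, max)` of lesion count per slice.
#' @param lesion_area_frac Range of the total lesion area as a fraction of
#'   the image area.
#' @param parenchyma_band,hemorrhage_band Intensity bands in `[0, 1]`; the
#'   hemorrhage band must lie strictly above the parenchyma band.
#' @param irregularity Amplitude of the radial boundary perturbation
#'   (0 = exact ellipses).
#' @param noise_sd Standard deviation of the additive Gaussian image noise.
#' @param preset `"standard"` or `"easy"`; `"easy"` gives fewer, smoother,
#'   higher-contrast lesions with less noise (useful for quick training
#'   experiments with known headroom).
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(size = 256L,
                           n_lesions = c(1L, 3L),
                           lesion_area_frac = c(0.01, 0.06),
                           parenchyma_band = c(0.28, 0.45),
                           hemorrhage_band = c(0.65, 1.0),
                           irregularity = 0.15,
                           noise_sd = 0.03,
                           preset = c("standard", "easy")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    if (missing(n_lesions)) n_lesions <- c(1L, 2L)
    if (missing(lesion_area_frac)) lesion_area_frac <- c(0.02, 0.08)
    if (missing(hemorrhage_band)) hemorrhage_band <- c(0.70, 0.95)
    if (missing(irregularity)) irregularity <- 0.08
    if (missing(noise_sd)) noise_sd <- 0.02
  }
  stopifnot(size >= 32, length(n_lesions) == 2L, n_lesions[1L] >= 0,
            n_lesions[2L] >= n_lesions[1L],
            length(lesion_area_frac) == 2L,
            all(lesion_area_frac > 0), all(lesion_area_frac < 1),
            all(parenchyma_band >= 0), all(parenchyma_band <= 1),
            all(hemorrhage_band >= 0), all(hemorrhage_band <= 1),
            irregularity >= 0, noise_sd >= 0)
  if (hemorrhage_band[1L] <= parenchyma_band[2L])
    stop("hemorrhage band must lie strictly above the parenchyma band ",
         "(hemorrhage is hyperdense on non-contrast CT)")
  structure(list(size = as.integer(size), n_lesions = as.integer(n_lesions),
                 lesion_area_frac = lesion_area_frac,
                 parenchyma_band = parenchyma_band,
                 hemorrhage_band = hemorrhage_band,
                 irregularity = irregularity, noise_sd = noise_sd,
                 preset = preset),
            class = "phantom_config")
}

# bilinear upscale of a small matrix to n x n (for smooth texture fields)
.upscale <- function(m, n) {
  k <- nrow(m)
  if (k == n) return(m)
  src <- seq(1, k, length.out = n)
  i0 <- pmin(floor(src), k - 1L); fi <- src - i0
  row <- m[i0, , drop = FALSE] * (1 - fi) + m[i0 + 1L, , drop = FALSE] * fi
  col <- t(row)
  j0 <- i0; fj <- fi
  t(col[j0, , drop = FALSE] * (1 - fj) + col[j0 + 1L, , drop = FALSE] * fj)
}

#' Generate one phantom slice with its ground-truth lesion mask
#'
#' Deterministic given `seed`. The image is snapped to the 8-bit grid so
#' that PNG round trips are exact; the mask is exactly the generative lesion
#' support.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for this slice.
#' @return A list of class `"slice_sample"` with elements `image`
#'   (`size x size` matrix in `[0, 1]`), `mask` (binary matrix), `id`, `z`.
#' @export
#' @examples
#' s <- generate_phantom(phantom_config(size = 64), seed = 1)
#' mean(s$mask)
generate_phantom <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  .with_seed(seed, {
    n <- config$size
    xs <- matrix(seq_len(n), n, n)
    ys <- t(xs)
    cx <- n / 2 + stats::runif(1, -0.03, 0.03) * n
    cy <- n / 2 + stats::runif(1, -0.03, 0.03) * n
    a <- stats::runif(1, 0.40, 0.46) * n
    b <- stats::runif(1, 0.40, 0.46) * n
    th <- stats::runif(1, 0.03, 0.05) * n
    e_out <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
    e_in <- ((xs - cx) / (a - th))^2 + ((ys - cy) / (b - th))^2
    skull <- e_out <= 1 & e_in > 1
    brain <- e_in <= 1
    pb <- config$parenchyma_band
    tex <- .upscale(matrix(stats::rnorm(64), 8, 8), n)
    tex <- tex / max(abs(tex), 1e-9)
    img <- matrix(0, n, n)
    base <- mean(pb) + tex * diff(pb) / 2
    img[brain] <- pmin(pmax(base[brain], pb[1L]), pb[2L])
    img[skull] <- stats::runif(1, 0.95, 1.0)

    n_les <- if (config$n_lesions[2L] == 0L) 0L else
      sample(config$n_lesions[1L]:config$n_lesions[2L], 1L)
    mask <- matrix(0L, n, n)
    if (n_les > 0L) {
      total_frac <- stats::runif(1, config$lesion_area_frac[1L],
                                 config$lesion_area_frac[2L])
      w <- stats::runif(n_les, 0.5, 1); w <- w / sum(w)
      hb <- config$hemorrhage_band
      for (li in seq_len(n_les)) {
        area <- total_frac * w[li] * n * n
        placed <- FALSE
        for (try in seq_len(60L)) {
          r0 <- sqrt(area / pi)
          q <- stats::runif(1, 0.6, 1.6)
          ra <- r0 * sqrt(q); rb <- r0 / sqrt(q)
          phi <- stats::runif(1, 0, pi)
          rad <- stats::runif(1, 0, 0.55)
          ang <- stats::runif(1, 0, 2 * pi)
          lx <- cx + rad * (a - th) * cos(ang)
          ly <- cy + rad * (b - th) * sin(ang)
          dx <- xs - lx; dy <- ys - ly
          xr <- (dx * cos(phi) + dy * sin(phi)) / ra
          yr <- (-dx * sin(phi) + dy * cos(phi)) / rb
          rho <- sqrt(xr^2 + yr^2)
          theta <- atan2(yr, xr)
          pert <- 0
          for (k in 2:5)
            pert <- pert + stats::runif(1, 0, config$irregularity) / (k / 2) *
              cos(k * theta + stats::runif(1, 0, 2 * pi))
          support <- rho <= 1 + pert
          # lesion must sit inside the brain and avoid other lesions
          if (any(support) && all(e_in[support] <= 0.92) &&
              !any(mask[support] > 0L)) {
            lesion_mean <- stats::runif(1, hb[1L] + 0.05 * diff(hb),
                                        hb[2L] - 0.05 * diff(hb))
            val <- lesion_mean + stats::rnorm(sum(support), sd = 0.02)
            img[support] <- pmin(pmax(val, hb[1L]), hb[2L])
            mask[support] <- 1L
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("phantom generation failed: requested lesion area fraction ",
               signif(total_frac, 3), " cannot be placed inside the brain")
      }
    }
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, sd = config$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255   # PNG-representable, so file round trips are exact
    structure(list(image = img, mask = mask,
                   id = sprintf("phantom%09d", as.integer(seed %% 1e9)),
                   z = 1L),
              class = "slice_sample")
  })
}

#' Generate a reproducible phantom dataset
#'
#' Per-slice seeds are derived from the master seed, so the same
#' `(config, n, seed)` always produces bit-identical slices. Optionally
#' writes the dataset as PNG images + masks with a CSV manifest, the same
#' layout [write_slice_dataset()] uses for real CT slices.
#'
#' @param n Number of slices.
#' @param config A [phantom_config()].
#' @param seed Master seed.
#' @param dir If non-`NULL`, directory to write PNGs and `manifest.csv` to.
#' @param k_folds If non-`NULL`, assign slices to this many
#'   cross-validation folds (balanced, seeded permutation).
#' @return Invisibly, a list with `samples` (list of `slice_sample`) and
#'   `manifest` (data frame with `id`, `z`, `fold`, `seed`).
#' @export
generate_phantom_dataset <- function(n, config = phantom_config(), seed = 1L,
                                     dir = NULL, k_folds = NULL) {
  stopifnot(n >= 1)
  seeds <- (as.numeric(seed) * 1000 + seq_len(n)) %% 2147483647
  samples <- lapply(seeds, function(s) generate_phantom(config, s))
  for (i in seq_len(n)) samples[[i]]$id <- sprintf("phantom%05d", i)
  fold <- rep(NA_integer_, n)
  if (!is.null(k_folds))
    fold <- .with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  manifest <- data.frame(id = vapply(samples, `[[`, "", "id"),
                         z = 1L, fold = fold, seed = seeds)
  for (i in seq_len(n)) samples[[i]]$fold <- fold[i]
  if (!is.null(dir)) write_slice_dataset(samples, dir, manifest)
  invisible(list(samples = samples, manifest = manifest))
}
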