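#' Default ground-truth coefficients for simulation
#'
#' The cubic coefficient vector used as the generator's ground truth,
#' `(-4.0180, 12.5609, -11.1670, 3.5632)`: a published best-fitting cubic
#' for cantaloupe-slice microwave drying. Over shrinkage in about
#' [0.55, 1] it yields moisture ratios in [0, 1]; below S of roughly 0.52
#' the cubic goes negative, which is why the generator's default shrinkage
#' range stops at 0.55.
#'
#' @return Named numeric vector of length 4.
#' @export
default_true_gamma <- function() {
  c(r0 = -4.0180, r1 = 12.5609, r2 = -11.1670, r3 = 3.5632)
}

#' Monotone shrinkage trajectory
#'
#' `S(k) = 1 - (1 - s_min) * (k / kmax)^beta` for k = 1..kmax: strictly
#' decreasing from just below 1 to exactly `s_min`, emulating the monotone
#' loss of projected slice area during drying. `beta = 1` gives a linear
#' decline; `beta > 1` starts slow and accelerates, `beta < 1` the
#' opposite.
#'
#' @param kmax Number of samples (>= 2).
#' @param s_min Final shrinkage in (0, 1).
#' @param beta Positive shape parameter.
#' @return Numeric vector of length `kmax`, strictly decreasing, in (0, 1].
#' @export
#' @examples
#' shrinkage_trajectory(9, s_min = 0.55, beta = 1) # 0.95, 0.90, ..., 0.55
shrinkage_trajectory <- function(kmax, s_min = 0.55, beta = 1) {
  stopifnot(
    "kmax must be at least 2" = kmax >= 2,
    "s_min must lie in (0, 1)" = s_min > 0 && s_min < 1,
    "beta must be positive" = beta > 0
  )
  1 - (1 - s_min) * (seq_len(kmax) / kmax)^beta
}

#' Simulate a drying dataset
#'
#' Generates moisture ratios from a ground-truth polynomial evaluated on a
#' monotone shrinkage trajectory plus additive white Gaussian noise —
#' exactly the statistical structure the estimators assume. The noise is
#' not clipped, so moisture ratios may stray slightly outside [0, 1], as
#' real normalised measurements do.
#'
#' The defaults (cubic truth, kmax = 100, sigma = 0.02, shrinkage from
#' 0.95 down to 0.55) match the study conditions the package's tests and
#' acceptance checks run under; sigma = 0.02 is of the same magnitude as
#' the best published fit RMSE for this system (0.0239).
#'
#' @param kmax Number of samples.
#' @param true_gamma Ground-truth coefficient vector (constant term
#'   first); default [default_true_gamma()].
#' @param sigma Noise standard deviation (>= 0).
#' @param s_min,beta Shrinkage-trajectory parameters, see
#'   [shrinkage_trajectory()].
#' @param delta Sampling period in minutes (metadata; also fills the
#'   `time_min` column as `k * delta`).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A drying-data tibble with attributes `true_gamma`, `sigma`, and
#'   `noise` (the realised noise vector), so recovery tests can compare
#'   against the hidden truth.
#' @export
#' @examples
#' d <- simulate_drying(kmax = 50, sigma = 0.02, seed = 7)
#' mlf(attr(d, "true_gamma"), d) # about sigma^2
simulate_drying <- function(kmax = 100, true_gamma = default_true_gamma(),
                            sigma = 0.02, s_min = 0.55, beta = 1,
                            delta = 0.5, seed = NULL) {
  stopifnot(
    "sigma must be non-negative" = sigma >= 0,
    "kmax must be at least length(true_gamma) + 1" =
      kmax >= length(true_gamma) + 1
  )
  if (!is.null(seed)) set.seed(seed)
  true_gamma <- as.numeric(true_gamma)
  s <- shrinkage_trajectory(kmax, s_min = s_min, beta = beta)
  model <- polynomial_model(true_gamma)
  noise <- stats::rnorm(kmax, 0, sigma)
  out <- drying_data(
    shrinkage = s,
    moisture_ratio = predict(model, s) + noise,
    time_min = seq_len(kmax) * delta,
    delta = delta
  )
  attr(out, "true_gamma") <- true_gamma
  attr(out, "sigma") <- sigma
  attr(out, "noise") <- noise
  out
}

# raster of a filled disk: TRUE inside radius r around (cx, cy); pixel
# centres at integer coordinates
disk_raster <- function(size, cx, cy, r) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Generate a synthetic shrinking-disk image stack
#'
#' Produces one grayscale frame per sample: a bright disk (the slice) on a
#' dark background whose radius follows `r(k) = r0 * sqrt(S(k))`, so the
#' true pixel-area ratio equals the commanded shrinkage. Frames are
#' optionally decorated with small bright specks outside the disk and
#' small dark holes inside it, which is what the particle-filtering and
#' hole-filling stages of the measurement pipeline exist to remove, plus
#' additive Gaussian pixel noise.
#'
#' @param kmax Number of frames.
#' @param size Square raster side in pixels.
#' @param r0 Initial disk radius in pixels; the final radius
#'   `r0 * sqrt(s_min)` must be at least 10 px.
#' @param s_min,beta Shrinkage-trajectory parameters.
#' @param fg,bg Foreground and background intensities in [0, 1].
#' @param n_specks,n_holes Decoration counts per frame.
#' @param speck_radius,hole_radius Decoration radii in pixels.
#' @param noise_sd Pixel-noise standard deviation (intensities are clipped
#'   back to [0, 1]).
#' @param seed Integer seed, or `NULL`.
#' @return List with `frames` (list of `size` x `size` matrices in
#'   [0, 1]) and `truth` (tibble `k`, `s_true`, `radius_px`,
#'   `area_ratio`). `s_true` is the commanded trajectory value (near 1 at
#'   the first frame but not exactly 1); `area_ratio` is the commanded
#'   area relative to the first frame, which is what [process_frames()]
#'   measures.
#' @export
generate_image_stack <- function(kmax = 8, size = 192, r0 = 70,
                                 s_min = 0.55, beta = 1,
                                 fg = 0.86, bg = 0.12,
                                 n_specks = 4, n_holes = 2,
                                 speck_radius = 2, hole_radius = 3,
                                 noise_sd = 0, seed = NULL) {
  s <- shrinkage_trajectory(kmax, s_min = s_min, beta = beta)
  radii <- r0 * sqrt(s)
  if (min(radii) < 10) {
    stop("final disk radius ", round(min(radii), 1),
         " px is below 10 px; increase r0 or s_min", call. = FALSE)
  }
  if (r0 >= size / 2 - 2) {
    stop("r0 must fit inside the raster with a margin", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  centre <- (size + 1) / 2
  frames <- purrr::map(seq_len(kmax), function(k) {
    disk <- disk_raster(size, centre, centre, radii[k])
    img <- matrix(bg, size, size)
    img[disk] <- fg
    if (n_holes > 0 && radii[k] > 4 * hole_radius) {
      for (i in seq_len(n_holes)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, radii[k] - 2 * hole_radius - 2)
        hole <- disk_raster(size, centre + rad * cos(ang),
                            centre + rad * sin(ang), hole_radius)
        img[hole] <- bg
      }
    }
    if (n_specks > 0) {
      placed <- 0
      while (placed < n_specks) {
        cx <- stats::runif(1, speck_radius + 1, size - speck_radius - 1)
        cy <- stats::runif(1, speck_radius + 1, size - speck_radius - 1)
        # keep specks clear of the slice so they stay separate components
        if (sqrt((cx - centre)^2 + (cy - centre)^2) >
            radii[k] + 3 * speck_radius) {
          img[disk_raster(size, cx, cy, speck_radius)] <- fg
          placed <- placed + 1
        }
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
      img <- pmin(pmax(img, 0), 1)
    }
    img
  })
  list(
    frames = frames,
    truth = tibble::tibble(k = seq_len(kmax), s_true = s,
                           radius_px = radii, area_ratio = s / s[1])
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits everything needed to exercise the whole toolchain from files:
#' `data.csv` (the drying dataset), `truth.json` (ground-truth
#' coefficients, sigma, seed — kept out of `data.csv` so estimator code
#' cannot accidentally read it), `frames/frame_001.png`, ..., and
#' `manifest.csv` mapping frame index to filename and commanded shrinkage.
#'
#' @param dir Output directory (created if needed).
#' @param kmax Number of samples/frames.
#' @param sigma Noise standard deviation of the tabular data.
#' @param s_min,beta Shrinkage-trajectory parameters shared by the table
#'   and the images.
#' @param seed Integer seed; recorded in the manifest so the bundle can be
#'   regenerated identically.
#' @param images Whether to write the image stack (default TRUE).
#' @param ... Further arguments passed to [generate_image_stack()].
#' @return Invisibly, a list with the dataset, the image truth table and
#'   the file paths.
#' @export
write_fixture_bundle <- function(dir, kmax = 20, sigma = 0.02,
                                 s_min = 0.55, beta = 1, seed = 1,
                                 images = TRUE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- simulate_drying(kmax = kmax, sigma = sigma, s_min = s_min,
                             beta = beta, seed = seed)
  data_path <- file.path(dir, "data.csv")
  write_drying_csv(dataset, data_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(true_gamma = attr(dataset, "true_gamma"), sigma = sigma,
         s_min = s_min, beta = beta, kmax = kmax, seed = seed),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  frame_files <- character(0)
  truth <- NULL
  if (images) {
    stack <- generate_image_stack(kmax = kmax, s_min = s_min, beta = beta,
                                  seed = seed, ...)
    truth <- stack$truth
    frame_dir <- file.path(dir, "frames")
    dir.create(frame_dir, showWarnings = FALSE)
    frame_files <- sprintf("frames/frame_%03d.png", seq_len(kmax))
    purrr::walk(seq_len(kmax), function(k) {
      png::writePNG(stack$frames[[k]], file.path(dir, frame_files[k]))
    })
    manifest <- tibble::tibble(
      k = seq_len(kmax), filename = frame_files,
      s_commanded = stack$truth$s_true, seed = seed
    )
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(dataset = dataset, truth = truth,
                 paths = list(data = data_path, truth = truth_path,
                              frames = frame_files)))
}
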