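SHAPE_KINDS <- c("cross", "disc", "disc_pair", "arrow", "line",
                 "trapezoid", "random_blob")

#' Generate a synthetic absorption anomaly
#'
#' Rasterizes a hand-drawn-like shape (plus sign, disc, disc pair, arrow,
#' diagonal line, trapezoid or random blob) at a random position, scale and
#' rotation inside the field of view. Every pixel of the shape's support gets
#' a single contrast value drawn uniformly from [0.25, 1]; the per-pixel
#' anomaly absorption is `0.5 + contrast * 0.22` mm^-1, spanning the
#' 0.5--0.72 mm^-1 contrast range of the emulated phantoms.
#'
#' @param seed Integer seed; the same seed reproduces the map bitwise.
#' @param shape_kind One of `"cross"`, `"disc"`, `"disc_pair"`, `"arrow"`,
#'   `"line"`, `"trapezoid"`, `"random_blob"`, or `"random"` to draw one.
#' @param grid Object grid as `c(rows, cols)`; at least 16 x 16.
#' @return An object of class `digp_anomaly`: list with `contrast` (grid
#'   matrix in [0, 1]), `mu_a_map` (mm^-1), `shape_kind`, `contrast_value`,
#'   `seed`.
#' @export
generate_anomaly <- function(seed, shape_kind = "random", grid = c(64, 64)) {
  grid <- as.integer(grid)
  if (any(grid < 16L)) stop("`grid` must be at least 16 x 16", call. = FALSE)
  if (!shape_kind %in% c(SHAPE_KINDS, "random")) {
    stop(sprintf("unknown shape_kind '%s'", shape_kind), call. = FALSE)
  }
  withr::with_seed(seed, {
    kind <- if (shape_kind == "random") sample(SHAPE_KINDS, 1) else shape_kind
    nr <- grid[1]; nc <- grid[2]
    # pixel-center coordinates relative to a random shape center
    cx <- stats::runif(1, 0.25 * nc, 0.75 * nc)
    cy <- stats::runif(1, 0.25 * nr, 0.75 * nr)
    theta <- stats::runif(1, 0, pi)
    R <- stats::runif(1, 0.12, 0.25) * min(grid)
    x <- rep(seq_len(nc), each = nr) - cx
    y <- rep(seq_len(nr), times = nc) - cy
    u <- cos(theta) * x + sin(theta) * y
    v <- -sin(theta) * x + cos(theta) * y
    support <- switch(kind,
      disc = u^2 + v^2 <= R^2,
      disc_pair = {
        rr <- R / 1.7
        ((u - 1.1 * R)^2 + v^2 <= rr^2) | ((u + 1.1 * R)^2 + v^2 <= rr^2)
      },
      cross = (abs(u) <= R & abs(v) <= R / 3) | (abs(v) <= R & abs(u) <= R / 3),
      line = abs(v) <= pmax(1.2, R / 7) & abs(u) <= R,
      arrow = {
        shaft <- abs(v) <= pmax(1.2, R / 7) & u >= -R & u <= R / 3
        head <- u > R / 3 & u <= R & abs(v) <= 0.8 * (R - u)
        shaft | head
      },
      trapezoid = abs(v) <= 0.55 * R &
        abs(u) <= 0.45 * R + 0.55 * R * (0.5 - v / (1.1 * R)),
      random_blob = {
        s <- rep(FALSE, length(u))
        for (i in seq_len(4)) {
          bu <- stats::runif(1, -0.6, 0.6) * R
          bv <- stats::runif(1, -0.6, 0.6) * R
          br <- stats::runif(1, 0.35, 0.65) * R
          s <- s | ((u - bu)^2 + (v - bv)^2 <= br^2)
        }
        s
      }
    )
    value <- stats::runif(1, 0.25, 1)
    contrast <- matrix(0, nr, nc)
    contrast[support] <- value
    structure(
      list(
        contrast = contrast,
        mu_a_map = ifelse(contrast > 0, 0.5 + contrast * 0.22, 0),
        shape_kind = kind,
        contrast_value = value,
        seed = seed
      ),
      class = "digp_anomaly"
    )
  })
}

#' @export
print.digp_anomaly <- function(x, ...) {
  cat(sprintf("<digp_anomaly> %s, contrast %.3f, support %.1f%% of %d x %d\n",
              x$shape_kind, x$contrast_value,
              100 * mean(x$contrast > 0), nrow(x$contrast), ncol(x$contrast)))
  invisible(x)
}

#' SNR thresholding mask
#'
#' Binary mask retaining measurement pixels whose signal-to-noise ratio
#' `M / sigma_n` is at least `thr` (>= comparison: a pixel exactly at the
#' threshold is retained).
#'
#' @param M_sub Reference-subtracted measurement image (unnormalized or
#'   normalized; the mask scales with whatever units `sigma_n` is in).
#' @param sigma_n Background noise standard deviation (> 0).
#' @param thr SNR threshold (default 3).
#' @return A 0/1 matrix of the same shape as `M_sub`.
#' @export
compute_snr_mask <- function(M_sub, sigma_n, thr = 3) {
  if (!is.numeric(sigma_n) || length(sigma_n) != 1L || sigma_n <= 0) {
    stop("`sigma_n` must be a single positive number", call. = FALSE)
  }
  (M_sub / sigma_n >= thr) * 1
}

#' Simulate a transmission measurement of an anomaly
#'
#' Forward-projects the anomaly's absorption perturbation through the Born
#' sensitivity matrix, adds the reference (anomaly-free) flux and per-pixel
#' Gaussian noise with standard deviation `noise_level * max(M_ref)`, then
#' forms the reference-subtracted, max-normalized measurement and its SNR
#' mask (threshold 3). The noise sd `sigma_n` is estimated from a noise-only
#' replicate, mirroring estimation from anomaly-free reference frames.
#'
#' @param J A [build_jacobian()] object (carries the geometry and optics used
#'   for the reference measurement).
#' @param anomaly A [generate_anomaly()] object on the same grid.
#' @param noise_level Gaussian noise level as a fraction of the reference
#'   maximum (default 0.02, i.e. 2%).
#' @param seed Integer seed for the noise draws.
#' @return An object of class `digp_measurement`: list with `M_raw`, `M_ref`,
#'   `M_sub` (in [0, 1]), `sub_scale` (the max used to normalize), `sigma_n`,
#'   `snr_mask`, `noise_level`, `seed`.
#' @export
simulate_measurement <- function(J, anomaly, noise_level = 0.02, seed = 1) {
  stopifnot(inherits(J, "digp_jacobian"))
  if (noise_level < 0) stop("`noise_level` must be non-negative", call. = FALSE)
  chi <- if (inherits(anomaly, "digp_anomaly")) {
    pmax(anomaly$mu_a_map - J$props$mu_a, 0)
  } else {
    as.matrix(anomaly)
  }
  if (!all(dim(chi) == J$geom$grid)) {
    stop("anomaly grid does not match the Jacobian's object grid", call. = FALSE)
  }
  M_ref <- reference_measurement(J$props, J$geom)
  dM <- forward_project(J, chi)
  sigma <- noise_level * max(M_ref)
  withr::with_seed(seed, {
    eps <- matrix(stats::rnorm(length(M_ref), 0, max(sigma, 0)), nrow(M_ref))
    eps_rep <- matrix(stats::rnorm(length(M_ref), 0, max(sigma, 0)), nrow(M_ref))
  })
  if (noise_level == 0) eps[] <- eps_rep[] <- 0
  M_raw <- M_ref + dM + eps
  sigma_n <- stats::sd(eps_rep)
  sub_raw <- pmax(M_ref - M_raw, 0)
  sub_scale <- max(sub_raw)
  M_sub <- if (sub_scale > 0) sub_raw / sub_scale else sub_raw
  snr_mask <- if (sigma_n > 0) {
    compute_snr_mask(sub_raw, sigma_n, 3)
  } else {
    (sub_raw > 0) * 1
  }
  structure(
    list(M_raw = M_raw, M_ref = M_ref, M_sub = M_sub, sub_scale = sub_scale,
         sigma_n = sigma_n, snr_mask = snr_mask, noise_level = noise_level,
         seed = seed),
    class = "digp_measurement"
  )
}

#' @export
print.digp_measurement <- function(x, ...) {
  cat(sprintf("<digp_measurement> %d x %d, sigma_n %.3g, %d SNR-retained pixels\n",
              nrow(x$M_sub), ncol(x$M_sub), x$sigma_n, sum(x$snr_mask)))
  invisible(x)
}

#' Build a synthetic training dataset
#'
#' Generates `n` (anomaly, measurement) pairs sharing one sensitivity matrix,
#' cycling through all shape kinds, with per-sample seeds derived from the
#' master seed, and a random train/test split holding out at least 20% of the
#' samples. Bitwise reproducible under a fixed `master_seed`.
#'
#' @param n Number of samples (default 30; at least 2).
#' @param master_seed Integer master seed.
#' @param props,geom Optics and geometry (defaults: the 110 x 60 x 30 mm slab
#'   with mu_a = 0.0035, mu_s' = 0.8090 mm^-1, 64 x 64 grids).
#' @param noise_level Measurement noise fraction (default 0.02).
#' @param holdout Fraction of samples held out for testing (default 0.2).
#' @param J Optional precomputed [build_jacobian()] for `props`/`geom`.
#' @return An object of class `digp_dataset`: list with `samples` (each a list
#'   `measurement`, `anomaly`), `J`, `props`, `geom`, `train_idx`, `test_idx`,
#'   `master_seed`.
#' @export
build_dataset <- function(n = 30, master_seed = 1,
                          props = optical_properties(0.0035, 0.8090),
                          geom = slab_geometry(),
                          noise_level = 0.02, holdout = 0.2, J = NULL) {
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (is.null(J)) J <- build_jacobian(props, geom)
  kinds <- rep_len(SHAPE_KINDS, n)
  samples <- lapply(seq_len(n), function(i) {
    anomaly <- generate_anomaly(master_seed + i, kinds[i], geom$grid)
    measurement <- simulate_measurement(J, anomaly, noise_level,
                                        seed = master_seed + 10000L + i)
    list(measurement = measurement, anomaly = anomaly)
  })
  n_test <- max(1L, ceiling(n * holdout))
  test_idx <- withr::with_seed(master_seed, sort(sample.int(n, n_test)))
  structure(
    list(samples = samples, J = J, props = props, geom = geom,
         train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx,
         master_seed = master_seed, noise_level = noise_level),
    class = "digp_dataset"
  )
}

#' @export
print.digp_dataset <- function(x, ...) {
  cat(sprintf("<digp_dataset> %d samples (%d train / %d test), %d x %d grids\n",
              length(x$samples), length(x$train_idx), length(x$test_idx),
              x$geom$grid[1], x$geom$grid[2]))
  invisible(x)
}

#' Persist a dataset sample to disk
#'
#' Writes the measurement and ground-truth contrast as 16-bit grayscale TIFF
#' plus a JSON sidecar (seed, shape kind, sigma_n, normalization scale).
#'
#' @param sample One element of `digp_dataset$samples`.
#' @param dir Output directory (created if needed).
#' @param stem File stem for the three files.
#' @return The sidecar path, invisibly.
#' @export
write_sample <- function(sample, dir, stem) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- sample$measurement
  save_measurement(m$M_sub, file.path(dir, paste0(stem, "_measurement.tiff")))
  save_measurement(sample$anomaly$contrast,
                   file.path(dir, paste0(stem, "_truth.tiff")))
  side <- list(seed = m$seed, shape_kind = sample$anomaly$shape_kind,
               sigma_n = m$sigma_n, sub_scale = m$sub_scale,
               noise_level = m$noise_level)
  p <- file.path(dir, paste0(stem, ".json"))
  write_json_atomic(side, p)
  invisible(p)
}
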