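# Atomic write helpers: write to a temp file in the same directory, then
# rename into place.
write_json_atomic <- function(x, path, ...) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, ...)
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a camera measurement image
#'
#' Reads an 8/16-bit grayscale PNG or TIFF raster, downsamples it to the
#' target grid by exact area averaging (fractional source-pixel overlaps are
#' weighted by covered area, so total intensity is conserved up to the grid
#' ratio) and min-max normalizes to [0, 1].
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`).
#' @param target_size Output grid `c(rows, cols)` (default 64 x 64).
#' @param convert_gray Convert color inputs by channel averaging; color input
#'   without this flag is an error.
#' @param normalize Min-max normalize after resizing (default TRUE).
#' @return A `target_size` matrix in [0, 1].
#' @export
load_measurement <- function(path, target_size = c(64, 64),
                             convert_gray = FALSE, normalize = TRUE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported raster format '.%s'", ext), call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (!convert_gray) {
      stop("color image: pass `convert_gray = TRUE` to average channels",
           call. = FALSE)
    }
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  out <- resize_area(img, target_size)
  if (normalize) {
    rng <- range(out)
    if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  }
  out
}

#' Area-average image resizing
#'
#' Downsamples (or upsamples) by exact area weighting: output pixel (i, j)
#' averages the source pixels its footprint covers, with fractional overlaps
#' weighted by covered length along each axis. For integer factors this is
#' plain block averaging.
#'
#' @param M Source matrix.
#' @param target_size Output `c(rows, cols)`.
#' @return The resized matrix.
#' @export
resize_area <- function(M, target_size) {
  target_size <- as.integer(target_size)
  Wr <- area_weights(nrow(M), target_size[1])
  Wc <- area_weights(ncol(M), target_size[2])
  Wr %*% M %*% t(Wc)
}

# n_out x n_in interval-overlap weight matrix; rows sum to 1.
area_weights <- function(n_in, n_out) {
  step <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * step
    b <- i * step
    j0 <- floor(a) + 1
    j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      W[i, j] <- max(0, min(b, j) - max(a, j - 1))
    }
  }
  W / step
}

#' Save an image as 16-bit grayscale
#'
#' Writes values in [0, 1] to TIFF at 16-bit depth (lossless to ~1.5e-5) or
#' PNG at 8-bit.
#'
#' @param M Matrix with values in [0, 1] (clipped on write).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_measurement <- function(M, path) {
  M <- pmin(pmax(M, 0), 1)
  ext <- tolower(tools::file_ext(path))
  tmp <- paste0(path, ".tmp.", ext)
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(M, tmp, bits.per.sample = 16),
    png = png::writePNG(M, tmp),
    stop(sprintf("unsupported raster format '.%s'", ext), call. = FALSE)
  )
  file.rename(tmp, path)
  invisible(path)
}

#' Reference subtraction
#'
#' Forms the reference-subtracted measurement `clip(M_ref - M_raw, 0)` --
#' oriented so added absorption gives a positive signal -- and max-normalizes
#' it to [0, 1] so measurement pixels match the GP terminal range.
#'
#' @param M_raw Measurement with the anomaly present.
#' @param M_ref Anomaly-free reference measurement (same shape).
#' @return A matrix in [0, 1]; all zeros when `M_raw = M_ref`.
#' @export
subtract_reference <- function(M_raw, M_ref) {
  if (!all(dim(as.matrix(M_raw)) == dim(as.matrix(M_ref)))) {
    stop("image shapes differ", call. = FALSE)
  }
  s <- pmax(M_ref - M_raw, 0)
  m <- max(s)
  if (m > 0) s / m else s
}

#' Default run configuration
#'
#' Nested list of every tunable of the pipeline with its default: optics,
#' geometry, dataset parameters, evolution hyperparameters, fitness weights,
#' SNR threshold and conjugate-gradient settings. [load_run_config()] merges a
#' YAML document over these defaults, rejecting unknown keys.
#'
#' @return A named nested list.
#' @export
default_run_config <- function() {
  list(
    optics = list(mu_a = 0.0035, mu_s_prime = 0.8090),
    geometry = list(height = 110, width = 60, thickness = 30,
                    source_radius = 15, wavelength = 639, anomaly_depth = 15,
                    grid = c(64, 64)),
    dataset = list(n_samples = 30, master_seed = 1, noise_level = 0.02, holdout = 0.2),
    evolution = list(pop_size = 200, generations = 30, p_crossover = 0.6,
                     p_mutation = 0.4, depth_min = 3, depth_max = 5,
                     tournament_size = 4, patch_width = 5, seed = 1),
    fitness = list(alpha = 0.7, beta = 0.25, gamma = 0.15, snr_threshold = 3),
    cgd = list(delta = NA, max_iters = 200, tol = 1e-6),
    output_dir = "digp-run"
  )
}

#' Load a run configuration from YAML
#'
#' Reads a single YAML document and merges it over [default_run_config()].
#' Unknown keys (at the section or field level) are rejected.
#'
#' @param path YAML file path.
#' @return The merged configuration list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (sec in names(user)) {
    if (is.list(defaults[[sec]]) && is.list(user[[sec]])) {
      badf <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
      if (length(badf)) {
        stop(sprintf("unknown key(s) in '%s': %s", sec,
                     paste(badf, collapse = ", ")), call. = FALSE)
      }
      defaults[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      defaults[[sec]] <- user[[sec]]
    }
  }
  defaults
}

# Materialize package objects from a configuration list.
config_objects <- function(cfg) {
  props <- optical_properties(cfg$optics$mu_a, cfg$optics$mu_s_prime)
  geom <- slab_geometry(
    height = cfg$geometry$height, width = cfg$geometry$width,
    thickness = cfg$geometry$thickness,
    source_radius = cfg$geometry$source_radius,
    wavelength = cfg$geometry$wavelength,
    anomaly_depth = cfg$geometry$anomaly_depth,
    grid = unlist(cfg$geometry$grid)
  )
  ev <- cfg$evolution
  config <- evolution_config(
    pop_size = ev$pop_size, generations = ev$generations,
    p_crossover = ev$p_crossover, p_mutation = ev$p_mutation,
    depth_range = c(ev$depth_min, ev$depth_max),
    tournament_size = ev$tournament_size, patch_width = ev$patch_width,
    seed = ev$seed
  )
  weights <- fitness_weights(cfg$fitness$alpha, cfg$fitness$beta,
                             cfg$fitness$gamma)
  list(props = props, geom = geom, config = config, weights = weights)
}
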