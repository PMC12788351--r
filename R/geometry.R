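#' Slab geometry for transmission imaging
#'
#' Describes the rectangular slab, the Gaussian source spot on the input face,
#' the anomaly (object) plane depth and the object/detector pixel grids used
#' by the forward model. The source is centered on the optical axis at z = 0,
#' the object plane sits at `anomaly_depth` and the detector grid on the exit
#' face at z = `thickness`. Both grids share a square field of view of
#' `pixel_pitch * grid` mm centered on the axis.
#'
#' @param height,width,thickness Slab dimensions (mm).
#' @param source_radius Radius of the Gaussian illumination spot (mm). The
#'   spot is discretized as a superposition of point sources with Gaussian
#'   weights of sd `source_radius / 2`, truncated at 3 sd.
#' @param wavelength Source wavelength (nm); bookkeeping only.
#' @param source_amplitude Source amplitude phi (arbitrary units).
#' @param anomaly_depth Depth of the object plane (mm); strictly inside the slab.
#' @param grid Object/detector grid as `c(rows, cols)`.
#' @param pixel_pitch Physical pixel pitch (mm); `pixel_pitch * cols` must not
#'   exceed `width`.
#' @param source_grid_step Spacing of the point sources used to discretize the
#'   Gaussian spot (mm).
#' @return An object of class `digp_geometry`.
#' @examples
#' slab_geometry() # the default 110 x 60 x 30 mm slab, 64 x 64 grids
#' @export
slab_geometry <- function(height = 110, width = 60, thickness = 30,
                          source_radius = 15, wavelength = 639,
                          source_amplitude = 1, anomaly_depth = 15,
                          grid = c(64, 64), pixel_pitch = width / max(grid),
                          source_grid_step = source_radius / 6) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) {
    stop("`grid` must be two positive integers (rows, cols)", call. = FALSE)
  }
  if (height <= 0 || width <= 0 || thickness <= 0) {
    stop("slab dimensions must be positive", call. = FALSE)
  }
  if (anomaly_depth <= 0 || anomaly_depth >= thickness) {
    stop("`anomaly_depth` must lie strictly inside the slab", call. = FALSE)
  }
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive", call. = FALSE)
  if (pixel_pitch * grid[2] > width + 1e-9) {
    stop("field of view exceeds the slab width (pixel_pitch * cols > width)",
         call. = FALSE)
  }
  if (source_radius <= 0 || source_grid_step <= 0) {
    stop("source radius and grid step must be positive", call. = FALSE)
  }
  structure(
    list(
      height = height, width = width, thickness = thickness,
      source_radius = source_radius, wavelength = wavelength,
      source_amplitude = source_amplitude,
      anomaly_depth = anomaly_depth,
      grid = grid, pixel_pitch = pixel_pitch,
      voxel_volume = pixel_pitch^3,
      source_grid_step = source_grid_step
    ),
    class = "digp_geometry"
  )
}

#' @export
print.digp_geometry <- function(x, ...) {
  cat("<digp_geometry>\n")
  cat(sprintf("  slab        %g x %g x %g mm\n", x$height, x$width, x$thickness))
  cat(sprintf("  grids       %d x %d @ %.4g mm pitch\n",
              x$grid[1], x$grid[2], x$pixel_pitch))
  cat(sprintf("  object at   %g mm depth\n", x$anomaly_depth))
  cat(sprintf("  source      Gaussian spot, radius %g mm, %g nm\n",
              x$source_radius, x$wavelength))
  invisible(x)
}

# Pixel-center coordinates of the (shared) object/detector grid, centered on
# the optical axis. Returns flattened column-major x/y vectors of length
# rows * cols, matching as.vector() on an image matrix.
grid_coords <- function(geom) {
  nr <- geom$grid[1]
  nc <- geom$grid[2]
  p <- geom$pixel_pitch
  y <- (seq_len(nr) - (nr + 1) / 2) * p
  x <- (seq_len(nc) - (nc + 1) / 2) * p
  list(x = rep(x, each = nr), y = rep(y, times = nc))
}

# Discretization of the Gaussian source spot: point-source positions on the
# input face (z = 0) with normalized Gaussian weights (sd = radius/2,
# truncated at 3 sd).
source_points <- function(geom) {
  sigma <- geom$source_radius / 2
  r_max <- 3 * sigma
  s <- geom$source_grid_step
  ax <- seq(-r_max, r_max, by = s)
  pts <- expand.grid(x = ax, y = ax)
  keep <- pts$x^2 + pts$y^2 <= r_max^2
  pts <- pts[keep, , drop = FALSE]
  w <- exp(-(pts$x^2 + pts$y^2) / (2 * sigma^2))
  list(x = pts$x, y = pts$y, w = w / sum(w))
}
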