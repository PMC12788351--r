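#' Born-approximation sensitivity (Jacobian) matrix
#'
#' Assembles the dense sensitivity matrix J mapping per-pixel absorption
#' perturbations on the object plane to transmitted-flux changes on the
#' detector grid, under the first Born approximation of the continuous-wave
#' diffusion equation:
#' \deqn{J_{dv} = -\,\Phi_{src}(v)\; G(v, d)\; V_{voxel},}
#' where \eqn{\Phi_{src}(v)} is the source fluence at object voxel v (the
#' Gaussian spot integrated as a superposition of point sources) and
#' \eqn{G(v, d) = e^{-\mu_{eff} r}/(4\pi D r)} is the diffusion-operator
#' Green's function from the voxel to detector pixel d. The negative sign
#' encodes that added absorption reduces the transmitted flux, so all entries
#' are non-positive.
#'
#' @param props A [optical_properties()] object.
#' @param geom A [slab_geometry()] object.
#' @return An object of class `digp_jacobian`: a list with the dense matrix
#'   `entries` (detector pixels x object pixels, column-major pixel order),
#'   plus `props` and `geom`.
#' @export
build_jacobian <- function(props, geom) {
  stopifnot(inherits(props, "digp_optics"), inherits(geom, "digp_geometry"))
  g <- grid_coords(geom)
  src <- source_points(geom)
  dz_so <- geom$anomaly_depth
  dz_od <- geom$thickness - geom$anomaly_depth

  # source fluence at each object voxel (Eq.-2 flux, superposed spot)
  phi_src <- numeric(length(g$x))
  for (k in seq_along(src$x)) {
    r <- sqrt((g$x - src$x[k])^2 + (g$y - src$y[k])^2 + dz_so^2)
    phi_src <- phi_src + src$w[k] * point_source_flux(props, r, geom$source_amplitude)
  }

  # voxel -> detector operator Green's function (no 1/c)
  r2 <- outer(g$x, g$x, "-")^2
  r2 <- r2 + outer(g$y, g$y, "-")^2
  r <- sqrt(r2 + dz_od^2) # [detector, voxel]
  J <- green_flux(props, r)
  rm(r, r2)
  J <- -sweep(J, 2L, phi_src * geom$voxel_volume, "*")
  structure(list(entries = J, props = props, geom = geom),
            class = "digp_jacobian")
}

#' @export
print.digp_jacobian <- function(x, ...) {
  cat(sprintf("<digp_jacobian> %d detector x %d object pixels\n",
              nrow(x$entries), ncol(x$entries)))
  invisible(x)
}

# Raw dense matrix of a sensitivity object (or pass-through for matrices).
jacobian_entries <- function(J) {
  if (is.list(J) && !is.null(J$entries)) J$entries else as.matrix(J)
}

#' Linearized forward projection
#'
#' Computes the Born-model measurement change \eqn{\Delta M = J \chi} for an
#' object-plane absorption perturbation image `chi`, optionally added to a
#' reference measurement `M0`. Linear in `chi`.
#'
#' @param J A [build_jacobian()] object or a plain sensitivity matrix.
#' @param chi Object-plane perturbation: matrix on the object grid or a
#'   flattened (column-major) vector of length `ncol(J)`.
#' @param M0 Optional reference measurement (matrix or vector, detector grid).
#' @return The predicted measurement change (or `M0 + dM` when `M0` is given),
#'   shaped like the detector grid when `chi` was a matrix, else a vector.
#' @export
forward_project <- function(J, chi, M0 = NULL) {
  Jm <- jacobian_entries(J)
  was_matrix <- is.matrix(chi)
  dims <- dim(chi)
  v <- as.numeric(chi)
  if (length(v) != ncol(Jm)) {
    stop(sprintf("`chi` has %d pixels but J has %d columns",
                 length(v), ncol(Jm)), call. = FALSE)
  }
  dm <- as.numeric(Jm %*% v)
  if (!is.null(M0)) {
    if (length(as.numeric(M0)) != length(dm)) {
      stop("`M0` does not match the detector grid", call. = FALSE)
    }
    dm <- as.numeric(M0) + dm
  }
  if (was_matrix && inherits(J, "digp_jacobian")) {
    matrix(dm, nrow = J$geom$grid[1], ncol = J$geom$grid[2])
  } else if (was_matrix && nrow(Jm) == prod(dims)) {
    matrix(dm, nrow = dims[1], ncol = dims[2])
  } else {
    dm
  }
}

#' Reference (anomaly-free) detector measurement
#'
#' Transmitted flux on the detector grid for the homogeneous slab: the
#' Gaussian source spot propagated through the full slab thickness with the
#' analytical point-source flux.
#'
#' @inheritParams build_jacobian
#' @return A detector-grid matrix of fluxes.
#' @export
reference_measurement <- function(props, geom) {
  stopifnot(inherits(props, "digp_optics"), inherits(geom, "digp_geometry"))
  g <- grid_coords(geom)
  src <- source_points(geom)
  m <- numeric(length(g$x))
  for (k in seq_along(src$x)) {
    r <- sqrt((g$x - src$x[k])^2 + (g$y - src$y[k])^2 + geom$thickness^2)
    m <- m + src$w[k] * point_source_flux(props, r, geom$source_amplitude)
  }
  matrix(m, nrow = geom$grid[1], ncol = geom$grid[2])
}

#' Persist / load a sensitivity matrix
#'
#' Writes the dense matrix as tab-delimited text next to a JSON sidecar
#' carrying the shape, pixel pitch, optical properties and geometry summary,
#' so a saved Jacobian can be audited and reloaded without recomputation.
#' Writes are atomic (write-then-rename).
#'
#' @param J A [build_jacobian()] object.
#' @param path Output path for the matrix (the sidecar gets `.json` appended).
#' @return `path`, invisibly (for `write_jacobian`); a `digp_jacobian`-like
#'   list for `read_jacobian` (without the full geometry objects).
#' @export
write_jacobian <- function(J, path) {
  stopifnot(inherits(J, "digp_jacobian"))
  header <- list(
    shape = dim(J$entries),
    pixel_pitch = J$geom$pixel_pitch,
    grid = J$geom$grid,
    anomaly_depth = J$geom$anomaly_depth,
    thickness = J$geom$thickness,
    mu_a = J$props$mu_a,
    mu_s_prime = J$props$mu_s_prime,
    geometry_hash = digest_geometry(J$geom)
  )
  tmp <- paste0(path, ".tmp")
  utils::write.table(J$entries, tmp, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  file.rename(tmp, path)
  write_json_atomic(header, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_jacobian
#' @export
read_jacobian <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  if (!all(dim(m) == header$shape)) {
    stop("matrix shape does not match its sidecar header", call. = FALSE)
  }
  structure(list(entries = m, header = header), class = "digp_jacobian_file")
}

# Cheap content hash of the geometry for provenance sidecars.
digest_geometry <- function(geom) {
  s <- paste(unlist(geom[c("height", "width", "thickness", "source_radius",
                           "anomaly_depth", "grid", "pixel_pitch")]),
             collapse = ",")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}
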