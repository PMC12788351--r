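#' Optical properties of a homogeneous diffuse medium
#'
#' Bundles the background absorption and reduced scattering coefficients with
#' the derived diffusion-theory constants: the diffusion coefficient
#' \eqn{D = 1/(3(\mu_a + \mu_s'))}, the effective attenuation
#' \eqn{\mu_{eff} = \sqrt{\mu_a / D}} and the transport mean free path
#' \eqn{l_{tr} = 1/(\mu_a + \mu_s')}.
#'
#' The reduced scattering coefficient may be supplied directly, or computed
#' from the raw scattering coefficient and anisotropy factor as
#' \eqn{\mu_s' = \mu_s (1 - g)}.
#'
#' @param mu_a Background absorption coefficient (mm^-1). Must be positive.
#' @param mu_s_prime Reduced scattering coefficient (mm^-1). Must be positive.
#'   Ignored when both `mu_s` and `g` are given.
#' @param c_medium Speed of light in the medium (mm/s). Enters the analytical
#'   flux only as a global amplitude scale; defaults to c0 / 1.33.
#' @param mu_s,g Optional raw scattering coefficient (mm^-1) and anisotropy
#'   factor (mean cosine of the scattering angle, in [0, 1)).
#'
#' @return An object of class `digp_optics`: a list with fields `mu_a`,
#'   `mu_s_prime`, `c_medium`, and derived `D`, `mu_eff`, `l_tr` (all mm-based).
#' @examples
#' op <- optical_properties(0.0035, 0.8090)
#' op$l_tr # 1.2308 mm, i.e. a 1230 um transport mean free path
#' @export
optical_properties <- function(mu_a, mu_s_prime = NULL,
                               c_medium = 2.99792458e11 / 1.33,
                               mu_s = NULL, g = NULL) {
  if (!is.null(mu_s) && !is.null(g)) {
    if (mu_s <= 0 || g < 0 || g >= 1) {
      stop("`mu_s` must be positive and `g` in [0, 1)", call. = FALSE)
    }
    mu_s_prime <- mu_s * (1 - g)
  }
  if (is.null(mu_s_prime)) {
    stop("supply `mu_s_prime`, or both `mu_s` and `g`", call. = FALSE)
  }
  if (!is.numeric(mu_a) || length(mu_a) != 1L || !is.finite(mu_a) || mu_a <= 0) {
    stop("`mu_a` must be a single positive number (mm^-1)", call. = FALSE)
  }
  if (!is.numeric(mu_s_prime) || length(mu_s_prime) != 1L ||
      !is.finite(mu_s_prime) || mu_s_prime <= 0) {
    stop("`mu_s_prime` must be a single positive number (mm^-1)", call. = FALSE)
  }
  if (c_medium <= 0) stop("`c_medium` must be positive", call. = FALSE)
  mu_t <- mu_a + mu_s_prime
  l_tr <- 1 / mu_t
  D <- l_tr / 3 # so D = l_tr / 3 holds exactly in floating point
  structure(
    list(
      mu_a = mu_a,
      mu_s_prime = mu_s_prime,
      c_medium = c_medium,
      D = D,
      mu_eff = sqrt(mu_a / D),
      l_tr = l_tr
    ),
    class = "digp_optics"
  )
}

#' @export
print.digp_optics <- function(x, ...) {
  cat("<digp_optics>\n")
  cat(sprintf("  mu_a       %.5g mm^-1\n", x$mu_a))
  cat(sprintf("  mu_s'      %.5g mm^-1\n", x$mu_s_prime))
  cat(sprintf("  D          %.5g mm\n", x$D))
  cat(sprintf("  mu_eff     %.5g mm^-1\n", x$mu_eff))
  cat(sprintf("  l_tr       %.5g mm (%.0f um)\n", x$l_tr, 1000 * x$l_tr))
  invisible(x)
}

#' Slab thickness expressed in transport mean free paths
#'
#' @param props A [optical_properties()] object.
#' @param thickness Slab thickness (mm).
#' @return `thickness / l_tr`, the dimensionless optical thickness tau.
#' @examples
#' thickness_in_mfp(optical_properties(0.0035, 0.8090), 30) # ~24.4
#' @export
thickness_in_mfp <- function(props, thickness) {
  stopifnot(inherits(props, "digp_optics"))
  if (thickness <= 0) stop("`thickness` must be positive", call. = FALSE)
  thickness / props$l_tr
}

# CW diffusion-operator Green's function exp(-mu_eff r) / (4 pi D r).
# This is the propagator of (mu_a - D lap) G = delta; it carries no 1/c.
green_flux <- function(props, r) {
  exp(-props$mu_eff * r) / (4 * pi * props$D * r)
}

#' Analytical point-source photon flux
#'
#' Continuous-wave diffusion-approximation flux at distance `r` from an
#' isotropic point source in an infinite homogeneous medium:
#' \deqn{\Phi(r) = \varphi \, e^{-\mu_{eff} r} / (4 \pi D r c).}
#' Strictly positive and strictly decreasing in `r`; linear in the source
#' amplitude `phi`. The 1/c factor is a global amplitude convention that
#' cancels in all normalized quantities.
#'
#' @param props A [optical_properties()] object.
#' @param r Distance(s) from the source (mm); must all be positive (the
#'   point-source solution is singular at r = 0).
#' @param phi Source amplitude (arbitrary units).
#' @return Flux values, same length as `r`.
#' @export
point_source_flux <- function(props, r, phi = 1) {
  stopifnot(inherits(props, "digp_optics"))
  if (!is.numeric(r) || length(r) == 0L || any(!is.finite(r)) || any(r <= 0)) {
    stop("`r` must be positive (point-source singularity at r = 0)",
         call. = FALSE)
  }
  phi * green_flux(props, r) / props$c_medium
}

#' Monte Carlo random-walk flux validator
#'
#' Brute-force isotropic random-walk estimate of the continuous-wave fluence
#' around a point source in an infinite homogeneous medium. Photons take
#' exponentially distributed steps with rate \eqn{\mu_a + \mu_s'} and carry a
#' survival weight multiplied by the single-scatter albedo
#' \eqn{\mu_s'/(\mu_a+\mu_s')} at each collision; the fluence at radius r is
#' estimated with a collision-density estimator over thin spherical shells.
#' In the diffusive range the log-slope of `r * flux` versus `r` approaches
#' \eqn{-\mu_{eff}}, which is what this validator is for.
#'
#' @param props A [optical_properties()] object.
#' @param distances Shell-center radii (mm) at which to estimate the fluence.
#' @param n_photons Number of photon packets (>= 1e4 recommended for
#'   meaningful error bars).
#' @param seed Integer seed; the same seed yields bitwise-identical output.
#' @param shell_width Width of the tally shells (mm).
#' @param n_batches Number of photon batches used for the standard errors.
#' @param max_steps Hard cap on the number of collisions per photon.
#' @return A tibble with columns `distance`, `flux`, `se` (standard error of
#'   the batch means).
#' @export
mc_random_walk_flux <- function(props, distances, n_photons = 2e4, seed = 1,
                                shell_width = 1, n_batches = 20,
                                max_steps = 5000) {
  stopifnot(inherits(props, "digp_optics"))
  if (length(distances) == 0L) {
    stop("`distances` must contain at least one radius", call. = FALSE)
  }
  if (any(distances <= 0)) stop("`distances` must be positive", call. = FALSE)
  n_photons <- as.integer(n_photons)
  mu_t <- props$mu_a + props$mu_s_prime
  albedo <- props$mu_s_prime / mu_t
  r_kill <- max(distances) + 25 * props$l_tr
  breaks <- sort(unique(c(distances - shell_width / 2,
                          distances + shell_width / 2)))
  lo <- distances - shell_width / 2
  batch <- rep_len(seq_len(n_batches), n_photons)

  tally <- matrix(0, n_batches, length(distances))
  n_bins <- length(distances)

  withr::with_seed(seed, {
    pos <- matrix(0, n_photons, 3)
    w <- rep(1, n_photons)
    active <- rep(TRUE, n_photons)
    for (step in seq_len(max_steps)) {
      idx <- which(active)
      if (length(idx) == 0L) break
      n <- length(idx)
      len <- stats::rexp(n, rate = mu_t)
      # isotropic direction
      cz <- stats::runif(n, -1, 1)
      ph <- stats::runif(n, 0, 2 * pi)
      sz <- sqrt(pmax(0, 1 - cz^2))
      pos[idx, 1] <- pos[idx, 1] + len * sz * cos(ph)
      pos[idx, 2] <- pos[idx, 2] + len * sz * sin(ph)
      pos[idx, 3] <- pos[idx, 3] + len * cz
      r <- sqrt(rowSums(pos[idx, , drop = FALSE]^2))
      # tally collisions falling inside a shell
      bin <- findInterval(r, lo)
      bin_safe <- pmin(pmax(bin, 1L), n_bins)
      inside <- bin >= 1 & bin <= n_bins & r < lo[bin_safe] + shell_width
      if (any(inside)) {
        ii <- idx[inside]
        # column-major linear index into the n_batches x n_bins tally
        add <- rowsum(w[ii], group = (bin[inside] - 1L) * n_batches + batch[ii])
        at <- as.integer(rownames(add))
        tally[at] <- tally[at] + add
      }
      # absorb a fraction of the weight, then kill escapers / spent packets
      w[idx] <- w[idx] * albedo
      dead <- r > r_kill | w[idx] < 1e-4
      active[idx[dead]] <- FALSE
    }
  })

  per_batch <- tabulate(batch, nbins = n_batches)
  vol <- 4 / 3 * pi * ((lo + shell_width)^3 - lo^3)
  est <- sweep(tally, 1, per_batch * mu_t, "/")
  est <- sweep(est, 2, vol, "/")
  flux <- colMeans(est)
  se <- apply(est, 2, stats::sd) / sqrt(n_batches)
  tibble::tibble(distance = as.numeric(distances), flux = flux, se = se)
}
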