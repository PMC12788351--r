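#' Fitness weights
#'
#' Weights of the composite cost `F = alpha * xi_PI + beta * xi_mse +
#' gamma * xi_dice`. Training defaults are (0.7, 0.25, 0.15), used exactly as
#' stated (unnormalized). Test mode forces (1, 0, 0): only the
#' physics-informed component is used and ground truth is never consulted.
#'
#' @param alpha,beta,gamma Non-negative component weights.
#' @param mode `"train"` or `"test"`.
#' @return An object of class `digp_weights`.
#' @export
fitness_weights <- function(alpha = 0.7, beta = 0.25, gamma = 0.15,
                            mode = c("train", "test")) {
  mode <- match.arg(mode)
  if (mode == "test") {
    alpha <- 1; beta <- 0; gamma <- 0
  }
  if (alpha < 0 || beta < 0 || gamma < 0) {
    stop("weights must be non-negative", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, mode = mode),
            class = "digp_weights")
}

#' Physics-informed fitness
#'
#' Data-fidelity cost requiring no ground truth: the candidate reconstruction
#' is pushed through the Born forward model, the predicted and actual
#' reference-subtracted measurements are each max-normalized over the full
#' detector frame (identically), and the squared residuals are averaged over
#' the SNR-retained pixels only (a mean, commensurate with [mse_loss()], so the
#' composite weights act on comparable magnitudes).
#'
#' @param chi_pred Candidate reconstruction (object-grid matrix in [0, 1]).
#' @param J A [build_jacobian()] object or sensitivity matrix.
#' @param M_meas Reference-subtracted measurement (detector-grid matrix,
#'   max-normalized; oriented so absorption gives a positive signal).
#' @param mask Binary SNR mask on the detector grid.
#' @return Non-negative scalar. An all-zero mask yields 0 with a warning
#'   (degenerate objective).
#' @export
physics_fitness <- function(chi_pred, J, M_meas, mask) {
  if (!all(dim(as.matrix(M_meas)) == dim(as.matrix(mask)))) {
    stop("`mask` and `M_meas` shapes differ", call. = FALSE)
  }
  keep <- which(as.numeric(mask) > 0)
  if (length(keep) == 0L) {
    warning("all-zero SNR mask: physics fitness is degenerate (0)")
    return(0)
  }
  pred <- -as.numeric(forward_project(J, chi_pred)) # positive subtracted signal
  pm <- max(pred)
  if (pm > 0) pred <- pred / pm
  meas <- as.numeric(M_meas)
  mm <- max(meas)
  if (mm > 0) meas <- meas / mm
  mean((pred[keep] - meas[keep])^2)
}

#' Mean-squared-error loss
#'
#' @param chi_pred,G Equal-shaped images.
#' @return Mean of squared pixel differences.
#' @export
mse_loss <- function(chi_pred, G) {
  if (!all(dim(as.matrix(chi_pred)) == dim(as.matrix(G)))) {
    stop("image shapes differ", call. = FALSE)
  }
  mean((as.numeric(chi_pred) - as.numeric(G))^2)
}

#' Dice loss
#'
#' One minus the Dice overlap coefficient
#' \eqn{2 \sum \chi G / (\sum \chi^2 + \sum G^2 + \epsilon)} with
#' \eqn{\epsilon = 10^{-8}}: 0 for identical nonzero images, 1 for disjoint
#' supports. Since the evolutionary cost is minimized, the complement of the
#' overlap coefficient is the quantity that rewards overlap.
#'
#' @param chi_pred,G Equal-shaped images with values in [0, 1].
#' @return Scalar in [0, 1].
#' @export
dice_loss <- function(chi_pred, G) {
  if (!all(dim(as.matrix(chi_pred)) == dim(as.matrix(G)))) {
    stop("image shapes differ", call. = FALSE)
  }
  x <- as.numeric(chi_pred)
  g <- as.numeric(G)
  1 - 2 * sum(x * g) / (sum(x^2) + sum(g^2) + 1e-8)
}

#' Composite fitness of a GP individual
#'
#' Reconstructs every sample in the batch with the sliding-window operator and
#' averages the weighted per-sample cost `alpha * xi_PI + beta * xi_mse +
#' gamma * xi_dice` (train mode) or `xi_PI` alone (test mode, where the ground
#' truth is never consulted). Lower is better.
#'
#' @param tree A GP tree.
#' @param samples List of samples, each a list with `measurement` (a
#'   [simulate_measurement()] object) and, in train mode, `anomaly`.
#' @param J The shared sensitivity matrix.
#' @param weights A [fitness_weights()] object.
#' @param patch_width Neighborhood side N (default 5).
#' @return Scalar cost F.
#' @export
combined_fitness <- function(tree, samples, J, weights = fitness_weights(),
                             patch_width = 5) {
  vals <- vapply(samples, function(s) {
    m <- s$measurement
    chi <- reconstruct_image(tree, m$M_sub, patch_width)
    f <- weights$alpha * physics_fitness(chi, J, m$M_sub, m$snr_mask)
    if (weights$beta > 0 || weights$gamma > 0) {
      if (is.null(s$anomaly)) {
        stop("ground truth required in train mode", call. = FALSE)
      }
      g <- s$anomaly$contrast
      if (weights$beta > 0) f <- f + weights$beta * mse_loss(chi, g)
      if (weights$gamma > 0) f <- f + weights$gamma * dice_loss(chi, g)
    }
    f
  }, numeric(1))
  mean(vals)
}
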