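#' Image-quality metrics: MSE, SSIM, PCC
#'
#' Mean squared error, structural similarity index (Gaussian window of side 11
#' and sd 1.5, stability constants K1 = 0.01 and K2 = 0.03, data range 1) and
#' the Pearson correlation of the flattened pixels. PCC is undefined (NA) when
#' the reference image is constant.
#'
#' @param chi Reconstructed image.
#' @param G Reference (ground-truth) image of the same shape.
#' @return A one-row tibble with columns `mse`, `ssim`, `pcc`.
#' @examples
#' g <- matrix(runif(64), 8, 8)
#' image_metrics(g, g) # (0, 1, 1)
#' @export
image_metrics <- function(chi, G) {
  chi <- as.matrix(chi); G <- as.matrix(G)
  if (!all(dim(chi) == dim(G))) stop("image shapes differ", call. = FALSE)
  pcc <- if (stats::sd(as.numeric(G)) == 0 || stats::sd(as.numeric(chi)) == 0) {
    NA_real_
  } else {
    stats::cor(as.numeric(chi), as.numeric(G))
  }
  tibble::tibble(
    mse = mean((as.numeric(chi) - as.numeric(G))^2),
    ssim = ssim_index(chi, G),
    pcc = pcc
  )
}

# 1-D sampled Gaussian window, normalized to sum 1.
gaussian_window <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# Valid-region separable 2-D weighted filtering via banded matrices:
# out = Br %*% M %*% t(Bc), each band holding the window.
band_matrix <- function(n_in, g) {
  k <- length(g)
  n_out <- n_in - k + 1
  B <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) B[i, i:(i + k - 1)] <- g
  B
}

filter_valid <- function(M, g) {
  Br <- band_matrix(nrow(M), g)
  Bc <- band_matrix(ncol(M), g)
  Br %*% M %*% t(Bc)
}

#' Structural similarity index
#'
#' Mean SSIM over the valid filtering region, computed with Gaussian-weighted
#' local moments (window side `win_size`, sd `sigma`) and the standard
#' stability constants \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2} for data
#' range L.
#'
#' @param x,y Equal-shaped image matrices.
#' @param data_range Dynamic range L (default 1 for [0, 1] images).
#' @param win_size,sigma Gaussian window parameters (defaults 11 and 1.5).
#' @param K1,K2 Stability constants.
#' @return Scalar SSIM in [-1, 1].
#' @export
ssim_index <- function(x, y, data_range = 1, win_size = 11, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("image shapes differ", call. = FALSE)
  if (any(dim(x) < win_size)) {
    stop(sprintf("images must be at least %d x %d", win_size, win_size),
         call. = FALSE)
  }
  g <- gaussian_window(win_size, sigma)
  mx <- filter_valid(x, g)
  my <- filter_valid(y, g)
  sxx <- filter_valid(x * x, g) - mx^2
  syy <- filter_valid(y * y, g) - my^2
  sxy <- filter_valid(x * y, g) - mx * my
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  ssim_map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(ssim_map)
}
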