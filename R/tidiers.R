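#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the evolution history of a fit
#'
#' @param x A `digp_fit`.
#' @param ... Unused.
#' @return A tibble with `generation`, `best`, `mean`, `best_so_far` costs.
#' @method tidy digp_fit
#' @export
tidy.digp_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `digp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: final cost, generations, population size, and the
#'   size/depth of the best tree.
#' @method glance digp_fit
#' @export
glance.digp_fit <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    generations = x$config$generations,
    pop_size = x$config$pop_size,
    tree_nodes = tree_size(x$best_tree),
    tree_depth = tree_depth(x$best_tree),
    seed = x$config$seed
  )
}

#' Per-sample metrics of a reconstruction report
#'
#' @param x A `digp_report`.
#' @param ... Unused.
#' @return The per-sample metrics tibble.
#' @method tidy digp_report
#' @export
tidy.digp_report <- function(x, ...) x$metrics

#' Aggregated report summary
#'
#' @param x A `digp_report`.
#' @param ... Unused.
#' @return A one-row tibble of metric means and standard deviations
#'   (value +/- sd reporting style).
#' @method glance digp_report
#' @export
glance.digp_report <- function(x, ...) {
  m <- x$metrics
  out <- tibble::tibble(method = x$method, n_samples = nrow(m),
                        test_fitness = mean(m$test_fitness))
  if ("mse" %in% names(m)) {
    out <- dplyr::bind_cols(out, tibble::tibble(
      mse = mean(m$mse), mse_sd = stats::sd(m$mse),
      ssim = mean(m$ssim), ssim_sd = stats::sd(m$ssim),
      pcc = mean(m$pcc, na.rm = TRUE), pcc_sd = stats::sd(m$pcc, na.rm = TRUE)
    ))
  }
  out
}

#' Dataset manifest
#'
#' @param x A `digp_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per sample: shape kind, contrast, support
#'   fraction, noise sd, SNR-retained pixel count, split and seed.
#' @method tidy digp_dataset
#' @export
tidy.digp_dataset <- function(x, ...) {
  purrr::map_dfr(seq_along(x$samples), function(i) {
    s <- x$samples[[i]]
    tibble::tibble(
      sample = i,
      shape_kind = s$anomaly$shape_kind,
      contrast = s$anomaly$contrast_value,
      support_frac = mean(s$anomaly$contrast > 0),
      sigma_n = s$measurement$sigma_n,
      snr_pixels = sum(s$measurement$snr_mask),
      split = if (i %in% x$test_idx) "test" else "train",
      seed = s$anomaly$seed
    )
  })
}
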