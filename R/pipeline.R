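#' Train the genetic-programming reconstructor
#'
#' Runs the evolutionary loop over the dataset's training split with the
#' composite train-mode fitness. Thin orchestration over [evolve()].
#'
#' @param dataset A [build_dataset()] object.
#' @param config An [evolution_config()].
#' @param weights A [fitness_weights()] (train mode).
#' @param verbose Print per-generation progress.
#' @return A `digp_fit` (see [evolve()]).
#' @export
train_digp <- function(dataset, config = evolution_config(),
                       weights = fitness_weights(), verbose = FALSE) {
  evolve(dataset, config, weights, verbose = verbose)
}

#' Apply a trained individual to measurements
#'
#' Reconstructs every sample with the sliding-window operator, scores it with
#' the test-mode physics fitness (no ground truth consulted), and — when
#' ground truth is available — also reports MSE/SSIM/PCC per sample.
#'
#' @param fit A `digp_fit` or a bare GP tree.
#' @param samples A `digp_dataset` (its test split is used), or a list of
#'   samples (each a list with `measurement` and optionally `anomaly`).
#' @param J Sensitivity matrix; taken from the dataset when omitted.
#' @param patch_width Neighborhood side N.
#' @return An object of class `digp_report`: list with `method`,
#'   `reconstructions` (list of [0,1] matrices), `metrics` (tibble with one
#'   row per sample: `sample`, `test_fitness`, and `mse`/`ssim`/`pcc` when
#'   truth was available), `tree` (s-expression), `config` provenance.
#' @export
test_digp <- function(fit, samples, J = NULL, patch_width = NULL) {
  tree <- if (inherits(fit, "digp_fit")) fit$best_tree else fit
  if (is.null(patch_width)) {
    patch_width <- if (inherits(fit, "digp_fit")) fit$config$patch_width else 5
  }
  if (inherits(samples, "digp_dataset")) {
    if (is.null(J)) J <- samples$J
    samples <- samples$samples[samples$test_idx]
  }
  if (is.null(J)) stop("supply `J` when `samples` is not a dataset", call. = FALSE)

  recons <- vector("list", length(samples))
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    m <- samples[[i]]$measurement
    chi <- reconstruct_image(tree, m$M_sub, patch_width)
    recons[[i]] <- chi
    tf <- physics_fitness(chi, J, m$M_sub, m$snr_mask)
    row <- tibble::tibble(sample = i, test_fitness = tf)
    if (!is.null(samples[[i]]$anomaly)) {
      row <- dplyr::bind_cols(row, image_metrics(chi, samples[[i]]$anomaly$contrast))
    }
    rows[[i]] <- row
  }
  structure(
    list(method = "digp", reconstructions = recons,
         metrics = dplyr::bind_rows(rows),
         tree = serialize_tree(tree),
         provenance = list(patch_width = patch_width)),
    class = "digp_report"
  )
}

#' Analytical baseline reconstructions
#'
#' Runs the conjugate-gradient Tikhonov solve ([cgd_baseline()]) on each
#' sample's reference-subtracted measurement, max-normalizes and clips each
#' solution to [0, 1] for reporting, and scores it like [test_digp()].
#'
#' @param samples A `digp_dataset` (its test split is used) or a list of
#'   samples.
#' @param J Sensitivity matrix (signed as built: absorption reduces flux);
#'   taken from the dataset when omitted.
#' @param delta,max_iters,tol Passed to [cgd_baseline()].
#' @return A `digp_report` with `method = "cgd"`.
#' @export
reconstruct_cgd <- function(samples, J = NULL, delta = NULL,
                            max_iters = 200, tol = 1e-6) {
  if (inherits(samples, "digp_dataset")) {
    if (is.null(J)) J <- samples$J
    samples <- samples$samples[samples$test_idx]
  }
  if (is.null(J)) stop("supply `J` when `samples` is not a dataset", call. = FALSE)
  Jpos <- -jacobian_entries(J) # M_sub is reference-minus-raw: positive signal
  recons <- vector("list", length(samples))
  rows <- vector("list", length(samples))
  used_delta <- NA_real_
  for (i in seq_along(samples)) {
    m <- samples[[i]]$measurement
    chi <- cgd_baseline(Jpos, m$M_sub, delta = delta,
                        max_iters = max_iters, tol = tol)
    used_delta <- attr(chi, "delta")
    top <- max(chi)
    if (top > 0) chi <- chi / top
    chi <- pmin(pmax(chi, 0), 1)
    recons[[i]] <- chi
    tf <- physics_fitness(chi, J, m$M_sub, m$snr_mask)
    row <- tibble::tibble(sample = i, test_fitness = tf)
    if (!is.null(samples[[i]]$anomaly)) {
      row <- dplyr::bind_cols(row, image_metrics(chi, samples[[i]]$anomaly$contrast))
    }
    rows[[i]] <- row
  }
  structure(
    list(method = "cgd", reconstructions = recons,
         metrics = dplyr::bind_rows(rows),
         provenance = list(delta = used_delta, max_iters = max_iters, tol = tol)),
    class = "digp_report"
  )
}

#' @export
print.digp_report <- function(x, ...) {
  cat(sprintf("<digp_report> method '%s', %d samples\n",
              x$method, length(x$reconstructions)))
  if ("mse" %in% names(x$metrics)) {
    cat(sprintf("  MSE %.4f +/- %.4f  SSIM %.4f  PCC %.4f\n",
                mean(x$metrics$mse), stats::sd(x$metrics$mse),
                mean(x$metrics$ssim), mean(x$metrics$pcc, na.rm = TRUE)))
  }
  invisible(x)
}

#' Improvement ratios between two reconstruction reports
#'
#' Per-metric ratio `Lambda = metric(method 1) / metric(method 2)` of the
#' mean MSE, SSIM and PCC over identical samples. A ratio below 1 on MSE and
#' above 1 on SSIM/PCC means the first method improves on the second.
#'
#' @param report_a,report_b `digp_report` objects scored with ground truth on
#'   the same samples (conventionally the GP report first, baseline second).
#' @return A tibble with columns `metric`, the two methods' means and `ratio`.
#' @export
compare_methods <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "digp_report"), inherits(report_b, "digp_report"))
  need <- c("mse", "ssim", "pcc")
  if (!all(need %in% names(report_a$metrics)) ||
      !all(need %in% names(report_b$metrics))) {
    stop("both reports must carry ground-truth metrics", call. = FALSE)
  }
  if (nrow(report_a$metrics) != nrow(report_b$metrics)) {
    stop("reports were not scored on identical samples", call. = FALSE)
  }
  a <- colMeans(report_a$metrics[need], na.rm = TRUE)
  b <- colMeans(report_b$metrics[need], na.rm = TRUE)
  ratio <- ifelse(b == 0, NA_real_, a / b)
  if (any(b == 0)) warning("zero denominator: undefined improvement ratio flagged as NA")
  out <- tibble::tibble(metric = need, a = as.numeric(a), b = as.numeric(b),
                        ratio = as.numeric(ratio))
  names(out)[2:3] <- make.unique(c(report_a$method, report_b$method))
  out
}
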