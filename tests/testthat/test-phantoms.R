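test_that("anomaly generation is seeded and rasterizes sensible shapes", {
  a1 <- generate_anomaly(7, "disc", c(64, 64))
  a2 <- generate_anomaly(7, "disc", c(64, 64))
  expect_identical(a1$contrast, a2$contrast)
  supp <- mean(a1$contrast > 0)
  expect_gte(supp, 0.01)
  expect_lte(supp, 0.25)
  # support bounds hold across seeds and shapes
  for (s in 1:25) {
    a <- generate_anomaly(s, "random", c(64, 64))
    expect_gte(mean(a$contrast > 0), 0.005)
    expect_lte(mean(a$contrast > 0), 0.30)
    expect_true(all(a$contrast >= 0 & a$contrast <= 1))
  }
  expect_error(generate_anomaly(1, "hexagon"), "unknown shape_kind")
  expect_error(generate_anomaly(1, grid = c(8, 8)), "at least 16")
})

test_that("anomaly contrast spans [0.25, 1] and maps to the printed mu_a range", {
  vals <- vapply(1:100, function(s) generate_anomaly(s)$contrast_value,
                 numeric(1))
  expect_gte(min(vals), 0.25)
  expect_lte(max(vals), 1)
  expect_lt(min(vals), 0.35) # the sweep reaches both ends of the range
  expect_gt(max(vals), 0.9)
  a <- generate_anomaly(3, "disc")
  on <- a$contrast > 0
  expect_equal(a$mu_a_map[on], 0.5 + a$contrast[on] * 0.22)
  expect_true(all(a$mu_a_map[on] >= 0.5 & a$mu_a_map[on] <= 0.72))
  expect_true(all(a$mu_a_map[!on] == 0))
})

test_that("SNR mask keeps pixels at or above the threshold only", {
  m <- matrix(c(3, 2.999, 0, 6), 2, 2)
  mask <- compute_snr_mask(m, sigma_n = 1, thr = 3)
  expect_equal(as.numeric(mask), c(1, 0, 0, 1)) # exactly 3*sigma is retained
  expect_equal(compute_snr_mask(m, 1, thr = 0), matrix(1, 2, 2))
  expect_error(compute_snr_mask(m, 0), "positive")
  # monotone in thr: raising the threshold never adds pixels
  img <- matrix(withr::with_seed(4, stats::rexp(64)), 8, 8)
  prev <- compute_snr_mask(img, 0.3, 0)
  for (thr in c(1, 2, 3, 5, 10)) {
    cur <- compute_snr_mask(img, 0.3, thr)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("measurement simulation follows the stated noise model", {
  J <- small_jacobian()
  # noiseless null: no anomaly, no noise
  z <- matrix(0, 16, 16)
  m0 <- simulate_measurement(J, z, noise_level = 0, seed = 1)
  expect_equal(m0$M_raw, m0$M_ref)
  expect_true(all(m0$M_sub == 0))
  # 2% noise: residual sd within 10% of 0.02 * max(M_ref) (64 x 64 pixels)
  Jf <- full_jacobian()
  a <- generate_anomaly(5, "cross", c(64, 64))
  mm <- simulate_measurement(Jf, a, noise_level = 0.02, seed = 8)
  chi <- pmax(a$mu_a_map - 0.0035, 0)
  resid <- mm$M_raw - mm$M_ref - forward_project(Jf, chi)
  expect_lt(abs(stats::sd(resid) / (0.02 * max(mm$M_ref)) - 1), 0.1)
  expect_lt(abs(mm$sigma_n / (0.02 * max(mm$M_ref)) - 1), 0.1)
  # stronger contrast gives a larger unnormalized subtracted peak
  s1 <- matrix(0, 16, 16); s1[6:10, 6:10] <- 0.5
  s2 <- matrix(0, 16, 16); s2[6:10, 6:10] <- 0.72
  p1 <- simulate_measurement(J, s1, noise_level = 0, seed = 1)
  p2 <- simulate_measurement(J, s2, noise_level = 0, seed = 1)
  expect_gt(p2$sub_scale, p1$sub_scale)
  expect_error(simulate_measurement(J, z, noise_level = -0.1), "non-negative")
})

test_that("datasets are reproducible, split and forward-consistent", {
  ds <- small_dataset()
  expect_length(ds$samples, 6)
  expect_gte(length(ds$test_idx), ceiling(0.2 * 6))
  expect_length(intersect(ds$train_idx, ds$test_idx), 0)
  ds2 <- build_dataset(n = 6, master_seed = 11, props = paper_optics(),
                       geom = small_geom(), J = small_jacobian())
  expect_identical(tidy(ds), tidy(ds2))
  expect_identical(ds$samples[[3]]$measurement$M_raw,
                   ds2$samples[[3]]$measurement$M_raw)
  # forward projection of the ground truth reproduces the measurement up to
  # the injected noise
  for (s in ds$samples) {
    chi <- pmax(s$anomaly$mu_a_map - 0.0035, 0)
    resid <- s$measurement$M_raw - s$measurement$M_ref -
      forward_project(ds$J, chi)
    nominal <- 0.02 * max(s$measurement$M_ref)
    expect_lt(stats::sd(resid), 2 * nominal)
  }
  expect_error(build_dataset(n = 1, master_seed = 1), "at least 2")
})

test_that("full datasets cycle shape kinds on 64 x 64 grids", {
  ds <- full_dataset()
  expect_length(ds$samples, 30)
  expect_true(all(vapply(ds$samples, function(s)
    all(dim(s$measurement$M_sub) == c(64, 64)), logical(1))))
  kinds <- vapply(ds$samples, function(s) s$anomaly$shape_kind, character(1))
  expect_gte(length(unique(kinds)), 4)
  expect_length(ds$test_idx, 6)
  expect_length(ds$train_idx, 24)
})

test_that("samples persist as 16-bit rasters with JSON sidecars", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  write_sample(ds$samples[[1]], dir, "s1")
  expect_true(file.exists(file.path(dir, "s1_measurement.tiff")))
  expect_true(file.exists(file.path(dir, "s1_truth.tiff")))
  side <- jsonlite::read_json(file.path(dir, "s1.json"))
  expect_equal(side$shape_kind, ds$samples[[1]]$anomaly$shape_kind)
  back <- load_measurement(file.path(dir, "s1_truth.tiff"),
                           target_size = c(16, 16), normalize = FALSE)
  expect_equal(back, ds$samples[[1]]$anomaly$contrast, tolerance = 1e-4)
})
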