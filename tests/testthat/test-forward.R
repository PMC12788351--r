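test_that("sensitivity matrix agrees with a brute-force assembly on a toy grid", {
  op <- paper_optics()
  geom <- slab_geometry(grid = c(4, 4), pixel_pitch = 60 / 4)
  J <- build_jacobian(op, geom)
  # independent assembly: explicit loops over detector/object pixels and
  # source points, scalar flux evaluations
  src <- digp:::source_points(geom)
  p <- geom$pixel_pitch
  xs <- (seq_len(4) - 2.5) * p
  coords <- expand.grid(y = xs, x = xs) # column-major: rows vary fastest
  Jref <- matrix(0, 16, 16)
  for (d in 1:16) {
    for (v in 1:16) {
      phi_src <- 0
      for (k in seq_along(src$x)) {
        r_sv <- sqrt((coords$x[v] - src$x[k])^2 + (coords$y[v] - src$y[k])^2 +
                       geom$anomaly_depth^2)
        phi_src <- phi_src + src$w[k] * point_source_flux(op, r_sv)
      }
      r_vd <- sqrt((coords$x[v] - coords$x[d])^2 + (coords$y[v] - coords$y[d])^2 +
                     (geom$thickness - geom$anomaly_depth)^2)
      green <- exp(-op$mu_eff * r_vd) / (4 * pi * op$D * r_vd)
      Jref[d, v] <- -phi_src * green * geom$voxel_volume
    }
  }
  expect_equal(J$entries, Jref, tolerance = 1e-12)
  # forward projection equals the dense matrix-vector product
  chi <- matrix(withr::with_seed(3, stats::runif(16)), 4, 4)
  expect_equal(as.numeric(forward_project(J, chi)),
               as.numeric(Jref %*% as.numeric(chi)))
})

test_that("sensitivity entries are non-positive and strongest on axis", {
  J <- small_jacobian()
  expect_true(all(J$entries <= 0))
  expect_true(all(is.finite(J$entries)))
  n <- J$geom$grid[1]
  center_pix <- (n / 2 - 1) * n + n / 2 # near-axis pixel (column-major)
  corner_pix <- 1
  # detector pixel on axis: voxel below the source center beats an off-axis
  # voxel at the same depth
  expect_gt(abs(J$entries[center_pix, center_pix]),
            abs(J$entries[center_pix, corner_pix]))
})

test_that("the Jacobian respects the slab's mirror symmetry", {
  J <- small_jacobian()$entries
  n <- small_geom()$grid[1]
  # reflect rows of the image about the horizontal axis => permutation of
  # flattened indices; the homogeneous slab with a centered source is invariant
  idx <- as.vector(matrix(seq_len(n * n), n, n)[n:1, ])
  expect_equal(J, J[idx, idx], tolerance = 1e-12)
})

test_that("forward projection is linear and shape-checked", {
  J <- small_jacobian()
  n <- prod(small_geom()$grid)
  z <- matrix(0, 16, 16)
  expect_true(all(forward_project(J, z) == 0))
  m0 <- reference_measurement(paper_optics(), small_geom())
  expect_equal(forward_project(J, z, M0 = m0), m0)
  c1 <- withr::with_seed(1, matrix(stats::runif(n), 16, 16))
  c2 <- withr::with_seed(2, matrix(stats::runif(n), 16, 16))
  expect_equal(forward_project(J, c1 + c2),
               forward_project(J, c1) + forward_project(J, c2))
  # single-pixel perturbation reads out one Jacobian column
  v <- 37
  e <- matrix(0, 16, 16); e[v] <- 1
  expect_equal(as.numeric(forward_project(J, e)), J$entries[, v])
  expect_error(forward_project(J, matrix(0, 4, 4)), "pixels")
  expect_error(forward_project(J, z, M0 = matrix(0, 2, 2)), "detector")
})

test_that("degenerate geometry is rejected", {
  expect_error(slab_geometry(anomaly_depth = 40), "inside the slab")
  expect_error(slab_geometry(anomaly_depth = 0), "inside the slab")
  expect_error(slab_geometry(pixel_pitch = 0), "positive")
  expect_error(slab_geometry(grid = c(0, 10)), "positive integers")
  expect_error(slab_geometry(grid = c(128, 128), pixel_pitch = 1),
               "exceeds the slab width")
})

test_that("a sensitivity matrix survives a disk round trip with its header", {
  op <- paper_optics()
  geom <- slab_geometry(grid = c(4, 4), pixel_pitch = 15)
  J <- build_jacobian(op, geom)
  path <- file.path(withr::local_tempdir(), "jacobian.tsv")
  write_jacobian(J, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  back <- read_jacobian(path)
  expect_equal(back$entries, J$entries, tolerance = 1e-12)
  expect_equal(back$header$mu_a, 0.0035)
  expect_equal(unlist(back$header$shape), c(16L, 16L))
})

test_that("reference measurement is positive, symmetric and source-peaked", {
  m <- reference_measurement(paper_optics(), small_geom())
  expect_true(all(m > 0))
  expect_equal(m, m[16:1, ], tolerance = 1e-12) # mirror symmetry
  expect_true(which.max(m) %in% c(120, 121, 136, 137)) # the four central pixels
})
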