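# Shared fixtures and independent reference implementations for the suite.
# Heavy objects (the 64x64 sensitivity matrix and the 30-sample dataset) are
# built once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

paper_optics <- function() optical_properties(0.0035, 0.8090)

# Small geometry for fast unit tests: 16 x 16 grids on the default slab.
small_geom <- function() slab_geometry(grid = c(16, 16), pixel_pitch = 60 / 16)

small_jacobian <- function() {
  if (is.null(.fixtures$J_small)) {
    .fixtures$J_small <- build_jacobian(paper_optics(), small_geom())
  }
  .fixtures$J_small
}

small_dataset <- function() {
  if (is.null(.fixtures$ds_small)) {
    .fixtures$ds_small <- build_dataset(
      n = 6, master_seed = 11, props = paper_optics(), geom = small_geom(),
      J = small_jacobian()
    )
  }
  .fixtures$ds_small
}

# Full-size study fixtures (64 x 64, 30 samples) shared by the acceptance
# blocks so the Jacobian is assembled only once.
full_jacobian <- function() {
  if (is.null(.fixtures$J_full)) {
    .fixtures$J_full <- build_jacobian(paper_optics(), slab_geometry())
  }
  .fixtures$J_full
}

full_dataset <- function() {
  if (is.null(.fixtures$ds_full)) {
    .fixtures$ds_full <- build_dataset(
      n = 30, master_seed = 1, props = paper_optics(), geom = slab_geometry(),
      J = full_jacobian()
    )
  }
  .fixtures$ds_full
}

# ---------------------------------------------------------------------------
# Naive scalar GP-tree interpreter: an independent oracle for the compiled
# evaluator. Works on one patch at a time with plain scalar arithmetic.
naive_eval_raw <- function(tree, patch) {
  rec <- function(node) {
    if (node$type == "pix") return(patch[node$k])
    if (node$type == "const") return(node$value)
    a <- vapply(node$args, rec, numeric(1))
    switch(node$name,
      Add = a[1] + a[2],
      Subtract = a[1] - a[2],
      Multiply = a[1] * a[2],
      ProtectedDivision = if (abs(a[2]) < 1e-12) 1 else a[1] / a[2],
      Minus = -a[1],
      Square = a[1]^2,
      Tri = a[1]^3,
      SquareRoot = sign(a[1]) * sqrt(abs(a[1])),
      Complement = 1 - a[1],
      Min3 = min(a), Min6 = min(a), Min9 = min(a),
      Max3 = max(a), Max6 = max(a), Max9 = max(a),
      If_Then_Else = if (isTRUE(a[1] > 0.5)) a[2] else a[3],
      If_Larger = if (isTRUE(a[1] > a[2])) a[3] else a[4],
      If_In_Range = if (isTRUE(a[2] <= a[1] && a[1] < a[3])) a[4] else a[5],
      stop("unknown op in naive interpreter: ", node$name)
    )
  }
  rec(tree)
}

naive_eval <- function(tree, patch) {
  v <- naive_eval_raw(tree, patch)
  if (is.na(v)) v <- 0
  min(max(v, 0), 1)
}

# ---------------------------------------------------------------------------
# Naive SSIM: direct per-window loops over every valid 11 x 11 neighborhood,
# Gaussian-weighted moments, standard constants. Independent of the banded
# matrix-product implementation in the package.
naive_ssim <- function(x, y, data_range = 1, win = 11, sigma = 1.5) {
  r <- (win - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  nr <- nrow(x) - win + 1
  nc <- ncol(x) - win + 1
  total <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      xi <- x[i:(i + win - 1), j:(j + win - 1)]
      yi <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(w * xi); my <- sum(w * yi)
      vx <- sum(w * xi^2) - mx^2
      vy <- sum(w * yi^2) - my^2
      cxy <- sum(w * xi * yi) - mx * my
      total <- total + ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  }
  total / (nr * nc)
}

# Random tree helper with a seeded RNG stream.
seeded_random_tree <- function(seed, min_d = 1, max_d = 4) {
  withr::with_seed(seed, {
    random_tree(gp_primitives(), min_d, sample(min_d:max_d, 1),
                sample(c("grow", "full"), 1))
  })
}
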