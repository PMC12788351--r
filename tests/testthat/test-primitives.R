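test_that("primitive semantics match their definitions exactly", {
  fns <- gp_primitives()$functions
  f <- function(name, ...) fns[[name]]$fun(list(...))
  expect_identical(f("Add", 0.2, 0.3), 0.5)
  expect_equal(f("Subtract", 0.2, 0.3), -0.1)
  expect_identical(f("Multiply", 0.5, 0.5), 0.25)
  expect_identical(f("ProtectedDivision", 1, 4), 0.25)
  expect_identical(f("ProtectedDivision", 0.7, 0), 1)       # guarded
  expect_identical(f("ProtectedDivision", 0.7, 1e-13), 1)   # |den| < 1e-12
  expect_identical(f("Minus", 0.4), -0.4)
  expect_identical(f("Square", -0.5), 0.25)
  expect_identical(f("Tri", 0.5), 0.125)
  expect_identical(f("SquareRoot", -0.25), -0.5)            # signed root
  expect_identical(f("SquareRoot", 0.25), 0.5)
  expect_identical(f("Complement", 0.3), 0.7)
  expect_identical(f("Min3", 3, 1, 2), 1)
  expect_identical(f("Max3", 3, 1, 2), 3)
  expect_identical(f("Min9", 9, 8, 7, 6, 5, 4, 3, 2, 1), 1)
  expect_identical(f("Max6", 1, 2, 6, 4, 5, 3), 6)
  expect_identical(f("If_Then_Else", 0.6, 10, 20), 10)      # x > 0.5 takes y
  expect_identical(f("If_Then_Else", 0.5, 10, 20), 20)      # boundary is else
  expect_identical(f("If_Larger", 2, 1, 10, 20), 10)
  expect_identical(f("If_Larger", 1, 1, 10, 20), 20)
  expect_identical(f("If_In_Range", 0.5, 0.5, 1, 10, 20), 10) # y <= x < z
  expect_identical(f("If_In_Range", 1, 0.5, 1, 10, 20), 20)   # x = z excluded
  # arity bookkeeping: MinK/MaxK arity equals the suffix
  expect_equal(fns$Min3$arity, 3L)
  expect_equal(fns$Min6$arity, 6L)
  expect_equal(fns$Max9$arity, 9L)
  expect_equal(fns$If_In_Range$arity, 5L)
})

test_that("tree evaluation clips only the root and is total", {
  patch <- matrix(0.5, 5, 5)
  expect_equal(eval_tree(parse_tree("0.75"), patch), 0.75)
  # Minus(Square(Pixel1)) at 0.5: raw -0.25 clips to 0
  expect_equal(eval_tree(parse_tree("(Minus (Square Pixel1))"), patch), 0)
  expect_equal(eval_tree(parse_tree("(ProtectedDivision Pixel1 0.0)"), patch), 1)
  expect_error(eval_tree(parse_tree("Pixel1"), matrix(0.5, 4, 4)), "5 x 5")
  expect_error(eval_tree(parse_tree("Pixel1"), rep(0.5, 24)), "25 values")
  # patches are read row-major: Pixel2 is row 1, column 2
  p <- matrix(0, 5, 5); p[1, 2] <- 0.9
  expect_equal(eval_tree(parse_tree("Pixel2"), p), 0.9)
  expect_equal(eval_tree(parse_tree("Pixel6"), p), 0)  # row 2, column 1
  # totality: no NaN/Inf escapes over random trees and patches
  for (s in 1:200) {
    tr <- seeded_random_tree(s)
    pv <- withr::with_seed(1000 + s, stats::runif(25))
    v <- eval_tree(tr, pv)
    expect_true(is.finite(v) && v >= 0 && v <= 1)
  }
})

test_that("compiled and pure-R evaluators agree bitwise", {
  P <- withr::with_seed(99, matrix(stats::runif(50 * 25), 50, 25))
  for (s in 1:300) {
    tr <- seeded_random_tree(s, min_d = 1, max_d = 5)
    expect_identical(digp:::eval_tree_matrix(tr, P),
                     as.numeric(digp:::eval_tree_matrix_r(tr, P)))
  }
})

test_that("serialization round-trips and the parser rejects malformed input", {
  expect_equal(serialize_tree(parse_tree("(Compl Pixel1)")),
               "(Complement Pixel1)")
  for (s in 1:100) {
    tr <- seeded_random_tree(s)
    txt <- serialize_tree(tr)
    expect_identical(serialize_tree(parse_tree(txt)), txt)
  }
  # rendered-tree aliases are accepted
  ali <- parse_tree("(if.then.else (sqr Pixel3) (pDiv Pixel1 Pixel2) (min3 0.25 Pixel4 (max9 1 2 3 4 5 6 7 8 9)))")
  expect_equal(ali$name, "If_Then_Else")
  expect_error(parse_tree("(bogus 1 2)"), "bogus")
  expect_error(parse_tree("(Add Pixel1)"), "expects 2")
  expect_error(parse_tree("(Add Pixel1 Pixel2"), "missing ')'")
  expect_error(parse_tree("(Add Pixel1 Pixel2) junk"), "trailing")
  expect_error(parse_tree("Pixel99"), "out of range")
  expect_error(parse_tree(""), "empty")
})

test_that("the shipped synthetic evolved individual parses and reconstructs", {
  p <- system.file("extdata", "synthetic_evolved_individual.sexp",
                   package = "digp")
  expect_true(nzchar(p))
  tr <- parse_tree(readLines(p, warn = FALSE))
  expect_equal(tr$name, "If_Then_Else")
  M <- withr::with_seed(5, matrix(stats::runif(32 * 32), 32, 32))
  out <- reconstruct_image(tr, M)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out[1:2, ] == 0))
})

test_that("random trees respect depth constraints by construction", {
  prims <- gp_primitives()
  withr::with_seed(7, {
    for (i in 1:50) {
      tf <- random_tree(prims, 3, 5, "full")
      tg <- random_tree(prims, 3, 5, "grow")
      expect_gte(tree_depth(tf), 3)
      expect_lte(tree_depth(tf), 5)
      expect_gte(tree_depth(tg), 3)
      expect_lte(tree_depth(tg), 5)
    }
  })
})
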