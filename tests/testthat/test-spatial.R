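# Geometric substrate: grids, resampling, composition, upsampling.

test_that("identity grid maps corners to exactly +/-1 and centres to 0", {
  g <- makeIdentityGrid(c(2L, 2L))
  expect_equal(sort(unique(as.vector(gridCoords(g)))), c(-1, 1))
  g3 <- makeIdentityGrid(c(3L, 3L))
  expect_identical(gridCoords(g3)[5, ], c(Var1 = 0, Var2 = 0),
                   ignore_attr = TRUE)
  g45 <- makeIdentityGrid(c(4L, 5L))
  expect_identical(unname(gridCoords(g45)[1, ]), c(-1, -1))
  expect_identical(unname(gridCoords(g45)[20, ]), c(1, 1))
  # strictly increasing along each axis
  expect_true(all(diff(gridCoords(g45)[1:4, 1]) > 0))
  expect_error(makeIdentityGrid(c(1L, 4L)), "degenerate")
})

test_that("affineToGrid applies A p + t and matches a per-point oracle", {
  shape <- c(5L, 5L)
  expect_equal(gridCoords(affineToGrid(identityAffine(2), shape)),
               gridCoords(makeIdentityGrid(shape)), ignore_attr = TRUE)
  tr <- AffineParams(cbind(diag(2), c(0.1, 0)))
  expect_equal(gridCoords(affineToGrid(tr, shape)),
               gridCoords(makeIdentityGrid(shape)) +
                 matrix(rep(c(0.1, 0), each = 25), 25),
               ignore_attr = TRUE)
  set.seed(7)
  A <- matrix(rnorm(6, sd = 0.4), 2, 3) + cbind(diag(2), c(0, 0))
  expect_lt(max(abs(gridCoords(affineToGrid(AffineParams(A), shape)) -
                      affineOracle(A, shape))), 1e-12)
  expect_error(affineToGrid(AffineParams(cbind(diag(3), rep(0, 3))), shape),
               "dimensionality")
})

test_that("linear resampling at the identity grid reproduces the input", {
  set.seed(1)
  x <- ImageVolume(matrix(runif(64, -1, 1), 8, 8))
  out <- resampleImage(x, makeIdentityGrid(c(8L, 8L)), "linear")
  expect_identical(imageValues(out), imageValues(x))
  x3 <- ImageVolume(array(runif(4 * 4 * 4, -1, 1), c(4, 4, 4)))
  expect_identical(
    imageValues(resampleImage(x3, makeIdentityGrid(c(4L, 4L, 4L)))),
    imageValues(x3))
})

test_that("resampling matches the scalar bilinear oracle and preserves constants", {
  set.seed(2)
  img <- matrix(runif(64, -1, 1), 8, 8)
  coords <- matrix(runif(2 * 40, -0.95, 0.95), 40, 2)
  grid <- new("CoordinateGrid", coords = coords, shape = c(8L, 5L))
  out <- synthreg:::.gs(matrix(as.vector(img), ncol = 1), c(8L, 8L), grid)
  expect_lt(max(abs(as.vector(out) - bilinearOracle(img, coords))), 1e-6)
  # constancy under any in-range grid
  cimg <- ImageVolume(matrix(0.4, 8, 8))
  warped <- resampleImage(cimg, grid <- affineToGrid(
    AffineParams(cbind(0.7 * diag(2), c(0.05, -0.1))), c(8L, 8L)))
  expect_lt(max(abs(imageValues(warped) - 0.4)), 1e-12)
  # nearest keeps original values
  lab <- matrix(sample.int(3L, 36, replace = TRUE), 6, 6)
  nn <- resampleImage(lab, affineToGrid(
    AffineParams(cbind(diag(2) * 0.9, c(0, 0))), c(6L, 6L)), "nearest")
  expect_true(all(nn %in% 1:3))
})

test_that("grid composition equals sequential warping at interior points", {
  # identity neutrality
  g <- affineToGrid(AffineParams(cbind(0.8 * diag(2), c(0.1, 0))), c(9L, 9L))
  id <- makeIdentityGrid(c(9L, 9L))
  expect_equal(gridCoords(composeGrids(id, g)), gridCoords(g),
               tolerance = 1e-12)
  expect_equal(gridCoords(composeGrids(g, id)), gridCoords(g),
               tolerance = 1e-12)
  # translations add
  t1 <- affineToGrid(AffineParams(cbind(diag(2), c(0.1, 0))), c(9L, 9L))
  t2 <- affineToGrid(AffineParams(cbind(diag(2), c(0.2, 0))), c(9L, 9L))
  t3 <- composeGrids(t1, t2)
  interior <- which(abs(gridCoords(id)[, 1]) < 0.6 &
                      abs(gridCoords(id)[, 2]) < 0.6)
  expect_lt(max(abs(gridCoords(t3)[interior, 1] -
                      (gridCoords(id)[interior, 1] + 0.3))), 1e-10)
  # composed-grid warp vs two sequential warps of a smooth image
  set.seed(3)
  img <- smoothImage(3, c(24L, 24L))
  f1 <- randomSmoothField(4, c(24L, 24L), amplitude = 0.06, smoothness = 4)
  f2 <- randomSmoothField(5, c(24L, 24L), amplitude = 0.06, smoothness = 4)
  id24 <- makeIdentityGrid(c(24L, 24L))
  g1 <- new("CoordinateGrid", coords = gridCoords(id24) + fieldValues(f1),
            shape = c(24L, 24L))
  g2 <- new("CoordinateGrid", coords = gridCoords(id24) + fieldValues(f2),
            shape = c(24L, 24L))
  seq2 <- resampleImage(resampleImage(img, g1), g2)
  once <- resampleImage(img, composeGrids(g1, g2))
  interior <- as.vector(matrix(seq_len(24 * 24), 24, 24)[5:20, 5:20])
  expect_lt(max(abs(imageValues(seq2)[interior] -
                      imageValues(once)[interior])), 2e-2)
  expect_error(composeGrids(makeIdentityGrid(c(4L, 4L, 4L)), id24),
               "dimensionality")
})

test_that("grid composition is associative within interpolation tolerance", {
  shape <- c(20L, 20L)
  id <- makeIdentityGrid(shape)
  mk <- function(seed) new("CoordinateGrid",
    coords = gridCoords(id) +
      fieldValues(randomSmoothField(seed, shape, 0.05, 4)),
    shape = shape)
  g1 <- mk(11); g2 <- mk(12); g3 <- mk(13)
  left <- composeGrids(composeGrids(g1, g2), g3)
  right <- composeGrids(g1, composeGrids(g2, g3))
  interior <- as.vector(matrix(seq_len(400), 20, 20)[5:16, 5:16])
  expect_lt(max(abs(gridCoords(left)[interior, ] -
                      gridCoords(right)[interior, ])), 2e-2)
})

test_that("field upsampling interpolates linearly and preserves constants", {
  cst <- DisplacementField(matrix(c(0.03, -0.02), 16, 2, byrow = TRUE),
                           c(4L, 4L))
  up <- upsampleField(cst, c(16L, 16L))
  expect_lt(max(abs(fieldValues(up) -
                      matrix(c(0.03, -0.02), 256, 2, byrow = TRUE))), 1e-12)
  z <- upsampleField(zeroField(c(4L, 4L)), c(13L, 17L))
  expect_identical(unique(as.vector(fieldValues(z))), 0)
  # a per-axis linear ramp stays an exact linear ramp at any resolution
  g0 <- makeIdentityGrid(c(5L, 5L))
  ramp <- DisplacementField(0.1 * gridCoords(g0), c(5L, 5L))
  up2 <- upsampleField(ramp, c(21L, 17L))
  expect_lt(max(abs(fieldValues(up2) -
                      0.1 * gridCoords(makeIdentityGrid(c(21L, 17L))))), 1e-10)
  expect_error(upsampleField(ramp, c(4L, 4L)), ">=")
})

test_that("composite transforms realise one composed grid and invert numerically", {
  aff <- AffineParams(cbind(diag(2) * 1.1, c(0.05, -0.02)))
  u <- randomSmoothField(21, c(16L, 16L), 0.04, 3)
  ct <- CompositeTransform(aff, u, "AB")
  g <- transformGrid(ct)
  expect_equal(gridCoords(g),
               gridCoords(affineToGrid(aff, c(16L, 16L))) + fieldValues(u),
               ignore_attr = TRUE)
  inv <- invertGrid(g)
  comp <- composeGrids(g, inv)
  interior <- as.vector(matrix(seq_len(256), 16, 16)[4:13, 4:13])
  expect_lt(max(abs(gridCoords(comp)[interior, ] -
                      gridCoords(makeIdentityGrid(c(16L, 16L)))[interior, ])),
            5e-3)
})

test_that("spatial operations are deterministic", {
  g <- affineToGrid(AffineParams(cbind(diag(2), c(0.07, 0.01))), c(10L, 10L))
  img <- smoothImage(9, c(10L, 10L))
  expect_identical(imageValues(resampleImage(img, g)),
                   imageValues(resampleImage(img, g)))
})
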