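# Loss algebra: RMS, the synthesis/registration/regularisation terms, the
# bending energy and the smoothness-weight rule.

test_that("rmsError matches its definition and an elementwise oracle", {
  a <- matrix(1:6 / 6, 2, 3)
  expect_identical(rmsError(a, a), 0)
  expect_equal(rmsError(a, a - 3), 3)
  set.seed(4)
  x <- matrix(rnorm(40), 8, 5); y <- matrix(rnorm(40), 8, 5)
  expect_lt(abs(rmsError(x, y) - rmsOracle(x, y)), 1e-12)
  expect_identical(rmsError(x, y), rmsError(y, x))
  expect_error(rmsError(x, matrix(0, 4, 5)), "shapes")
})

test_that("smoothWeight implements 2^(2n) / (10 N)", {
  expect_identical(smoothWeight(2, 16384), 9.765625e-5)
  expect_identical(smoothWeight(3, 32768), 1.953125e-4)
  expect_identical(smoothWeight(2, 10), 0.16)
  expect_error(smoothWeight(2, 0), "positive")
  expect_error(smoothWeight(4, 10), "must be 2 or 3")
})

test_that("bending energy vanishes for affine fields and matches an
           independent stencil oracle", {
  expect_identical(bendingEnergy(zeroField(c(8L, 8L))), 0)
  # affine displacement: u(p) = A p + t has zero second derivatives
  g <- makeIdentityGrid(c(9L, 7L))
  u <- gridCoords(g) %*% t(matrix(c(0.2, -0.1, 0.05, 0.3), 2, 2)) +
    matrix(rep(c(0.03, -0.07), each = 63), 63)
  expect_lt(bendingEnergy(DisplacementField(u, c(9L, 7L))), 1e-28)
  # sinusoidal field vs the independent finite-difference oracle
  pts <- gridCoords(makeIdentityGrid(c(10L, 12L)))
  d <- cbind(sin(pi * pts[, 1]), cos(pi * pts[, 2] / 2))
  f <- DisplacementField(d, c(10L, 12L))
  expect_lt(abs(bendingEnergy(f) - bendingOracle(d, c(10L, 12L))), 1e-10)
  # translation invariance
  d2 <- d + matrix(rep(c(0.4, -0.2), each = 120), 120)
  expect_equal(bendingEnergy(DisplacementField(d2, c(10L, 12L))),
               bendingEnergy(f), tolerance = 1e-12)
  expect_error(bendingEnergy(zeroField(c(2L, 8L))), ">= 3")
})

test_that("3-D bending energy matches the oracle", {
  set.seed(5)
  shape <- c(5L, 4L, 6L)
  pts <- gridCoords(makeIdentityGrid(shape))
  d <- cbind(sin(pi * pts[, 1]) * pts[, 2], cos(pi * pts[, 3]),
             pts[, 1] * pts[, 2])
  f <- DisplacementField(d, shape)
  expect_lt(abs(bendingEnergy(f) - bendingOracle(d, shape)), 1e-10)
})

test_that("the squared-Laplacian variant is available and nonnegative", {
  set.seed(6)
  f <- randomSmoothField(6, c(8L, 8L), 0.1, 2)
  expect_gte(bendingEnergy(f, "laplacian"), 0)
  expect_false(isTRUE(all.equal(bendingEnergy(f, "laplacian"),
                                bendingEnergy(f, "bending"))))
})

test_that("every loss term is zero at the all-zero fixed point", {
  b <- fixedPointBundle()
  syn <- synthesisLoss(b)
  expect_identical(unname(syn), rep(0, 5))
  reg <- registrationLoss(b)
  expect_identical(unname(reg), rep(0, 3))
  r <- regularizationLoss(b, 0.01)
  expect_identical(unname(r), rep(0, 4))
  expect_identical(lossTerms(totalLoss(b, 0.01))[["total"]], 0)
})

test_that("loss sums satisfy the component identities on a real bundle", {
  m <- activeTinyModel(3)
  b <- forwardPass(m, noiseImage(30, c(16L, 16L)),
                   noiseImage(31, c(16L, 16L), "B"))
  syn <- synthesisLoss(b)
  expect_lt(abs(syn[["total"]] - sum(syn[1:4])), 1e-10)
  reg <- registrationLoss(b)
  expect_lt(abs(reg[["total"]] - reg[["regAcc"]] - reg[["regIc"]]), 1e-10)
  lam <- 0.37
  r <- regularizationLoss(b, lam)
  expect_lt(abs(r[["total"]] - r[["rSyn"]] - r[["rReg"]] -
                  lam * r[["rSmooth"]]), 1e-10)
  tot <- lossTerms(totalLoss(b, lam))
  expect_lt(abs(tot[["total"]] -
                  (syn[["total"]] + reg[["total"]] + r[["total"]])), 1e-10)
  expect_true(all(tot[1:9] >= 0))
  expect_gte(tot[["total"]], max(tot[1:9]))
  # regularisation is linear in lambda: doubling lambda adds rSmooth once
  r2 <- regularizationLoss(b, 2 * lam)
  expect_lt(abs((r2[["total"]] - r[["total"]]) - lam * r[["rSmooth"]]), 1e-12)
})

test_that("identity transforms give zero inverse-consistency loss", {
  m <- buildModel(tinyConfig(C = 8L))
  b <- forwardPass(m, noiseImage(32, c(16L, 16L)),
                   noiseImage(33, c(16L, 16L), "B"))
  reg <- registrationLoss(b)
  expect_identical(reg[["regIc"]], 0)
  r <- regularizationLoss(b, 1)
  expect_identical(r[["rSmooth"]], 0)
})

test_that("an exact translation inverse pair has near-zero IC loss on smooth
           images away from the border", {
  shape <- c(24L, 24L)
  img <- smoothImage(40, shape)
  gAB <- affineToGrid(AffineParams(cbind(diag(2), c(0.08, 0))), shape)
  gBA <- affineToGrid(AffineParams(cbind(diag(2), c(-0.08, 0))), shape)
  comp <- composeGrids(gAB, gBA)
  warped <- resampleImage(img, comp)
  interior <- as.vector(matrix(seq_len(prod(shape)), 24, 24)[5:20, 5:20])
  expect_lt(max(abs(imageValues(warped)[interior] -
                      imageValues(img)[interior])), 1e-6)
  # composed-grid path agrees with sequential double warping
  seq2 <- resampleImage(resampleImage(img, gAB), gBA)
  expect_lt(max(abs(imageValues(seq2)[interior] -
                      imageValues(warped)[interior])), 2e-2)
})

test_that("loss terms are symmetric under swapping the A and B roles", {
  m <- activeTinyModel(4)
  xA <- noiseImage(41, c(16L, 16L))
  xB <- noiseImage(42, c(16L, 16L), "B")
  b1 <- forwardPass(m, xA, xB)
  # swap roles: images exchanged; direction-tagged fields exchange as well,
  # but the networks are direction-specific, so compare term structure by
  # swapping decoders' roles through the mirrored call
  b2 <- forwardPass(m, ImageVolume(imageValues(xB)),
                    ImageVolume(imageValues(xA), modality = "B"))
  t1 <- lossTerms(totalLoss(b1, 0.1))
  t2 <- lossTerms(totalLoss(b2, 0.1))
  # each term is a sum over both directions of the same functional form,
  # so totals in the swapped pass stay finite and nonnegative with the same
  # algebraic identities
  expect_true(all(t2[1:9] >= 0))
  expect_lt(abs(t2[["total"]] - (sum(t2[1:8]) + 0.1 * t2[["rSmooth"]])), 1e-10)
})

test_that("the API takes no balancing weight other than lambda", {
  expect_identical(sort(names(formals(totalLoss))), sort(c("bundle", "lambda")))
})
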