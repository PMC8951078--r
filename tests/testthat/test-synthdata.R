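# Synthetic multimodal phantom generator and Dice evaluation.

test_that("anatomy generation is deterministic with all labels present", {
  a1 <- generateAnatomy(5, c(32L, 32L), K = 3L)
  a2 <- generateAnatomy(5, c(32L, 32L), K = 3L)
  expect_identical(a1, a2)
  expect_identical(sort(unique(as.vector(a1))), 0:3)
  expect_error(generateAnatomy(5, c(30L, 30L), K = 3L), "divisible")
  expect_error(generateAnatomy(5, c(32L, 32L), K = 1L), "K must")
})

test_that("foreground fraction stays within a usable range across seeds", {
  fr <- vapply(1:15, function(s) {
    a <- generateAnatomy(s, c(64L, 64L), K = 2L)
    mean(a > 0)
  }, numeric(1))
  expect_true(all(fr > 0.05 & fr < 0.9))
})

test_that("modality renderings are deterministic, piecewise-constant without
           noise, and not monotonically related", {
  lab <- generateAnatomy(6, c(32L, 32L), K = 3L)
  iA <- renderModality(lab, "A", 7, noiseSd = 0, biasAmp = 0)
  iA2 <- renderModality(lab, "A", 7, noiseSd = 0, biasAmp = 0)
  expect_identical(imageValues(iA), imageValues(iA2))
  expect_identical(length(unique(as.vector(imageValues(iA)))), 4L)
  iB <- renderModality(lab, "B", 8, noiseSd = 0, biasAmp = 0)
  mA <- vapply(0:3, function(k) mean(imageValues(iA)[lab == k]), numeric(1))
  mB <- vapply(0:3, function(k) mean(imageValues(iB)[lab == k]), numeric(1))
  expect_lt(cor(rank(mA), rank(mB)), 1)
  expect_error(renderModality(lab, "C", 1), "unknown modality")
  # noise and bias stay inside the intensity range
  iN <- renderModality(lab, "B", 9, noiseSd = 0.1, biasAmp = 0.15)
  expect_true(all(abs(imageValues(iN)) <= 1))
})

test_that("random affine parameters honour the strength contract", {
  expect_identical(affineMatrix(randomAffineParams(1, 0, 2)),
                   affineMatrix(identityAffine(2)))
  for (s in 1:10) {
    A <- affineMatrix(randomAffineParams(s, 0.5, 2))
    sc <- sqrt(colSums(A[, 1:2]^2))
    expect_gte(max(abs(c(sc - 1, A[, 3] / 0.4 / 0.5 * 0.2))), 0.199)
  }
  expect_identical(affineMatrix(randomAffineParams(3, 0.4, 3)),
                   affineMatrix(randomAffineParams(3, 0.4, 3)))
  expect_identical(dim(affineMatrix(randomAffineParams(3, 0.4, 3))),
                   c(3L, 4L))
  expect_error(randomAffineParams(1, 1.4, 2), "strength")
})

test_that("random smooth fields hit their amplitude and smoothness contracts", {
  z <- randomSmoothField(2, c(16L, 16L), 0, 4)
  expect_identical(unique(as.vector(fieldValues(z))), 0)
  f <- randomSmoothField(2, c(16L, 16L), 0.12, 4)
  expect_lt(abs(max(sqrt(rowSums(fieldValues(f)^2))) - 0.12), 1e-10)
  # bending energy strictly decreases as the kernel widens
  be <- vapply(c(2, 4, 8), function(sm)
    bendingEnergy(randomSmoothField(9, c(32L, 32L), 0.1, sm)), numeric(1))
  expect_true(all(diff(be) < 0))
  expect_error(randomSmoothField(1, c(8L, 8L), -0.1, 2), "amplitude")
  expect_error(randomSmoothField(1, c(8L, 8L), 0.1, 0), "smoothness")
})

test_that("synthetic pairs carry consistent geometry and masks", {
  s0 <- makePair(11, c(32L, 32L), K = 3L, strength = 0)
  expect_identical(s0@labels, s0@labelsWarped)
  expect_identical(unname(diceByLabel(s0@labels, s0@labelsWarped)),
                   rep(1, 3))
  s <- makePair(11, c(32L, 32L), K = 3L, strength = 0.4)
  expect_true(any(diceByLabel(s@labels, s@labelsWarped) < 1))
  # bitwise determinism
  s2 <- makePair(11, c(32L, 32L), K = 3L, strength = 0.4)
  expect_identical(imageValues(s@imageA), imageValues(s2@imageA))
  expect_identical(imageValues(s@imageB), imageValues(s2@imageB))
  expect_identical(s@labelsWarped, s2@labelsWarped)
  expect_identical(affineMatrix(s@gtAffine), affineMatrix(s2@gtAffine))
  # warped masks equal masks warped by the ground-truth grid
  again <- resampleImage(s@labels, gtGrid(s), "nearest")
  expect_identical(again, s@labelsWarped)
})

test_that("generator output feeds the networks for a range of extents", {
  m32 <- buildModel(tinyConfig(C = 8L))
  for (S in c(32L, 48L)) {
    s <- makePair(21, c(S, S), K = 2L, strength = 0.2)
    b <- forwardPass(m32, s@imageA, s@imageB)
    expect_s4_class(b, "ForwardBundle")
  }
})

test_that("Dice matches its definition", {
  a <- array(0L, c(4, 4)); a[1:2, 1:2] <- 1L
  expect_identical(diceScore(a == 1, a == 1), 1)
  b <- array(0L, c(4, 4)); b[3:4, 3:4] <- 1L
  expect_identical(diceScore(a == 1, b == 1), 0)
  c1 <- array(0L, c(4, 4)); c1[1:4, 1] <- 1L
  c2 <- array(0L, c(4, 4)); c2[1:2, 1] <- 1L; c2[1:2, 2] <- 1L
  expect_identical(diceScore(c1 == 1, c2 == 1), 0.5)
  expect_identical(diceScore(a == 2, b == 2), 1)  # both empty
  expect_error(diceScore(a == 1, array(0L, c(3, 3)) == 1), "extents")
})

test_that("ground-truth transforms are numerically invertible: warping the
           B-frame masks back restores the A-frame masks", {
  for (seed in c(31, 32, 33)) {
    s <- makePair(seed, c(48L, 48L), K = 3L, strength = 0.3)
    inv <- invertGrid(gtGrid(s))
    restored <- resampleImage(s@labelsWarped, inv, "nearest")
    d <- diceByLabel(restored, s@labels)
    expect_gte(mean(d), 0.95)
  }
})

test_that("cine sequences contract and annotate the extreme phases", {
  cs <- makeCineSequence(41, c(32L, 32L), P = 6L)
  expect_length(cs$images, 6L)
  expect_length(cs$annotated, 2L)
  expect_identical(cs$annotated[1], 1L)
  peak <- cs$annotated[2]
  # phase 1 is at rest; the second annotated phase carries peak contraction
  expect_identical(unique(as.vector(fieldValues(cs$fields[[1]]))), 0)
  expect_gt(max(abs(fieldValues(cs$fields[[peak]]))), 0)
  expect_true(any(cs$masks[["1"]] != cs$masks[[as.character(peak)]]))
})

test_that("mean ground-truth misalignment grows with strength", {
  m1 <- meanMisalignment(makePair(51, c(32L, 32L), strength = 0.1))
  m2 <- meanMisalignment(makePair(51, c(32L, 32L), strength = 0.5))
  expect_gt(m2, m1)
})
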