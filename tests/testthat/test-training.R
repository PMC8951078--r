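# Training procedure: Adam groups, steps, the fit loop and the inference
# path.  Runs use tiny models (C = 8, 16x16 phantoms) so the file stays fast.

smallDataset <- function(n = 3, shape = c(16L, 16L), strength = 0)
  makeDataset(n, seed = 70, shape = shape, K = 2L, strength = strength)

test_that("a zero-learning-rate step leaves every parameter bit-identical", {
  m <- activeTinyModel(5)
  st <- initTrainState(m)
  h0 <- paramHash(m)
  cfg <- trainConfig(lrAffine = 0, lrNonrigid = 0, lrSynthesis = 0,
                     iterations = 1L)
  r <- trainStep(smallDataset()[[1]], st, cfg)
  expect_identical(paramHash(r$state@model), h0)
  expect_identical(r$state@iteration, 1L)
})

test_that("a training step returns finite, nonnegative loss terms", {
  m <- activeTinyModel(6)
  st <- initTrainState(m)
  r <- trainStep(smallDataset()[[1]], st, scaledTrainConfig(iterations = 1L))
  terms <- lossTerms(r$report)
  expect_true(all(is.finite(terms)))
  expect_true(all(terms[1:9] >= 0))
})

test_that("each optimiser updates exactly its own parameter group", {
  ds <- smallDataset()
  groups <- paramGroups(buildModel(tinyConfig()))
  freeze <- list(
    list(cfg = scaledTrainConfig(iterations = 1L, lrAffine = 0),
         frozen = "affine"),
    list(cfg = scaledTrainConfig(iterations = 1L, lrNonrigid = 0),
         frozen = "nonrigid"),
    list(cfg = scaledTrainConfig(iterations = 1L, lrSynthesis = 0),
         frozen = "synthesis"))
  for (case in freeze) {
    m <- activeTinyModel(7)
    h0 <- paramHash(m)
    r <- trainStep(ds[[1]], initTrainState(m), case$cfg)
    h1 <- paramHash(r$state@model)
    moved <- names(h0)[h0 != h1]
    frozenNames <- groups[[case$frozen]]
    expect_length(intersect(moved, frozenNames), 0)
    expect_gt(length(moved), 0)
  }
})

test_that("the loss decreases over a short optimisation on one fixed pair", {
  m <- buildModel(tinyConfig(seed = 8, C = 8L))
  st <- initTrainState(m)
  cfg <- scaledTrainConfig(iterations = 1L, seed = 8)
  pair <- smallDataset(1)[[1]]
  totals <- numeric(120)
  for (i in seq_len(120)) {
    r <- trainStep(pair, st, cfg)
    st <- r$state
    totals[i] <- lossTerms(r$report)[["total"]]
  }
  expect_lt(median(totals[91:120]), median(totals[1:30]))
})

test_that("fitModel is reproducible: same seed gives an identical history", {
  ds <- smallDataset(2)
  cfg <- scaledTrainConfig(iterations = 12L, seed = 31)
  s1 <- fitModel(ds, cfg, modelCfg = tinyConfig(seed = 31))
  s2 <- fitModel(ds, cfg, modelCfg = tinyConfig(seed = 31))
  expect_identical(attr(s1, "history"), attr(s2, "history"))
  expect_identical(paramHash(s1@model), paramHash(s2@model))
  expect_identical(nrow(attr(s1, "history")), 12L)
})

test_that("fitModel applies the auto smoothness weight and writes outputs", {
  ds <- smallDataset(2)
  out <- file.path(tempdir(), "fitrun")
  cfg <- scaledTrainConfig(iterations = 4L, seed = 32, logEvery = 1L)
  st <- fitModel(ds, cfg, modelCfg = tinyConfig(seed = 32), outDir = out)
  h <- attr(st, "history")
  expect_equal(unique(h$lambda), smoothWeight(2, 256))
  expect_true(file.exists(file.path(out, "loss.csv")))
  expect_true(file.exists(file.path(out, "run.yaml")))
  expect_true(file.exists(file.path(out, "checkpoint_final.rds")))
  csv <- read.csv(file.path(out, "loss.csv"))
  expect_identical(nrow(csv), 4L)
  expect_error(fitModel(list(), cfg), "nonempty")
  unlink(out, recursive = TRUE)
})

test_that("registerPair with an identity-initialised model is a no-op and
           never invokes the decoders", {
  m <- buildModel(tinyConfig(seed = 9))
  ds <- smallDataset(1, strength = 0.3)
  res <- registerPair(m, ds[[1]]@imageA, ds[[1]]@imageB, "AB")
  expect_lt(max(abs(imageValues(res$warped) -
                      imageValues(ds[[1]]@imageA))), 1e-6)
  expect_s4_class(res$transform, "CompositeTransform")
  # decoders untouched: corrupting them does not change the result
  m@params[["dec.AB.up1.W"]][] <- NaN
  res2 <- registerPair(m, ds[[1]]@imageA, ds[[1]]@imageB, "AB")
  expect_identical(imageValues(res2$warped), imageValues(res$warped))
})

test_that("checkpoints round-trip the model, optimisers and transforms", {
  ds <- smallDataset(2)
  cfg <- scaledTrainConfig(iterations = 3L, seed = 33)
  st <- fitModel(ds, cfg, modelCfg = tinyConfig(seed = 33))
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(st, path)
  st2 <- loadCheckpoint(path)
  expect_identical(paramHash(st2@model), paramHash(st@model))
  expect_identical(st2@iteration, st@iteration)
  r1 <- registerPair(st, ds[[1]]@imageA, ds[[1]]@imageB)
  r2 <- registerPair(st2, ds[[1]]@imageA, ds[[1]]@imageB)
  expect_identical(gridCoords(transformGrid(r1$transform)),
                   gridCoords(transformGrid(r2$transform)))
  # continued training from the checkpoint matches continued training
  # from the live state (optimiser moments restored)
  a <- trainStep(ds[[1]], st, cfg)
  b <- trainStep(ds[[1]], st2, cfg)
  expect_identical(paramHash(a$state@model), paramHash(b$state@model))
  unlink(path)
})

test_that("training aborts with a named term on non-finite loss", {
  m <- activeTinyModel(10)
  m@params[["dec.AB.up1.W"]][1] <- Inf
  st <- initTrainState(m)
  expect_error(trainStep(smallDataset(1)[[1]], st,
                         scaledTrainConfig(iterations = 1L)),
               "non-finite loss term")
})

test_that("single-precision convolution gives the same learning behaviour", {
  ds <- smallDataset(1)
  cfg <- scaledTrainConfig(iterations = 1L, seed = 12)
  md <- buildModel(tinyConfig(seed = 12))
  ms <- buildModel(tinyConfig(seed = 12, precision = "single"))
  rd <- trainStep(ds[[1]], initTrainState(md), cfg)
  rs <- trainStep(ds[[1]], initTrainState(ms), cfg)
  expect_lt(abs(lossTerms(rd$report)[["total"]] -
                  lossTerms(rs$report)[["total"]]), 1e-3)
})

test_that("3-D volumes train and register end to end", {
  m <- buildModel(modelConfig(n = 3L, C = 8L, resnetBlocks = 1L, seed = 2))
  s <- makePair(5, c(16L, 16L, 16L), K = 2L, strength = 0.3)
  r <- trainStep(s, initTrainState(m), scaledTrainConfig(iterations = 1L))
  expect_true(all(is.finite(lossTerms(r$report))))
  reg <- registerPair(r$state, s@imageA, s@imageB, "AB")
  expect_identical(gridShape(reg$transform@nonrigid), c(16L, 16L, 16L))
})
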