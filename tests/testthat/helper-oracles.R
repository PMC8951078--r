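# Independent oracles and small fixtures used across the suite.  Oracles are
# deliberately written as plain per-point loops, sharing no code with the
# package's vectorised/compiled implementations.

# scalar per-pixel bilinear interpolation (align-corners, border clamp)
bilinearOracle <- function(img, coords) {
  sdim <- dim(img)
  out <- numeric(nrow(coords))
  for (p in seq_len(nrow(coords))) {
    f <- (coords[p, ] + 1) / 2 * (sdim - 1)
    f <- pmin(pmax(f, 0), sdim - 1)
    i0 <- pmin(floor(f), sdim - 2); i0[i0 < 0] <- 0
    w <- f - i0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) {
      wt <- (if (di) w[1] else 1 - w[1]) * (if (dj) w[2] else 1 - w[2])
      acc <- acc + wt * img[i0[1] + di + 1, i0[2] + dj + 1]
    }
    out[p] <- acc
  }
  out
}

# explicit per-point affine map of the identity grid
affineOracle <- function(A, shape) {
  axes <- lapply(shape, function(S) seq(-1, 1, length.out = S))
  pts <- as.matrix(do.call(expand.grid, axes))
  out <- matrix(0, nrow(pts), length(shape))
  for (p in seq_len(nrow(pts)))
    out[p, ] <- as.vector(A[, seq_len(length(shape))] %*% pts[p, ] +
                            A[, length(shape) + 1])
  out
}

# elementwise-loop RMS
rmsOracle <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

# independent bending-energy implementation: explicit central-difference
# stencils per interior point, mixed partials counted for both axis orders
bendingOracle <- function(disp, shape) {
  n <- length(shape)
  total <- 0
  arr <- lapply(seq_len(n), function(c) array(disp[, c], shape))
  idx <- as.matrix(do.call(expand.grid,
                           lapply(shape, function(S) 2:(S - 1))))
  for (c in seq_len(n)) {
    u <- arr[[c]]
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      at <- function(off) do.call(`[`, c(list(u), as.list(p + off)))
      for (a in seq_len(n)) {
        ea <- integer(n); ea[a] <- 1L
        total <- total + (at(ea) - 2 * at(integer(n)) + at(-ea))^2
      }
      if (n >= 2) for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        ea <- integer(n); ea[a] <- 1L
        eb <- integer(n); eb[b] <- 1L
        mix <- (at(ea + eb) - at(ea - eb) - at(-ea + eb) + at(-ea - eb)) / 4
        total <- total + 2 * mix^2
      }
    }
  }
  total / (nrow(idx) * n)
}

# small deterministic images
smoothImage <- function(seed, shape) {
  set.seed(seed)
  axes <- lapply(shape, function(S) seq(-1, 1, length.out = S))
  pts <- as.matrix(do.call(expand.grid, axes))
  f <- runif(length(shape), 0.5, 1.5)
  ph <- runif(length(shape), 0, pi)
  v <- tanh(rowSums(sin(sweep(sweep(pts, 2, f, "*") * pi, 2, ph, "+"))) / 2)
  ImageVolume(array(v, shape))
}

noiseImage <- function(seed, shape, modality = "A") {
  set.seed(seed)
  ImageVolume(array(tanh(rnorm(prod(shape))), shape), modality = modality)
}

tinyConfig <- function(seed = 1L, C = 8L, n = 2L, ...) {
  modelConfig(n = n, C = C, resnetBlocks = 1L, seed = seed, ...)
}

# a tiny model whose transform heads are nudged off the identity, so that
# warps, composed grids and all loss branches are active
activeTinyModel <- function(seed = 1L, headSd = 0.05, ...) {
  m <- buildModel(tinyConfig(seed = seed, ...))
  set.seed(seed + 1000L)
  m@params[["aff.fc2.W"]][] <- rnorm(length(m@params[["aff.fc2.W"]]),
                                     sd = headSd)
  m@params[["nr.final.W"]][] <- rnorm(length(m@params[["nr.final.W"]]),
                                      sd = headSd)
  m
}

# hash of all model parameters, for parameter-freeze checks
paramHash <- function(model) {
  nms <- sort(ls(model@params))
  vapply(nms, function(nm) sum(model@params[[nm]] * seq_along(model@params[[nm]])),
         numeric(1))
}

# hand-built bundle at the perfect fixed point: identical inputs, perfect
# synthesis, identity transforms
fixedPointBundle <- function(shape = c(8L, 8L)) {
  set.seed(8)
  x <- matrix(tanh(rnorm(prod(shape))), prod(shape), 1)
  lat <- shape %/% 4L
  g <- matrix(rnorm(prod(lat) * 4), prod(lat), 4)
  z <- matrix(0, prod(lat), 2)
  A <- cbind(diag(2), c(0, 0))
  f <- list(xA = x, xB = x, gA = g, gB = g, hatA = x, hatB = x,
            hatTA = x, hatTB = x, gAwarpAB = g, gBwarpBA = g,
            gAaff = g, gBaff = g, encHatA = g, encHatB = g,
            cycAB = x, cycBA = x, regAB = x, regBA = x,
            rsynAB = x, rsynBA = x, rregAB = x, rregBA = x,
            xAic = x, xBic = x, xAwarp = x, xBwarp = x,
            uAB = z, uBA = z, affAB = A, affBA = A)
  new("ForwardBundle", fields = f, shape = shape, latentShape = lat)
}

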