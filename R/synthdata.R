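# Synthetic multimodal phantom generator with ground-truth transforms and
# label masks, plus Dice evaluation.  The phantoms preserve the statistical
# structure the registration model assumes: one shared anatomy, two distinct
# (non-affinely-related, possibly non-monotone) intensity renderings, smooth
# multiplicative bias, additive noise, and a known affine + smooth non-rigid
# misalignment carried by nearest-neighbour-consistent label masks.

# ---- low-level randomness (draws from the CURRENT RNG stream) -------------

# random affine matrix: rotation x anisotropic scale + translation, acting on
# normalised coordinates.  Guarantees at least one axis changes by
# >= 0.4*strength (scale), matching the moderate-to-strong protocol where
# strength 0.5 means a >= 20% change across at least one dimension.
.random_affine_mat <- function(strength, n) {
  s <- runif(n, 1 - 0.5 * strength, 1 + 0.5 * strength)
  need <- 0.4 * strength
  if (max(abs(s - 1)) < need) {
    i <- which.max(abs(s - 1))
    sg <- if (s[i] >= 1) 1 else -1
    s[i] <- 1 + sg * need
  }
  maxAngle <- strength * 30 * pi / 180
  R <- if (n == 2L) {
    a <- runif(1, -maxAngle, maxAngle)
    matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  } else {
    ang <- runif(3, -maxAngle, maxAngle)
    rot <- function(a, i, j) {
      m <- diag(3)
      m[i, i] <- cos(a); m[j, j] <- cos(a)
      m[i, j] <- -sin(a); m[j, i] <- sin(a)
      m
    }
    rot(ang[1], 1, 2) %*% rot(ang[2], 1, 3) %*% rot(ang[3], 2, 3)
  }
  tr <- runif(n, -0.4 * strength, 0.4 * strength)
  cbind(R %*% diag(s, n), tr)
}

# separable Gaussian smoothing of an n-D array, border-renormalised
.gauss_smooth <- function(arr, sigma) {
  sdim <- dim(arr)
  n <- length(sdim)
  for (a in seq_len(n)) {
    S <- sdim[a]
    K <- exp(-outer(seq_len(S), seq_len(S), "-")^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- c(a, setdiff(seq_len(n), a))
    m <- matrix(aperm(arr, perm), nrow = S)
    m <- K %*% m
    arr <- aperm(array(m, sdim[perm]), order(perm))
  }
  arr
}

# smooth random displacement (npos x n) with max pointwise norm = amplitude
.random_smooth_disp <- function(shape, amplitude, smoothness) {
  n <- length(shape)
  npos <- prod(shape)
  d <- matrix(0, npos, n)
  for (a in seq_len(n))
    d[, a] <- as.vector(.gauss_smooth(array(rnorm(npos), shape), smoothness))
  if (amplitude == 0) return(d * 0)
  mx <- max(sqrt(rowSums(d^2)))
  if (mx > 0) d <- d * (amplitude / mx)
  d
}

# ---- public generator operations ------------------------------------------

#' Random affine augmentation parameters
#'
#' Scale factors lie in \eqn{[1 - 0.5s, 1 + 0.5s]}, rotation up to
#' \eqn{s \cdot 30^\circ} and translation up to \eqn{0.4 s} normalised units
#' at strength \eqn{s}; at least one axis is guaranteed a relative scale
#' change of \eqn{0.4 s} (so strength 0.5 changes some dimension by at least
#' 20\%).
#'
#' @param seed integer seed (deterministic output).
#' @param strength perturbation strength in \eqn{[0, 1]}; 0 gives the
#'   identity.
#' @param n spatial dimensionality (2 or 3).
#' @return An \linkS4class{AffineParams}.
#' @export
randomAffineParams <- function(seed, strength, n = 2L) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  if (!n %in% c(2L, 3L)) stop("n must be 2 or 3")
  if (strength == 0) return(identityAffine(n))
  .with_seed(seed, function() AffineParams(.random_affine_mat(strength, n)))
}

#' Random smooth displacement field
#'
#' Componentwise Gaussian noise smoothed with a Gaussian kernel of width
#' \code{smoothness} (voxels) and rescaled so the maximum pointwise norm
#' equals \code{amplitude} (normalised units).
#'
#' @param seed integer seed.
#' @param shape integer extents.
#' @param amplitude maximum displacement norm; 0 gives the zero field.
#' @param smoothness Gaussian kernel width in voxels (> 0).
#' @return A \linkS4class{DisplacementField}.
#' @export
randomSmoothField <- function(seed, shape, amplitude, smoothness) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (smoothness <= 0) stop("smoothness must be positive")
  shape <- .check_shape(shape)
  disp <- .with_seed(seed, function()
    .random_smooth_disp(shape, amplitude, smoothness))
  DisplacementField(disp, shape)
}

#' Generate a nested-structure anatomy label volume
#'
#' K nested smooth structures (randomised ellipsoids with smoothed-noise
#' boundary perturbation) on a background; labels \code{0..K} are all
#' present and deterministic per seed.
#'
#' @param seed integer seed.
#' @param shape integer extents, divisible by 4.
#' @param K number of structures (\eqn{\ge 2}).
#' @return Integer array of labels.
#' @export
generateAnatomy <- function(seed, shape, K = 3L) {
  if (K < 2L) stop("K must be >= 2")
  shape <- .check_shape(shape)
  if (any(shape %% 4L != 0L)) stop("extents must be divisible by 4")
  n <- length(shape)
  .with_seed(seed, function() {
    coords <- .id_coords(shape)
    centre0 <- runif(n, -0.12, 0.12)
    radii0 <- runif(n, 0.55, 0.72)
    ang <- runif(1, 0, pi)
    Rm <- if (n == 2L)
      matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2) else diag(3)
    pert <- .gauss_smooth(array(rnorm(prod(shape)), shape), max(shape) / 10)
    pert <- 0.18 * as.vector(pert) / max(abs(pert))
    labels <- integer(prod(shape))
    for (k in seq_len(K)) {
      shrink <- 1 - (k - 1) * 0.62 / K
      centre <- centre0 + if (k == 1) 0 else runif(n, -0.06, 0.06)
      pc <- sweep(coords, 2, centre) %*% Rm
      q <- rowSums(sweep(pc, 2, radii0 * shrink, "/")^2)
      inside <- q <= 1 + pert
      labels[inside] <- k
    }
    lab <- array(as.integer(labels), shape)
    present <- sort(unique(as.vector(lab)))
    if (!identical(present, 0:K)) {
      # fall back to clean concentric structures (guaranteed contract)
      q0 <- rowSums(sweep(coords, 2, radii0, "/")^2)
      labels <- integer(prod(shape))
      for (k in seq_len(K)) labels[q0 <= (1 - (k - 1) * 0.62 / K)^2] <- k
      lab <- array(as.integer(labels), shape)
    }
    lab
  })
}

# deterministic per-modality intensity lookup tables: monotone for A,
# non-monotone (background lowest, then reversed) for B, so the two
# renderings are not affinely related in intensity
.modality_lut <- function(K, modality, jitter = NULL) {
  base <- seq(-0.8, 0.8, length.out = K + 1)
  lut <- if (modality == "A") base else base[c(1, seq(K + 1, 2))]
  if (!is.null(jitter)) lut <- lut + jitter
  lut
}

#' Render a label volume in one modality
#'
#' Applies the modality's per-label intensity lookup (monotone for A;
#' non-monotone for B, emulating inverted-contrast sequences), a smooth
#' multiplicative bias field, and additive Gaussian noise; the output is
#' clipped to \eqn{[-1, 1]}.
#'
#' @param labels integer label array.
#' @param modality \code{"A"} or \code{"B"}.
#' @param seed integer seed (noise, bias and level jitter).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param biasAmp amplitude of the multiplicative bias field (0 disables).
#' @return An \linkS4class{ImageVolume}.
#' @export
renderModality <- function(labels, modality, seed, noiseSd = 0.05,
                           biasAmp = 0.1) {
  if (!modality %in% c("A", "B")) stop("unknown modality tag: ", modality)
  shape <- dim(labels)
  K <- max(labels)
  .with_seed(seed, function() {
    jitter <- runif(K + 1, -0.03, 0.03)
    lut <- .modality_lut(K, modality, jitter)
    img <- lut[as.vector(labels) + 1L]
    if (biasAmp > 0) {
      bias <- .gauss_smooth(array(rnorm(prod(shape)), shape), max(shape) / 6)
      bias <- as.vector(bias) / max(abs(bias))
      img <- img * (1 + biasAmp * bias)
    }
    if (noiseSd > 0) img <- img + rnorm(length(img), sd = noiseSd)
    img[img > 1] <- 1; img[img < -1] <- -1
    ImageVolume(array(img, shape), modality = modality)
  })
}

#' Generate one synthetic multimodal sample with known misalignment
#'
#' Renders one anatomy in modality A, warps the anatomy by a random
#' ground-truth affine + smooth non-rigid transform of the given strength,
#' and renders the warped anatomy in modality B; masks are carried through
#' both frames with nearest-neighbour interpolation.  The ground-truth grid
#' (affine grid plus field) is exactly the ideal A-to-B pull transform.
#'
#' @param seed integer seed (the whole sample is a pure function of it).
#' @param shape integer extents, divisible by 4.
#' @param K number of structures.
#' @param strength misalignment strength in \eqn{[0, 1]}; the non-rigid
#'   amplitude defaults to \code{0.15 * strength} with kernel width
#'   \code{max(shape)/8}.
#' @param nonrigidAmplitude override for the ground-truth non-rigid
#'   displacement amplitude (0 gives affine-only misalignment).
#' @param noiseSd,biasAmp rendering parameters (see
#'   \code{\link{renderModality}}).
#' @return A \linkS4class{SyntheticSample}.
#' @export
makePair <- function(seed, shape = c(64L, 64L), K = 3L, strength = 0.3,
                     nonrigidAmplitude = NULL, noiseSd = 0.05,
                     biasAmp = 0.1) {
  shape <- .check_shape(shape)
  n <- length(shape)
  if (is.null(nonrigidAmplitude)) nonrigidAmplitude <- 0.15 * strength
  ss <- .with_seed(seed, function() sample.int(.Machine$integer.max, 5L))
  labels <- generateAnatomy(ss[1], shape, K)
  imageA <- renderModality(labels, "A", ss[2], noiseSd, biasAmp)
  gtAffine <- randomAffineParams(ss[3], strength, n)
  gtNonrigid <- if (nonrigidAmplitude == 0) zeroField(shape) else
    randomSmoothField(ss[4], shape, amplitude = nonrigidAmplitude,
                      smoothness = max(shape) / 8)
  grid <- transformGrid(CompositeTransform(gtAffine, gtNonrigid, "AB"))
  labelsWarped <- resampleImage(labels, grid, "nearest")
  imageB <- renderModality(labelsWarped, "B", ss[5], noiseSd, biasAmp)
  new("SyntheticSample", imageA = imageA, imageB = imageB, labels = labels,
      labelsWarped = labelsWarped, gtAffine = gtAffine,
      gtNonrigid = gtNonrigid, seed = as.integer(seed))
}

#' Generate a dataset of synthetic samples
#'
#' @param nSamples number of samples.
#' @param seed base seed; sample i uses \code{seed + i}.
#' @param ... passed to \code{\link{makePair}}.
#' @return List of \linkS4class{SyntheticSample}s.
#' @export
makeDataset <- function(nSamples, seed = 1L, ...) {
  lapply(seq_len(nSamples), function(i) makePair(seed + i, ...))
}

#' Ground-truth sampling grid of a synthetic sample
#'
#' @param sample a \linkS4class{SyntheticSample}.
#' @return The \linkS4class{CoordinateGrid} of the ideal A-to-B transform.
#' @export
gtGrid <- function(sample) {
  transformGrid(CompositeTransform(sample@gtAffine, sample@gtNonrigid, "AB"))
}

#' Mean ground-truth misalignment magnitude
#'
#' Mean norm of the total ground-truth displacement over interior points
#' (normalised units).
#'
#' @param sample a \linkS4class{SyntheticSample}.
#' @export
meanMisalignment <- function(sample) {
  g <- gtGrid(sample)
  .interior_mean_norm(g@coords - .id_coords(g@shape), g@shape)
}

# mean row-norm over interior points of an (npos x n) displacement matrix
.interior_mean_norm <- function(d, shape) {
  idx <- array(seq_len(prod(shape)), shape)
  interior <- as.vector(do.call(`[`, c(list(idx),
                                       lapply(shape, function(S) 2:(S - 1)))))
  mean(sqrt(rowSums(d[interior, , drop = FALSE]^2)))
}

#' Dice overlap coefficient of two binary masks
#'
#' \eqn{2 |X \cap Y| / (|X| + |Y|)}; defined as 1 when both masks are empty.
#'
#' @param maskX,maskY logical/0-1 arrays of identical extents.
#' @export
diceScore <- function(maskX, maskY) {
  if (!identical(dim(maskX), dim(maskY)))
    stop("diceScore: mask extents must match")
  x <- as.logical(maskX); y <- as.logical(maskY)
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0) return(1)
  2 * sum(x & y) / (sx + sy)
}

#' Per-label Dice between two label volumes
#'
#' @param labelsX,labelsY integer label volumes of identical extents.
#' @param labels labels to evaluate (default: all nonzero labels present in
#'   either volume).
#' @return Named numeric of Dice scores.
#' @export
diceByLabel <- function(labelsX, labelsY, labels = NULL) {
  if (is.null(labels))
    labels <- sort(setdiff(unique(c(as.vector(labelsX), as.vector(labelsY))), 0))
  vapply(labels, function(k) diceScore(labelsX == k, labelsY == k),
         numeric(1), USE.NAMES = FALSE) -> d
  names(d) <- as.character(labels)
  d
}

#' Cine-like phantom sequence
#'
#' Emits P phases of one anatomy under a sinusoidally modulated radial
#' contraction (emulating a cardiac cycle between full diastole and
#' systole); the two geometric extremes (rest and peak contraction) carry
#' annotation masks.
#'
#' @param seed integer seed.
#' @param shape integer extents, divisible by 4.
#' @param P number of phases (\eqn{\ge 2}).
#' @param amplitude peak contraction displacement (normalised units).
#' @return List with \code{images} (list of \linkS4class{ImageVolume}s),
#'   \code{masks} (named list of label arrays for the annotated phases),
#'   \code{annotated} (their indices) and \code{fields} (per-phase
#'   ground-truth \linkS4class{DisplacementField}s).
#' @export
makeCineSequence <- function(seed, shape = c(64L, 64L), P = 8L,
                             amplitude = 0.25) {
  shape <- .check_shape(shape)
  labels <- generateAnatomy(seed, shape, K = 2L)
  coords <- .id_coords(shape)
  r <- sqrt(rowSums(coords^2))
  decay <- exp(-(r / 0.7)^2)
  images <- vector("list", P)
  fields <- vector("list", P)
  phaseAmp <- amplitude * sin(pi * (seq_len(P) - 1) / (P - 1))
  annotated <- c(1L, which.max(phaseAmp))
  masks <- list()
  for (t in seq_len(P)) {
    a <- phaseAmp[t]
    disp <- -coords * (a * decay)  # contraction toward the centre
    fields[[t]] <- DisplacementField(disp, shape)
    grid <- new("CoordinateGrid", coords = coords + disp, shape = shape)
    labT <- resampleImage(labels, grid, "nearest")
    images[[t]] <- renderModality(labT, "A", seed + t, noiseSd = 0.03)
    if (t %in% annotated) masks[[as.character(t)]] <- labT
  }
  list(images = images, masks = masks, annotated = annotated,
       fields = fields)
}
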