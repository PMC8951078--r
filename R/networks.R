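# Trainable components: shared synthesis encoder G, the two synthesis
# decoders F^(A->B) and F^(B->A), the affine subnetwork T_af, the non-rigid
# subnetwork T_nr, and the full bi-directional forward pass.
#
# Every layer follows "convolution + LeakyReLU + instance norm" (activation
# before normalisation; plain ReLU available via config).  The encoder
# downsamples by exactly 4 (two stride-2 stages); the transformation heads
# start at the identity: the affine head's final dense layer has zero weights
# and an identity bias, and the non-rigid head's final convolution is
# zero-initialised, so an untrained model realises the identity transform.

#' Model architecture configuration
#'
#' @param n spatial dimensionality, 2 or 3.
#' @param C encoder width (channels of the latent representation); the
#'   encoder stages use C/4, C/2, C channels.  Must be divisible by 4.
#' @param resnetBlocks number of Resnet blocks in the encoder and in each
#'   decoder (default 4).
#' @param affineChannels widths of the three affine-head convolutions
#'   (default scales with \code{C}: \code{C/2, C/4, C/8}).
#' @param nonrigidWidth width of the non-rigid head's parallel branches
#'   (default \code{C/2}).
#' @param denseHidden width of the affine head's hidden dense layer.
#' @param headChannels channels of the decoder's 7x7 output block before the
#'   final 1x1 convolution.
#' @param tanhScale maximum non-rigid displacement in normalised units
#'   (the Tanh output is scaled by this; default 0.25).
#' @param activation \code{"leakyrelu"} (slope 0.2) or \code{"relu"}.
#' @param inputChannels image channels (grayscale default 1).
#' @param epsNorm instance-normalisation epsilon.
#' @param precision convolution arithmetic: \code{"double"} (default) or
#'   \code{"single"} (standard network-training precision; roughly twice the
#'   throughput on one CPU).  All other operations stay in double precision.
#' @param seed seed for weight initialisation.
#' @return A validated configuration list.
#' @export
modelConfig <- function(n = 2L, C = 256L, resnetBlocks = 4L,
                        affineChannels = NULL, nonrigidWidth = NULL,
                        denseHidden = NULL, headChannels = 3L,
                        tanhScale = 0.25, activation = c("leakyrelu", "relu"),
                        inputChannels = 1L, epsNorm = 1e-5,
                        precision = c("double", "single"), seed = 1L) {
  activation <- match.arg(activation)
  precision <- match.arg(precision)
  n <- as.integer(n); C <- as.integer(C)
  if (!n %in% c(2L, 3L)) stop("n must be 2 or 3")
  if (C < 4L || C %% 4L != 0L) stop("C must be a positive multiple of 4")
  if (resnetBlocks < 1L) stop("resnetBlocks must be >= 1")
  if (!(tanhScale > 0 && tanhScale <= 2)) stop("tanhScale must be in (0, 2]")
  if (is.null(affineChannels)) affineChannels <- pmax(4L, C %/% c(2L, 4L, 8L))
  if (is.null(nonrigidWidth)) nonrigidWidth <- max(4L, C %/% 2L)
  if (is.null(denseHidden)) denseHidden <- max(8L, C %/% 8L)
  list(n = n, C = C, resnetBlocks = as.integer(resnetBlocks),
       affineChannels = as.integer(affineChannels),
       nonrigidWidth = as.integer(nonrigidWidth),
       denseHidden = as.integer(denseHidden),
       headChannels = as.integer(headChannels),
       tanhScale = tanhScale, activation = activation,
       inputChannels = as.integer(inputChannels), epsNorm = epsNorm,
       precision = precision, seed = as.integer(seed))
}

# run fn with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# ---- parameter construction -----------------------------------------------

.init_conv <- function(params, name, n, k, inch, outch, zero = FALSE) {
  fan <- k^n * inch
  W <- if (zero) matrix(0, fan, outch)
       else matrix(rnorm(fan * outch, sd = sqrt(2 / fan)), fan, outch)
  params[[paste0(name, ".W")]] <- W
  params[[paste0(name, ".b")]] <- rep(0, outch)
}

.init_dense <- function(params, name, dIn, dOut, zero = FALSE, bias = NULL) {
  W <- if (zero) matrix(0, dIn, dOut)
       else matrix(rnorm(dIn * dOut, sd = sqrt(2 / dIn)), dIn, dOut)
  params[[paste0(name, ".W")]] <- W
  params[[paste0(name, ".b")]] <- if (is.null(bias)) rep(0, dOut) else bias
}

#' Build a model with freshly initialised weights
#'
#' Weight initialisation is He-scaled Gaussian except for the transformation
#' heads, which are initialised so that the untrained model realises the
#' identity transform exactly.
#'
#' @param config a list from \code{\link{modelConfig}}.
#' @return A \linkS4class{SynthRegModel}.
#' @export
buildModel <- function(config = modelConfig()) {
  n <- config$n; C <- config$C
  params <- new.env(parent = emptyenv())
  .with_seed(config$seed, function() {
    # encoder: 7x7 C/4, two stride-2 3x3 (C/2, C), resnet blocks at C
    .init_conv(params, "enc.c1", n, 7L, config$inputChannels, C %/% 4L)
    .init_conv(params, "enc.c2", n, 3L, C %/% 4L, C %/% 2L)
    .init_conv(params, "enc.c3", n, 3L, C %/% 2L, C)
    for (i in seq_len(config$resnetBlocks)) {
      .init_conv(params, sprintf("enc.res%d.c1", i), n, 3L, C, C)
      .init_conv(params, sprintf("enc.res%d.c2", i), n, 3L, C, C)
    }
    # decoders: resnet blocks at C, two upsampling 3x3 (C/2, C/4),
    # 7x7 head, final 1x1 + Tanh
    for (d in c("AB", "BA")) {
      for (i in seq_len(config$resnetBlocks)) {
        .init_conv(params, sprintf("dec.%s.res%d.c1", d, i), n, 3L, C, C)
        .init_conv(params, sprintf("dec.%s.res%d.c2", d, i), n, 3L, C, C)
      }
      .init_conv(params, sprintf("dec.%s.up1", d), n, 3L, C, C %/% 2L)
      .init_conv(params, sprintf("dec.%s.up2", d), n, 3L, C %/% 2L, C %/% 4L)
      .init_conv(params, sprintf("dec.%s.head7", d), n, 7L, C %/% 4L,
                 config$headChannels)
      .init_conv(params, sprintf("dec.%s.head1", d), n, 1L,
                 config$headChannels, config$inputChannels)
    }
    # affine head: three stride-2 convolutions (kernels 7, 5, 2), GAP,
    # two dense layers -> n(n+1); final layer encodes the identity
    ac <- config$affineChannels
    .init_conv(params, "aff.c1", n, 7L, 2L * C, ac[1])
    .init_conv(params, "aff.c2", n, 5L, ac[1], ac[2])
    .init_conv(params, "aff.c3", n, 2L, ac[2], ac[3])
    .init_dense(params, "aff.fc1", ac[3], config$denseHidden)
    idbias <- c(as.vector(diag(n)), rep(0, n))  # column-major [A | t]
    .init_dense(params, "aff.fc2", config$denseHidden, n * (n + 1L),
                zero = TRUE, bias = idbias)
    # non-rigid head: parallel branch convolutions, one resnet block,
    # zero-initialised final convolution + scaled Tanh
    w <- config$nonrigidWidth
    .init_conv(params, "nr.pA", n, 3L, C, w)
    .init_conv(params, "nr.pB", n, 3L, C, w)
    .init_conv(params, "nr.res.c1", n, 3L, 2L * w, 2L * w)
    .init_conv(params, "nr.res.c2", n, 3L, 2L * w, 2L * w)
    .init_conv(params, "nr.final", n, 3L, 2L * w, n, zero = TRUE)
  })
  new("SynthRegModel", config = config, params = params)
}

#' Disjoint, jointly exhaustive parameter groups for the three optimisers
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @return Named list of parameter-name vectors: \code{synthesis} (encoder and
#'   both decoders), \code{affine}, \code{nonrigid}.
#' @export
paramGroups <- function(model) {
  nms <- ls(model@params)
  list(synthesis = nms[startsWith(nms, "enc.") | startsWith(nms, "dec.")],
       affine = nms[startsWith(nms, "aff.")],
       nonrigid = nms[startsWith(nms, "nr.")])
}

# ---- graph-building context -----------------------------------------------

# ctx: tape, model params, lazily-created parameter nodes (cached so the
# encoder's weights are the SAME node objects for both modalities)
.ctx_new <- function(model, train = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- .tape_new()
  ctx$params <- model@params
  ctx$pnodes <- new.env(parent = emptyenv())
  ctx$train <- train
  ctx$cfg <- model@config
  ctx
}

.pn <- function(ctx, name) {
  nd <- ctx$pnodes[[name]]
  if (is.null(nd)) {
    v <- ctx$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    nd <- .ad_leaf(ctx$tape, v, req = ctx$train)
    ctx$pnodes[[name]] <- nd
  }
  nd
}

.act <- function(ctx, x) {
  if (ctx$cfg$activation == "relu") .ad_lrelu(ctx$tape, x, 0) else
    .ad_lrelu(ctx$tape, x, 0.2)
}

# convolution block: conv (+activation) (+instance norm).  `fitPad` raises the
# padding so tiny inputs (small latent grids) still produce a nonempty output.
.conv_block <- function(ctx, x, name, k, stride = 1L, pad = (k - 1L) %/% 2L,
                        act = TRUE, norm = TRUE, fitPad = FALSE) {
  if (fitPad) {
    smin <- min(x$sdim)
    pad <- max(pad, as.integer(ceiling((k - smin) / 2)))
  }
  out <- .ad_conv(ctx$tape, x, .pn(ctx, paste0(name, ".W")),
                  .pn(ctx, paste0(name, ".b")), k, stride, pad,
                  single = identical(ctx$cfg$precision, "single"))
  if (act) out <- .act(ctx, out)
  # instance statistics are undefined on a single spatial position; skip the
  # normalisation there rather than zeroing the features
  if (norm && nrow(out$v) > 1L)
    out <- .ad_instnorm(ctx$tape, out, ctx$cfg$epsNorm)
  out
}

.resnet_block <- function(ctx, x, name) {
  h <- .conv_block(ctx, x, paste0(name, ".c1"), 3L)
  h <- .conv_block(ctx, h, paste0(name, ".c2"), 3L, act = FALSE)
  .ad_add(ctx$tape, x, h)
}

# ---- network graphs -------------------------------------------------------

.encode_graph <- function(ctx, x) {
  sdim <- x$sdim
  if (any(sdim %% 4L != 0L))
    stop("image extents must be divisible by 4; pad the input first")
  h <- .conv_block(ctx, x, "enc.c1", 7L)
  h <- .conv_block(ctx, h, "enc.c2", 3L, stride = 2L, pad = 1L)
  h <- .conv_block(ctx, h, "enc.c3", 3L, stride = 2L, pad = 1L)
  for (i in seq_len(ctx$cfg$resnetBlocks))
    h <- .resnet_block(ctx, h, sprintf("enc.res%d", i))
  h
}

.decode_graph <- function(ctx, g, direction) {
  if (!direction %in% c("AB", "BA")) stop("direction must be 'AB' or 'BA'")
  h <- g
  for (i in seq_len(ctx$cfg$resnetBlocks))
    h <- .resnet_block(ctx, h, sprintf("dec.%s.res%d", direction, i))
  h <- .ad_resize(ctx$tape, h, h$sdim * 2L)
  h <- .conv_block(ctx, h, sprintf("dec.%s.up1", direction), 3L)
  h <- .ad_resize(ctx$tape, h, h$sdim * 2L)
  h <- .conv_block(ctx, h, sprintf("dec.%s.up2", direction), 3L)
  h <- .conv_block(ctx, h, sprintf("dec.%s.head7", direction), 7L)
  h <- .conv_block(ctx, h, sprintf("dec.%s.head1", direction), 1L,
                   act = FALSE, norm = FALSE)
  .ad_tanh(ctx$tape, h)
}

.affine_graph <- function(ctx, gMoving, gFixed) {
  if (!identical(dim(gMoving$v), dim(gFixed$v)))
    stop("latent shapes must match")
  n <- ctx$cfg$n
  h <- .ad_concat(ctx$tape, gMoving, gFixed)
  h <- .conv_block(ctx, h, "aff.c1", 7L, stride = 2L, pad = 3L, fitPad = TRUE)
  h <- .conv_block(ctx, h, "aff.c2", 5L, stride = 2L, pad = 2L, fitPad = TRUE)
  h <- .conv_block(ctx, h, "aff.c3", 2L, stride = 2L, pad = 0L, fitPad = TRUE)
  h <- .ad_gap(ctx$tape, h)
  h <- .ad_dense(ctx$tape, h, .pn(ctx, "aff.fc1.W"), .pn(ctx, "aff.fc1.b"))
  h <- .act(ctx, h)
  h <- .ad_dense(ctx$tape, h, .pn(ctx, "aff.fc2.W"), .pn(ctx, "aff.fc2.b"))
  # reshape the n(n+1) outputs to the affine matrix [A | t], column-major
  .ad_make(ctx$tape, matrix(h$v, n, n + 1L), list(h), function(nd) {
    .acc(h, matrix(as.vector(nd$g), nrow = 1))
  })
}

.nonrigid_graph <- function(ctx, gMovingAff, gFixed) {
  if (!identical(dim(gMovingAff$v), dim(gFixed$v)))
    stop("latent shapes must match")
  a <- .conv_block(ctx, gMovingAff, "nr.pA", 3L)
  b <- .conv_block(ctx, gFixed, "nr.pB", 3L)
  h <- .ad_concat(ctx$tape, a, b)
  h <- .resnet_block(ctx, h, "nr.res")
  h <- .conv_block(ctx, h, "nr.final", 3L, act = FALSE, norm = FALSE)
  .ad_scale(ctx$tape, .ad_tanh(ctx$tape, h), ctx$cfg$tanhScale)
}

# one direction's transform subgraph: affine params, affine grids (latent and
# image), affinely-warped moving features, non-rigid field, full grids
.transform_graph <- function(ctx, gMoving, gFixed, imgShape) {
  latShape <- gMoving$sdim
  A <- .affine_graph(ctx, gMoving, gFixed)
  affLat <- .ad_affine_grid(ctx$tape, A, latShape)
  gMovAff <- .ad_gridsample(ctx$tape, gMoving, affLat, latShape)
  u <- .nonrigid_graph(ctx, gMovAff, gFixed)
  fullLat <- .ad_add(ctx$tape, affLat, u)
  uImg <- .ad_resize(ctx$tape, u, imgShape)
  affImg <- .ad_affine_grid(ctx$tape, A, imgShape)
  fullImg <- .ad_add(ctx$tape, affImg, uImg)
  list(A = A, affLat = affLat, affImg = affImg, gMovAff = gMovAff, u = u,
       uImg = uImg, fullLat = fullLat, fullImg = fullImg)
}

# full bi-directional forward graph; returns an environment of nodes.
# `regVariant` chooses between warping the image before encoding (default,
# the stated intent) and the literal warped-feature form; `affineReg` builds
# the affine-elimination branches (decodes of affine-only warps).
#
# Independent images that pass through the same network are stacked into one
# batched pass (the encoder runs twice, each decoder twice), which keeps the
# compiled GEMMs large; per-image warps run on the unstacked nodes.
.forward_graph <- function(ctx, xAv, xBv, regVariant = c("image", "feature"),
                          affineReg = TRUE) {
  regVariant <- match.arg(regVariant)
  tp <- ctx$tape
  imgShape <- .sdim(xAv)
  xA <- .ad_leaf(tp, xAv); xB <- .ad_leaf(tp, xBv)
  # stage 1: encode both inputs
  enc1 <- .encode_graph(ctx, .ad_stack(tp, list(xA, xB)))
  gA <- .ad_part(tp, enc1, 1L)
  gB <- .ad_part(tp, enc1, 2L)
  latShape <- gA$sdim
  tAB <- .transform_graph(ctx, gA, gB, imgShape)
  tBA <- .transform_graph(ctx, gB, gA, imgShape)
  o <- new.env(parent = emptyenv())
  o$xA <- xA; o$xB <- xB; o$gA <- gA; o$gB <- gB
  o$tAB <- tAB; o$tBA <- tBA
  o$latShape <- latShape; o$imgShape <- imgShape
  o$gAwarpAB <- .ad_gridsample(tp, gA, tAB$fullLat, latShape)
  o$gBwarpBA <- .ad_gridsample(tp, gB, tBA$fullLat, latShape)
  # stage 2: first decoder pass (plain, warped-feature, affine-only feature)
  inAB <- list(gA, o$gAwarpAB)
  inBA <- list(gB, o$gBwarpBA)
  if (affineReg) {
    inAB <- c(inAB, list(tAB$gMovAff))
    inBA <- c(inBA, list(tBA$gMovAff))
  }
  decAB1 <- .decode_graph(ctx, .ad_stack(tp, inAB), "AB")
  decBA1 <- .decode_graph(ctx, .ad_stack(tp, inBA), "BA")
  o$hatB <- .ad_part(tp, decAB1, 1L); o$hatTB <- .ad_part(tp, decAB1, 2L)
  o$hatA <- .ad_part(tp, decBA1, 1L); o$hatTA <- .ad_part(tp, decBA1, 2L)
  if (affineReg) {
    o$rsynAB <- .ad_part(tp, decAB1, 3L)
    o$rsynBA <- .ad_part(tp, decBA1, 3L)
  }
  # image-level warps with the upsampled fields
  o$xAwarp <- .ad_gridsample(tp, xA, tAB$fullImg, imgShape)
  o$xBwarp <- .ad_gridsample(tp, xB, tBA$fullImg, imgShape)
  # stage 3: re-encodings (cycle/alignment, registration, affine-only)
  encIn <- list(o$hatB, o$hatA)
  if (regVariant == "image") encIn <- c(encIn, list(o$xAwarp, o$xBwarp))
  if (affineReg) {
    xAaffw <- .ad_gridsample(tp, xA, tAB$affImg, imgShape)
    xBaffw <- .ad_gridsample(tp, xB, tBA$affImg, imgShape)
    encIn <- c(encIn, list(xAaffw, xBaffw))
  }
  enc2 <- .encode_graph(ctx, .ad_stack(tp, encIn))
  o$encHatB <- .ad_part(tp, enc2, 1L)
  o$encHatA <- .ad_part(tp, enc2, 2L)
  k <- 2L
  if (regVariant == "image") {
    eAw <- .ad_part(tp, enc2, k + 1L); eBw <- .ad_part(tp, enc2, k + 2L)
    k <- k + 2L
  }
  if (affineReg) {
    eAaff <- .ad_part(tp, enc2, k + 1L); eBaff <- .ad_part(tp, enc2, k + 2L)
  }
  # stage 4: second decoder pass (cycle, registration, affine-only image)
  inAB2 <- list(o$encHatA)   # decoder AB synthesises B from A-features
  inBA2 <- list(o$encHatB)
  if (regVariant == "image") {
    inAB2 <- c(inAB2, list(eAw)); inBA2 <- c(inBA2, list(eBw))
  }
  if (affineReg) {
    inAB2 <- c(inAB2, list(eAaff)); inBA2 <- c(inBA2, list(eBaff))
  }
  decAB2 <- .decode_graph(ctx, .ad_stack(tp, inAB2), "AB")
  decBA2 <- .decode_graph(ctx, .ad_stack(tp, inBA2), "BA")
  o$cycAB <- .ad_part(tp, decAB2, 1L)
  o$cycBA <- .ad_part(tp, decBA2, 1L)
  k <- 1L
  if (regVariant == "image") {
    o$regAB <- .ad_part(tp, decAB2, 2L)
    o$regBA <- .ad_part(tp, decBA2, 2L)
    k <- 2L
  } else {
    o$regAB <- o$hatTB
    o$regBA <- o$hatTA
  }
  if (affineReg) {
    o$rregAB <- .ad_part(tp, decAB2, k + 1L)
    o$rregBA <- .ad_part(tp, decBA2, k + 1L)
  }
  # inverse consistency through composed grids (single interpolation of x)
  cAB <- .ad_gridsample(tp, tAB$fullImg, tBA$fullImg, imgShape)
  cBA <- .ad_gridsample(tp, tBA$fullImg, tAB$fullImg, imgShape)
  o$xAic <- .ad_gridsample(tp, xA, cAB, imgShape)
  o$xBic <- .ad_gridsample(tp, xB, cBA, imgShape)
  o
}

.as_feature_matrix <- function(x, what = "image") {
  if (is(x, "ImageVolume"))
    return(.with_sdim(matrix(as.vector(x@values), ncol = 1),
                      as.integer(dim(x@values))))
  if (is(x, "LatentFeature"))
    return(.with_sdim(x@values, x@shape))
  stop("expected an ImageVolume or LatentFeature for ", what)
}

# ---- public network operations --------------------------------------------

#' Encode an image into the modality-invariant latent representation
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @param x an \linkS4class{ImageVolume} with extents divisible by 4.
#' @return A \linkS4class{LatentFeature} with C channels at 1/4 resolution.
#' @export
encodeImage <- function(model, x) {
  ctx <- .ctx_new(model)
  g <- .encode_graph(ctx, .ad_leaf(ctx$tape, .as_feature_matrix(x)))
  LatentFeature(g$v, g$sdim)
}

#' Decode a latent representation into a synthesised image
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @param g a \linkS4class{LatentFeature}.
#' @param direction \code{"AB"} (synthesise modality B) or \code{"BA"}.
#' @return An \linkS4class{ImageVolume} with values strictly in \eqn{(-1, 1)}
#'   (Tanh output) and extents 4x the latent extents.
#' @export
decodeImage <- function(model, g, direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  ctx <- .ctx_new(model)
  out <- .decode_graph(ctx, .ad_leaf(ctx$tape, .as_feature_matrix(g, "latent")),
                       direction)
  ImageVolume(array(out$v, out$sdim),
              modality = if (direction == "AB") "B" else "A")
}

#' Predict affine transformation parameters from two latent representations
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @param gMoving,gFixed \linkS4class{LatentFeature}s of equal shape.
#' @return An \linkS4class{AffineParams} (n x (n+1)); the identity transform
#'   at freshly initialised weights.
#' @export
predictAffine <- function(model, gMoving, gFixed) {
  ctx <- .ctx_new(model)
  A <- .affine_graph(ctx, .ad_leaf(ctx$tape, .as_feature_matrix(gMoving, "latent")),
                     .ad_leaf(ctx$tape, .as_feature_matrix(gFixed, "latent")))
  AffineParams(A$v)
}

#' Predict the non-rigid displacement field on the latent grid
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @param gMovingAff the moving latent representation, already affinely
#'   warped.
#' @param gFixed the fixed latent representation.
#' @return A \linkS4class{DisplacementField} on the latent grid, each
#'   component bounded by the configured Tanh scale; the zero field at
#'   freshly initialised weights.
#' @export
predictNonrigid <- function(model, gMovingAff, gFixed) {
  ctx <- .ctx_new(model)
  u <- .nonrigid_graph(ctx,
                       .ad_leaf(ctx$tape, .as_feature_matrix(gMovingAff, "latent")),
                       .ad_leaf(ctx$tape, .as_feature_matrix(gFixed, "latent")))
  DisplacementField(u$v, u$sdim)
}

# extract a numeric ForwardBundle from a forward graph
.bundle_from_graph <- function(o) {
  f <- list(
    xA = o$xA$v, xB = o$xB$v, gA = o$gA$v, gB = o$gB$v,
    hatA = o$hatA$v, hatB = o$hatB$v, hatTA = o$hatTA$v, hatTB = o$hatTB$v,
    gAwarpAB = o$gAwarpAB$v, gBwarpBA = o$gBwarpBA$v,
    gAaff = o$tAB$gMovAff$v, gBaff = o$tBA$gMovAff$v,
    encHatA = o$encHatA$v, encHatB = o$encHatB$v,
    cycAB = o$cycAB$v, cycBA = o$cycBA$v,
    regAB = o$regAB$v, regBA = o$regBA$v,
    rsynAB = o$rsynAB$v, rsynBA = o$rsynBA$v,
    rregAB = o$rregAB$v, rregBA = o$rregBA$v,
    xAic = o$xAic$v, xBic = o$xBic$v,
    xAwarp = o$xAwarp$v, xBwarp = o$xBwarp$v,
    uAB = o$tAB$u$v, uBA = o$tBA$u$v,
    affAB = o$tAB$A$v, affBA = o$tBA$A$v)
  new("ForwardBundle", fields = f, shape = as.integer(o$imgShape),
      latentShape = as.integer(o$latShape))
}

#' Run the full bi-directional forward pass
#'
#' Produces every intermediate of one training evaluation: latent features,
#' both composite transforms, synthesised images (plain, warped-feature,
#' cycle, registration and affine-only variants) and both latent-resolution
#' non-rigid fields.  All loss terms can be computed from the returned bundle
#' with \code{\link{totalLoss}}.
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @param xA,xB \linkS4class{ImageVolume}s of equal extents divisible by 4.
#' @param regVariant \code{"image"} warps the image before re-encoding for
#'   the registration-accuracy term (the default); \code{"feature"} uses the
#'   literal warped-feature form.
#' @return A \linkS4class{ForwardBundle}.
#' @export
forwardPass <- function(model, xA, xB, regVariant = c("image", "feature")) {
  regVariant <- match.arg(regVariant)
  if (!identical(dim(xA@values), dim(xB@values)))
    stop("xA and xB must have the same extents")
  ctx <- .ctx_new(model)
  o <- .forward_graph(ctx, .as_feature_matrix(xA), .as_feature_matrix(xB),
                      regVariant = regVariant, affineReg = TRUE)
  .bundle_from_graph(o)
}

#' Composite transforms of a forward bundle
#'
#' @param model the model that produced the bundle (for the field upsampling
#'   resolution only; the stored latent fields are upsampled to image
#'   resolution).
#' @param bundle a \linkS4class{ForwardBundle}.
#' @param direction \code{"AB"} or \code{"BA"}.
#' @return A \linkS4class{CompositeTransform} at image resolution.
#' @export
bundleTransform <- function(bundle, direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  u <- if (direction == "AB") bundle@fields$uAB else bundle@fields$uBA
  A <- if (direction == "AB") bundle@fields$affAB else bundle@fields$affBA
  uImg <- upsampleField(DisplacementField(u, bundle@latentShape),
                        bundle@shape)
  CompositeTransform(AffineParams(A), uImg, direction)
}
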