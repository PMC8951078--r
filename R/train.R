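# Training procedure: three Adam optimisers over disjoint parameter groups
# (affine head, non-rigid head, synthesis encoder/decoders), one image pair
# per step, a single backward pass over the full composite loss (the circular
# graph is handled by the separate optimisers, not by stop-gradients), and
# per-iteration random augmentation of the sampled pair.

#' Training configuration
#'
#' Learning-rate defaults follow the published schedule for the full
#' 144,000-iteration budget (affine 1e-5, non-rigid 5e-5, synthesis 1e-4);
#' shorter runs should scale them up (see the methods vignette and
#' \code{\link{scaledTrainConfig}}).
#'
#' @param lrAffine,lrNonrigid,lrSynthesis Adam learning rates of the three
#'   parameter groups.
#' @param iterations training iterations.
#' @param seed seed deriving all training randomness.
#' @param lambda \code{"auto"} (the \code{\link{smoothWeight}} rule for the
#'   image size) or an explicit scalar.
#' @param augmentStrength range of per-iteration augmentation strengths
#'   (fraction; the published protocol uses moderate-to-strong transforms,
#'   0.2--0.5).
#' @param augmentBoth transform both images (independently) instead of the
#'   moving image only.
#' @param augmentNonrigid amplitude factor of the augmentation's smooth
#'   displacement relative to strength (0 disables non-rigid augmentation).
#' @param useAffineReg build and apply the affine-elimination regularisers.
#' @param regVariant registration-accuracy form: \code{"image"} (warp the
#'   image before encoding, default) or \code{"feature"} (literal
#'   warped-feature form).
#' @param logEvery record a loss row every this many iterations (1 = all).
#' @param checkpointEvery write a checkpoint every this many iterations when
#'   fitting with an output directory (0 = final only).
#' @param beta1,beta2,epsilon Adam moment/stability constants.
#' @export
trainConfig <- function(lrAffine = 1e-5, lrNonrigid = 5e-5, lrSynthesis = 1e-4,
                        iterations = 144000L, seed = 1L, lambda = "auto",
                        augmentStrength = c(0.2, 0.5), augmentBoth = FALSE,
                        augmentNonrigid = 0.15, useAffineReg = TRUE,
                        regVariant = c("image", "feature"), logEvery = 1L,
                        checkpointEvery = 0L, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8) {
  regVariant <- match.arg(regVariant)
  if (any(c(lrAffine, lrNonrigid, lrSynthesis) < 0))
    stop("learning rates must be nonnegative")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (length(augmentStrength) != 2L || any(augmentStrength < 0) ||
      any(augmentStrength > 1) || diff(augmentStrength) < 0)
    stop("augmentStrength must be an increasing range within [0, 1]")
  list(lrAffine = lrAffine, lrNonrigid = lrNonrigid,
       lrSynthesis = lrSynthesis, iterations = as.integer(iterations),
       seed = as.integer(seed), lambda = lambda,
       augmentStrength = augmentStrength, augmentBoth = augmentBoth,
       augmentNonrigid = augmentNonrigid, useAffineReg = useAffineReg,
       regVariant = regVariant, logEvery = as.integer(logEvery),
       checkpointEvery = as.integer(checkpointEvery),
       beta1 = beta1, beta2 = beta2, epsilon = epsilon)
}

#' Training configuration for desk-scale runs
#'
#' The published learning rates are tied to the 144,000-iteration budget
#' (total parameter travel is roughly rate x iterations).  For runs of a few
#' thousand iterations this preset scales the rates up while preserving the
#' published ordering (affine smallest), and keeps every other default.
#'
#' @param iterations iterations of the scaled run (default 2000).
#' @param lrAffine,lrNonrigid,lrSynthesis scaled learning rates (overridable).
#' @param ... further arguments passed to \code{\link{trainConfig}}.
#' @export
scaledTrainConfig <- function(iterations = 2000L, lrAffine = 5e-4,
                              lrNonrigid = 1e-3, lrSynthesis = 1e-3, ...) {
  trainConfig(lrAffine = lrAffine, lrNonrigid = lrNonrigid,
              lrSynthesis = lrSynthesis, iterations = iterations, ...)
}

#' Initialise a training state
#'
#' @param model a \linkS4class{SynthRegModel}.
#' @return A \linkS4class{TrainState} with fresh Adam states for the three
#'   parameter groups.
#' @export
initTrainState <- function(model) {
  opt <- new.env(parent = emptyenv())
  for (grp in names(paramGroups(model))) {
    st <- new.env(parent = emptyenv())
    st$m <- new.env(parent = emptyenv())
    st$v <- new.env(parent = emptyenv())
    st$t <- 0L
    opt[[grp]] <- st
  }
  new("TrainState", model = model, opt = opt, iteration = 0L)
}

# one Adam update of a parameter group from a named gradient list
.adam_step <- function(params, st, grads, names, lr, b1, b2, eps) {
  if (lr == 0 || length(names) == 0L) return(invisible(NULL))
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(NULL)
}

.pair_matrices <- function(pair) {
  if (is(pair, "SyntheticSample")) pair <- list(pair@imageA, pair@imageB)
  xA <- .as_feature_matrix(pair[[1]])
  xB <- .as_feature_matrix(pair[[2]])
  if (!identical(.sdim(xA), .sdim(xB)))
    stop("pair images must have equal extents")
  if (any(.sdim(xA) %% 4L != 0L))
    stop("image extents must be divisible by 4")
  list(xA = xA, xB = xB)
}

.resolve_lambda <- function(config, sdim) {
  if (identical(config$lambda, "auto"))
    smoothWeight(length(sdim), prod(sdim)) else as.numeric(config$lambda)
}

#' One training step on an image pair
#'
#' Runs one forward pass, one total-loss evaluation and one backward pass,
#' then lets each of the three Adam optimisers update its own parameter
#' group.
#'
#' @param pair a \linkS4class{SyntheticSample} or a list of two
#'   \linkS4class{ImageVolume}s (moving A, fixed B).
#' @param state a \linkS4class{TrainState}.
#' @param config a list from \code{\link{trainConfig}}.
#' @return \code{list(state =, report =)} with the advanced state and the
#'   \linkS4class{LossReport} of the step.
#' @export
trainStep <- function(pair, state, config = trainConfig()) {
  pm <- .pair_matrices(pair)
  model <- state@model
  lambda <- .resolve_lambda(config, .sdim(pm$xA))
  ctx <- .ctx_new(model, train = TRUE)
  o <- .forward_graph(ctx, pm$xA, pm$xB, regVariant = config$regVariant,
                      affineReg = config$useAffineReg)
  lg <- .loss_graph(ctx, o, lambda, affineReg = config$useAffineReg)
  for (nm in names(lg$terms)) {
    tv <- lg$terms[[nm]]$v
    if (!is.finite(tv))
      stop("non-finite loss term '", nm, "' at iteration ",
           state@iteration + 1L)
  }
  .ad_backward(ctx$tape, lg$total)
  grads <- new.env(parent = emptyenv())
  for (nm in ls(ctx$pnodes)) grads[[nm]] <- ctx$pnodes[[nm]]$g
  groups <- paramGroups(model)
  .adam_step(model@params, state@opt$synthesis, grads, groups$synthesis,
             config$lrSynthesis, config$beta1, config$beta2, config$epsilon)
  .adam_step(model@params, state@opt$affine, grads, groups$affine,
             config$lrAffine, config$beta1, config$beta2, config$epsilon)
  .adam_step(model@params, state@opt$nonrigid, grads, groups$nonrigid,
             config$lrNonrigid, config$beta1, config$beta2, config$epsilon)
  report <- .report_from_terms(lg$terms, lambda, config$useAffineReg)
  list(state = new("TrainState", model = model, opt = state@opt,
                   iteration = state@iteration + 1L),
       report = report)
}

.report_from_terms <- function(terms, lambda, affineReg) {
  val <- function(nm) if (is.null(terms[[nm]])) 0 else terms[[nm]]$v
  v <- c(synAcc = val("synAcc"), synFea = val("synFea"),
         synCyc = val("synCyc"), synAlign = val("synAlign"),
         regAcc = val("regAcc"), regIc = val("regIc"),
         rSyn = val("rSyn"), rReg = val("rReg"), rSmooth = val("rSmooth"))
  total <- sum(v[1:8]) + lambda * v[["rSmooth"]]
  LossReport(c(v, lambda = lambda, total = total))
}

# random augmentation transform at a given strength: affine plus (optionally)
# a smooth displacement, realised as one composed grid
.augment_image <- function(x, sdim, strength, nrAmp) {
  n <- length(sdim)
  A <- .random_affine_mat(strength, n)
  g <- .homog_coords(sdim) %*% t(A)
  if (nrAmp > 0) {
    u <- .random_smooth_disp(sdim, amplitude = nrAmp * strength,
                             smoothness = max(sdim) / 8)
    g <- g + u
  }
  .with_sdim(.cpp_grid_sample_fw(x, as.integer(sdim), g, FALSE),
             as.integer(sdim))
}

#' Fit the model on a dataset of image pairs
#'
#' Loops \code{\link{trainStep}} for \code{config$iterations}, sampling pairs
#' uniformly with fresh random augmentation each iteration.  Fully
#' reproducible given the seed.
#'
#' @param dataset nonempty list of \linkS4class{SyntheticSample}s or
#'   two-image lists.
#' @param config a list from \code{\link{trainConfig}}.
#' @param model optional pre-built \linkS4class{SynthRegModel}; by default a
#'   2-D model matching the first pair is built from the training seed.
#' @param modelCfg model configuration used when \code{model} is NULL.
#' @param outDir optional output directory: receives \code{loss.csv}, a
#'   config snapshot (\code{run.yaml}) and a final checkpoint.
#' @return A \linkS4class{TrainState}; the loss history is attached as
#'   attribute \code{"history"} (data frame).
#' @export
fitModel <- function(dataset, config = trainConfig(), model = NULL,
                     modelCfg = NULL, outDir = NULL) {
  if (length(dataset) == 0L) stop("dataset must be nonempty")
  pm0 <- .pair_matrices(dataset[[1]])
  sdim <- .sdim(pm0$xA)
  if (is.null(model)) {
    if (is.null(modelCfg))
      modelCfg <- modelConfig(n = length(sdim), seed = config$seed)
    model <- buildModel(modelCfg)
  }
  state <- initTrainState(model)
  lambda <- .resolve_lambda(config, sdim)
  rows <- vector("list", config$iterations)
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  oldSeed <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(config$seed)
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(length(dataset), 1L)
    pm <- .pair_matrices(dataset[[idx]])
    sA <- runif(1, config$augmentStrength[1], config$augmentStrength[2])
    xA <- .augment_image(pm$xA, sdim, sA, config$augmentNonrigid)
    xB <- pm$xB
    if (config$augmentBoth) {
      sB <- runif(1, config$augmentStrength[1], config$augmentStrength[2])
      xB <- .augment_image(pm$xB, sdim, sB, config$augmentNonrigid)
    }
    step <- trainStep(list(ImageVolume(array(xA, sdim)),
                           ImageVolume(array(xB, sdim), modality = "B")),
                      state, config)
    state <- step$state
    if (it %% config$logEvery == 0L)
      rows[[it]] <- c(iteration = it, lossTerms(step$report))
    if (!is.null(outDir) && config$checkpointEvery > 0L &&
        it %% config$checkpointEvery == 0L)
      saveCheckpoint(state, file.path(outDir,
                                      sprintf("checkpoint_%06d.rds", it)))
  }
  history <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    # per-value formatting keeps rows identical regardless of run length
    fmt <- data.frame(lapply(history, function(col)
      formatC(col, digits = 12, format = "g")), check.names = FALSE)
    write.csv(fmt, file.path(outDir, "loss.csv"),
              row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(train = config[setdiff(names(config), "lambda")],
                          lambda = lambda,
                          model = model@config,
                          package = as.character(utils::packageVersion("synthreg"))),
                     file.path(outDir, "run.yaml"))
    saveCheckpoint(state, file.path(outDir, "checkpoint_final.rds"))
  }
  attr(state, "history") <- history
  state
}

#' Register a moving image to a fixed image
#'
#' The inference path: encodes both images, predicts the direction's affine
#' and non-rigid transform, upsamples the field and warps the moving image
#' once.  The decoders are not invoked.
#'
#' @param state a \linkS4class{TrainState} or \linkS4class{SynthRegModel}.
#' @param moving,fixed \linkS4class{ImageVolume}s of equal extents.
#' @param direction \code{"AB"} (moving plays A) or \code{"BA"}.
#' @return \code{list(warped =, transform =)}: the warped moving image and
#'   the \linkS4class{CompositeTransform} at image resolution.
#' @export
registerPair <- function(state, moving, fixed, direction = c("AB", "BA")) {
  direction <- match.arg(direction)
  model <- if (is(state, "TrainState")) state@model else state
  if (!identical(dim(moving@values), dim(fixed@values)))
    stop("moving and fixed images must have equal extents")
  ctx <- .ctx_new(model)
  xM <- .ad_leaf(ctx$tape, .as_feature_matrix(moving))
  xF <- .ad_leaf(ctx$tape, .as_feature_matrix(fixed))
  imgShape <- xM$sdim
  gM <- .encode_graph(ctx, xM)
  gF <- .encode_graph(ctx, xF)
  tr <- .transform_graph(ctx, gM, gF, imgShape)
  warped <- .cpp_grid_sample_fw(xM$v, imgShape, tr$fullImg$v, FALSE)
  transform <- CompositeTransform(
    AffineParams(tr$A$v),
    DisplacementField(.strip(tr$uImg$v), imgShape),
    direction)
  list(warped = ImageVolume(array(warped, imgShape), moving@spacing,
                            moving@modality, moving@header),
       transform = transform)
}

.strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }

#' Save a training checkpoint
#'
#' Stores the model configuration, all parameters, the three optimiser
#' states and the iteration counter in a single RDS file.
#'
#' @param state a \linkS4class{TrainState}.
#' @param path output file path.
#' @export
saveCheckpoint <- function(state, path) {
  env2list <- function(e) mget(ls(e), envir = e)
  opt <- lapply(c(synthesis = "synthesis", affine = "affine",
                  nonrigid = "nonrigid"), function(grp) {
    st <- state@opt[[grp]]
    list(m = env2list(st$m), v = env2list(st$v), t = st$t)
  })
  saveRDS(list(config = state@model@config,
               params = env2list(state@model@params),
               opt = opt, iteration = state@iteration), path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path file written by \code{\link{saveCheckpoint}}.
#' @return A \linkS4class{TrainState}.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  params <- list2env(ck$params, parent = emptyenv())
  model <- new("SynthRegModel", config = ck$config, params = params)
  state <- initTrainState(model)
  for (grp in names(ck$opt)) {
    st <- state@opt[[grp]]
    st$m <- list2env(ck$opt[[grp]]$m, parent = emptyenv())
    st$v <- list2env(ck$opt[[grp]]$v, parent = emptyenv())
    st$t <- ck$opt[[grp]]$t
  }
  new("TrainState", model = model, opt = state@opt,
      iteration = as.integer(ck$iteration))
}
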