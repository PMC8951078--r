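#' @import methods
#' @importFrom stats rnorm runif median setNames
#' @importFrom utils write.csv read.csv modifyList
#' @useDynLib synthreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# package-level cache for shape-dependent constant objects (identity grids,
# bending-energy stencil matrices).  Keys are built from the shape vector.
.synthreg_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, build) {
  if (is.null(.synthreg_cache[[key]])) .synthreg_cache[[key]] <- build()
  .synthreg_cache[[key]]
}

#' ImageVolume: an n-D scalar image with spacing and a modality tag
#'
#' Intensities are stored normalised to \eqn{[-1, 1]}; \code{spacing} is
#' carried through as metadata (mm) and never enters the geometry, which is
#' expressed in normalised coordinates.
#'
#' @slot values n-D numeric array (2-D matrix or 3-D array), values in
#'   \eqn{[-1, 1]}.
#' @slot spacing positive numeric vector, one entry per axis.
#' @slot modality single character, conventionally \code{"A"} or \code{"B"}.
#' @slot header optional NIfTI header carried through for write-back.
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric",
                 modality = "character", header = "ANY"),
  prototype(header = NULL))

setValidity("ImageVolume", function(object) {
  v <- object@values
  n <- length(dim(v))
  if (!n %in% c(2L, 3L)) return("values must be a 2-D or 3-D array")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (max(abs(v)) > 1 + 1e-9) return("values must lie in [-1, 1]")
  if (length(object@spacing) != n) return("spacing length must match dimensionality")
  if (any(object@spacing <= 0)) return("spacing must be strictly positive")
  if (length(object@modality) != 1L) return("modality must be a single tag")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param values numeric array with values in \eqn{[-1, 1]}.
#' @param spacing voxel spacing in mm (defaults to 1 per axis).
#' @param modality modality tag, \code{"A"} or \code{"B"}.
#' @param header optional NIfTI header for write-back.
#' @return An \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(values, spacing = rep(1, length(dim(values))),
                        modality = "A", header = NULL) {
  values <- as.array(values)
  # guard against interpolation round-off nudging values past the bounds
  values[values > 1] <- 1
  values[values < -1] <- -1
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      modality = modality, header = header)
}

#' CoordinateGrid: per-voxel absolute sampling coordinates
#'
#' Coordinates use the align-corners convention: index \eqn{i} on an axis of
#' extent \eqn{S \ge 2} maps to \eqn{-1 + 2i/(S-1)}, so corners are exactly
#' \eqn{\pm 1}.  After transformation coordinates may leave \eqn{[-1, 1]};
#' resampling clamps to the border.
#'
#' @slot coords (npos x n) matrix, column j = coordinate along axis j, rows
#'   enumerating voxels column-major (axis 1 fastest).
#' @slot shape integer extents.
#' @export
setClass("CoordinateGrid",
  representation(coords = "matrix", shape = "integer"))

setValidity("CoordinateGrid", function(object) {
  n <- length(object@shape)
  if (ncol(object@coords) != n) return("coords must have one column per axis")
  if (nrow(object@coords) != prod(object@shape))
    return("coords must have one row per grid point")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  TRUE
})

#' AffineParams: an n x (n+1) affine transformation matrix
#'
#' Acts on normalised coordinates: a grid point p maps to
#' \eqn{A p + t} where the linear part A is the first n columns and the
#' translation t is the last column.
#'
#' @slot mat numeric n x (n+1) matrix.
#' @export
setClass("AffineParams", representation(mat = "matrix"))

setValidity("AffineParams", function(object) {
  m <- object@mat
  if (!nrow(m) %in% c(2L, 3L)) return("affine matrix must be 2x3 or 3x4")
  if (ncol(m) != nrow(m) + 1L) return("affine matrix must be n x (n+1)")
  if (any(!is.finite(m))) return("affine entries must be finite")
  TRUE
})

#' @param mat numeric n x (n+1) matrix.
#' @rdname AffineParams-class
#' @export
AffineParams <- function(mat) new("AffineParams", mat = mat)

#' Identity affine parameters
#' @param n spatial dimensionality (2 or 3).
#' @return An \linkS4class{AffineParams} encoding \eqn{[I | 0]}.
#' @export
identityAffine <- function(n) AffineParams(cbind(diag(n), rep(0, n)))

#' DisplacementField: per-point displacement in normalised coordinates
#'
#' @slot disp (npos x n) matrix of displacements, same voxel ordering as
#'   \linkS4class{CoordinateGrid}.
#' @slot shape integer extents of the grid the field lives on.
#' @export
setClass("DisplacementField",
  representation(disp = "matrix", shape = "integer"))

setValidity("DisplacementField", function(object) {
  n <- length(object@shape)
  if (ncol(object@disp) != n) return("disp must have one column per axis")
  if (nrow(object@disp) != prod(object@shape))
    return("disp must have one row per grid point")
  if (any(!is.finite(object@disp))) return("displacements must be finite")
  TRUE
})

#' @param disp (npos x n) displacement matrix.
#' @param shape integer extents.
#' @rdname DisplacementField-class
#' @export
DisplacementField <- function(disp, shape) {
  new("DisplacementField", disp = as.matrix(disp), shape = as.integer(shape))
}

#' Zero displacement field
#' @param shape integer extents.
#' @export
zeroField <- function(shape) {
  DisplacementField(matrix(0, prod(shape), length(shape)), shape)
}

#' CompositeTransform: affine followed by additive non-rigid displacement
#'
#' The realised sampling grid is the affine grid plus the displacement field,
#' applied with a single interpolation (the moving image is resampled once).
#'
#' @slot affine \linkS4class{AffineParams}.
#' @slot nonrigid \linkS4class{DisplacementField} at image resolution.
#' @slot direction \code{"AB"} or \code{"BA"}.
#' @export
setClass("CompositeTransform",
  representation(affine = "AffineParams", nonrigid = "DisplacementField",
                 direction = "character"))

setValidity("CompositeTransform", function(object) {
  if (!object@direction %in% c("AB", "BA"))
    return("direction must be 'AB' or 'BA'")
  if (nrow(object@affine@mat) != length(object@nonrigid@shape))
    return("affine and non-rigid dimensionality must agree")
  TRUE
})

#' @param affine \linkS4class{AffineParams}.
#' @param nonrigid \linkS4class{DisplacementField} at image resolution.
#' @param direction \code{"AB"} or \code{"BA"}.
#' @rdname CompositeTransform-class
#' @export
CompositeTransform <- function(affine, nonrigid, direction = "AB") {
  new("CompositeTransform", affine = affine, nonrigid = nonrigid,
      direction = direction)
}

#' LatentFeature: modality-invariant feature map at 1/4 spatial resolution
#'
#' @slot values (npos x C) matrix of features.
#' @slot shape integer spatial extents of the latent grid.
#' @export
setClass("LatentFeature",
  representation(values = "matrix", shape = "integer"))

setValidity("LatentFeature", function(object) {
  if (nrow(object@values) != prod(object@shape))
    return("values must have one row per latent grid point")
  if (any(!is.finite(object@values))) return("features must be finite")
  TRUE
})

LatentFeature <- function(values, shape) {
  new("LatentFeature", values = values, shape = as.integer(shape))
}

#' ForwardBundle: all intermediates of one bi-directional pass
#'
#' Holds the inputs, latent features, both composite transforms, all decoded
#' images (synthesised, warped-feature, cycle, registration and affine-only
#' variants) and the latent-resolution non-rigid fields, so that every loss
#' term can be evaluated from the bundle alone.
#'
#' @slot fields named list of intermediates (matrices with voxel-major layout).
#' @slot shape image extents.
#' @slot latentShape latent extents (image extents / 4).
#' @export
setClass("ForwardBundle",
  representation(fields = "list", shape = "integer", latentShape = "integer"))

.bundle_required <- c(
  "xA", "xB", "gA", "gB", "hatA", "hatB", "hatTA", "hatTB",
  "gAwarpAB", "gBwarpBA", "gAaff", "gBaff", "encHatA", "encHatB",
  "cycAB", "cycBA", "regAB", "regBA", "rsynAB", "rsynBA", "rregAB", "rregBA",
  "xAic", "xBic", "xAwarp", "xBwarp", "uAB", "uBA", "affAB", "affBA")

setValidity("ForwardBundle", function(object) {
  missing <- setdiff(.bundle_required, names(object@fields))
  if (length(missing))
    return(paste("bundle is missing fields:", paste(missing, collapse = ", ")))
  TRUE
})

#' LossReport: every loss and regularisation term of one evaluation
#'
#' @slot terms named numeric vector with elements \code{synAcc}, \code{synFea},
#'   \code{synCyc}, \code{synAlign}, \code{regAcc}, \code{regIc}, \code{rSyn},
#'   \code{rReg}, \code{rSmooth}, \code{lambda}, \code{total}.
#' @export
setClass("LossReport", representation(terms = "numeric"))

.loss_term_names <- c("synAcc", "synFea", "synCyc", "synAlign",
                      "regAcc", "regIc", "rSyn", "rReg", "rSmooth",
                      "lambda", "total")

setValidity("LossReport", function(object) {
  if (!identical(names(object@terms), .loss_term_names))
    return("terms must carry the canonical named elements")
  if (any(!is.finite(object@terms))) return("loss terms must be finite")
  if (any(object@terms[1:9] < -1e-12)) return("loss terms must be nonnegative")
  TRUE
})

LossReport <- function(terms) new("LossReport", terms = terms[.loss_term_names])

#' SyntheticSample: phantom pair with ground-truth transforms and masks
#'
#' @slot imageA,imageB two modality renderings of one anatomy;
#'   \code{imageB} is geometrically warped by the ground-truth transform.
#' @slot labels integer mask volume in the A frame (0 = background).
#' @slot labelsWarped the same masks carried into the B frame
#'   (nearest-neighbour).
#' @slot gtAffine,gtNonrigid ground-truth transform components (image
#'   resolution, normalised coordinates).
#' @slot seed the seed that regenerates the sample bitwise.
#' @export
setClass("SyntheticSample",
  representation(imageA = "ImageVolume", imageB = "ImageVolume",
                 labels = "array", labelsWarped = "array",
                 gtAffine = "AffineParams", gtNonrigid = "DisplacementField",
                 seed = "integer"))

setValidity("SyntheticSample", function(object) {
  dA <- dim(object@imageA@values)
  if (!identical(dA, dim(object@imageB@values)))
    return("imageA and imageB must share extents")
  if (!identical(dA, dim(object@labels)))
    return("labels must share extents with the images")
  if (!identical(dA, dim(object@labelsWarped)))
    return("warped labels must share extents with the images")
  TRUE
})

#' SynthRegModel: trainable parameters plus architecture configuration
#'
#' Parameters live in an environment keyed by layer name; the single encoder
#' parameter set is shared between both modalities by construction.
#'
#' @slot config list produced by \code{\link{modelConfig}}.
#' @slot params environment mapping parameter names to numeric arrays.
#' @export
setClass("SynthRegModel",
  representation(config = "list", params = "environment"))

#' TrainState: model, three Adam optimiser states and iteration counter
#'
#' @slot model \linkS4class{SynthRegModel}.
#' @slot opt environment holding one Adam state per parameter group
#'   (\code{synthesis}, \code{affine}, \code{nonrigid}).
#' @slot iteration iterations completed.
#' @export
setClass("TrainState",
  representation(model = "SynthRegModel", opt = "environment",
                 iteration = "integer"))

# ---- show methods ---------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("ImageVolume [%s] modality %s, spacing %s mm, range [%.3f, %.3f]\n",
              paste(dim(object@values), collapse = "x"), object@modality,
              paste(signif(object@spacing, 3), collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "CoordinateGrid", function(object) {
  cat(sprintf("CoordinateGrid [%s], coordinate range [%.3f, %.3f]\n",
              paste(object@shape, collapse = "x"),
              min(object@coords), max(object@coords)))
})

setMethod("show", "AffineParams", function(object) {
  cat(sprintf("AffineParams (%dD):\n", nrow(object@mat)))
  print(signif(object@mat, 4))
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(rowSums(object@disp^2))
  cat(sprintf("DisplacementField [%s], |u| mean %.4g max %.4g\n",
              paste(object@shape, collapse = "x"), mean(mag), max(mag)))
})

setMethod("show", "CompositeTransform", function(object) {
  cat(sprintf("CompositeTransform %s: affine + non-rigid on [%s]\n",
              object@direction, paste(object@nonrigid@shape, collapse = "x")))
})

setMethod("show", "LossReport", function(object) {
  cat("LossReport:\n")
  print(signif(object@terms, 6))
})

setMethod("show", "SyntheticSample", function(object) {
  cat(sprintf("SyntheticSample [%s], %d structures, seed %d\n",
              paste(dim(object@labels), collapse = "x"),
              length(setdiff(unique(as.vector(object@labels)), 0L)),
              object@seed))
})

setMethod("show", "SynthRegModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(ls(object@params),
                   function(nm) length(object@params[[nm]]), numeric(1)))
  cat(sprintf("SynthRegModel: n=%d, C=%d, %d Resnet blocks, %d parameters\n",
              cfg$n, cfg$C, cfg$resnetBlocks, np))
})

setMethod("show", "TrainState", function(object) {
  cat(sprintf("TrainState at iteration %d\n", object@iteration))
  show(object@model)
})

# ---- accessors ------------------------------------------------------------

#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' Raw array of an ImageVolume
#' @param x an \linkS4class{ImageVolume}.
#' @export
setMethod("imageValues", "ImageVolume", function(x) x@values)

#' @export
setGeneric("imageSpacing", function(x) standardGeneric("imageSpacing"))
#' Voxel spacing of an ImageVolume
#' @param x an \linkS4class{ImageVolume}.
#' @export
setMethod("imageSpacing", "ImageVolume", function(x) x@spacing)

#' @export
setGeneric("gridCoords", function(x) standardGeneric("gridCoords"))
#' Coordinate matrix of a CoordinateGrid
#' @param x a \linkS4class{CoordinateGrid}.
#' @export
setMethod("gridCoords", "CoordinateGrid", function(x) x@coords)

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @describeIn gridCoords extents of the grid.
#' @export
setMethod("gridShape", "CoordinateGrid", function(x) x@shape)
#' @export
setMethod("gridShape", "DisplacementField", function(x) x@shape)
#' @export
setMethod("gridShape", "LatentFeature", function(x) x@shape)

#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' Affine matrix of AffineParams
#' @param x an \linkS4class{AffineParams} or \linkS4class{CompositeTransform}.
#' @export
setMethod("affineMatrix", "AffineParams", function(x) x@mat)
#' @export
setMethod("affineMatrix", "CompositeTransform", function(x) x@affine@mat)

#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' Displacement matrix of a DisplacementField
#' @param x a \linkS4class{DisplacementField} or
#'   \linkS4class{CompositeTransform}.
#' @export
setMethod("fieldValues", "DisplacementField", function(x) x@disp)
#' @export
setMethod("fieldValues", "CompositeTransform", function(x) x@nonrigid@disp)

#' @export
setGeneric("latentValues", function(x) standardGeneric("latentValues"))
#' Feature matrix of a LatentFeature
#' @param x a \linkS4class{LatentFeature}.
#' @export
setMethod("latentValues", "LatentFeature", function(x) x@values)

#' @export
setGeneric("lossTerms", function(x) standardGeneric("lossTerms"))
#' Named loss terms of a LossReport
#' @param x a \linkS4class{LossReport}.
#' @export
setMethod("lossTerms", "LossReport", function(x) x@terms)

#' @export
setGeneric("bundleField", function(x, name) standardGeneric("bundleField"))
#' Extract one intermediate from a ForwardBundle
#' @param x a \linkS4class{ForwardBundle}.
#' @param name field name, one of the canonical bundle fields.
#' @export
setMethod("bundleField", "ForwardBundle", function(x, name) {
  if (!name %in% names(x@fields)) stop("unknown bundle field: ", name)
  x@fields[[name]]
})
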