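# Geometric substrate: normalised-coordinate grids, differentiable resampling,
# affine/non-rigid field application, composition and upsampling.
#
# Conventions (documented in the methods vignette):
#   * align-corners: index 0 <-> -1, index S-1 <-> +1, so corners are exact;
#   * pull (backward) warping: a grid maps OUTPUT coordinates to INPUT
#     sampling coordinates, so warping x by grid g gives out(p) = x(g(p));
#   * sampling coordinates outside [-1, 1] are clamped to the border.

.check_shape <- function(shape) {
  shape <- as.integer(shape)
  n <- length(shape)
  if (!n %in% c(2L, 3L)) stop("shape must have 2 or 3 extents")
  if (any(shape < 2L)) stop("degenerate axis: every extent must be >= 2")
  shape
}

# identity coordinate matrix (npos x n), cached per shape
.id_coords <- function(shape) {
  .cache_get(paste0("id:", paste(shape, collapse = ",")), function() {
    axes <- lapply(shape, function(S) seq(-1, 1, length.out = S))
    as.matrix(do.call(expand.grid, axes))
  })
}

# homogeneous coordinate matrix [coords | 1] (npos x (n+1)), cached
.homog_coords <- function(shape) {
  .cache_get(paste0("hg:", paste(shape, collapse = ",")), function() {
    cbind(.id_coords(shape), 1)
  })
}

#' Identity sampling grid on a normalised coordinate system
#'
#' @param shape integer extents (each \eqn{\ge 2}).
#' @return A \linkS4class{CoordinateGrid} whose corners map to exactly
#'   \eqn{\pm 1}.
#' @examples
#' g <- makeIdentityGrid(c(3, 3))
#' gridCoords(g)[5, ]  # centre point is (0, 0)
#' @export
makeIdentityGrid <- function(shape) {
  shape <- .check_shape(shape)
  m <- .id_coords(shape)
  dimnames(m) <- NULL
  new("CoordinateGrid", coords = m, shape = shape)
}

#' Apply affine parameters to the identity grid
#'
#' Each identity grid point \eqn{p} is mapped to \eqn{A p + t}.
#'
#' @param params \linkS4class{AffineParams} or a plain n x (n+1) matrix.
#' @param shape integer extents of the target grid.
#' @return A \linkS4class{CoordinateGrid}.
#' @export
affineToGrid <- function(params, shape) {
  shape <- .check_shape(shape)
  A <- if (is(params, "AffineParams")) params@mat else params
  if (nrow(A) != length(shape) || ncol(A) != length(shape) + 1L)
    stop("affine matrix dimensions do not match the grid dimensionality")
  new("CoordinateGrid", coords = .homog_coords(shape) %*% t(A), shape = shape)
}

# core resampler on an (npos x C) value matrix
.gs <- function(xmat, sdim, grid, interp = "linear") {
  if (ncol(grid@coords) != length(sdim))
    stop("grid dimensionality does not match the image dimensionality")
  .cpp_grid_sample_fw(xmat, as.integer(sdim), grid@coords,
                      identical(interp, "nearest"))
}

#' Resample an image, label volume or feature map at a coordinate grid
#'
#' Pull warping: \code{out(p) = x(grid(p))} by n-linear (or nearest)
#' interpolation, with border clamping for out-of-range coordinates.  The
#' output has the grid's spatial shape.
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{LatentFeature}, or a
#'   plain numeric array (e.g. an integer label volume).
#' @param grid a \linkS4class{CoordinateGrid}.
#' @param interp \code{"linear"} or \code{"nearest"} (use nearest for label
#'   masks).
#' @return The same kind of object as \code{x}, on the grid's shape.
#' @export
setGeneric("resampleImage",
           function(x, grid, interp = c("linear", "nearest"))
             standardGeneric("resampleImage"))

#' @rdname resampleImage
#' @export
setMethod("resampleImage", "ImageVolume", function(x, grid, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  out <- .gs(matrix(as.vector(x@values), ncol = 1), dim(x@values), grid, interp)
  ImageVolume(array(out, grid@shape), x@spacing, x@modality, x@header)
})

#' @rdname resampleImage
#' @export
setMethod("resampleImage", "LatentFeature", function(x, grid, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  LatentFeature(.gs(x@values, x@shape, grid, interp), grid@shape)
})

#' @rdname resampleImage
#' @export
setMethod("resampleImage", "array", function(x, grid, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  out <- .gs(matrix(as.vector(x), ncol = 1), dim(x), grid, interp)
  if (interp == "nearest" && is.integer(x)) storage.mode(out) <- "integer"
  array(out, grid@shape)
})

#' @rdname resampleImage
#' @export
setMethod("resampleImage", "matrix", function(x, grid, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  out <- .gs(matrix(as.vector(x), ncol = 1), dim(x), grid, interp)
  if (interp == "nearest" && is.integer(x)) storage.mode(out) <- "integer"
  array(out, grid@shape)
})

#' Compose two sampling grids
#'
#' Returns the grid realising "apply \code{first}, then \code{second}":
#' sequentially warping an image by \code{first} and then by \code{second}
#' equals a single warp by the composed grid (up to interpolation error at
#' interior points).  In pull convention the composed grid is
#' \code{first(second(p))}, i.e. \code{first}'s coordinate map resampled at
#' \code{second}.
#'
#' @param first,second \linkS4class{CoordinateGrid}s of equal dimensionality.
#' @return A \linkS4class{CoordinateGrid} on \code{second}'s shape.
#' @export
composeGrids <- function(first, second) {
  if (length(first@shape) != length(second@shape))
    stop("grids must have the same dimensionality")
  coords <- .cpp_grid_sample_fw(first@coords, first@shape, second@coords, FALSE)
  new("CoordinateGrid", coords = coords, shape = second@shape)
}

#' Linearly upsample a displacement field onto a finer grid
#'
#' Each displacement component is linearly interpolated onto the target grid.
#' Displacements are expressed in normalised coordinates, so values need no
#' rescaling when the resolution changes.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param targetShape integer extents, each \eqn{\ge} the source extent.
#' @return A \linkS4class{DisplacementField} on \code{targetShape}.
#' @export
upsampleField <- function(field, targetShape) {
  targetShape <- .check_shape(targetShape)
  if (length(targetShape) != length(field@shape))
    stop("target dimensionality does not match the field dimensionality")
  if (any(targetShape < field@shape))
    stop("target extents must be >= source extents")
  disp <- .cpp_grid_sample_fw(field@disp, field@shape,
                              .id_coords(targetShape), FALSE)
  DisplacementField(disp, targetShape)
}

#' Realised sampling grid of a composite transform
#'
#' The affine map is applied first; the non-rigid displacement is then added,
#' yielding a single composed grid so the moving image is interpolated once.
#'
#' @param transform a \linkS4class{CompositeTransform}.
#' @return A \linkS4class{CoordinateGrid} on the transform's field shape.
#' @export
transformGrid <- function(transform) {
  shape <- transform@nonrigid@shape
  g <- affineToGrid(transform@affine, shape)
  new("CoordinateGrid", coords = g@coords + transform@nonrigid@disp,
      shape = shape)
}

#' Apply a composite transform to an image or label volume
#'
#' @param x an \linkS4class{ImageVolume} or array.
#' @param transform a \linkS4class{CompositeTransform}.
#' @param interp interpolation scheme; label masks should use
#'   \code{"nearest"}.
#' @export
applyTransform <- function(x, transform, interp = c("linear", "nearest")) {
  resampleImage(x, transformGrid(transform), match.arg(interp))
}

#' Numerically invert a sampling grid by fixed-point iteration
#'
#' Solves \eqn{g(p + e(p)) = p} for the inverse displacement \eqn{e} by the
#' iteration \eqn{e \leftarrow -D(p + e)}, where \eqn{D = g - \mathrm{id}} is
#' the total displacement (evaluated off-grid by linear interpolation).
#' Converges for moderate, smooth transforms; used to verify that generated
#' ground-truth transforms are self-consistent.
#'
#' @param grid a \linkS4class{CoordinateGrid}.
#' @param iterations fixed-point iterations (default 20).
#' @return The inverse \linkS4class{CoordinateGrid}.
#' @export
invertGrid <- function(grid, iterations = 20L) {
  idm <- .id_coords(grid@shape)
  D <- grid@coords - idm
  e <- matrix(0, nrow(idm), ncol(idm))
  for (i in seq_len(iterations)) {
    probe <- new("CoordinateGrid", coords = idm + e, shape = grid@shape)
    e <- -.cpp_grid_sample_fw(D, grid@shape, probe@coords, FALSE)
  }
  new("CoordinateGrid", coords = idm + e, shape = grid@shape)
}
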