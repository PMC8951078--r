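# NIfTI input/output and run-configuration handling.
#
# Images are normalised to [-1, 1] per volume min/max at load time (constant
# volumes map to 0); voxel spacing is read from the header and the header is
# retained for write-back.  Axis order follows the NIfTI array order as
# loaded; no reorientation to RAS is attempted.

#' Read a NIfTI image as a normalised ImageVolume
#'
#' Intensities are linearly rescaled to \eqn{[-1, 1]} using the volume's own
#' min/max (a constant volume maps to all zeros); NaN voxels are rejected.
#'
#' @param path a readable \code{.nii} / \code{.nii.gz} file.
#' @param modality modality tag to attach.
#' @return An \linkS4class{ImageVolume} carrying the source header.
#' @export
readImageVolume <- function(path, modality = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (anyNA(arr)) stop("volume contains NaN voxels: ", path)
  if (length(dim(arr)) == 1L) stop("expected a 2-D or 3-D volume: ", path)
  rng <- range(arr)
  vals <- if (rng[2] > rng[1])
    2 * (arr - rng[1]) / (rng[2] - rng[1]) - 1 else arr * 0
  spacing <- RNifti::pixdim(img)[seq_along(dim(arr))]
  ImageVolume(array(vals, dim(arr)), spacing = spacing, modality = modality,
              header = RNifti::niftiHeader(img))
}

#' Read a NIfTI label volume (no rescaling)
#'
#' @param path a readable NIfTI file of integer labels.
#' @return Integer array.
#' @export
readLabelVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  if (anyNA(arr)) stop("label volume contains NaN voxels: ", path)
  storage.mode(arr) <- "integer"
  arr
}

#' Write an ImageVolume as NIfTI
#'
#' Values are written in normalised units unless a de-normalisation range is
#' supplied; the reference header's affine and spacing are preserved.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param reference optional NIfTI header (defaults to the volume's own, if
#'   carried).
#' @param denorm optional \code{c(min, max)} range to map \eqn{[-1, 1]} back
#'   onto.
#' @export
writeImageVolume <- function(vol, path, reference = NULL, denorm = NULL) {
  vals <- vol@values
  if (!is.null(denorm))
    vals <- (vals + 1) / 2 * (denorm[2] - denorm[1]) + denorm[1]
  ref <- if (!is.null(reference)) reference else vol@header
  img <- if (!is.null(ref)) RNifti::asNifti(vals, reference = ref)
         else RNifti::asNifti(vals)
  if (is.null(ref)) RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an integer label volume as NIfTI
#'
#' Masks are written as unsigned integers; the header description notes the
#' nearest-neighbour provenance.
#'
#' @param labels integer array.
#' @param path output path.
#' @param reference optional NIfTI header.
#' @export
writeLabelVolume <- function(labels, path, reference = NULL) {
  storage.mode(labels) <- "integer"
  img <- if (!is.null(reference))
    RNifti::asNifti(labels, reference = reference)
  else RNifti::asNifti(labels)
  img <- RNifti::asNifti(img, reference = list(
    descrip = "labels; warp with nearest-neighbour"))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a displacement field as multi-component NIfTI with a JSON sidecar
#'
#' The field is stored as an (extents..., n) array in normalised-coordinate
#' units; the sidecar documents the convention (pull warping, align-corners).
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param path output path (\code{.nii} / \code{.nii.gz}); the sidecar gets
#'   the same name with extension \code{.json}.
#' @export
writeField <- function(field, path) {
  n <- length(field@shape)
  arr <- array(field@disp, c(field@shape, n))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(kind = "displacement_field",
                            units = "normalized_coordinates",
                            convention = list(warp = "pull",
                                              corners = "align-corners",
                                              out_of_range = "clamp"),
                            shape = field@shape, components = n),
                       side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a displacement field written by \code{\link{writeField}}
#'
#' @param path the NIfTI path.
#' @return A \linkS4class{DisplacementField}.
#' @export
readField <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  n <- d[length(d)]
  shape <- d[-length(d)]
  DisplacementField(matrix(as.vector(arr), prod(shape), n), shape)
}

# ---- run configuration ----------------------------------------------------

.runconfig_keys <- function() list(
  model = names(formals(modelConfig)),
  train = names(formals(trainConfig)),
  data = c("nSamples", "nEval", "shape", "K", "strength", "noiseSd",
           "biasAmp", "pairs"),
  output = c("dir"))

#' Read and validate a YAML run configuration
#'
#' Recognised top-level sections: \code{model}, \code{train}, \code{data},
#' \code{output}.  Unknown keys (at either level) are rejected; values
#' round-trip through serialisation unchanged.
#'
#' @param path a YAML file.
#' @return Validated nested list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  keys <- .runconfig_keys()
  bad <- setdiff(names(cfg), names(keys))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    extra <- setdiff(names(cfg[[sec]]), keys[[sec]])
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
  }
  cfg
}

#' Write a run configuration
#' @param cfg nested configuration list.
#' @param path output YAML path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
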