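# The full loss and regularisation system, evaluated from a ForwardBundle.
#
# Every similarity term is a root-mean-square (RMS) error on normalised
# inputs, so apart from the smoothness weight lambda no hyperparameter
# balances the terms.  The same term formulas serve both the numeric path
# (public functions on a ForwardBundle) and the training path (autodiff
# nodes), through a small interface of get/rms/bend callbacks.

#' Root-mean-square error between two equally-shaped arrays
#'
#' @param a,b numeric arrays of identical shape.
#' @return \eqn{\sqrt{\mathrm{mean}((a-b)^2)}}; symmetric, zero iff
#'   \code{a == b}.
#' @export
rmsError <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("rmsError: shapes must match")
  d <- as.numeric(a) - as.numeric(b)
  sqrt(mean(d * d))
}

#' Smoothness weight for the bending-energy regulariser
#'
#' The single hyperparameter of the loss system:
#' \eqn{\lambda = 2^{2n} / (10 N)} for n-D images with N voxels.
#'
#' @param n spatial dimensionality (2 or 3).
#' @param N number of points in the input image.
#' @export
smoothWeight <- function(n, N) {
  if (!n %in% c(2, 3)) stop("n must be 2 or 3")
  if (N <= 0) stop("N must be positive")
  2^(2 * n) / (10 * N)
}

#' Bending energy of a displacement field
#'
#' Mean over interior points and components of the sum of squared
#' second-order finite differences (central differences; mixed partials
#' counted for both axis orders).  Zero for any globally affine displacement.
#' The \code{"laplacian"} variant penalises the squared discrete Laplacian
#' instead.
#'
#' @param field a \linkS4class{DisplacementField} (extents \eqn{\ge 3}).
#' @param type \code{"bending"} (default) or \code{"laplacian"}.
#' @export
bendingEnergy <- function(field, type = c("bending", "laplacian")) {
  type <- match.arg(type)
  if (any(field@shape < 3L))
    stop("field extents must be >= 3 for bending energy")
  D <- .bending_operator(field@shape, type)
  e <- as.matrix(D %*% field@disp)
  sum(e * e) / (attr(D, "ninterior") * ncol(field@disp))
}

# ---- shared term assembly -------------------------------------------------

# Fi: list(get = function(name), rms = function(a, b), bend = function(u),
#          plus = function(a, b), affineReg = logical)
.loss_terms <- function(Fi) {
  g <- Fi$get
  p2 <- function(a, b) Fi$plus(a, b)
  terms <- list(
    synAcc   = p2(Fi$rms(g("hatTB"), g("xB")), Fi$rms(g("hatTA"), g("xA"))),
    synFea   = p2(Fi$rms(g("gA"), g("gBwarpBA")), Fi$rms(g("gB"), g("gAwarpAB"))),
    synCyc   = p2(Fi$rms(g("cycBA"), g("xA")), Fi$rms(g("cycAB"), g("xB"))),
    synAlign = p2(Fi$rms(g("gA"), g("encHatB")), Fi$rms(g("gB"), g("encHatA"))),
    regAcc   = p2(Fi$rms(g("regAB"), g("xB")), Fi$rms(g("regBA"), g("xA"))),
    regIc    = p2(Fi$rms(g("xA"), g("xAic")), Fi$rms(g("xB"), g("xBic"))))
  if (isTRUE(Fi$affineReg)) {
    terms$rSyn <- p2(Fi$rms(g("xB"), g("rsynAB")), Fi$rms(g("xA"), g("rsynBA")))
    terms$rReg <- p2(Fi$rms(g("xB"), g("rregAB")), Fi$rms(g("xA"), g("rregBA")))
  }
  terms$rSmooth <- p2(Fi$bend(g("uAB")), Fi$bend(g("uBA")))
  terms
}

.numeric_interface <- function(bundle) {
  lat <- bundle@latentShape
  list(
    get = function(name) bundle@fields[[name]],
    rms = function(a, b) rmsError(a, b),
    bend = function(u) if (any(lat < 3L)) 0 else
      bendingEnergy(DisplacementField(u, lat)),
    plus = `+`,
    affineReg = TRUE)
}

# ---- public loss operations -----------------------------------------------

#' Synthesis loss components
#'
#' Four RMS terms: synthesis accuracy (warped-feature decodes vs the
#' targets), modality-invariant feature agreement (each latent vs the
#' other's warped latent, at latent resolution), cycle consistency
#' (re-encode/decode of the synthesised images vs the originals) and
#' synthesis alignment (each latent vs the re-encoded synthesis).
#'
#' @param bundle a \linkS4class{ForwardBundle}.
#' @return Named numeric: \code{synAcc}, \code{synFea}, \code{synCyc},
#'   \code{synAlign}, and their sum \code{total}.
#' @export
synthesisLoss <- function(bundle) {
  t <- .loss_terms(.numeric_interface(bundle))
  out <- c(synAcc = t$synAcc, synFea = t$synFea, synCyc = t$synCyc,
           synAlign = t$synAlign)
  c(out, total = sum(out))
}

#' Registration loss components
#'
#' The registration-accuracy term compares the synthesis of the warped
#' moving image with the fixed image (the transform is applied to the image
#' before encoding), and the inverse-consistency term compares each image
#' with itself warped through both transforms composed (single composed-grid
#' interpolation).
#'
#' @param bundle a \linkS4class{ForwardBundle}.
#' @return Named numeric: \code{regAcc}, \code{regIc}, and their sum
#'   \code{total}.
#' @export
registrationLoss <- function(bundle) {
  t <- .loss_terms(.numeric_interface(bundle))
  out <- c(regAcc = t$regAcc, regIc = t$regIc)
  c(out, total = sum(out))
}

#' Regularisation components
#'
#' Affine-elimination terms (synthesis and registration through the
#' affine-only warps) plus the bending-energy smoothness penalty of both
#' non-rigid fields, combined as \eqn{R_{syn} + R_{reg} + \lambda R_{smooth}}.
#'
#' @param bundle a \linkS4class{ForwardBundle}.
#' @param lambda smoothness weight (see \code{\link{smoothWeight}}).
#' @return Named numeric: \code{rSyn}, \code{rReg}, \code{rSmooth}, and the
#'   weighted sum \code{total}.
#' @export
regularizationLoss <- function(bundle, lambda) {
  t <- .loss_terms(.numeric_interface(bundle))
  out <- c(rSyn = t$rSyn, rReg = t$rReg, rSmooth = t$rSmooth)
  c(out, total = t$rSyn + t$rReg + lambda * t$rSmooth)
}

#' Total loss of a forward bundle
#'
#' The sum of the synthesis terms, the registration terms and the
#' regularisation; apart from \code{lambda}, no hyperparameter weights any
#' term.
#'
#' @param bundle a \linkS4class{ForwardBundle}.
#' @param lambda smoothness weight; \code{NULL} applies the
#'   \code{\link{smoothWeight}} rule for the bundle's image size.
#' @return A \linkS4class{LossReport}.
#' @export
totalLoss <- function(bundle, lambda = NULL) {
  if (is.null(lambda))
    lambda <- smoothWeight(length(bundle@shape), prod(bundle@shape))
  t <- .loss_terms(.numeric_interface(bundle))
  v <- unlist(t)
  total <- v[["synAcc"]] + v[["synFea"]] + v[["synCyc"]] + v[["synAlign"]] +
    v[["regAcc"]] + v[["regIc"]] + v[["rSyn"]] + v[["rReg"]] +
    lambda * v[["rSmooth"]]
  LossReport(c(v[.loss_term_names[1:9]], lambda = lambda, total = total))
}

# training-path assembly on autodiff nodes; returns list(total node, term
# nodes) so non-finite diagnostics can name the offending term
.loss_graph <- function(ctx, o, lambda, affineReg = TRUE) {
  tp <- ctx$tape
  Fi <- list(
    get = function(name) {
      switch(name,
             gAaff = o$tAB$gMovAff, gBaff = o$tBA$gMovAff,
             uAB = o$tAB$u, uBA = o$tBA$u,
             o[[name]])
    },
    rms = function(a, b) .ad_rms(tp, a, b),
    bend = function(u) .ad_bending(tp, u),
    plus = function(a, b) .ad_sum(tp, list(a, b)),
    affineReg = affineReg)
  terms <- .loss_terms(Fi)
  parts <- terms[setdiff(names(terms), "rSmooth")]
  parts$rSmoothW <- .ad_scale(tp, terms$rSmooth, lambda)
  total <- .ad_sum(tp, unname(parts))
  list(total = total, terms = terms, lambda = lambda)
}
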