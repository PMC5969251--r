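#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib atriascar, .registration = TRUE
NULL

#' Default voxel-to-world affine for a given spacing
#'
#' Maps 0-based voxel indices to world millimetres with axis-aligned scaling
#' and zero origin.
#'
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return 4x4 affine matrix.
#' @export
defaultAffine <- function(spacing) {
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values (mm)")
  }
  diag(c(spacing, 1))
}

setClass("ImageGrid", representation("VIRTUAL",
  spacing = "numeric",
  affine = "matrix"
))

validImageGrid <- function(object) {
  msg <- NULL
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three strictly positive finite values (mm)")
  }
  if (!identical(dim(object@affine), c(4L, 4L))) {
    msg <- c(msg, "affine must be a 4x4 matrix")
  } else if (abs(det(object@affine)) < 1e-12) {
    msg <- c(msg, "affine must be invertible")
  }
  if (is.null(msg)) TRUE else msg
}

#' Volume3D: a 3D scalar image with voxel spacing and voxel-to-world affine
#'
#' The central image container of the pipeline: a 3D array of finite scalar
#' intensities, per-axis voxel spacing in millimetres, and a 4x4 affine that
#' maps 0-based voxel indices (homogeneous) to world coordinates in mm.
#' Slices run along the third array dimension.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), strictly positive, mm.
#' @slot affine 4x4 invertible voxel-to-world matrix.
#' @export
setClass("Volume3D", contains = "ImageGrid", representation(data = "array"),
  validity = function(object) {
    msg <- validImageGrid(object)
    msg <- if (isTRUE(msg)) NULL else msg
    if (length(dim(object@data)) != 3) {
      msg <- c(msg, "data must be a 3D array")
    }
    if (any(!is.finite(object@data))) {
      msg <- c(msg, "data must be finite everywhere")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn Volume3D-class Constructor.
#' @param data 3D numeric array.
#' @param spacing voxel spacing (mm), default c(1, 1, 1).
#' @param affine voxel-to-world matrix; default axis-aligned from spacing.
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), affine = defaultAffine(spacing)) {
  new("Volume3D", data = data, spacing = as.numeric(spacing), affine = affine)
}

#' LabelMap: multi-label whole-heart segmentation on a volume grid
#'
#' Integer labels for cardiac substructures on the same grid conventions as
#' \linkS4class{Volume3D}. The label dictionary maps structure names to
#' integer codes; background is 0 and the left atrium plus pulmonary veins
#' (\code{"LA_PV"}) is 1 by convention.
#'
#' @slot data 3D integer array.
#' @slot labelDict named integer vector, name -> label code.
#' @export
setClass("LabelMap", contains = "ImageGrid",
  representation(data = "array", labelDict = "integer"),
  validity = function(object) {
    msg <- validImageGrid(object)
    msg <- if (isTRUE(msg)) NULL else msg
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be a 3D array")
    vals <- unique(as.integer(object@data))
    if (!all(vals %in% object@labelDict)) {
      msg <- c(msg, "every voxel value must appear in labelDict")
    }
    if (is.null(names(object@labelDict)) && length(object@labelDict) > 0) {
      msg <- c(msg, "labelDict must be named")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Standard whole-heart label dictionary
#'
#' Background plus six substructures: LA+PV, LV, RV, RA, aorta, pulmonary
#' artery.
#' @return named integer vector.
#' @export
heartLabelDict <- function() {
  c(background = 0L, LA_PV = 1L, LV = 2L, RV = 3L, RA = 4L, AO = 5L, PA = 6L)
}

#' @describeIn LabelMap-class Constructor.
#' @param data 3D integer array.
#' @param spacing voxel spacing (mm).
#' @param affine voxel-to-world matrix.
#' @param labelDict named integer vector.
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1),
                     affine = defaultAffine(spacing),
                     labelDict = heartLabelDict()) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing), affine = affine,
      labelDict = labelDict)
}

#' BinaryMask: a single-structure mask on a volume grid
#'
#' @slot data 3D logical array.
#' @export
setClass("BinaryMask", contains = "ImageGrid", representation(data = "array"),
  validity = function(object) {
    msg <- validImageGrid(object)
    msg <- if (isTRUE(msg)) NULL else msg
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be a 3D array")
    if (!is.logical(object@data)) msg <- c(msg, "data must be logical")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn BinaryMask-class Constructor.
#' @param data 3D logical array.
#' @param spacing voxel spacing (mm).
#' @param affine voxel-to-world matrix.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1),
                       affine = defaultAffine(spacing)) {
  storage.mode(data) <- "logical"
  new("BinaryMask", data = data, spacing = as.numeric(spacing), affine = affine)
}

#' SuperpixelMap: per-slice super-pixel assignment
#'
#' Every pixel of every slice belongs to exactly one super-pixel; ids are
#' globally unique across slices. The centers table carries one row per
#' super-pixel: id, slice, size, mean intensity and spatial centroid
#' (0-based pixel coordinates within the slice).
#'
#' @slot data 3D integer array of super-pixel ids (>= 1).
#' @slot centers data.frame with columns sp_id, slice, size, mean_intensity,
#'   cx, cy.
#' @export
setClass("SuperpixelMap", contains = "ImageGrid",
  representation(data = "array", centers = "data.frame"),
  validity = function(object) {
    msg <- validImageGrid(object)
    msg <- if (isTRUE(msg)) NULL else msg
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be a 3D array")
    if (anyNA(object@data)) msg <- c(msg, "every pixel must be assigned")
    need <- c("sp_id", "slice", "size", "mean_intensity", "cx", "cy")
    if (!all(need %in% names(object@centers))) {
      msg <- c(msg, "centers must have columns sp_id, slice, size, mean_intensity, cx, cy")
    }
    if (is.null(msg)) TRUE else msg
  })

#' TransformChain: ordered composition of spatial transforms
#'
#' Each element is a list with a \code{kind} field: \code{"affine"} (4x4
#' world-to-world matrix), \code{"local_affine_set"} (per-substructure
#' affines blended by Gaussian distance weights) or \code{"deformation_field"}
#' (dense world-mm displacements on a reference grid). Applying the chain to
#' target-space world points maps them into the moving (atlas) image's world
#' space; transforms are applied left to right.
#'
#' @slot transforms list of transform descriptors.
#' @export
setClass("TransformChain", representation(transforms = "list"),
  validity = function(object) {
    kinds <- vapply(object@transforms, function(t) t$kind %||% "", "")
    ok <- kinds %in% c("affine", "local_affine_set", "deformation_field")
    if (all(ok)) TRUE else "unknown transform kind"
  })

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn TransformChain-class Constructor.
#' @param transforms list of transform descriptors (may be empty: identity).
#' @export
TransformChain <- function(transforms = list()) {
  new("TransformChain", transforms = transforms)
}

#' RegistrationResult: transform chain plus optimisation diagnostics
#'
#' @slot chain the estimated \linkS4class{TransformChain}.
#' @slot similarity final similarity value (spatially encoded MI).
#' @slot trace numeric vector of similarity values across optimisation.
#' @slot extras list of stage-specific diagnostics (e.g. per-substructure
#'   affines for the local-affine stage).
#' @export
setClass("RegistrationResult", representation(
  chain = "TransformChain", similarity = "numeric", trace = "numeric",
  extras = "list"),
  validity = function(object) {
    msg <- NULL
    if (!is.finite(object@similarity)) msg <- c(msg, "similarity must be finite")
    if (length(object@trace) < 1) msg <- c(msg, "trace must be non-empty")
    if (is.null(msg)) TRUE else msg
  })

RegistrationResult <- function(chain, similarity, trace, extras = list()) {
  new("RegistrationResult", chain = chain, similarity = similarity,
      trace = as.numeric(trace), extras = extras)
}
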