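# Binary morphology with ellipsoidal structuring elements sized in mm.
# The per-axis voxel radius is round(mm / spacing), minimum 1, so anisotropic
# grids get anisotropic (ellipsoidal) elements.

ellipsoidOffsets <- function(radiiVox) {
  r <- pmax(1L, as.integer(radiiVox))
  g <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  keep <- (g$x / r[1])^2 + (g$y / r[2])^2 + (g$z / r[3])^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

mmRadiusToVox <- function(mm, spacing) pmax(1L, as.integer(round(mm / spacing)))

#' Binary dilation / erosion by a metric radius
#'
#' Structuring element: ellipsoid with per-axis voxel radius
#' \code{round(mm / spacing)} (minimum 1 voxel).
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param mm structuring radius in millimetres.
#' @return a \linkS4class{BinaryMask} on the same grid.
#' @export
dilateMask <- function(mask, mm) {
  off <- ellipsoidOffsets(mmRadiusToVox(mm, mask@spacing))
  d <- dim(mask@data)
  out <- cpp_dilate_offsets(as.logical(mask@data), d, off)
  BinaryMask(array(out, d), spacing = mask@spacing, affine = mask@affine)
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, mm) {
  off <- ellipsoidOffsets(mmRadiusToVox(mm, mask@spacing))
  d <- dim(mask@data)
  inv <- cpp_dilate_offsets(!as.logical(mask@data), d, off)
  BinaryMask(array(!inv & mask@data, d), spacing = mask@spacing,
             affine = mask@affine)
}
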