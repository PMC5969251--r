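#' Image data accessor
#' @param x an image-like object.
#' @return the underlying 3D array.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Voxel spacing accessor (mm)
#' @param x an image-like object.
#' @return numeric(3).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Voxel-to-world affine accessor
#' @param x an image-like object.
#' @return 4x4 matrix.
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' Label dictionary accessor
#' @param x a LabelMap.
#' @return named integer vector.
#' @export
setGeneric("labelDict", function(x) standardGeneric("labelDict"))

#' Super-pixel centers table accessor
#' @param x a SuperpixelMap.
#' @return data.frame of per-super-pixel summaries.
#' @export
setGeneric("spCenters", function(x) standardGeneric("spCenters"))

#' @rdname imgData
#' @export
setMethod("imgData", "ImageGrid", function(x) x@data)
#' @rdname spacing
#' @export
setMethod("spacing", "ImageGrid", function(x) x@spacing)
#' @rdname affine
#' @export
setMethod("affine", "ImageGrid", function(x) x@affine)
#' @rdname labelDict
#' @export
setMethod("labelDict", "LabelMap", function(x) x@labelDict)
#' @rdname spCenters
#' @export
setMethod("spCenters", "SuperpixelMap", function(x) x@centers)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D %dx%dx%d, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  tab <- table(factor(object@data, levels = object@labelDict))
  names(tab) <- names(object@labelDict)[match(names(tab), as.character(object@labelDict))]
  cat(sprintf("LabelMap %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat("  voxels per label:", paste(names(tab), as.integer(tab), sep = "=",
                                   collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask %dx%dx%d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "SuperpixelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("SuperpixelMap %dx%dx%d, %d super-pixels on %d slices\n",
              d[1], d[2], d[3], nrow(object@centers),
              length(unique(object@centers$slice))))
})

setMethod("show", "TransformChain", function(object) {
  kinds <- vapply(object@transforms, function(t) t$kind, "")
  if (length(kinds) == 0) kinds <- "identity"
  cat("TransformChain:", paste(kinds, collapse = " -> "), "\n")
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: similarity %.6g after %d evaluations\n",
              object@similarity, length(object@trace)))
  show(object@chain)
})
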