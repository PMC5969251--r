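#' @importFrom RNifti readNifti writeNifti asNifti pixdim xform
NULL

# 0-based voxel index grid of a volume, column-major order (N x 3)
voxelGrid <- function(d) {
  cbind(rep.int(0:(d[1] - 1L), times = d[2] * d[3]),
        rep.int(rep.int(0:(d[2] - 1L), rep.int(d[1], d[2])), d[3]),
        rep.int(0:(d[3] - 1L), rep.int(d[1] * d[2], d[3])))
}

# apply a 4x4 affine to N x 3 points
applyAffine <- function(A, pts) {
  sweep(pts %*% t(A[1:3, 1:3, drop = FALSE]), 2, A[1:3, 4], "+")
}

voxToWorld <- function(A, vox) applyAffine(A, vox)
worldToVox <- function(A, pts) applyAffine(solve(A), pts)

sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@affine - b@affine)) < tol
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a \linkS4class{Volume3D}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3) stop("expected a 3D image, got ", length(d), " dimensions")
  arr <- array(as.numeric(im), dim = d)
  if (any(!is.finite(arr))) stop("volume contains non-finite voxels")
  A <- structure(RNifti::xform(im, useQuaternionFirst = FALSE), class = NULL)
  A <- matrix(as.numeric(A), 4, 4)
  sp <- abs(RNifti::pixdim(im))[1:3]
  Volume3D(arr, spacing = sp, affine = A)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' The voxel-to-world affine is stored in the sform; data are written as
#' float32 (or int32 for integer arrays), so round trips are bit-exact for
#' those types.
#'
#' @param v a \linkS4class{Volume3D} (or the grid information of a LabelMap /
#'   BinaryMask via their writers).
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(v, path) {
  writeNiftiArray(v@data, v@spacing, v@affine, path,
                  datatype = if (is.integer(v@data)) "int32" else "float")
  invisible(path)
}

writeNiftiArray <- function(arr, sp, A, path, datatype = "float") {
  if (is.logical(arr)) { arr <- array(as.integer(arr), dim(arr)); datatype <- "int32" }
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- sp
  RNifti::sform(im) <- structure(A, code = 2L)
  RNifti::writeNifti(im, path, datatype = datatype)
}

#' Read / write a LabelMap with its JSON label-dictionary sidecar
#'
#' The label dictionary (structure name to integer code) is stored next to
#' the NIfTI file with extension \code{.labels.json}.
#'
#' @param path NIfTI path.
#' @return a \linkS4class{LabelMap}.
#' @export
readLabelMap <- function(path) {
  v <- readVolume(path)
  side <- labelSidecar(path)
  dict <- if (file.exists(side)) {
    d <- jsonlite::read_json(side)
    stats::setNames(as.integer(unlist(d)), names(d))
  } else heartLabelDict()
  LabelMap(array(as.integer(round(v@data)), dim(v@data)), spacing = v@spacing,
           affine = v@affine, labelDict = dict)
}

#' @rdname readLabelMap
#' @param lm a \linkS4class{LabelMap} to write.
#' @export
writeLabelMap <- function(lm, path) {
  writeNiftiArray(lm@data, lm@spacing, lm@affine, path, datatype = "int32")
  jsonlite::write_json(as.list(lm@labelDict), labelSidecar(path),
                       auto_unbox = TRUE)
  invisible(path)
}

labelSidecar <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.json", path)
}

#' Resample a volume, label map or mask onto a reference grid
#'
#' Pull-back resampling: every reference voxel is mapped to world
#' coordinates, optionally pushed through a \linkS4class{TransformChain}
#' (target world to moving world), converted to moving voxel coordinates and
#' interpolated. Label maps and masks always use nearest-neighbour
#' interpolation; samples outside the moving grid are filled with background
#' (0 / FALSE).
#'
#' @param moving a Volume3D, LabelMap or BinaryMask.
#' @param reference a Volume3D (or any ImageGrid) defining the output grid.
#' @param interp "linear" or "nearest" (ignored for labels/masks: nearest).
#' @param chain optional TransformChain applied to reference world points.
#' @return an object of the same class as \code{moving} on the reference grid.
#' @export
resampleToGrid <- function(moving, reference, interp = c("linear", "nearest"),
                           chain = TransformChain()) {
  interp <- match.arg(interp)
  if (is(moving, "LabelMap") || is(moving, "BinaryMask")) interp <- "nearest"
  d <- dim(reference@data)
  pts <- voxToWorld(reference@affine, voxelGrid(d))
  pts <- applyTransformChain(chain, pts)
  vox <- worldToVox(moving@affine, pts)
  icode <- if (interp == "nearest") 0L else 1L
  src <- moving@data
  vals <- cpp_interp(as.numeric(src), dim(src), vox, icode, 0)
  if (is(moving, "LabelMap")) {
    LabelMap(array(as.integer(round(vals)), d), spacing = reference@spacing,
             affine = reference@affine, labelDict = moving@labelDict)
  } else if (is(moving, "BinaryMask")) {
    BinaryMask(array(vals > 0.5, d), spacing = reference@spacing,
               affine = reference@affine)
  } else {
    Volume3D(array(vals, d), spacing = reference@spacing,
             affine = reference@affine)
  }
}

#' Apply a transform chain to world points
#'
#' @param chain a \linkS4class{TransformChain}.
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of mapped world coordinates.
#' @export
applyTransformChain <- function(chain, pts) {
  for (tr in chain@transforms) {
    pts <- switch(tr$kind,
      affine = applyAffine(tr$matrix, pts),
      local_affine_set = applyLocalAffineSet(tr, pts),
      deformation_field = applyDeformationField(tr, pts),
      stop("unknown transform kind: ", tr$kind))
  }
  pts
}

applyLocalAffineSet <- function(tr, pts) {
  k <- length(tr$affines)
  if (k == 0) return(pts)
  wsum <- rep(tr$floor %||% 1e-6, nrow(pts))
  disp <- matrix(0, nrow(pts), 3)
  for (i in seq_len(k)) {
    di <- applyAffine(tr$affines[[i]], pts) - pts
    dd <- sweep(pts, 2, tr$centers[i, ], "-")
    w <- exp(-0.5 * rowSums(dd^2) / tr$sigmas[i]^2)
    disp <- disp + w * di
    wsum <- wsum + w
  }
  pts + disp / wsum
}

applyDeformationField <- function(tr, pts) {
  vox <- worldToVox(tr$affine, pts)
  d <- tr$dim
  disp <- vapply(1:3, function(ax)
    cpp_interp(tr$field[, ax], d, vox, 1L, 0), numeric(nrow(pts)))
  pts + disp
}

#' Compose two transform chains
#'
#' \code{composeChains(a, b)} applies \code{a} first, then \code{b}.
#' @param a,b TransformChain objects.
#' @return a TransformChain.
#' @export
composeChains <- function(a, b) {
  TransformChain(c(a@transforms, b@transforms))
}

affineTransform <- function(M) list(kind = "affine", matrix = M)
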