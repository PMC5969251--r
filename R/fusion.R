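# Label fusion: combine N warped atlas segmentations into one consensus
# labeling. Per voxel, each atlas votes for its label with a weight
# proportional to a local target-atlas similarity; the fused label is the
# weighted argmax (Kronecker-delta accumulation), with ties broken toward
# the lowest label id. Methods: majority vote (MV), local weighted voting
# (LWV, Gaussian of the local mean squared intensity difference),
# single-scale patch fusion (PF, patch-wise conditional probability) and
# multiscale patch fusion (MSP, the PF similarity summed over a Gaussian
# scale space).

#' Label-fusion configuration
#'
#' @param method one of "MV", "LWV", "PF", "MSP".
#' @param patch_radius patch radius in voxels (default 2, i.e. 5^3 patches).
#' @param scales Gaussian scale-space sigmas in voxels (sorted,
#'   non-negative). PF uses the first scale only; MSP sums over all.
#' @param bins Parzen bins for the patch conditional probability.
#' @return a list of class "FusionConfig".
#' @export
fusionConfig <- function(method = c("MSP", "PF", "LWV", "MV"),
                         patch_radius = 2, scales = c(0, 1, 2), bins = 32) {
  method <- match.arg(method)
  stopifnot(patch_radius >= 0, all(scales >= 0), !is.unsorted(scales),
            bins >= 2)
  structure(list(method = method, patch_radius = as.integer(patch_radius),
                 scales = scales, bins = as.integer(bins)),
            class = "FusionConfig")
}

#' Majority-vote label fusion
#'
#' Per voxel the most frequent atlas label wins; ties break to the lowest
#' label id.
#'
#' @param warpedLabels list of \linkS4class{LabelMap}s on a common grid.
#' @return a \linkS4class{LabelMap}.
#' @export
majorityVote <- function(warpedLabels) {
  if (length(warpedLabels) == 0) stop("empty atlas list")
  ref <- warpedLabels[[1]]
  d <- dim(ref@data)
  labs <- sort(unique(unlist(lapply(warpedLabels, function(l)
    unique(as.integer(l@data))))))
  votes <- matrix(0L, prod(d), length(labs))
  for (l in warpedLabels) {
    stopifnot(identical(dim(l@data), d))
    votes <- votes + outer(as.integer(l@data), labs, "==")
  }
  win <- max.col(votes, ties.method = "first") # columns in ascending label order
  LabelMap(array(labs[win], d), spacing = ref@spacing, affine = ref@affine,
           labelDict = ref@labelDict)
}

#' Gaussian scale space of a volume
#'
#' Separable Gaussian smoothing at each requested scale; scale 0 returns the
#' input unchanged. Kernels are truncated at 3 sigma and renormalised at the
#' boundaries, so constant volumes (and total intensity, up to boundary
#' handling) are preserved.
#'
#' @param I a \linkS4class{Volume3D}.
#' @param scales non-negative sigmas in voxels.
#' @return list of Volume3D, one per scale.
#' @export
gaussianScaleSpace <- function(I, scales) {
  if (any(scales < 0)) stop("negative scale")
  lapply(scales, function(s) {
    if (s == 0) return(I)
    hw <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-hw:hw, sd = s)
    k <- k / sum(k)
    arr <- as.numeric(I@data)
    d <- dim(I@data)
    for (ax in 0:2) arr <- cpp_conv1d(arr, d, k, ax)
    Volume3D(array(arr, d), spacing = I@spacing, affine = I@affine)
  })
}

# equal-width global binning to 0-based integer bins
binVolume <- function(arr, bins) {
  r <- range(arr)
  if (r[2] <= r[1]) return(array(0L, dim(arr)))
  array(as.integer(floor((arr - r[1]) / (r[2] - r[1]) * (bins - 1e-9))),
        dim(arr))
}

#' Patch-wise conditional-probability similarity at one voxel
#'
#' Estimates p(i_x | j_x) = p(i_x, j_x) / p(j_x), where i and j are the
#' binned target and atlas intensities and the joint/marginal probabilities
#' are Parzen (box) histograms accumulated over the cubic patch around x.
#' Returns 0 when the marginal p(j_x) is zero.
#'
#' @param I,A target and atlas \linkS4class{Volume3D}s on a common grid
#'   (already at the desired scale).
#' @param x voxel index, 1-based c(i, j, k).
#' @param cfg a \code{\link{fusionConfig}} (patch_radius and bins are used).
#' @return scalar in [0, 1].
#' @export
localSimilarityConditional <- function(I, A, x, cfg = fusionConfig()) {
  d <- dim(I@data)
  stopifnot(identical(d, dim(A@data)), length(x) == 3,
            all(x >= 1), all(x <= d))
  ib <- binVolume(I@data, cfg$bins)
  jb <- binVolume(A@data, cfg$bins)
  idx0 <- (x[1] - 1) + d[1] * ((x[2] - 1) + d[2] * (x[3] - 1))
  p <- cpp_patch_cond_prob(matrix(as.integer(ib), ncol = 1),
                           matrix(as.integer(jb), ncol = 1),
                           d, as.integer(idx0), cfg$patch_radius, cfg$bins)
  p[1, 1]
}

#' Multiscale patch similarity at one voxel
#'
#' Sum over the configured scales of the patch conditional-probability
#' similarity between the target and atlas scale-space images. With a single
#' scale this equals the single-scale patch-fusion similarity.
#'
#' @param I,A target and atlas volumes on a common grid.
#' @param x voxel index, 1-based c(i, j, k).
#' @param cfg a \code{\link{fusionConfig}}.
#' @return scalar (non-negative, at most the number of scales).
#' @export
mspSimilarity <- function(I, A, x, cfg = fusionConfig()) {
  Is <- gaussianScaleSpace(I, cfg$scales)
  As <- gaussianScaleSpace(A, cfg$scales)
  sum(vapply(seq_along(cfg$scales), function(s)
    localSimilarityConditional(Is[[s]], As[[s]], x, cfg), 0))
}

#' Fuse warped atlas segmentations into a consensus labeling
#'
#' Per voxel, accumulates each atlas's label weighted by the configured
#' local similarity and takes the weighted argmax (ties to the lowest label
#' id). With uniform weights (MV, or LWV/PF/MSP on voxels where weights tie)
#' this reduces to majority voting. Voxels where all atlases agree take the
#' consensus label directly.
#'
#' @param warped list of lists with elements \code{volume}
#'   (\linkS4class{Volume3D}) and \code{labels} (\linkS4class{LabelMap}), on
#'   the target grid.
#' @param target target \linkS4class{Volume3D}.
#' @param cfg a \code{\link{fusionConfig}}.
#' @return a \linkS4class{LabelMap}.
#' @export
fuseLabels <- function(warped, target, cfg = fusionConfig()) {
  if (length(warped) == 0) stop("empty atlas list")
  d <- dim(target@data)
  for (w in warped) {
    stopifnot(identical(dim(w$labels@data), d),
              identical(dim(w$volume@data), d))
  }
  labelArrs <- lapply(warped, function(w) as.integer(w$labels@data))
  if (cfg$method == "MV") {
    return(majorityVote(lapply(warped, `[[`, "labels")))
  }
  # voxels where atlases disagree need weighted votes
  agree <- Reduce(`&`, lapply(labelArrs, function(l) l == labelArrs[[1]]))
  cand <- which(!agree)
  fused <- labelArrs[[1]] # consensus everywhere the atlases agree
  if (length(cand) > 0) {
    labs <- sort(unique(unlist(lapply(labelArrs, function(l) unique(l[cand])))))
    votes <- matrix(0, length(cand), length(labs))
    scales <- if (cfg$method == "PF") cfg$scales[1] else cfg$scales
    if (cfg$method %in% c("PF", "MSP")) {
      Is <- gaussianScaleSpace(target, scales)
      tgtBins <- vapply(Is, function(v) as.integer(binVolume(v@data, cfg$bins)),
                        integer(prod(d)))
    }
    for (ai in seq_along(warped)) {
      w <- if (cfg$method == "LWV") {
        lwvWeights(target, warped[[ai]]$volume, cand, cfg)
      } else {
        As <- gaussianScaleSpace(warped[[ai]]$volume, scales)
        atlBins <- vapply(As, function(v) as.integer(binVolume(v@data, cfg$bins)),
                          integer(prod(d)))
        p <- cpp_patch_cond_prob(tgtBins, atlBins, d,
                                 as.integer(cand - 1L), cfg$patch_radius,
                                 cfg$bins)
        rowSums(p)
      }
      li <- labelArrs[[ai]][cand]
      for (j in seq_along(labs)) {
        sel <- li == labs[j]
        votes[sel, j] <- votes[sel, j] + w[sel]
      }
    }
    fused[cand] <- labs[max.col(votes, ties.method = "first")]
  }
  ref <- warped[[1]]$labels
  LabelMap(array(fused, d), spacing = target@spacing, affine = target@affine,
           labelDict = ref@labelDict)
}

# LWV weight: Gaussian of the local mean squared difference over the patch,
# bandwidth = intensity SD of the target
lwvWeights <- function(target, atlasVol, cand, cfg) {
  d <- dim(target@data)
  diff2 <- as.numeric(target@data - atlasVol@data)^2
  k <- rep(1, 2 * cfg$patch_radius + 1)
  k <- k / sum(k)
  for (ax in 0:2) diff2 <- cpp_conv1d(diff2, d, k, ax)
  h <- stats::sd(as.numeric(target@data))
  if (h <= 0) h <- 1
  exp(-diff2[cand] / (2 * h^2))
}
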