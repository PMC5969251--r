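# Training-set construction around the LA wall: the wall is the 3 mm
# morphological dilation shell of the endocardial LA+PV segmentation, the
# blood pool its 5 mm erosion; LGE intensities are z-normalised by
# blood-pool statistics; clicked super-pixels with >= 20% wall overlap
# become "enhanced" training rows, unclicked overlapping ones
# "nonenhanced", and everything else is excluded.

#' Training-set specification
#'
#' @param dilation_mm wall dilation radius in mm (default 3, the assumed LA
#'   wall thickness).
#' @param erosion_mm blood-pool erosion radius in mm (default 5).
#' @param overlap_threshold minimum super-pixel/wall overlap ratio for a
#'   super-pixel to enter the training set (default 0.20).
#' @return a list of class "TrainingSetSpec".
#' @export
trainingSetSpec <- function(dilation_mm = 3, erosion_mm = 5,
                            overlap_threshold = 0.20) {
  stopifnot(dilation_mm > 0, erosion_mm > 0,
            overlap_threshold > 0, overlap_threshold <= 1)
  structure(list(dilation_mm = dilation_mm, erosion_mm = erosion_mm,
                 overlap_threshold = overlap_threshold),
            class = "TrainingSetSpec")
}

#' Extract the LA wall from the endocardial segmentation
#'
#' Wall = dilation of the endocardial LA+PV mask by a metric radius, minus
#' the endocardium itself (so wall and endocardium never intersect).
#'
#' @param endo endocardial \linkS4class{BinaryMask}.
#' @param dilation_mm dilation radius in mm.
#' @return wall \linkS4class{BinaryMask}.
#' @export
extractWall <- function(endo, dilation_mm = 3) {
  if (!any(endo@data)) stop("empty endocardial mask")
  dil <- dilateMask(endo, dilation_mm)
  BinaryMask(dil@data & !endo@data, spacing = endo@spacing,
             affine = endo@affine)
}

#' Extract the blood pool by erosion of the endocardium
#'
#' @param endo endocardial \linkS4class{BinaryMask}.
#' @param erosion_mm erosion radius in mm.
#' @return blood-pool \linkS4class{BinaryMask} (subset of endo).
#' @export
extractBloodPool <- function(endo, erosion_mm = 5) {
  if (!any(endo@data)) stop("empty endocardial mask")
  er <- erodeMask(endo, erosion_mm)
  if (!any(er@data)) {
    stop("erosion of ", erosion_mm,
         " mm emptied the mask; use a smaller radius")
  }
  er
}

#' Normalise LGE intensities by blood-pool statistics
#'
#' Voxelwise z-normalisation (I - mean_bp) / sd_bp, so normalised units are
#' blood-pool standard deviations. Invariant to affine intensity rescaling
#' of the input.
#'
#' @param lge a \linkS4class{Volume3D}.
#' @param blood_pool a \linkS4class{BinaryMask} on the same grid.
#' @return normalised \linkS4class{Volume3D}.
#' @export
normalizeIntensities <- function(lge, blood_pool) {
  if (!any(blood_pool@data)) stop("empty blood pool")
  v <- lge@data[blood_pool@data]
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (!is.finite(sdv) || sdv == 0) stop("blood-pool SD is zero")
  Volume3D((lge@data - mu) / sdv, spacing = lge@spacing, affine = lge@affine)
}

#' Map clicks to super-pixel ids
#'
#' Multiple clicks inside the same super-pixel count once.
#'
#' @param clicks data.frame with columns slice, row, col (1-based).
#' @param spmap a \linkS4class{SuperpixelMap}.
#' @return sorted integer vector of clicked super-pixel ids.
#' @export
clicksToSuperpixels <- function(clicks, spmap) {
  if (nrow(clicks) == 0) return(integer(0))
  d <- dim(spmap@data)
  bad <- clicks$row < 1 | clicks$row > d[1] | clicks$col < 1 |
    clicks$col > d[2] | clicks$slice < 1 | clicks$slice > d[3]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("click (slice %d, row %d, col %d) is outside the grid",
                 clicks$slice[i], clicks$row[i], clicks$col[i]))
  }
  ids <- spmap@data[cbind(clicks$row, clicks$col, clicks$slice)]
  sort(unique(as.integer(ids)))
}

#' Super-pixel / wall overlap ratio
#'
#' Fraction of the super-pixel's own pixels that lie inside the wall mask
#' (evaluated on the super-pixel's slice; super-pixels are per-slice).
#'
#' @param sp_id super-pixel id.
#' @param spmap a \linkS4class{SuperpixelMap}.
#' @param wall wall \linkS4class{BinaryMask} on the same grid.
#' @return scalar in [0, 1].
#' @export
overlapRatio <- function(sp_id, spmap, wall) {
  sel <- spmap@data == sp_id
  n <- sum(sel)
  if (n == 0) stop("unknown super-pixel id: ", sp_id)
  sum(sel & wall@data) / n
}

# vectorised overlap ratios for all super-pixels
allOverlapRatios <- function(spmap, wall) {
  ids <- as.integer(spmap@data)
  inWall <- as.numeric(wall@data)
  size <- as.numeric(rowsum(rep(1, length(ids)), ids))
  hit <- as.numeric(rowsum(inWall, ids))
  data.frame(sp_id = sort(unique(ids)), size = size, ratio = hit / size)
}

#' Build the labeled super-pixel training set
#'
#' Applies the click / overlap rules: super-pixels with wall overlap at or
#' above the threshold are labeled \code{enhanced} if clicked and
#' \code{nonenhanced} otherwise; clicked super-pixels below the threshold
#' are discarded (enhancement of other substructures), as are all
#' non-overlapping super-pixels. Each retained super-pixel contributes one
#' row of 16 intensity features computed from the normalised LGE
#' intensities.
#'
#' @param spmap a \linkS4class{SuperpixelMap}.
#' @param clicked_ids integer vector of clicked super-pixel ids.
#' @param wall wall \linkS4class{BinaryMask}.
#' @param normalized_lge blood-pool-normalised \linkS4class{Volume3D}.
#' @param spec a \code{\link{trainingSetSpec}}.
#' @param case case identifier recorded in the table.
#' @return data.frame with columns case, slice, sp_id, the 16 features and
#'   \code{label} (factor enhanced/nonenhanced).
#' @export
buildTrainingSet <- function(spmap, clicked_ids, wall, normalized_lge,
                             spec = trainingSetSpec(), case = "case1") {
  stopifnot(identical(dim(spmap@data), dim(wall@data)),
            identical(dim(spmap@data), dim(normalized_lge@data)))
  rat <- allOverlapRatios(spmap, wall)
  keep <- rat$sp_id[rat$ratio >= spec$overlap_threshold & rat$size >= 4]
  if (length(keep) == 0) stop("no super-pixels overlap the wall")
  ord <- order(as.integer(spmap@data))
  idsSorted <- as.integer(spmap@data)[ord]
  valsSorted <- as.numeric(normalized_lge@data)[ord]
  bounds <- c(0, cumsum(as.numeric(table(idsSorted))))
  uid <- sort(unique(idsSorted))
  ctab <- spmap@centers
  rows <- lapply(keep, function(id) {
    k <- match(id, uid)
    px <- valsSorted[(bounds[k] + 1):bounds[k + 1]]
    fv <- computeFeatures(px)
    cbind(data.frame(case = case,
                     slice = ctab$slice[match(id, ctab$sp_id)],
                     sp_id = id), as.data.frame(as.list(fv)))
  })
  tab <- do.call(rbind, rows)
  tab$label <- factor(ifelse(tab$sp_id %in% clicked_ids, "enhanced",
                             "nonenhanced"),
                      levels = c("nonenhanced", "enhanced"))
  if (!all(c("enhanced", "nonenhanced") %in% tab$label)) {
    stop("untrainable: need both enhanced and nonenhanced super-pixels")
  }
  tab
}
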