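# Hierarchical atlas-to-target registration scored by spatially encoded
# mutual information (SEMI): MI accumulated over Gaussian-weighted spatial
# subregions of the joint histogram, which keeps the similarity sensitive to
# local intensity relationships and robust to smooth intensity
# nonuniformity. Stages: global affine -> per-substructure local affines
# (blended into a continuous displacement) -> B-spline free-form
# deformation.

#' SEMI similarity configuration
#'
#' @param bins joint-histogram bins (>= 8).
#' @param kernel Parzen kernel, "box" or "gaussian".
#' @param n_s number of spatial subregions (>= 1); subregion centers are
#'   placed on a near-balanced regular grid factorisation of n_s.
#' @param bandwidth_mm Gaussian bandwidth of the spatial weights; default a
#'   quarter of the mean volume extent.
#' @param weights optional user-supplied n_voxels x n_s spatial weight
#'   matrix (overrides the generated weights; used mainly for testing).
#' @return a list of class "SEMIConfig".
#' @export
semiConfig <- function(bins = 64, kernel = c("box", "gaussian"), n_s = 8,
                       bandwidth_mm = NULL, weights = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(bins >= 8, n_s >= 1)
  structure(list(bins = as.integer(bins), kernel = kernel,
                 n_s = as.integer(n_s), bandwidth_mm = bandwidth_mm,
                 weights = weights), class = "SEMIConfig")
}

# balanced triple factorisation of n_s for subregion grid placement
factorTriple <- function(n) {
  best <- c(n, 1, 1)
  for (a in 1:n) {
    if (n %% a != 0) next
    for (b in 1:(n / a)) {
      if ((n / a) %% b != 0) next
      c3 <- n / a / b
      tr <- sort(c(a, b, c3), decreasing = TRUE)
      if (max(tr) / min(tr) < max(best) / min(best)) best <- tr
    }
  }
  best
}

semiWeights <- function(d, affineM, n_s, bandwidth_mm = NULL) {
  pts <- voxToWorld(affineM, voxelGrid(d))
  if (n_s == 1) return(matrix(1, nrow(pts), 1))
  ext <- apply(pts, 2, range)
  span <- ext[2, ] - ext[1, ]
  if (is.null(bandwidth_mm)) bandwidth_mm <- mean(span) / 4
  k <- factorTriple(n_s)
  # more subregions along larger extents
  k <- k[order(order(span, decreasing = TRUE))]
  centers <- as.matrix(expand.grid(
    seq(ext[1, 1] + span[1] / (2 * k[1]), ext[2, 1], length.out = k[1]),
    seq(ext[1, 2] + span[2] / (2 * k[2]), ext[2, 2], length.out = k[2]),
    seq(ext[1, 3] + span[3] / (2 * k[3]), ext[2, 3], length.out = k[3])))
  W <- vapply(seq_len(nrow(centers)), function(s) {
    dd <- sweep(pts, 2, centers[s, ], "-")
    exp(-0.5 * rowSums(dd^2) / bandwidth_mm^2)
  }, numeric(nrow(pts)))
  W
}

#' Spatially encoded joint histogram
#'
#' Resamples the atlas through the transform chain onto the target grid and
#' accumulates one Parzen joint histogram per spatial subregion, each sample
#' weighted by that subregion's spatial weight. Intensities are linearly
#' rescaled to the bin range over the overlap region.
#'
#' @param I target \linkS4class{Volume3D}.
#' @param A atlas \linkS4class{Volume3D}.
#' @param chain \linkS4class{TransformChain} mapping target world to atlas
#'   world.
#' @param cfg a \code{\link{semiConfig}}.
#' @return 3D array bins x bins x n_s of per-subregion joint histograms.
#' @export
spatialJointHistogram <- function(I, A, chain = TransformChain(),
                                  cfg = semiConfig()) {
  d <- dim(I@data)
  pts <- voxToWorld(I@affine, voxelGrid(d))
  pts <- applyTransformChain(chain, pts)
  vox <- worldToVox(A@affine, pts)
  av <- cpp_interp(as.numeric(A@data), dim(A@data), vox, 1L, NA_real_)
  ok <- !is.na(av)
  if (!any(ok)) stop("empty overlap region between target and atlas")
  iv <- as.numeric(I@data)[ok]
  av <- av[ok]
  bins <- cfg$bins
  toPos <- function(x) {
    r <- range(x)
    if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) * (bins - 1) else rep(0, length(x))
  }
  pi <- toPos(iv); pj <- toPos(av)
  W <- cfg$weights
  if (is.null(W)) W <- semiWeights(d, I@affine, cfg$n_s, cfg$bandwidth_mm)
  stopifnot(ncol(W) == cfg$n_s)
  kcode <- if (cfg$kernel == "box") 0L else 1L
  H <- array(0, c(bins, bins, cfg$n_s))
  for (s in seq_len(cfg$n_s)) {
    H[, , s] <- cpp_parzen_hist2(pi, pj, W[ok, s], bins, kcode)
  }
  H
}

#' Mutual information of a joint histogram
#'
#' Shannon MI in bits of the normalised joint histogram.
#' @param H bins x bins matrix of non-negative weights.
#' @return scalar MI.
#' @export
miFromHist <- function(H) {
  tot <- sum(H)
  if (tot <= 0) return(0)
  P <- H / tot
  pi <- rowSums(P); pj <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log2(P[nz] / outer(pi, pj)[nz]))
}

#' Spatially encoded mutual information similarity
#'
#' Sum over spatial subregions of the MI of each subregion's joint
#' histogram. With a single subregion and uniform weights this is exactly
#' the standard mutual information of the images.
#'
#' @inheritParams spatialJointHistogram
#' @return scalar similarity (higher is better).
#' @export
semiSimilarity <- function(I, A, chain = TransformChain(),
                           cfg = semiConfig()) {
  H <- spatialJointHistogram(I, A, chain, cfg)
  sum(vapply(seq_len(dim(H)[3]), function(s) miFromHist(H[, , s]), 0))
}

# --- affine parameterisation -------------------------------------------------

# p = (tx,ty,tz, rx,ry,rz, log sx, log sy, log sz, hxy, hxz, hyz)
paramsToAffine <- function(p, center) {
  t <- p[1:3]; r <- p[4:6]; s <- exp(p[7:9]); h <- p[10:12]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  Sh <- rbind(c(1, h[1], h[2]), c(0, 1, h[3]), c(0, 0, 1))
  M3 <- Rz %*% Ry %*% Rx %*% diag(s) %*% Sh
  M <- diag(4)
  M[1:3, 1:3] <- M3
  M[1:3, 4] <- center - M3 %*% center + t
  M
}

downsampleVolume <- function(v, f) {
  if (f == 1) return(v)
  d <- dim(v@data)
  nd <- d %/% f
  arr <- v@data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  dim(arr) <- c(f, nd[1], f, nd[2], f, nd[3])
  arr <- apply(arr, c(2, 4, 6), mean)
  S <- diag(c(f, f, f, 1))
  S[1:3, 4] <- (f - 1) / 2
  Volume3D(arr, spacing = v@spacing * f, affine = v@affine %*% S)
}

#' Global affine registration
#'
#' Maximises SEMI over a staged affine parameterisation (translation, then
#' rotation + scale, then shear) with Nelder-Mead on a 3-level
#' multiresolution pyramid. The optimum is guaranteed not to score below the
#' identity transform.
#'
#' @param I target volume.
#' @param A atlas (moving) volume.
#' @param cfg a \code{\link{semiConfig}}.
#' @param levels pyramid downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration caps per level.
#' @param shear whether to optimise the shear stage.
#' @return a \linkS4class{RegistrationResult} whose chain holds one affine.
#' @export
registerGlobalAffine <- function(I, A, cfg = semiConfig(),
                                 levels = c(4, 2, 1),
                                 maxit = c(250, 150, 80), shear = FALSE) {
  center <- voxToWorld(I@affine, matrix((dim(I@data) - 1) / 2, 1))[1, ]
  p <- rep(0, 12)
  trace <- numeric(0)
  stages <- list(1:3, 4:9)
  if (shear) stages <- c(stages, list(10:12))
  for (li in seq_along(levels)) {
    f <- levels[li]
    Il <- downsampleVolume(I, f)
    Al <- downsampleVolume(A, f)
    cfgl <- semiConfig(bins = max(16, cfg$bins %/% f), kernel = cfg$kernel,
                       n_s = cfg$n_s, bandwidth_mm = cfg$bandwidth_mm)
    cost <- function(psub, idx) {
      pp <- p; pp[idx] <- psub
      M <- paramsToAffine(pp, center)
      -semiSimilarity(Il, Al, TransformChain(list(affineTransform(M))), cfgl)
    }
    for (idx in stages) {
      scale <- ifelse(idx <= 3, max(I@spacing) * 2, 0.05)
      opt <- stats::optim(p[idx], cost, idx = idx, method = "Nelder-Mead",
                          control = list(maxit = maxit[li],
                                         parscale = scale,
                                         reltol = 1e-5))
      p[idx] <- opt$par
      trace <- c(trace, -opt$value)
    }
  }
  M <- paramsToAffine(p, center)
  chain <- TransformChain(list(affineTransform(M)))
  simFinal <- semiSimilarity(I, A, chain, cfg)
  simId <- semiSimilarity(I, A, TransformChain(), cfg)
  if (simFinal < 0.98 * simId) {
    # materially worse than doing nothing: keep the identity. Tiny deficits
    # are interpolation smoothing (fractional sampling lowers MI slightly)
    # and do not indicate optimizer failure.
    warning("optimum scored below identity; returning identity transform")
    chain <- TransformChain(list(affineTransform(diag(4))))
    simFinal <- simId
    p <- rep(0, 12)
  }
  if (det(paramsToAffine(p, center)[1:3, 1:3]) <= 0) {
    stop("optimizer failure: non-positive determinant")
  }
  RegistrationResult(chain, simFinal, c(trace, simFinal),
                     extras = list(params = p))
}

#' Local affine registration of cardiac substructures
#'
#' Refines the global stage with one translation + scale transform per
#' substructure, each scored by MI over a dilated bounding region of that
#' structure; the per-structure affines are blended into a continuous
#' displacement by normalised Gaussian distance weights centred on the
#' structure centroids. Structures with fewer than \code{minVoxels} warped
#' voxels are skipped with a warning and inherit the initial transform.
#'
#' @param I target volume.
#' @param A atlas volume.
#' @param init \linkS4class{TransformChain} from the global stage.
#' @param substructures atlas \linkS4class{LabelMap}.
#' @param cfg a \code{\link{semiConfig}} (used with n_s = 1 per structure).
#' @param minVoxels skip threshold.
#' @param maxit Nelder-Mead cap per structure.
#' @return a \linkS4class{RegistrationResult}; extras$localAffines holds the
#'   per-structure matrices.
#' @export
registerLocalAffine <- function(I, A, init, substructures,
                                cfg = semiConfig(), minVoxels = 100,
                                maxit = 120) {
  warpedL <- resampleToGrid(substructures, I, chain = init)
  warpedA <- resampleToGrid(A, I, interp = "linear", chain = init)
  d <- dim(I@data)
  labs <- setdiff(sort(unique(as.integer(warpedL@data))), 0L)
  affines <- list(); centers <- NULL; sigmas <- numeric(0)
  perStructure <- list()
  trace <- numeric(0)
  for (l in labs) {
    idx <- which(warpedL@data == l)
    nm <- names(substructures@labelDict)[match(l, substructures@labelDict)]
    if (length(idx) < minVoxels) {
      warning("substructure ", nm, " has ", length(idx),
              " voxels; skipped (inherits global affine)")
      perStructure[[nm]] <- diag(4)
      next
    }
    ai <- arrayInd(idx, d)
    margin <- 6L
    lo <- pmax(apply(ai, 2, min) - margin, 1L)
    hi <- pmin(apply(ai, 2, max) + margin, d)
    cropGrid <- function(v) {
      arr <- v@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      S <- diag(4); S[1:3, 4] <- lo - 1L
      Volume3D(arr, spacing = v@spacing, affine = v@affine %*% S)
    }
    Ic <- cropGrid(I)
    Ac <- cropGrid(warpedA)
    ctrWorld <- colMeans(voxToWorld(I@affine, ai - 1L))
    cfg1 <- semiConfig(bins = min(cfg$bins, 32), kernel = cfg$kernel, n_s = 1)
    cost <- function(p6) {
      pp <- rep(0, 12); pp[1:3] <- p6[1:3]; pp[7:9] <- p6[4:6]
      M <- paramsToAffine(pp, ctrWorld)
      -semiSimilarity(Ic, Ac, TransformChain(list(affineTransform(M))), cfg1)
    }
    opt <- stats::optim(rep(0, 6), cost, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(rep(2, 3), rep(0.05, 3)),
                                       reltol = 1e-5))
    trace <- c(trace, -opt$value)
    pp <- rep(0, 12); pp[1:3] <- opt$par[1:3]; pp[7:9] <- opt$par[4:6]
    M <- paramsToAffine(pp, ctrWorld)
    affines <- c(affines, list(M))
    centers <- rbind(centers, ctrWorld)
    extent <- (hi - lo + 1) * I@spacing
    sigmas <- c(sigmas, mean(extent) / 2)
    perStructure[[nm]] <- M
  }
  tr <- list(kind = "local_affine_set", affines = affines,
             centers = centers, sigmas = sigmas, floor = 1e-6)
  chain <- composeChains(TransformChain(list(tr)), init)
  sim <- semiSimilarity(I, A, chain, cfg)
  RegistrationResult(chain, sim, c(trace, sim),
                     extras = list(localAffines = perStructure))
}

# discrete 6-neighbour Laplacian of control coefficients (per component)
coefLaplacian <- function(coef, ncp) {
  out <- matrix(0, nrow(coef), 3)
  for (comp in 1:3) {
    arr <- array(coef[, comp], ncp)
    lap <- -6 * arr
    lap <- lap + arr[c(2:ncp[1], ncp[1]), , ] + arr[c(1, 1:(ncp[1] - 1)), , ]
    lap <- lap + arr[, c(2:ncp[2], ncp[2]), ] + arr[, c(1, 1:(ncp[2] - 1)), ]
    lap <- lap + arr[, , c(2:ncp[3], ncp[3])] + arr[, , c(1, 1:(ncp[3] - 1))]
    out[, comp] <- as.numeric(lap)
  }
  out
}

#' Deformable (B-spline FFD) registration
#'
#' Dense refinement on a cubic B-spline control grid. Control-point updates
#' follow the analytic intensity-difference force (residual times warped
#' image gradient) projected onto the control grid, with a bending-energy
#' penalty and a backtracking step search; spatially encoded MI is tracked
#' across outer iterations and the best-scoring state is returned if the
#' similarity diverges.
#'
#' @param I target volume.
#' @param A atlas volume.
#' @param init initial \linkS4class{TransformChain} (affine stages).
#' @param cfg a \code{\link{semiConfig}} for the reported similarity.
#' @param controlSpacing control-point spacing in voxels.
#' @param lambda bending-energy weight (> 0).
#' @param maxIter outer iteration cap.
#' @param tol divergence tolerance on the similarity trace.
#' @return a \linkS4class{RegistrationResult}; the chain prepends a dense
#'   deformation field to \code{init}.
#' @export
registerDeformable <- function(I, A, init = TransformChain(),
                               cfg = semiConfig(), controlSpacing = 10,
                               lambda = 0.01, maxIter = 25, tol = 0.2) {
  d <- dim(I@data)
  warpedA <- resampleToGrid(A, I, interp = "linear", chain = init)
  ncp <- as.integer(ceiling((d - 1) / controlSpacing) + 3L)
  coef <- matrix(0, prod(ncp), 3) # voxel-unit displacements
  grid <- voxelGrid(d)
  tgt <- as.numeric(I@data)
  mov <- as.numeric(warpedA@data)
  # border-clamp sampling: zero-filling outside the grid would make the
  # cost explode for any displacement at an intensity-bearing boundary
  clamp <- function(xyz) {
    for (ax in 1:3) xyz[, ax] <- pmin(pmax(xyz[, ax], 0), d[ax] - 1)
    xyz
  }
  ssdOf <- function(coefM) {
    D <- cpp_bspline_field(coefM, ncp, d, controlSpacing)
    w <- cpp_interp(mov, d, clamp(grid + D), 1L, 0)
    sum((tgt - w)^2)
  }
  semiOf <- function(coefM) {
    D <- cpp_bspline_field(coefM, ncp, d, controlSpacing)
    field <- sweep(D, 2, I@spacing, "*")
    tr <- list(kind = "deformation_field", field = field, dim = d,
               affine = I@affine)
    semiSimilarity(I, A, composeChains(TransformChain(list(tr)), init), cfg)
  }
  ssd <- ssdOf(coef)
  sim <- semiOf(coef)
  trace <- sim
  bestCoef <- coef; bestSim <- sim
  stepVox <- 0.8
  for (it in seq_len(maxIter)) {
    D <- cpp_bspline_field(coef, ncp, d, controlSpacing)
    w <- cpp_interp(mov, d, clamp(grid + D), 1L, 0)
    warr <- array(w, d)
    res <- tgt - w
    gx <- warr; gy <- warr; gz <- warr
    gx[] <- 0; gy[] <- 0; gz[] <- 0
    gx[2:(d[1] - 1), , ] <- (warr[3:d[1], , ] - warr[1:(d[1] - 2), , ]) / 2
    gy[, 2:(d[2] - 1), ] <- (warr[, 3:d[2], ] - warr[, 1:(d[2] - 2), ]) / 2
    gz[, , 2:(d[3] - 1)] <- (warr[, , 3:d[3]] - warr[, , 1:(d[3] - 2)]) / 2
    force <- cbind(res * as.numeric(gx), res * as.numeric(gy),
                   res * as.numeric(gz))
    g <- cpp_bspline_project(force, d, ncp, controlSpacing)
    g <- g - lambda * (-coefLaplacian(coef, ncp))
    gmax <- max(abs(g))
    if (gmax < 1e-12) break
    g <- g / gmax
    improved <- FALSE
    for (s in stepVox * c(1, 0.5, 0.25)) {
      cand <- coef + s * g
      if (ssdOf(cand) < ssd * (1 - 1e-5)) {
        coef <- cand
        ssd <- ssdOf(cand)
        improved <- TRUE
        break
      }
    }
    if (!improved) {
      stepVox <- stepVox / 2
      if (stepVox < 0.05) break
      next
    }
    sim <- semiOf(coef)
    trace <- c(trace, sim)
    if (sim > bestSim) { bestSim <- sim; bestCoef <- coef }
    if (sim < bestSim - tol) break # divergence: stop early, keep best
  }
  D <- cpp_bspline_field(bestCoef, ncp, d, controlSpacing)
  field <- sweep(D, 2, I@spacing, "*")
  tr <- list(kind = "deformation_field", field = field, dim = d,
             affine = I@affine)
  chain <- composeChains(TransformChain(list(tr)), init)
  RegistrationResult(chain, bestSim, trace,
                     extras = list(coef = bestCoef, ncp = ncp,
                                   controlSpacing = controlSpacing))
}

#' Map Roadmap-derived anatomy onto the LGE grid
#'
#' The voxel-to-world affines of the two acquisitions provide the initial
#' (header-geometry) alignment; this is refined by affine and deformable
#' registration, and the whole-heart labels are warped onto the LGE grid
#' with nearest-neighbour sampling.
#'
#' @param roadmap anatomical \linkS4class{Volume3D}.
#' @param lge LGE \linkS4class{Volume3D} (target grid).
#' @param labels \linkS4class{LabelMap} on the roadmap grid.
#' @param cfg a \code{\link{semiConfig}}.
#' @param deformable run the deformable refinement stage.
#' @return list(labels = LabelMap on the LGE grid, chain = TransformChain).
#' @export
mapRoadmapToLGE <- function(roadmap, lge, labels, cfg = semiConfig(),
                            deformable = TRUE) {
  glob <- registerGlobalAffine(lge, roadmap, cfg)
  chain <- glob@chain
  if (deformable) {
    def <- registerDeformable(lge, roadmap, init = chain, cfg = cfg,
                              maxIter = 15)
    chain <- def@chain
  }
  list(labels = resampleToGrid(labels, lge, chain = chain), chain = chain)
}
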