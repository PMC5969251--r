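# Synthetic cardiac phantoms: a whole-heart "Roadmap"-like anatomical volume
# with multi-label ground truth, an LGE-like contrast volume with a known
# scar mask inside the left atrial wall, randomly deformed atlas sets, and
# simulated expert clicks. The geometry is deliberately simple (ellipsoidal
# chambers, tubular pulmonary-vein stubs and great vessels) but reproduces
# the statistical structure the pipeline relies on: a bright blood pool, a
# thin (~3 mm) atrial wall, and scar as wall sub-regions enhanced above
# blood-pool statistics.

#' Phantom configuration
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing in mm.
#' @param la_radii left-atrium ellipsoid radii in mm.
#' @param wall_mm atrial wall thickness in mm (default 3, the usual LA wall
#'   thickness).
#' @param blood_mean,blood_sd blood-pool intensity mean / SD.
#' @param myo_mean,myo_sd myocardium intensity mean / SD.
#' @param bg_mean background intensity mean.
#' @param scar_offset scar enhancement above the blood-pool mean, in units of
#'   the blood-pool SD.
#' @param scar_fraction target fraction of the atrial wall occupied by scar.
#' @param n_scar_patches number of contiguous scar patches.
#' @param scar_heterogeneity within-patch enhancement falloff: voxels at a
#'   patch edge are enhanced by (1 - scar_heterogeneity) times the nominal
#'   offset (contrast wash-out makes lesion rims fainter than cores; 0 gives
#'   uniform enhancement).
#' @param confounder_n number of bright non-scar enhancement foci placed
#'   just outside the LA wall in the LGE phantom (aortic wall, valve and
#'   artifactual enhancement are the dominant false-positive sources in
#'   real LGE; 0 disables them).
#' @param confounder_scale intensity of the confounders relative to the
#'   scar enhancement offset (default 0.65: bright, but a different tissue).
#' @param psf_sigma in-plane Gaussian point-spread blur in voxels applied to
#'   the noise-free LGE tissue image (partial-volume effect).
#' @param noise_model "gaussian" or "rician" acquisition noise.
#' @param noise_sd acquisition noise SD (intensity units).
#' @param bias_amp amplitude of the multiplicative low-order polynomial bias
#'   field (0 disables it).
#' @param deform_amp amplitude (mm) of the random smooth inter-subject
#'   deformation used for atlases.
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return a validated list of class "PhantomConfig".
#' @export
phantomConfig <- function(shape = c(80, 80, 24),
                          spacing = c(0.75, 0.75, 2),
                          la_radii = c(13, 11, 9), wall_mm = 3,
                          blood_mean = 120, blood_sd = 15,
                          myo_mean = 100, myo_sd = 25, bg_mean = 30,
                          scar_offset = 4, scar_fraction = 0.2,
                          n_scar_patches = 2, scar_heterogeneity = 0.5,
                          confounder_n = 3,
                          confounder_scale = 0.65, psf_sigma = 0.5,
                          noise_model = c("gaussian", "rician"),
                          noise_sd = 8, bias_amp = 0, deform_amp = 3,
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(shape) == 3, all(shape >= 8),
            length(spacing) == 3, all(spacing > 0),
            wall_mm > 0, blood_sd >= 0, myo_sd >= 0,
            scar_fraction >= 0, scar_fraction <= 1,
            scar_offset >= 0, noise_sd >= 0, deform_amp >= 0)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 la_radii = la_radii, wall_mm = wall_mm,
                 blood_mean = blood_mean, blood_sd = blood_sd,
                 myo_mean = myo_mean, myo_sd = myo_sd, bg_mean = bg_mean,
                 scar_offset = scar_offset, scar_fraction = scar_fraction,
                 n_scar_patches = n_scar_patches,
                 scar_heterogeneity = scar_heterogeneity,
                 confounder_n = confounder_n,
                 confounder_scale = confounder_scale, psf_sigma = psf_sigma,
                 noise_model = noise_model,
                 noise_sd = noise_sd, bias_amp = bias_amp,
                 deform_amp = deform_amp, seed = as.integer(seed)),
            class = "PhantomConfig")
}

# chamber geometry in world mm, scaled to the field of view
phantomGeometry <- function(cfg) {
  fov <- cfg$shape * cfg$spacing
  sc <- fov / c(64, 64, 48) # geometry designed on a 64x64x48 mm box
  ctr <- function(x, y, z) c(x, y, z) * sc
  rad <- function(r) r * mean(sc)
  list(
    LA_PV = list(center = ctr(32, 40, 24), radii = cfg$la_radii * mean(sc)),
    LV = list(center = ctr(32, 14, 24), radii = rad(1) * c(12, 11, 10)),
    RV = list(center = ctr(10, 18, 24), radii = rad(1) * c(8, 8, 8)),
    RA = list(center = ctr(10, 42, 24), radii = rad(1) * c(7, 7, 7)),
    AO = list(center = ctr(50, 24, 24), radii = rad(1) * c(5, 5, 18)),
    PA = list(center = ctr(52, 46, 24), radii = rad(1) * c(4.5, 4.5, 16))
  )
}

# pulmonary-vein stubs: tubes leaving the LA surface
pvStubs <- function(cfg) {
  fov <- cfg$shape * cfg$spacing
  sc <- mean(fov / c(64, 64, 48))
  la <- cfg$la_radii * sc
  dirs <- rbind(c(0.9, 0.44, 0), c(-0.9, 0.44, 0), c(0.5, 0.6, 0.62))
  lapply(seq_len(nrow(dirs)), function(i) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    list(dir = d, radius = 3 * sc, length = 7 * sc, start = la * d)
  })
}

insideEllipsoid <- function(pts, center, radii) {
  u <- sweep(pts, 2, center, "-")
  (u[, 1] / radii[1])^2 + (u[, 2] / radii[2])^2 + (u[, 3] / radii[3])^2 <= 1
}

#' Generate a whole-heart anatomical phantom
#'
#' Produces a Roadmap-like intensity volume and its ground-truth multi-label
#' segmentation (background, LA+PV, LV, RV, RA, AO, PA). Blood-filled
#' chambers are bright, the myocardial shell around the LA and LV is
#' intermediate, background is dark; tissue intensities are drawn from the
#' configured Gaussian distributions, then acquisition noise and an optional
#' bias field are applied.
#'
#' @param cfg a \code{\link{phantomConfig}}.
#' @return list(volume = Volume3D, labels = LabelMap).
#' @export
makeHeartPhantom <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  if (cfg$wall_mm < min(cfg$spacing)) {
    stop("degenerate geometry: wall (", cfg$wall_mm,
         " mm) thinner than one voxel")
  }
  set.seed(cfg$seed)
  d <- cfg$shape
  A <- defaultAffine(cfg$spacing)
  pts <- voxToWorld(A, voxelGrid(d))
  geo <- phantomGeometry(cfg)
  lab <- integer(nrow(pts))
  dict <- heartLabelDict()
  for (nm in names(geo)) {
    inside <- insideEllipsoid(pts, geo[[nm]]$center, geo[[nm]]$radii)
    lab[inside & lab == 0L] <- dict[[nm]]
  }
  # PV stubs attach to the LA
  laC <- geo$LA_PV$center
  for (st in pvStubs(cfg)) {
    p0 <- laC + st$start
    u <- sweep(pts, 2, p0, "-")
    t <- u %*% st$dir
    perp2 <- rowSums(u^2) - t^2
    inside <- t >= -st$length * 0.3 & t <= st$length & perp2 <= st$radius^2
    lab[inside & lab == 0L] <- dict[["LA_PV"]]
  }
  # myocardial shell around LA and LV (for anatomical contrast only)
  myo <- rep(FALSE, nrow(pts))
  for (nm in c("LA_PV", "LV")) {
    g <- geo[[nm]]
    grow <- g$radii + cfg$wall_mm
    myo <- myo | (insideEllipsoid(pts, g$center, grow) &
                  !insideEllipsoid(pts, g$center, g$radii))
  }
  myo <- myo & lab == 0L
  n <- nrow(pts)
  img <- stats::rnorm(n, cfg$bg_mean, cfg$noise_sd + 1)
  img[myo] <- stats::rnorm(sum(myo), cfg$myo_mean, cfg$myo_sd)
  bp <- lab > 0L
  img[bp] <- stats::rnorm(sum(bp), cfg$blood_mean, cfg$blood_sd)
  img <- corruptImage(img, pts, cfg)
  img <- pmax(img, 0)
  list(volume = Volume3D(array(img, d), spacing = cfg$spacing, affine = A),
       labels = LabelMap(array(as.integer(lab), d), spacing = cfg$spacing,
                         affine = A))
}

corruptImage <- function(img, pts, cfg) {
  if (cfg$bias_amp > 0) {
    z <- scale(pts)
    field <- 1 + cfg$bias_amp * ((z[, 1]^2 + z[, 2] * z[, 3]) / 3)
    img <- img * field
  }
  if (cfg$noise_sd > 0) {
    if (cfg$noise_model == "gaussian") {
      img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    } else {
      img <- sqrt((img + stats::rnorm(length(img), 0, cfg$noise_sd))^2 +
                  stats::rnorm(length(img), 0, cfg$noise_sd)^2)
    }
  }
  img
}

#' Generate an LGE-like phantom with ground-truth scar
#'
#' Builds a contrast volume on the grid of \code{labels}: nulled myocardium
#' and wall, intermediate blood pool, and scar as contiguous angular patches
#' of the LA wall with intensities drawn at
#' \code{blood_mean + scar_offset * blood_sd}. The wall is the
#' \code{wall_mm} dilation shell of the endocardial LA+PV mask; exactly
#' \code{round(scar_fraction * |wall|)} wall voxels become scar.
#'
#' @param labels ground-truth \linkS4class{LabelMap} containing LA_PV.
#' @param cfg a \code{\link{phantomConfig}}.
#' @return list(volume = Volume3D, scar = BinaryMask, wall = BinaryMask).
#' @export
makeLGEPhantom <- function(labels, cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  dict <- labels@labelDict
  if (!"LA_PV" %in% names(dict)) stop("labels must include LA_PV")
  set.seed(cfg$seed + 1000L)
  d <- dim(labels@data)
  endo <- BinaryMask(array(labels@data == dict[["LA_PV"]], d),
                     spacing = labels@spacing, affine = labels@affine)
  wall <- extractWall(endo, cfg$wall_mm)
  wallIdx <- which(wall@data)
  if (cfg$scar_fraction > 0 && length(wallIdx) == 0) {
    stop("scar_fraction > 0 with an empty wall")
  }
  scar <- array(FALSE, d)
  if (cfg$scar_fraction > 0) {
    pts <- voxToWorld(labels@affine, voxelGrid(d))[wallIdx, , drop = FALSE]
    ctr <- colMeans(voxToWorld(labels@affine,
                               voxelGrid(d))[which(endo@data), , drop = FALSE])
    u <- sweep(pts, 2, ctr, "-")
    u <- u / sqrt(rowSums(u^2))
    k <- max(1L, as.integer(cfg$n_scar_patches))
    seeds <- matrix(stats::rnorm(3 * k), k, 3)
    seeds <- seeds / sqrt(rowSums(seeds^2))
    ang <- apply(u %*% t(seeds), 1, max) # cosine to the nearest seed
    nScar <- round(cfg$scar_fraction * length(wallIdx))
    take <- order(ang, decreasing = TRUE)[seq_len(nScar)]
    scar[wallIdx[take]] <- TRUE
    # wash-out: enhancement falls off from patch core to patch rim
    h <- cfg$scar_heterogeneity %||% 0
    scarFactor <- 1 - h * (seq_len(nScar) - 1) / max(nScar - 1, 1)
    scarFactorIdx <- wallIdx[take]
  }
  img <- numeric(prod(d))
  img[] <- stats::rnorm(length(img), cfg$bg_mean, cfg$noise_sd + 1)
  bp <- labels@data > 0L
  img[bp] <- stats::rnorm(sum(bp), cfg$blood_mean, cfg$blood_sd)
  img[wall@data] <- stats::rnorm(sum(wall@data), cfg$myo_mean, cfg$myo_sd)
  if (any(scar)) {
    img[scarFactorIdx] <- stats::rnorm(
      length(scarFactorIdx),
      cfg$blood_mean + scarFactor * cfg$scar_offset * cfg$blood_sd,
      cfg$blood_sd)
  }
  pts <- voxToWorld(labels@affine, voxelGrid(d))
  # bright non-scar enhancement foci just outside the LA wall (aortic wall,
  # valve and artifactual enhancement): the dominant false-positive source
  # in LGE; never overwrite the blood pool or the true scar
  if (cfg$confounder_n > 0 && any(endo@data)) {
    ctrEndo <- colMeans(pts[which(endo@data), , drop = FALSE])
    rEff <- mean(cfg$la_radii) + cfg$wall_mm
    for (ci in seq_len(cfg$confounder_n)) {
      dirv <- stats::rnorm(3)
      dirv <- dirv / sqrt(sum(dirv^2))
      ctr <- ctrEndo + dirv * (rEff + stats::runif(1, 0, 2))
      rad <- stats::runif(1, 3, 5)
      inside <- rowSums(sweep(pts, 2, ctr, "-")^2) <= rad^2
      sel <- inside & !as.logical(endo@data) & !scar
      img[sel] <- stats::rnorm(sum(sel),
                               cfg$blood_mean +
                                 cfg$confounder_scale * cfg$scar_offset *
                                 cfg$blood_sd,
                               cfg$blood_sd)
    }
  }
  # in-plane point-spread blur (partial-volume effect), then noise/bias
  if (cfg$psf_sigma > 0) {
    hw <- max(1L, ceiling(3 * cfg$psf_sigma))
    k <- stats::dnorm(-hw:hw, sd = cfg$psf_sigma)
    for (ax in 0:1) img <- cpp_conv1d(img, d, k / sum(k), ax)
  }
  img <- corruptImage(img, pts, cfg)
  img <- pmax(img, 0)
  list(volume = Volume3D(array(img, d), spacing = labels@spacing,
                         affine = labels@affine),
       scar = BinaryMask(scar, spacing = labels@spacing,
                         affine = labels@affine),
       wall = wall)
}

# smooth sinusoidal displacement field (mm), invertible for small amplitude
sinusoidalField <- function(pts, fov, amp, seed) {
  set.seed(seed)
  disp <- matrix(0, nrow(pts), 3)
  for (comp in 1:3) {
    for (k in 1:2) {
      lambda <- stats::runif(3, 0.5, 1.0) * fov # low-frequency waves
      phase <- stats::runif(3, 0, 2 * pi)
      a <- amp / 2 * stats::runif(1, 0.5, 1)
      disp[, comp] <- disp[, comp] +
        a * sin(2 * pi * pts[, 1] / lambda[1] + phase[1]) *
            sin(2 * pi * pts[, 2] / lambda[2] + phase[2]) *
            sin(2 * pi * pts[, 3] / lambda[3] + phase[3])
    }
  }
  disp
}

#' Generate a randomly deformed atlas set
#'
#' Each atlas is the base phantom warped by a random smooth sinusoidal
#' displacement field (amplitude \code{deform_amp} mm, wavelengths of the
#' order of the field of view, hence invertible) with independent
#' acquisition noise; labels are warped with the same field using
#' nearest-neighbour sampling.
#'
#' @param n number of atlases (the multi-atlas set size; 30 in routine use).
#' @param cfg a \code{\link{phantomConfig}}.
#' @return list of n lists (volume = Volume3D, labels = LabelMap).
#' @export
makeAtlasSet <- function(n, cfg) {
  stopifnot(n >= 1)
  base <- makeHeartPhantom(cfg)
  d <- cfg$shape
  A <- affine(base$volume)
  pts <- voxToWorld(A, voxelGrid(d))
  fov <- cfg$shape * cfg$spacing
  lapply(seq_len(n), function(a) {
    disp <- sinusoidalField(pts, fov, cfg$deform_amp, cfg$seed + 7919L * a)
    vox <- worldToVox(A, pts + disp)
    img <- cpp_interp(as.numeric(base$volume@data), d, vox, 1L, cfg$bg_mean)
    lab <- cpp_interp(as.numeric(base$labels@data), d, vox, 0L, 0)
    set.seed(cfg$seed + 7919L * a + 1L)
    if (cfg$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    list(volume = Volume3D(array(pmax(img, 0), d), spacing = cfg$spacing,
                           affine = A),
         labels = LabelMap(array(as.integer(round(lab)), d),
                           spacing = cfg$spacing, affine = A,
                           labelDict = base$labels@labelDict))
  })
}

#' Simulate expert mouse clicks on scar
#'
#' Emulates the interactive training-set construction: the expert places
#' relatively dense clicks inside enhanced regions. A fraction
#' \code{density} of the super-pixels that overlap the true scar receive at
#' least one click, each click landing on a scar voxel of that super-pixel.
#'
#' @param scar a \linkS4class{BinaryMask} of true scar.
#' @param spmap a \linkS4class{SuperpixelMap} on the same grid.
#' @param density fraction in (0, 1] of scar-overlapping super-pixels that
#'   get clicked.
#' @param seed integer seed.
#' @return a data.frame with columns slice, row, col (1-based voxel
#'   coordinates; empty when the scar is empty).
#' @export
makeClicks <- function(scar, spmap, density = 1, seed = 1L) {
  stopifnot(density > 0, density <= 1)
  idx <- which(scar@data)
  empty <- data.frame(slice = integer(0), row = integer(0), col = integer(0))
  if (length(idx) == 0) return(empty)
  sp <- spmap@data[idx]
  ids <- unique(sp)
  set.seed(seed)
  nPick <- ceiling(density * length(ids))
  picked <- if (nPick >= length(ids)) ids else sample(ids, nPick)
  d <- dim(scar@data)
  rows <- lapply(picked, function(id) {
    vox <- idx[sp == id]
    v <- vox[sample.int(length(vox), 1L)]
    ar <- arrayInd(v, d)
    data.frame(slice = ar[3], row = ar[1], col = ar[2])
  })
  do.call(rbind, rows)
}
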