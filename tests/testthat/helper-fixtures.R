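# fixtures built in code: small volumes, masks and structured phantoms

randomVolume <- function(d = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  Volume3D(array(stats::rnorm(prod(d)), d), spacing = spacing)
}

# smooth structured volume with several Gaussian blobs (for registration)
blobVolume <- function(d = c(32, 32, 32), spacing = c(1, 1, 1), seed = 1,
                       nblobs = 6) {
  set.seed(seed)
  pts <- atriascar:::voxelGrid(d)
  img <- numeric(prod(d))
  fov <- d * spacing
  for (i in seq_len(nblobs)) {
    ctr <- stats::runif(3, 0.25, 0.75) * fov
    sg <- stats::runif(1, 3, 6)
    dd <- sweep(sweep(pts, 2, spacing, "*"), 2, ctr, "-")
    img <- img + stats::runif(1, 50, 150) * exp(-rowSums(dd^2) / (2 * sg^2))
  }
  Volume3D(array(img, d), spacing = spacing)
}

ballMask <- function(d = c(24, 24, 24), r = 8, spacing = c(1, 1, 1),
                     center = (d - 1) / 2 * spacing) {
  pts <- atriascar:::voxToWorld(defaultAffine(spacing),
                                atriascar:::voxelGrid(d))
  dd <- sweep(pts, 2, center, "-")
  BinaryMask(array(rowSums(dd^2) <= r^2, d), spacing = spacing)
}

maskFromArray <- function(arr, spacing = c(1, 1, 1)) {
  BinaryMask(array(as.logical(arr), dim(arr)), spacing = spacing)
}

# deterministic tiny feature table for classifier tests
blobTable <- function(n = 40, sep = 6, seed = 1) {
  set.seed(seed)
  x1 <- c(stats::rnorm(n), stats::rnorm(n) + sep)
  x2 <- c(stats::rnorm(n), stats::rnorm(n) + sep)
  tab <- data.frame(f_mean = x1, f_sd = x2,
                    label = factor(rep(c("nonenhanced", "enhanced"),
                                       each = n),
                                   levels = c("nonenhanced", "enhanced")))
  tab
}
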