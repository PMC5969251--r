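test_that("wall extraction produces a ~3 mm shell disjoint from the endo", {
  ball <- ballMask(c(28, 28, 28), r = 10)
  wall <- extractWall(ball, 3)
  expect_false(any(imgData(wall) & imgData(ball)))
  # shell thickness by distance transform against the endo surface
  d <- dim(imgData(wall))
  wp <- atriascar:::voxToWorld(affine(wall),
                               arrayInd(which(imgData(wall)), d) - 1L)
  ep <- atriascar:::voxToWorld(affine(ball),
                               arrayInd(which(imgData(ball)), d) - 1L)
  dist <- atriascar:::cpp_min_dists(wp, ep)
  expect_lte(max(dist), 4)
  expect_gte(max(dist), 2)
  expect_error(extractWall(maskFromArray(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("anisotropic spacing rounds the per-axis radius as specified", {
  # 3 mm at spacing (1, 1, 2): x/y radius 3 voxels, z radius round(1.5) = 2
  r <- atriascar:::mmRadiusToVox(3, c(1, 1, 2))
  expect_identical(r, c(3L, 3L, 2L))
  off <- atriascar:::ellipsoidOffsets(r)
  expect_equal(max(off[, 1]), 3)
  expect_equal(max(off[, 3]), 2)
  # radius never drops below one voxel
  expect_identical(atriascar:::mmRadiusToVox(1, c(3, 3, 3)), c(1L, 1L, 1L))
})

test_that("blood-pool erosion shrinks the ball by the metric radius", {
  ball <- ballMask(c(28, 28, 28), r = 10)
  bp <- extractBloodPool(ball, 5)
  expect_true(all(imgData(ball)[imgData(bp)]))
  # eroded ball radius ~ 5 voxels: check via max distance from center
  d <- dim(imgData(bp))
  ctr <- (d - 1) / 2
  pts <- arrayInd(which(imgData(bp)), d) - 1L
  rmax <- sqrt(max(rowSums(sweep(pts, 2, ctr, "-")^2)))
  expect_lte(rmax, 6.5)
  expect_gte(rmax, 4)
  # zero-ish erosion keeps the mask; over-erosion errors
  thin <- maskFromArray(array(rep(c(TRUE, FALSE), c(2, 26 * 28 * 28 - 2)),
                              c(28, 28, 28)))
  expect_error(extractBloodPool(thin, 5), "smaller radius")
})

test_that("normalisation is exact and affine-invariant", {
  set.seed(1)
  v <- randomVolume(c(10, 10, 10), seed = 1)
  v@data <- v@data * 10 + 100
  bp <- maskFromArray(array(stats::runif(1000) < 0.3, c(10, 10, 10)))
  nv <- normalizeIntensities(v, bp)
  expect_equal(mean(imgData(nv)[imgData(bp)]), 0, tolerance = 1e-6)
  expect_equal(stats::sd(imgData(nv)[imgData(bp)]), 1, tolerance = 1e-6)
  # voxel arithmetic: mu 100, sd 10, value 120 -> 2
  idx <- which(!imgData(bp))[1]
  mu <- mean(imgData(v)[imgData(bp)]); sdv <- stats::sd(imgData(v)[imgData(bp)])
  expect_equal(imgData(nv)[idx], (imgData(v)[idx] - mu) / sdv)
  # affine intensity transform invariance
  v2 <- Volume3D(3 * imgData(v) + 7, spacing = spacing(v))
  nv2 <- normalizeIntensities(v2, bp)
  expect_equal(imgData(nv2), imgData(nv), tolerance = 1e-10)
  const <- Volume3D(array(1, c(10, 10, 10)))
  expect_error(normalizeIntensities(const, bp), "SD is zero")
})

test_that("clicks deduplicate per super-pixel and reject out-of-grid", {
  img <- matrix(0, 16, 16)
  sp <- oversegmentVolume(Volume3D(array(img, c(16, 16, 1))), S = 4, m = 1)
  # three clicks inside one super-pixel
  id <- imgData(sp)[2, 2, 1]
  cl <- data.frame(slice = c(1, 1, 1), row = c(1, 2, 2), col = c(1, 1, 2))
  expect_identical(clicksToSuperpixels(cl, sp), as.integer(id))
  expect_identical(clicksToSuperpixels(cl[0, ], sp), integer(0))
  bad <- data.frame(slice = 1, row = 99, col = 1)
  expect_error(clicksToSuperpixels(bad, sp), "outside the grid")
})

test_that("overlap ratio counts pixels and the threshold splits at 20%", {
  img <- matrix(0, 16, 16)
  sp <- oversegmentVolume(Volume3D(array(img, c(16, 16, 1))), S = 4, m = 1)
  ids <- spCenters(sp)$sp_id
  # wall covering 3 of the 16 pixels of one super-pixel -> 0.1875
  target <- ids[6]
  sel <- which(imgData(sp) == target)
  wall3 <- array(FALSE, dim(imgData(sp))); wall3[sel[1:3]] <- TRUE
  expect_equal(overlapRatio(target, sp, maskFromArray(wall3, spacing(sp))),
               0.1875)
  wall4 <- array(FALSE, dim(imgData(sp))); wall4[sel[1:4]] <- TRUE
  expect_equal(overlapRatio(target, sp, maskFromArray(wall4, spacing(sp))),
               0.25)
  full <- array(FALSE, dim(imgData(sp))); full[sel] <- TRUE
  expect_equal(overlapRatio(target, sp, maskFromArray(full, spacing(sp))), 1)
  expect_error(overlapRatio(max(ids) + 1, sp, maskFromArray(full)), "unknown")
})

test_that("training-set construction applies the click/overlap rules", {
  set.seed(2)
  d <- c(16, 16, 1)
  img <- array(stats::rnorm(prod(d)), d)
  sp <- oversegmentVolume(Volume3D(img), S = 4, m = 1e6) # regular grid cells
  ids <- spCenters(sp)$sp_id
  wall <- array(FALSE, d)
  # full overlap for ids 1..6; 3/16 (below threshold) for id 7
  for (id in ids[1:6]) wall[imgData(sp) == id] <- TRUE
  sel7 <- which(imgData(sp) == ids[7])
  wall[sel7[1:3]] <- TRUE
  clicked <- c(ids[1], ids[2], ids[7])
  tab <- buildTrainingSet(sp, clicked, maskFromArray(wall, spacing(sp)),
                          Volume3D(img), trainingSetSpec())
  # clicked below-threshold super-pixel is absent
  expect_false(ids[7] %in% tab$sp_id)
  # clicked overlapping ones are enhanced, unclicked overlapping nonenhanced
  expect_setequal(tab$sp_id[tab$label == "enhanced"], ids[1:2])
  expect_setequal(tab$sp_id[tab$label == "nonenhanced"], ids[3:6])
  # enhanced and nonenhanced are disjoint and all rows overlap the wall
  expect_length(intersect(tab$sp_id[tab$label == "enhanced"],
                          tab$sp_id[tab$label == "nonenhanced"]), 0)
  # untrainable when no nonenhanced rows remain
  expect_error(buildTrainingSet(sp, ids[1:6],
                                maskFromArray(wall, spacing(sp)),
                                Volume3D(img), trainingSetSpec()),
               "untrainable")
})

test_that("phantom training rows labeled enhanced do overlap true scar", {
  cfg <- phantomConfig(shape = c(64, 64, 16), spacing = c(1, 1, 2),
                       la_radii = c(10, 9, 7), seed = 11L)
  cs <- makePhantomCase(cfg, seed = 11)
  enh <- cs$table$sp_id[cs$table$label == "enhanced"]
  overlaps <- vapply(enh, function(id)
    sum(imgData(cs$spmap) == id & imgData(cs$scar)) > 0, NA)
  expect_true(all(overlaps))
})
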