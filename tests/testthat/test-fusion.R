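smallDict <- c(background = 0L, LA_PV = 1L)

labOf <- function(arr) LabelMap(array(as.integer(arr), dim(arr)),
                                labelDict = smallDict)

test_that("majority vote returns the modal label with lowest-id ties", {
  d <- c(2, 2, 2)
  l1 <- labOf(array(1L, d))
  l0 <- labOf(array(0L, d))
  # single atlas: identity
  expect_identical(imgData(majorityVote(list(l1))), imgData(l1))
  # (1,1,0) votes -> 1
  mv <- majorityVote(list(l1, l1, l0))
  expect_true(all(imgData(mv) == 1L))
  # (1,0) tie -> lowest label id 0
  tie <- majorityVote(list(l1, l0))
  expect_true(all(imgData(tie) == 0L))
  expect_error(majorityVote(list()), "empty")
})

test_that("gaussian scale space preserves identity, constants and mass", {
  v <- randomVolume(c(12, 12, 8), seed = 2)
  ss <- gaussianScaleSpace(v, c(0, 1))
  expect_identical(imgData(ss[[1]]), imgData(v))
  cv <- Volume3D(array(3.5, c(8, 8, 8)))
  sm <- gaussianScaleSpace(cv, 2)[[1]]
  expect_equal(imgData(sm), imgData(cv), tolerance = 1e-12)
  # delta impulse smoothed by sigma = 1 approximates the sampled 3D Gaussian
  dd <- c(15, 15, 15)
  imp <- array(0, dd); imp[8, 8, 8] <- 1
  g <- gaussianScaleSpace(Volume3D(imp), 1)[[1]]
  ii <- as.matrix(expand.grid(1:15, 1:15, 1:15)) - 8
  k1 <- stats::dnorm(-3:3); k1 <- k1 / sum(k1)
  gv <- function(x) {
    v <- numeric(length(x))
    s <- abs(x) <= 3
    v[s] <- k1[x[s] + 4]
    v
  }
  expected <- array(gv(ii[, 1]) * gv(ii[, 2]) * gv(ii[, 3]), dd)
  expect_lt(max(abs(imgData(g) - expected)), 1e-4)
  expect_error(gaussianScaleSpace(v, -1), "negative")
})

test_that("patch conditional probability matches counting oracles", {
  # identical integer images: p = 1 everywhere
  set.seed(3)
  arr <- array(sample(0:4, 9^3, TRUE), c(9, 9, 9))
  vI <- Volume3D(arr)
  cfg <- fusionConfig(patch_radius = 2, bins = 32)
  for (x in list(c(5, 5, 5), c(2, 3, 4), c(1, 1, 1))) {
    expect_equal(localSimilarityConditional(vI, vI, x, cfg), 1)
  }
  # independent random binary images: p approx marginal frequency of i_x
  set.seed(4)
  a <- array(sample(0:1, 9^3, TRUE), c(9, 9, 9))
  b <- array(sample(0:1, 9^3, TRUE), c(9, 9, 9))
  cfgBig <- fusionConfig(patch_radius = 4, bins = 32)
  x <- c(5, 5, 5)
  p <- localSimilarityConditional(Volume3D(a), Volume3D(b), x, cfgBig)
  marg <- mean(a == a[5, 5, 5])
  expect_lt(abs(p - marg), 0.1)
  # hand-computed 2x2 joint table: p(i=1 | j=1) = 0.4/0.5 = 0.8
  # build a patch whose joint counts realise {40,10,10,40}/100 within the
  # 5x5x4 = 100-voxel patch around the corner (patch clipped to the grid)
  ii <- array(0L, c(5, 5, 4))
  jj <- array(0L, c(5, 5, 4))
  pairs <- rbind(matrix(c(0, 0), 40, 2, byrow = TRUE),
                 matrix(c(0, 1), 10, 2, byrow = TRUE),
                 matrix(c(1, 0), 10, 2, byrow = TRUE),
                 matrix(c(1, 1), 40, 2, byrow = TRUE))
  ii[] <- pairs[, 1]; jj[] <- pairs[, 2]
  ii[3, 3, 2] <- 1L; jj[3, 3, 2] <- 1L # query voxel holds (1, 1)
  # recount after the overwrite to keep the table interpretation exact
  H <- table(as.vector(ii), as.vector(jj))
  expected <- H["1", "1"] / sum(H[, "1"])
  got <- localSimilarityConditional(Volume3D(ii * 1), Volume3D(jj * 1),
                                    c(3, 3, 2),
                                    fusionConfig(patch_radius = 10, bins = 32))
  expect_equal(got, unname(expected), tolerance = 1e-12)
})

test_that("multiscale similarity degenerates to single scale and ranks pairs", {
  v <- blobVolume(c(16, 16, 16), seed = 5)
  cfg1 <- fusionConfig(method = "MSP", scales = 0)
  x <- c(8, 8, 8)
  expect_equal(mspSimilarity(v, v, x, cfg1),
               localSimilarityConditional(v, v, x, cfg1))
  # identical integer images over three scales with box Parzen: score = 3
  set.seed(6)
  vi <- Volume3D(array(sample(0:3, 11^3, TRUE), c(11, 11, 11)))
  cfg3 <- fusionConfig(scales = c(0, 1, 2))
  expect_equal(mspSimilarity(vi, vi, c(6, 6, 6), cfg3), 3)
  # identical beats shifted and noisy variants at several voxels
  sh <- Volume3D(imgData(v)[c(3:16, 1:2), , ], spacing = spacing(v))
  set.seed(7)
  ns <- Volume3D(imgData(v) + stats::rnorm(16^3, 0, stats::sd(imgData(v))))
  cfgR <- fusionConfig(scales = c(0, 1))
  for (x in list(c(8, 8, 8), c(5, 10, 7), c(12, 4, 9))) {
    sSelf <- mspSimilarity(v, v, x, cfgR)
    expect_gte(sSelf, mspSimilarity(v, sh, x, cfgR))
    expect_gte(sSelf, mspSimilarity(v, ns, x, cfgR))
  }
})

test_that("fuse matches an exhaustive per-voxel weighted-vote oracle", {
  set.seed(8)
  d <- c(2, 2, 2)
  tgt <- Volume3D(array(stats::rnorm(8, 100, 20), d))
  atlases <- lapply(1:3, function(i) {
    list(volume = Volume3D(array(imgData(tgt) + stats::rnorm(8, 0, 10), d)),
         labels = labOf(array(sample(0:1, 8, TRUE), d)))
  })
  for (method in c("MV", "LWV", "PF", "MSP")) {
    cfg <- fusionConfig(method = method, patch_radius = 1, scales = c(0, 1),
                        bins = 8)
    fused <- fuseLabels(atlases, tgt, cfg)
    # oracle: recompute each atlas's per-voxel weight with the exported
    # similarity primitives and take the weighted argmax (ties: lowest id)
    for (vx in 1:2) for (vy in 1:2) for (vz in 1:2) {
      x <- c(vx, vy, vz)
      wts <- vapply(atlases, function(a) {
        switch(method,
          MV = 1,
          LWV = atriascar:::lwvWeights(tgt, a$volume,
                                       (x[1] - 1) + 2 * ((x[2] - 1) +
                                                          2 * (x[3] - 1)) + 1,
                                       cfg),
          PF = localSimilarityConditional(
            gaussianScaleSpace(tgt, cfg$scales[1])[[1]],
            gaussianScaleSpace(a$volume, cfg$scales[1])[[1]], x, cfg),
          MSP = mspSimilarity(tgt, a$volume, x, cfg))
      }, 0)
      votes <- c(`0` = 0, `1` = 0)
      for (ai in 1:3) {
        l <- as.character(imgData(atlases[[ai]]$labels)[vx, vy, vz])
        votes[l] <- votes[l] + wts[ai]
      }
      want <- as.integer(names(votes)[which.max(votes)]) # ties: lowest id
      expect_identical(imgData(fused)[vx, vy, vz], want)
    }
  }
})

test_that("fusion reductions: consensus, uniform weights, single scale", {
  set.seed(9)
  d <- c(4, 4, 4)
  tgt <- blobVolume(d, seed = 9)
  lab <- labOf(array(sample(0:1, 64, TRUE), d))
  same <- lapply(1:3, function(i) list(volume = tgt, labels = lab))
  for (method in c("MV", "LWV", "PF", "MSP")) {
    f <- fuseLabels(same, tgt, fusionConfig(method = method))
    expect_identical(imgData(f), imgData(lab))
  }
  # LWV with spatially uniform similarities equals MV: identical atlas
  # volumes make every weight equal
  atl <- lapply(1:3, function(i)
    list(volume = tgt, labels = labOf(array(sample(0:1, 64, TRUE), d))))
  expect_identical(imgData(fuseLabels(atl, tgt, fusionConfig("LWV"))),
                   imgData(majorityVote(lapply(atl, `[[`, "labels"))))
  # MSP with a single scale is exactly PF
  atl2 <- lapply(1:3, function(i)
    list(volume = Volume3D(imgData(tgt) + stats::rnorm(64, 0, 5)),
         labels = labOf(array(sample(0:1, 64, TRUE), d))))
  msp1 <- fuseLabels(atl2, tgt, fusionConfig("MSP", scales = 1))
  pf1 <- fuseLabels(atl2, tgt, fusionConfig("PF", scales = 1))
  expect_identical(imgData(msp1), imgData(pf1))
})

test_that("fused labels are always proposed by at least one atlas", {
  set.seed(10)
  d <- c(6, 6, 4)
  tgt <- blobVolume(d, seed = 10)
  atl <- lapply(1:4, function(i)
    list(volume = Volume3D(imgData(tgt) + stats::rnorm(prod(d), 0, 10)),
         labels = LabelMap(array(sample(0:2, prod(d), TRUE,
                                        prob = c(0.5, 0.3, 0.2)), d),
                           labelDict = c(background = 0L, LA_PV = 1L,
                                         LV = 2L))))
  for (method in c("MV", "LWV", "MSP")) {
    f <- fuseLabels(atl, tgt, fusionConfig(method))
    proposed <- Reduce(`|`, lapply(atl, function(a)
      imgData(a$labels) == imgData(f)))
    expect_true(all(proposed))
  }
})

test_that("multiscale fusion outperforms single-scale and plain voting on average", {
  # seeded atlas cohorts at the package's default deformation and noise;
  # the mean LA Dice of multiscale patch fusion exceeds both the
  # single-scale patch similarity and majority voting
  res <- do.call(rbind, lapply(1:6, function(s)
    fusionExperiment(phantomConfig(), seed = 300 + s,
                     methods = c("MV", "PF", "MSP"), n_atlases = 10)))
  m <- tapply(res$dice, res$method, mean)
  expect_gte(m[["MSP"]], m[["PF"]])
  expect_gte(m[["MSP"]], m[["MV"]])
  expect_gt(min(res$dice), 0.9) # all methods segment the LA credibly
})
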