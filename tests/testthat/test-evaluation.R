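test_that("overlap metrics match hand-computed values", {
  d <- c(4, 2, 2) # T = 16
  m <- array(FALSE, d); a <- array(FALSE, d)
  m[1:4] <- TRUE          # |M| = 4
  a[3:6] <- TRUE          # |A| = 4, intersection = 2
  om <- overlapMetrics(maskFromArray(m), maskFromArray(a))
  expect_equal(om$dice, 0.5)
  expect_equal(om$jaccard, 1 / 3)
  expect_equal(om$precision, 0.5)
  expect_equal(om$npv, 10 / 12)
  # identity and disjoint cases
  id <- overlapMetrics(maskFromArray(m), maskFromArray(m))
  expect_equal(unlist(id[c("dice", "jaccard", "precision", "npv")]),
               c(dice = 1, jaccard = 1, precision = 1, npv = 1))
  b <- array(FALSE, d); b[9:12] <- TRUE
  dj <- overlapMetrics(maskFromArray(m), maskFromArray(b))
  expect_equal(unlist(dj[c("dice", "jaccard", "precision")]),
               c(dice = 0, jaccard = 0, precision = 0))
  # empty-mask conventions are flagged, not silent
  e <- overlapMetrics(maskFromArray(array(FALSE, d)),
                      maskFromArray(array(FALSE, d)))
  expect_equal(e$dice, 1)
  expect_true(length(e$flags) > 0)
})

test_that("jaccard = dice / (2 - dice) for random mask pairs", {
  set.seed(1)
  for (i in 1:10) {
    m <- maskFromArray(array(stats::runif(64) > 0.5, c(4, 4, 4)))
    a <- maskFromArray(array(stats::runif(64) > 0.5, c(4, 4, 4)))
    om <- overlapMetrics(m, a)
    expect_equal(om$jaccard, om$dice / (2 - om$dice), tolerance = 1e-12)
  }
})

test_that("surface distances match brute-force values", {
  d <- c(12, 12, 6)
  m <- array(FALSE, d); m[6, 6, 3] <- TRUE
  a <- array(FALSE, d); a[9, 6, 3] <- TRUE
  sm <- surfaceMetrics(maskFromArray(m), maskFromArray(a))
  expect_equal(sm$hausdorff, 3)
  expect_equal(sm$asd, 3)
  # identical masks: zero distances
  ball <- ballMask(c(16, 16, 16), r = 5)
  s0 <- surfaceMetrics(ball, ball)
  expect_equal(s0$hausdorff, 0)
  expect_equal(s0$asd, 0)
  # unit square contour shifted one voxel: hausdorff 1; asd equals the
  # brute-force symmetric mean closest-point distance
  sq <- array(FALSE, c(10, 10, 3)); sq[3:6, 3:6, 2] <- TRUE
  sq2 <- array(FALSE, c(10, 10, 3)); sq2[4:7, 3:6, 2] <- TRUE
  sm2 <- surfaceMetrics(maskFromArray(sq), maskFromArray(sq2))
  expect_equal(sm2$hausdorff, 1)
  P <- atriascar:::boundaryPoints(maskFromArray(sq))
  Q <- atriascar:::boundaryPoints(maskFromArray(sq2))
  alld <- function(X, Y) {
    apply(X, 1, function(p) min(sqrt(colSums((t(Y) - p)^2))))
  }
  asdBrute <- (mean(alld(P, Q)) + mean(alld(Q, P))) / 2
  expect_equal(sm2$asd, asdBrute, tolerance = 1e-12)
  expect_error(surfaceMetrics(maskFromArray(array(FALSE, d)),
                              maskFromArray(a)), "empty")
})

test_that("classifier metrics honour the BER identity and the ROC null", {
  # sens 0.90 / spec 0.79 -> BER 0.155 (rounds to 0.16)
  set.seed(2)
  yt <- rep(c(TRUE, FALSE), c(100, 100))
  yp <- c(rep(TRUE, 90), rep(FALSE, 10), rep(FALSE, 79), rep(TRUE, 21))
  cm <- classifierMetrics(yt, yp)
  expect_equal(cm$sensitivity, 0.90)
  expect_equal(cm$specificity, 0.79)
  expect_equal(cm$ber, 0.155)
  # half-up rounding at the printed precision (fp-tolerant)
  expect_equal(floor(cm$ber * 100 + 0.5 + 1e-9) / 100, 0.16)
  # perfect scores give AUC 1
  sc <- ifelse(yt, 1, -1)
  expect_equal(classifierMetrics(yt, yt, sc)$auc, 1)
  # label-independent scores give AUC ~ 0.5
  y2 <- sample(c(TRUE, FALSE), 2000, TRUE)
  s2 <- stats::rnorm(2000)
  expect_lt(abs(classifierMetrics(y2, y2, s2)$auc - 0.5), 0.05)
  # AUC is invariant to monotone transforms of the scores
  y3 <- sample(c(TRUE, FALSE), 200, TRUE)
  s3 <- stats::rnorm(200)
  expect_equal(classifierMetrics(y3, y3, s3)$auc,
               classifierMetrics(y3, y3, exp(2 * s3))$auc,
               tolerance = 1e-12)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- sample(c(TRUE, FALSE), 300, TRUE)
  s <- stats::rnorm(300) + y
  ours <- classifierMetrics(y, y, s)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("fibrosis extent weights voxels by physical volume", {
  d <- c(10, 10, 2)
  wall <- array(FALSE, d); wall[1:100] <- TRUE
  scar <- array(FALSE, d); scar[1:10] <- TRUE
  expect_equal(fibrosisExtent(maskFromArray(scar), maskFromArray(wall)), 10)
  expect_equal(fibrosisExtent(maskFromArray(array(FALSE, d)),
                              maskFromArray(wall)), 0)
  # anisotropic spacing: identical here because FEP is a ratio of volumes
  # on one grid, but verify the mm^3 arithmetic explicitly
  sp <- c(1, 1, 2)
  f <- fibrosisExtent(maskFromArray(scar, sp), maskFromArray(wall, sp))
  expect_equal(f, 100 * (10 * prod(sp)) / (100 * prod(sp)))
  expect_error(fibrosisExtent(maskFromArray(scar),
                              maskFromArray(array(FALSE, d))), "empty wall")
})

test_that("cross-validation harnesses partition correctly without leakage", {
  set.seed(4)
  cases <- lapply(1:6, function(i) {
    tab <- blobTable(n = 15, sep = 4, seed = i)
    tab$row_id <- paste0("c", i, "_", seq_len(nrow(tab)))
    tab
  })
  names(cases) <- paste0("case", 1:6)
  seenTrain <- list()
  train_fn <- function(tab) {
    seenTrain[[length(seenTrain) + 1]] <<- tab$row_id
    trainSvm(tab, selected = c("f_mean", "f_sd"),
             grid = list(C = 1, gamma = 0.1), seed = 1)
  }
  predict_fn <- predictScar
  cv <- looCV(cases, train_fn, predict_fn)
  expect_length(cv$per_case, 6)
  # leakage audit: no training fold saw the held-out case's rows
  for (i in seq_along(cases)) {
    expect_false(any(cases[[i]]$row_id %in% seenTrain[[i]]))
  }
  # identical cases give identical per-case metrics
  same <- lapply(1:3, function(i) blobTable(n = 15, sep = 4, seed = 9))
  cvs <- looCV(same, function(tab)
    trainSvm(tab, c("f_mean", "f_sd"), grid = list(C = 1, gamma = 0.1),
             seed = 1), predict_fn)
  accs <- vapply(cvs$per_case, `[[`, 0, "accuracy")
  expect_true(all(accs == accs[1]))
  # k-fold folds partition the cases, deterministically per seed
  kf1 <- kfoldCV(cases, k = 3, train_fn = function(tab)
    trainSvm(tab, c("f_mean", "f_sd"), grid = list(C = 1, gamma = 0.1),
             seed = 1), predict_fn = predict_fn, seed = 11)
  kf2 <- kfoldCV(cases, k = 3, train_fn = function(tab)
    trainSvm(tab, c("f_mean", "f_sd"), grid = list(C = 1, gamma = 0.1),
             seed = 1), predict_fn = predict_fn, seed = 11)
  expect_identical(kf1$folds, kf2$folds)
  expect_setequal(unique(kf1$folds), 1:3)
})

test_that("rank-sum test matches exact enumeration and detects shifts", {
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # 3 vs 3, complete separation: minimal attainable two-sided exact p = 0.1
  expect_equal(rankSumTest(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(5)
  hits <- vapply(1:100, function(i) {
    a <- stats::rnorm(50)
    b <- stats::rnorm(50) + 2
    rankSumTest(a, b)$p_value < 0.01
  }, NA)
  expect_gte(mean(hits), 0.95)
  expect_error(rankSumTest(1:2, 1:5), "at least 3")
})

test_that("Bland-Altman bias and limits follow the closed form", {
  a <- c(1, 2, 3, 4)
  expect_equal(blandAltman(a, a)$bias, 0)
  expect_equal(blandAltman(a, a)$lower, 0)
  ba <- blandAltman(a + 5, a)
  expect_equal(ba$bias, 5)
  expect_equal(ba$sd, 0)
  set.seed(6)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  bb <- blandAltman(x, y)
  expect_equal(bb$upper, mean(x - y) + 1.96 * stats::sd(x - y),
               tolerance = 1e-10)
  expect_error(blandAltman(1:3, 1:4), "mismatch")
})

test_that("baseline segmentations behave per definition", {
  set.seed(7)
  d <- c(12, 12, 4)
  wall <- array(FALSE, d)
  wall[2:11, 2:11, 2:3] <- TRUE
  z <- array(stats::rnorm(prod(d), 0, 0.5), d)
  hi <- wall & array(stats::runif(prod(d)) < 0.3, d)
  z[hi] <- stats::rnorm(sum(hi), 6, 0.5)
  nv <- Volume3D(z)
  wm <- maskFromArray(wall)
  # nsd(2) is exactly the z > 2 rule inside the wall
  ns <- baselineSegment(nv, wm, "nsd", n = 2)
  expect_identical(imgData(ns), array(z > 2 & wall, d))
  # well-separated bimodal wall: kmeans recovers the high cluster
  km <- baselineSegment(nv, wm, "kmeans")
  expect_gte(mean(imgData(km)[wall] == hi[wall]), 0.99)
  fc <- baselineSegment(nv, wm, "fcm")
  expect_gte(mean(imgData(fc)[wall] == hi[wall]), 0.99)
  # infinite threshold: empty mask
  expect_equal(sum(imgData(baselineSegment(nv, wm, "threshold", t = 1e9))), 0)
  expect_error(baselineSegment(nv, maskFromArray(array(FALSE, d)), "nsd"),
               "fewer than 10")
})
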