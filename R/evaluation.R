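# Evaluation: overlap and surface-distance metrics between manual and
# automatic segmentations, classifier metrics (accuracy, sensitivity,
# specificity, balanced error rate, ROC/AUC), fibrosis extent percentage,
# cross-validation harnesses, rank-sum and Bland-Altman statistics, and the
# conventional scar-segmentation baselines.

#' Overlap metrics between two binary masks
#'
#' Dice = 2|M&A| / (|M|+|A|), Jaccard = |M&A| / |M|A|union, Precision =
#' |M&A| / |A|, NPV = (T - |M u A|) / (T - |A|) with T the total voxel
#' count. When both masks are empty, Dice and Jaccard are defined as 1 and
#' flagged; an empty automatic mask flags precision as undefined (NaN).
#'
#' @param manual,auto \linkS4class{BinaryMask}s on the same grid.
#' @return list with dice, jaccard, precision, npv, the voxel counts and a
#'   \code{flags} character vector.
#' @export
overlapMetrics <- function(manual, auto) {
  stopifnot(identical(dim(manual@data), dim(auto@data)))
  M <- sum(manual@data); A <- sum(auto@data)
  I <- sum(manual@data & auto@data)
  U <- M + A - I
  T <- length(manual@data)
  flags <- character(0)
  if (M == 0 && A == 0) {
    dice <- 1; jac <- 1
    flags <- c(flags, "both masks empty: dice/jaccard defined as 1")
  } else {
    dice <- 2 * I / (M + A)
    jac <- I / U
  }
  prec <- if (A == 0) {
    flags <- c(flags, "empty automatic mask: precision undefined")
    NaN
  } else I / A
  npv <- (T - U) / (T - A)
  list(dice = dice, jaccard = jac, precision = prec, npv = npv,
       n_manual = M, n_auto = A, n_intersection = I, n_total = T,
       flags = flags)
}

# boundary voxels (6-connectivity) of a mask, as world-mm coordinates
boundaryPoints <- function(mask) {
  m <- mask@data
  d <- dim(m)
  shift <- function(arr, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    do.call(`[`, c(list(arr), idx))
  }
  interior <- m
  for (ax in 1:3) {
    interior <- interior & shift(m, ax, 1L) & shift(m, ax, -1L)
  }
  idx <- which(m & !interior)
  voxToWorld(mask@affine, arrayInd(idx, d) - 1L)
}

#' Surface distances between two masks
#'
#' Hausdorff distance: maximum over both directions of the sup-inf
#' closest-point distance between the 6-connectivity boundary voxel centers
#' (exact maximum, no percentile variant). ASD: the symmetric mean of the
#' closest-point distances. Distances in mm via the voxel-to-world affine.
#'
#' @param manual,auto non-empty \linkS4class{BinaryMask}s on the same grid.
#' @return list(hausdorff, asd) in mm.
#' @export
surfaceMetrics <- function(manual, auto) {
  if (!any(manual@data) || !any(auto@data)) stop("empty mask")
  P <- boundaryPoints(manual)
  Q <- boundaryPoints(auto)
  dPQ <- cpp_min_dists(P, Q)
  dQP <- cpp_min_dists(Q, P)
  list(hausdorff = max(max(dPQ), max(dQP)),
       asd = (mean(dPQ) + mean(dQP)) / 2)
}

#' Classifier metrics: accuracy, sensitivity, specificity, BER, ROC/AUC
#'
#' BER = ((1 - sensitivity) + (1 - specificity)) / 2. AUC by trapezoidal
#' integration of the ROC curve over all score thresholds; undefined
#' (flagged NaN) for single-class truth.
#'
#' @param y_true logical or factor truth (TRUE / "enhanced" = positive).
#' @param y_pred predicted labels, same coding.
#' @param scores real-valued decision scores (larger = more positive).
#' @return list with accuracy, sensitivity, specificity, ber, auc and the
#'   ROC curve (data.frame fpr, tpr).
#' @export
classifierMetrics <- function(y_true, y_pred, scores = NULL) {
  pos <- asPositive(y_true)
  pred <- asPositive(y_pred)
  acc <- mean(pos == pred)
  sens <- if (any(pos)) mean(pred[pos]) else NaN
  spec <- if (any(!pos)) mean(!pred[!pos]) else NaN
  ber <- ((1 - sens) + (1 - spec)) / 2
  auc <- NaN
  roc <- NULL
  if (!is.null(scores) && any(pos) && any(!pos)) {
    roc <- rocCurve(pos, scores)
    auc <- trapezoidAuc(roc$fpr, roc$tpr)
  } else if (!is.null(scores)) {
    auc <- NaN # single-class truth: AUC undefined
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec, ber = ber,
       auc = auc, roc = roc)
}

asPositive <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y) || is.character(y)) return(as.character(y) == "enhanced")
  y > 0
}

rocCurve <- function(pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  # collapse tied scores to the last point of each tie group
  last <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!pos)),
             tpr = c(0, tp[last] / sum(pos)))
}

trapezoidAuc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Fibrosis extent percentage (FEP)
#'
#' Scar volume as a percentage of atrial wall volume, in mm^3 via the voxel
#' spacing (so anisotropic voxels are weighted by their volume).
#'
#' @param scar scar \linkS4class{BinaryMask}.
#' @param wall non-empty wall \linkS4class{BinaryMask} on the same grid.
#' @return percent (0-100).
#' @export
fibrosisExtent <- function(scar, wall) {
  if (!any(wall@data)) stop("empty wall mask")
  vvox <- prod(wall@spacing)
  100 * sum(scar@data & wall@data) * vvox / (sum(wall@data) * vvox)
}

#' Leave-one-case-out cross-validation
#'
#' Each case is predicted by a model trained on all other cases; per-case
#' reports and a pooled classifier report (over all held-out rows) are
#' returned. A training failure on a fold is recorded and the fold skipped
#' with a warning.
#'
#' @param cases named list of data.frames (feature tables with a label
#'   column).
#' @param train_fn function(table) -> model.
#' @param predict_fn function(model, table) -> data.frame with label and
#'   score columns.
#' @return list(per_case, pooled, predictions, failed).
#' @export
looCV <- function(cases, train_fn, predict_fn) {
  stopifnot(length(cases) >= 2)
  foldIds <- seq_along(cases)
  runFolds(cases, split(foldIds, foldIds), train_fn, predict_fn)
}

#' k-fold cross-validation over cases
#'
#' Folds partition the cases (deterministic per seed); k = number of cases
#' reproduces the leave-one-out fold structure.
#'
#' @inheritParams looCV
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return list(per_case, pooled, predictions, failed, folds).
#' @export
kfoldCV <- function(cases, k, train_fn, predict_fn, seed = 1L) {
  stopifnot(length(cases) >= 2, k >= 2, k <= length(cases))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(cases)))
  out <- runFolds(cases, split(seq_along(cases), fold), train_fn, predict_fn)
  out$folds <- fold
  out
}

runFolds <- function(cases, folds, train_fn, predict_fn) {
  nm <- names(cases)
  if (is.null(nm)) nm <- as.character(seq_along(cases))
  preds <- list()
  perCase <- list()
  failed <- character(0)
  for (f in folds) {
    train <- do.call(rbind, cases[-f])
    model <- tryCatch(train_fn(train), error = function(e) e)
    if (inherits(model, "error")) {
      warning("training failed on fold {", paste(nm[f], collapse = ","),
              "}: ", conditionMessage(model))
      failed <- c(failed, nm[f])
      next
    }
    for (ci in f) {
      p <- predict_fn(model, cases[[ci]])
      p$case <- nm[ci]
      p$truth <- cases[[ci]]$label
      preds[[nm[ci]]] <- p
      perCase[[nm[ci]]] <- classifierMetrics(p$truth, p$label, p$score)
    }
  }
  all <- do.call(rbind, preds)
  pooled <- if (is.null(all)) NULL else
    classifierMetrics(all$truth, all$label, all$score)
  list(per_case = perCase, pooled = pooled, predictions = preds,
       failed = failed)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact two-sided test for small samples without ties, normal approximation
#' otherwise.
#'
#' @param a,b numeric samples (>= 3 each).
#' @return list(statistic, p_value).
#' @export
rankSumTest <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 values per group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Bias = mean(a - b); limits of agreement = bias +- 1.96 SD(a - b).
#'
#' @param a,b paired numeric vectors of equal length >= 3.
#' @return list(bias, sd, lower, upper, means, diffs).
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, sd = sdd, lower = bias - 1.96 * sdd,
       upper = bias + 1.96 * sdd, means = (a + b) / 2, diffs = d)
}

#' Conventional scar-segmentation baselines
#'
#' All operate on blood-pool-normalised intensities restricted to the wall:
#' \describe{
#'   \item{threshold}{wall voxels with normalised intensity > t.}
#'   \item{nsd}{wall voxels above n blood-pool SDs (normalised units).}
#'   \item{kmeans}{2-cluster k-means of wall intensities; scar = the
#'     higher-mean cluster.}
#'   \item{fcm}{2-cluster fuzzy c-means; scar = membership > 0.5 in the
#'     higher-mean cluster.}
#' }
#'
#' @param normalized_lge blood-pool-normalised \linkS4class{Volume3D}.
#' @param wall wall \linkS4class{BinaryMask} with at least 10 voxels.
#' @param method baseline name.
#' @param t threshold for \code{method = "threshold"}.
#' @param n SD multiplier for \code{method = "nsd"} (2, 4 or 6 in routine
#'   use).
#' @param seed seed for the clustering initialisations.
#' @return scar \linkS4class{BinaryMask}.
#' @export
baselineSegment <- function(normalized_lge, wall,
                            method = c("threshold", "nsd", "kmeans", "fcm"),
                            t = 2, n = 2, seed = 1L) {
  method <- match.arg(method)
  idx <- which(wall@data)
  if (length(idx) < 10) stop("wall has fewer than 10 voxels")
  v <- as.numeric(normalized_lge@data)[idx]
  pick <- switch(method,
    threshold = v > t,
    nsd = v > n,
    kmeans = {
      set.seed(seed)
      km <- stats::kmeans(v, centers = 2, nstart = 5)
      km$cluster == which.max(km$centers)
    },
    fcm = {
      set.seed(seed)
      fc <- e1071::cmeans(matrix(v, ncol = 1), centers = 2, m = 2)
      hi <- which.max(fc$centers)
      fc$membership[, hi] > 0.5
    })
  d <- dim(wall@data)
  arr <- array(FALSE, d)
  arr[idx[pick]] <- TRUE
  BinaryMask(arr, spacing = wall@spacing, affine = wall@affine)
}
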