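# Super-pixel scar classification: 16 intensity features per super-pixel,
# minimum-redundancy maximum-relevance (mutual-information-quotient) feature
# selection, and an RBF-kernel SVM tuned by grid-search cross-validation.

featureNames16 <- function() {
  c("f_min", "f_max", "f_mean", "f_median", "f_sd", "f_var", "f_mad_mean",
    "f_mad_median", "f_cov", "f_skew", "f_kurt", "f_mode", "f_cm3",
    "f_range", "f_iqr", "f_entropy")
}

#' Compute the 16 intensity features of a super-pixel
#'
#' Conventions: population SD/variance; Fisher skewness and excess kurtosis
#' (0 for constant input); third central moment; mode as the most frequent
#' 32-bin histogram center (ties to the lowest); interquartile range with
#' linear-interpolation quantiles; Shannon entropy (bits) of a 32-bin
#' histogram; coefficient of variance set to 0 when the mean is 0.
#'
#' @param pixels numeric vector of at least 4 intensities.
#' @return named numeric vector of length 16.
#' @export
computeFeatures <- function(pixels) {
  n <- length(pixels)
  if (n < 4) stop("need at least 4 pixels, got ", n)
  mu <- mean(pixels)
  sdp <- sqrt(mean((pixels - mu)^2)) # population SD
  rng <- range(pixels)
  m3 <- mean((pixels - mu)^3)
  m4 <- mean((pixels - mu)^4)
  if (rng[2] > rng[1]) {
    br <- seq(rng[1], rng[2], length.out = 33)
    cnt <- tabulate(findInterval(pixels, br, rightmost.closed = TRUE), 32)
    ctrs <- (br[-1] + br[-33]) / 2
    modev <- ctrs[which.max(cnt)]
    p <- cnt / n
    ent <- -sum(p[p > 0] * log2(p[p > 0]))
  } else {
    modev <- rng[1]
    ent <- 0
  }
  q <- stats::quantile(pixels, c(0.25, 0.75), type = 7, names = FALSE)
  c(f_min = rng[1], f_max = rng[2], f_mean = mu,
    f_median = stats::median(pixels), f_sd = sdp, f_var = sdp^2,
    f_mad_mean = mean(abs(pixels - mu)),
    f_mad_median = stats::median(abs(pixels - stats::median(pixels))),
    f_cov = if (mu == 0) 0 else sdp / mu,
    f_skew = if (sdp == 0) 0 else m3 / sdp^3,
    f_kurt = if (sdp == 0) 0 else m4 / sdp^4 - 3,
    f_mode = modev, f_cm3 = m3, f_range = rng[2] - rng[1],
    f_iqr = q[2] - q[1], f_entropy = ent)
}

# discrete mutual information (bits) between two integer vectors
discreteMI <- function(a, b) {
  tab <- table(a, b)
  miFromHist(unclass(tab))
}

# equal-frequency discretisation into at most `bins` levels
binEqualFreq <- function(x, bins = 8) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' mRMR (mutual-information-quotient) feature selection
#'
#' Greedy forward selection: the first feature maximises relevance
#' MI(feature; label); each subsequent pick maximises the quotient of
#' relevance over mean mutual information with the already-selected
#' features. Features are discretised into 8 equal-frequency bins; ties and
#' zero denominators are handled deterministically (first column wins, and
#' the redundancy denominator is floored at a small epsilon).
#'
#' @param table training data.frame containing the 16 feature columns and a
#'   \code{label} column with at least 2 classes.
#' @param k number of features to select (<= 16).
#' @return character vector of selected feature names, in selection order.
#' @export
mrmrSelect <- function(table, k = 3) {
  feats <- intersect(featureNames16(), names(table))
  stopifnot(k <= length(feats), nlevels(factor(table$label)) >= 2)
  y <- as.integer(factor(table$label))
  disc <- lapply(table[feats], binEqualFreq)
  rel <- vapply(disc, function(f) discreteMI(f, y), 0)
  selected <- names(which.max(rel))
  while (length(selected) < k) {
    rest <- setdiff(feats, selected)
    score <- vapply(rest, function(f) {
      red <- mean(vapply(selected, function(s)
        discreteMI(disc[[f]], disc[[s]]), 0))
      rel[f] / max(red, 1e-12)
    }, 0)
    selected <- c(selected, rest[which.max(score)])
  }
  selected
}

#' Train the RBF-SVM scar classifier
#'
#' Features are standardised to training mean/SD; (C, gamma) are chosen by
#' grid search maximising mean cross-validated accuracy (deterministic folds
#' per seed), and the final model is refit on all rows with balanced class
#' weights.
#'
#' @param table training data.frame (feature columns + \code{label}).
#' @param selected feature names to use (e.g. from \code{\link{mrmrSelect}}).
#' @param grid list with numeric vectors \code{C} and \code{gamma}; default
#'   C in 2^(-5..15), gamma in 2^(-15..3), powers of 4.
#' @param cv_folds internal CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return an object of class "TrainedScarClassifier": the fitted svm, the
#'   standardisation parameters, selected features, tuned (C, gamma) and the
#'   CV accuracy surface.
#' @export
trainSvm <- function(table, selected = featureNames16(),
                     grid = list(C = 2^seq(-5, 15, 4),
                                 gamma = 2^seq(-15, 3, 4)),
                     cv_folds = 5, seed = 1L) {
  y <- factor(table$label)
  if (nlevels(y) < 2) stop("single-class training data")
  stopifnot(length(grid$C) >= 1, length(grid$gamma) >= 1)
  X <- as.matrix(table[selected])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  set.seed(seed)
  n <- nrow(Xs)
  folds <- sample(rep_len(seq_len(min(cv_folds, n)), n))
  cw <- rev(as.numeric(table(y))) / length(y) * 2
  names(cw) <- levels(y)
  combos <- expand.grid(C = grid$C, gamma = grid$gamma)
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    mean(vapply(seq_len(max(folds)), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
      # looser KKT tolerance for the tuning fits only: selection is
      # unchanged and the expensive high-C corners run several-fold faster
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = combos$C[i], gamma = combos$gamma[i],
                        class.weights = cw, scale = FALSE, tolerance = 0.1)
      mean(stats::predict(fit, Xs[!tr, , drop = FALSE]) == y[!tr])
    }, 0), na.rm = TRUE)
  }, 0)
  best <- which.max(acc) # ties: first grid point, deterministic
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = combos$C[best],
                    gamma = combos$gamma[best], class.weights = cw,
                    scale = FALSE, probability = FALSE)
  structure(list(fit = fit, selected = selected, center = mu, scale = sdv,
                 C = combos$C[best], gamma = combos$gamma[best],
                 cv_accuracy = max(acc), grid = combos, grid_accuracy = acc,
                 levels = levels(y), seed = seed, cv_folds = cv_folds),
            class = "TrainedScarClassifier")
}

#' @export
print.TrainedScarClassifier <- function(x, ...) {
  cat(sprintf("RBF-SVM scar classifier: features [%s], C = %g, gamma = %g, CV accuracy %.3f\n",
              paste(x$selected, collapse = ", "), x$C, x$gamma,
              x$cv_accuracy))
  invisible(x)
}

#' Predict enhancement of super-pixels
#'
#' @param model a \code{\link{trainSvm}} fit.
#' @param table data.frame containing the model's selected feature columns.
#' @return data.frame with sp_id (if present), \code{label} and the signed
#'   decision \code{score} (positive = enhanced).
#' @export
predictScar <- function(model, table) {
  miss <- setdiff(model$selected, names(table))
  if (length(miss) > 0) stop("missing feature columns: ",
                             paste(miss, collapse = ", "))
  X <- scale(as.matrix(table[model$selected]), center = model$center,
             scale = model$scale)
  pr <- stats::predict(model$fit, X, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient the score so that positive margin means "enhanced"
  if (grepl("^enhanced", colnames(attr(pr, "decision.values"))[1])) {
    score <- dv
  } else {
    score <- -dv
  }
  out <- data.frame(label = factor(as.character(pr),
                                   levels = model$levels),
                    score = as.numeric(score))
  if ("sp_id" %in% names(table)) out <- cbind(table["sp_id"], out)
  if ("case" %in% names(table)) out <- cbind(table["case"], out)
  out
}

#' Assemble the binary scar mask from super-pixel predictions
#'
#' The mask is the union of the pixels of all super-pixels predicted
#' enhanced; everything else is 0.
#'
#' @param spmap a \linkS4class{SuperpixelMap}.
#' @param predictions data.frame with columns sp_id and label (or logical
#'   \code{enhanced}).
#' @param wall wall \linkS4class{BinaryMask} (grid reference; predictions
#'   must cover every super-pixel retained by the overlap rule).
#' @return scar \linkS4class{BinaryMask}.
#' @export
assembleScarMask <- function(spmap, predictions, wall) {
  stopifnot(identical(dim(spmap@data), dim(wall@data)))
  if (!all(predictions$sp_id %in% spmap@centers$sp_id)) {
    stop("prediction ids not present in the super-pixel map")
  }
  enh <- if ("label" %in% names(predictions)) {
    predictions$sp_id[predictions$label == "enhanced"]
  } else {
    predictions$sp_id[predictions$enhanced]
  }
  d <- dim(spmap@data)
  BinaryMask(array(spmap@data %in% enh, d), spacing = spmap@spacing,
             affine = spmap@affine)
}
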