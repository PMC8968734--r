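#' Gaussian kernel parameters
#'
#' @param sigma width of the Gaussian kernel (default 0.5).
#' @param c soft-margin penalty (default 1000).
#' @return a validated list of class `"KernelParams"`.
#' @export
kernelParams <- function(sigma = 0.5, c = 1000) {
  if (sigma <= 0 || c <= 0) stop("sigma and c must be > 0", call. = FALSE)
  structure(list(sigma = sigma, c = c), class = "KernelParams")
}

#' Gaussian (RBF) kernel
#'
#' `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`; symmetric, with values in
#' (0, 1].
#'
#' @param x,x_prime equal-length numeric vectors.
#' @param sigma kernel width (> 0).
#' @return the kernel value.
#' @export
gaussianKernel <- function(x, x_prime, sigma = 0.5) {
  if (length(x) != length(x_prime))
    stop("x and x_prime must have equal length", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  exp(-sum((x - x_prime)^2) / (2 * sigma^2))
}

# Kernel matrix between row-sets A (n x d) and B (m x d).
kernelMatrix <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

# Flatten an H x W x F feature array to an (H*W) x F matrix, pixel-major.
flattenFeatures <- function(feats) {
  d <- dim(feats)
  matrix(feats, d[1] * d[2], d[3],
         dimnames = list(NULL, dimnames(feats)[[3]]))
}

#' Stratified seeded sampling of training pixels
#'
#' Samples `n` pixels inside `mask` with non-background labels, allocated to
#' the tissue classes proportionally to their pixel counts (largest-remainder
#' rounding, at least 2 per class), and z-scores the feature columns using
#' the training sample's statistics (stored for reuse at prediction;
#' zero-variance columns are given unit scale).
#'
#' @param labels integer label matrix (ground truth or user-supplied).
#' @param mask logical matrix restricting eligible pixels.
#' @param feats feature array from [featureMap()] (plus any extra planes).
#' @param n number of training samples (default 1500).
#' @param seed integer seed.
#' @return list of class `"TrainingSet"` with `features` (n x d, z-scored),
#'   `labels`, `idx` (linear pixel indices), `center`, `scale`.
#' @export
sampleTrainingPixels <- function(labels, mask, feats, n = 1500L, seed = 1L) {
  eligible <- which(mask & labels != 0L)
  if (length(eligible) < n)
    stop("mask contains fewer eligible non-background pixels than n",
         call. = FALSE)
  allCls <- sort(setdiff(unique(as.vector(labels)), 0L))
  cls <- sort(unique(labels[eligible]))
  counts <- vapply(cls, function(k) sum(labels[eligible] == k), integer(1))
  if (length(setdiff(allCls, cls)) || any(counts < 2)) {
    missing <- union(setdiff(allCls, cls), cls[counts < 2])
    stop(sprintf("stratification failed: class %s has fewer than 2 pixels inside the mask",
                 paste(sort(missing), collapse = ",")), call. = FALSE)
  }
  # largest-remainder proportional allocation
  raw <- n * counts / sum(counts)
  alloc <- pmax(floor(raw), 2)
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    for (i in seq_len(rem)) {
      k <- ord[(i - 1) %% length(cls) + 1]
      alloc[k] <- alloc[k] + 1
    }
  } else if (rem < 0) {
    ord <- order(alloc, decreasing = TRUE)
    for (i in seq_len(-rem)) alloc[ord[(i - 1) %% length(cls) + 1]] <-
        alloc[ord[(i - 1) %% length(cls) + 1]] - 1
  }
  alloc <- pmin(alloc, counts)
  idx <- withSeed(seed, {
    unlist(lapply(seq_along(cls), function(k) {
      pool <- eligible[labels[eligible] == cls[k]]
      sort(pool[sample.int(length(pool), alloc[k])])
    }))
  })
  X <- flattenFeatures(feats)[idx, , drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xz <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  structure(list(features = Xz, labels = labels[idx], idx = idx,
                 center = ctr, scale = scl),
            class = "TrainingSet")
}

#' Train a one-vs-one Gaussian-kernel tissue SVM
#'
#' Fits one soft-margin SVM per label pair on the (already z-scored) training
#' set. The quadratic-programming step is delegated to the libsvm solver
#' (tolerance 1e-3); the support vectors, dual coefficients and bias of each
#' pairwise classifier are extracted into the returned [TissueSVM-class], and
#' all subsequent prediction is computed from those via [gaussianKernel()].
#' Dual coefficients are checked against the box constraint `|alpha_i| <= c`.
#'
#' @param train a `"TrainingSet"` from [sampleTrainingPixels()], or a list
#'   with z-scored `features`, `labels`, `center`, `scale`.
#' @param kernel a [kernelParams()].
#' @return a [TissueSVM-class].
#' @export
trainTissueSVM <- function(train, kernel = kernelParams()) {
  X <- train$features; y <- as.integer(train$labels)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("training set must contain at least two classes", call. = FALSE)
  if (min(table(y)) < 2)
    stop("every label class must be present at least twice", call. = FALSE)
  gamma <- 1 / (2 * kernel$sigma^2)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  classifiers <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    yf <- factor(y[sel], levels = pr)
    fit <- e1071::svm(x = X[sel, , drop = FALSE], y = yf,
                      type = "C-classification", kernel = "radial",
                      gamma = gamma, cost = kernel$c, scale = FALSE,
                      tolerance = 1e-3)
    # libsvm orders its internal labels by first appearance; fit$labels maps
    # them to factor levels. A positive decision value votes for the class
    # fit$levels[fit$labels[1]].
    list(classes = pr,
         sv = as.matrix(fit$SV),
         coefs = as.numeric(fit$coefs),
         rho = as.numeric(fit$rho),
         positive = as.integer(fit$levels[fit$labels[1]]))
  })
  new("TissueSVM", classifiers = classifiers,
      kernel = list(sigma = kernel$sigma, c = kernel$c),
      classes = as.integer(classes),
      center = as.numeric(train$center), scale = as.numeric(train$scale))
}

# Pairwise decision values for z-scored feature rows.
pairwiseDecisions <- function(model, Xz) {
  vapply(model@classifiers, function(cl) {
    K <- kernelMatrix(Xz, cl$sv, model@kernel$sigma)
    as.numeric(K %*% cl$coefs - cl$rho)
  }, numeric(nrow(Xz)))
}

#' Predict tissue labels with a trained SVM
#'
#' One-vs-one majority vote per pixel inside the mask; ties are broken by the
#' summed signed pairwise margins per class. Features are z-scored with the
#' statistics stored in the model.
#'
#' @param model a [TissueSVM-class].
#' @param feats feature array matching the training feature set.
#' @param mask logical matrix of pixels to predict (others stay 0).
#' @param return_votes also return the per-class vote tally.
#' @return integer label matrix; with `return_votes = TRUE`, a list with
#'   `labels` and `votes` (pixels x classes).
#' @export
predictTissue <- function(model, feats, mask = NULL, return_votes = FALSE) {
  d <- dim(feats)
  if (d[3] != length(model@center))
    stop("feature dimensionality does not match the trained model",
         call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  X <- flattenFeatures(feats)[which(mask), , drop = FALSE]
  Xz <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  dec <- pairwiseDecisions(model, Xz)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  ncls <- length(model@classes)
  votes <- matrix(0L, nrow(Xz), ncls)
  margins <- matrix(0, nrow(Xz), ncls)
  colnames(votes) <- colnames(margins) <- model@classes
  for (i in seq_along(model@classifiers)) {
    cl <- model@classifiers[[i]]
    pos <- match(cl$positive, model@classes)
    neg <- match(setdiff(cl$classes, cl$positive), model@classes)
    win <- ifelse(dec[, i] > 0, pos, neg)
    votes[cbind(seq_len(nrow(votes)), win)] <-
      votes[cbind(seq_len(nrow(votes)), win)] + 1L
    margins[, pos] <- margins[, pos] + dec[, i]
    margins[, neg] <- margins[, neg] - dec[, i]
  }
  # majority vote, margin-sum tie-break
  best <- max.col(votes, ties.method = "first")
  top <- votes[cbind(seq_len(nrow(votes)), best)]
  tied <- rowSums(votes == top) > 1
  if (any(tied)) {
    for (r in which(tied)) {
      cand <- which(votes[r, ] == top[r])
      best[r] <- cand[which.max(margins[r, cand])]
    }
  }
  labels <- matrix(0L, d[1], d[2])
  labels[which(mask)] <- model@classes[best]
  if (return_votes) list(labels = labels, votes = votes) else labels
}

#' C-SVM tissue segmentation pipeline
#'
#' The combined Chan-Vese / SVM segmentation: a two-phase Chan-Vese contour
#' isolates brain tissue from the background, then a Gaussian-kernel SVM
#' labels every in-contour pixel as CSF, gray matter or white matter from its
#' texture features (five GLCM statistics per orientation) plus the windowed
#' raw intensity mean (21 dimensions with the default four orientations).
#' Pixels outside the contour are labeled background, with provenance
#' recorded.
#'
#' @param image numeric intensity matrix.
#' @param train_labels integer label map supplying training classes (phantom
#'   ground truth or a user-provided partial map; 0 = unlabeled/background).
#' @param cv_params a [cvParams()].
#' @param texture_config a [textureConfig()].
#' @param kernel a [kernelParams()].
#' @param n_train number of training pixels (default 1500).
#' @param seed integer seed for the stratified sampling.
#' @return a [TissueLabelMap-class] with attribute `"model"` (the fitted
#'   [TissueSVM-class]) and `"cv"` (the [CVResult-class]).
#' @export
csvmSegment <- function(image, train_labels, cv_params = cvParams(),
                        texture_config = textureConfig(),
                        kernel = kernelParams(), n_train = 1500L,
                        seed = 1L) {
  cv <- segmentCV(image, cv_params)
  mask <- insideMask(cv)
  feats <- featureMap(image, texture_config)
  im <- windowMean(image, texture_config$window)
  feats <- array(c(feats, im), dim = dim(feats) + c(0, 0, 1),
                 dimnames = list(NULL, NULL,
                                 c(dimnames(feats)[[3]], "intensity_mean")))
  train <- sampleTrainingPixels(train_labels, mask, feats, n = n_train,
                                seed = seed)
  model <- trainTissueSVM(train, kernel)
  labels <- predictTissue(model, feats, mask)
  out <- new("TissueLabelMap", labels = labels,
             provenance = matrix(as.integer(mask), nrow(labels), ncol(labels)))
  attr(out, "model") <- model
  attr(out, "cv") <- cv
  out
}
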