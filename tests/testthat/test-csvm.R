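test_that("gaussian kernel matches its closed form and symmetry", {
  x <- c(1, 2, 3)
  expect_equal(gaussianKernel(x, x, 0.5), 1)
  expect_equal(gaussianKernel(c(0, 0), c(1, 0), 0.5), exp(-2))
  expect_error(gaussianKernel(1:3, 1:2), "equal length")
  set.seed(10)
  for (i in 1:100) {
    a <- stats::rnorm(5); b <- stats::rnorm(5)
    expect_identical(gaussianKernel(a, b), gaussianKernel(b, a))
  }
})

test_that("kernel Gram matrices are symmetric positive semi-definite", {
  set.seed(11)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(25 * 4), 25, 4)
    K <- neuroSegReg:::kernelMatrix(A, A, 0.5)
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_true(all(K > 0 & K <= 1 + 1e-12))
  }
})

test_that("stratified sampling honors size, strata and z-scoring", {
  ph <- defaultPhantom(7)
  feats <- featureMap(intensity(ph))
  mask <- tissueLabels(ph) != 0L
  tr <- sampleTrainingPixels(tissueLabels(ph), mask, feats, n = 1500,
                             seed = 4)
  expect_equal(nrow(tr$features), 1500)
  expect_true(all(table(tr$labels) >= 300))
  expect_true(all(abs(colMeans(tr$features)) < 1e-9))
  expect_true(all(abs(apply(tr$features, 2, stats::sd) - 1) < 1e-9))

  tr2 <- sampleTrainingPixels(tissueLabels(ph), mask, feats, n = 1500,
                              seed = 4)
  expect_identical(tr$idx, tr2$idx)

  # a class absent inside the mask is reported by name
  expect_error(sampleTrainingPixels(tissueLabels(ph),
                                    mask & tissueLabels(ph) != 1L, feats,
                                    n = 1000, seed = 1),
               "class 1")
  expect_error(sampleTrainingPixels(tissueLabels(ph), mask, feats,
                                    n = sum(mask) + 1, seed = 1),
               "fewer eligible")
})

test_that("SVM training fits separable and XOR layouts exactly", {
  X <- matrix(c(0, 0, 0, 1, 5, 5, 5, 6), ncol = 2, byrow = TRUE)
  tr <- list(features = X, labels = c(1, 1, 3, 3),
             center = c(0, 0), scale = c(1, 1))
  m <- trainTissueSVM(tr, kernelParams(0.5, 1000))
  expect_true(validObject(m))
  expect_equal(as.vector(predictTissue(m, array(X, c(4, 1, 2)))),
               c(1, 1, 3, 3))

  Xx <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  trx <- list(features = Xx, labels = c(1, 1, 2, 2),
              center = c(0, 0), scale = c(1, 1))
  mx <- trainTissueSVM(trx, kernelParams(0.5, 1000))
  expect_equal(as.vector(predictTissue(mx, array(Xx, c(4, 1, 2)))),
               c(1, 1, 2, 2))
})

test_that("duplicating training points leaves probe predictions unchanged", {
  X <- matrix(c(0, 0, 0, 1, 5, 5, 5, 6), ncol = 2, byrow = TRUE)
  tr <- list(features = X, labels = c(1, 1, 3, 3),
             center = c(0, 0), scale = c(1, 1))
  trd <- list(features = rbind(X, X), labels = rep(c(1, 1, 3, 3), 2),
              center = c(0, 0), scale = c(1, 1))
  m <- trainTissueSVM(tr, kernelParams(0.5, 1000))
  md <- trainTissueSVM(trd, kernelParams(0.5, 1000))
  probe <- as.matrix(expand.grid(seq(-1, 6, length.out = 10),
                                 seq(-1, 7, length.out = 10)))
  expect_identical(predictTissue(m, array(probe, c(100, 1, 2))),
                   predictTissue(md, array(probe, c(100, 1, 2))))
})

test_that("one-vs-one voting is complete and ties fall back to margins", {
  set.seed(6)
  X3 <- rbind(matrix(stats::rnorm(20, 0), 10, 2),
              matrix(stats::rnorm(20, 4), 10, 2),
              matrix(stats::rnorm(20, 8), 10, 2))
  tr3 <- list(features = X3, labels = rep(1:3, each = 10),
              center = c(0, 0), scale = c(1, 1))
  m3 <- trainTissueSVM(tr3, kernelParams(1, 10))
  pv <- predictTissue(m3, array(X3, c(30, 1, 2)), return_votes = TRUE)
  expect_true(all(rowSums(pv$votes) == length(m3@classifiers)))
  expect_equal(as.vector(pv$labels), rep(1:3, each = 10))

  # identical feature vectors collapse to a single class
  same <- array(rep(c(0.1, 0.1), each = 25), c(25, 1, 2))
  expect_equal(length(unique(as.vector(predictTissue(m3, same)))), 1L)

  # dimension mismatch is rejected
  expect_error(predictTissue(m3, array(0, c(4, 1, 5))), "dimensionality")
})

test_that("C-SVM pipeline reaches the expected accuracy regimes", {
  # separable-means limit: noiseless, bias-free phantom
  p0 <- makeBrainPhantom(phantomSpec(noise_fraction = 0, bias_fraction = 0,
                                     seed = 7))
  seg0 <- csvmSegment(intensity(p0), tissueLabels(p0), seed = 7)
  expect_gte(mean(tissueLabels(seg0) == tissueLabels(p0)), 0.99)

  # default phantom at the standard operating point
  ph <- defaultPhantom(7)
  seg <- csvmSegment(intensity(ph), tissueLabels(ph), seed = 7)
  lab <- tissueLabels(ph)
  met <- overallAccuracy(tissueLabels(seg), lab, lab != 0)
  expect_gte(met@overallAccuracy, 0.80)

  # gating: everything outside the contour is background
  expect_true(all(tissueLabels(seg)[seg@provenance == 0L] == 0L))
  cv <- attr(seg, "cv")
  expect_true(all(tissueLabels(seg)[!insideMask(cv)] == 0L))

  # determinism of the full pipeline
  seg2 <- csvmSegment(intensity(ph), tissueLabels(ph), seed = 7)
  expect_identical(tissueLabels(seg), tissueLabels(seg2))
})

test_that("pipeline accuracy degrades monotonically with noise", {
  acc <- sapply(c(0, 0.02, 0.10), function(nf) {
    mean(sapply(1:3, function(r) {
      ph <- makeBrainPhantom(phantomSpec(noise_fraction = nf,
                                         seed = 200 + r))
      lab <- tissueLabels(ph)
      seg <- csvmSegment(intensity(ph), lab, seed = 200 + r)
      overallAccuracy(tissueLabels(seg), lab, lab != 0)@overallAccuracy
    }))
  })
  expect_true(acc[1] >= acc[2] && acc[2] >= acc[3])
})
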