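test_that("quantization bins uniformly and degrades gracefully", {
  expect_equal(quantizeImage(matrix(c(0, 1), 1, 2), 2),
               matrix(c(0L, 1L), 1, 2))
  ramp <- matrix(seq(0, 1, length.out = 8), 1, 8)
  q <- quantizeImage(ramp, 4)
  expect_equal(as.vector(table(q)), rep(2L, 4))
  expect_true(all(quantizeImage(matrix(3.7, 5, 5), 16) == 0L))
})

test_that("co-occurrence counts match brute-force enumeration", {
  # constant window: single pair type
  g <- computeGLCM(matrix(2L, 7, 7), d = 1, theta = 0, n_levels = 4)
  expect_equal(g@p[3, 3], 1)
  expect_equal(sum(g@p), 1)

  # checkerboard, horizontal offset: 12 alternating pairs
  cb <- checkerboard4()
  g2 <- computeGLCM(cb, d = 1, theta = 0, n_levels = 2)
  expect_equal(g2@p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # marginal identities
  expect_equal(rowSums(g2@p), g2@px)
  expect_equal(sum(g2@px), 1)

  # offset too large for the window
  expect_error(computeGLCM(matrix(0L, 2, 2), d = 5, theta = 0, n_levels = 2),
               "empty GLCM")
})

test_that("texture statistics match hand-derived fixtures", {
  gc <- computeGLCM(matrix(0L, 7, 7), n_levels = 16)
  expect_equal(textureFeatures(gc),
               c(asm = 1, contrast = 0, correlation = 0, variance = 0,
                 entropy = 0))

  g2 <- computeGLCM(checkerboard4(), d = 1, theta = 0, n_levels = 2)
  expect_equal(textureFeatures(g2, log_base = 2),
               c(asm = 0.5, contrast = 1, correlation = -1,
                 variance = -0.25, entropy = 1))

  # uniform 4-level GLCM attains the maximum entropy log2(16) = 4 bits
  gu <- new("GLCM", p = matrix(1 / 16, 4, 4), px = rep(0.25, 4),
            py = rep(0.25, 4), muX = 1.5, muY = 1.5,
            sigmaX = sqrt(1.25), sigmaY = sqrt(1.25), nLevels = 4L,
            d = 1L, theta = 0, symmetric = FALSE)
  expect_equal(unname(textureFeatures(gu, 2)["entropy"]), 4)
  set.seed(9)
  for (i in 1:25) {
    p <- matrix(stats::rexp(16), 4, 4); p <- p / sum(p)
    nz <- p[p > 0]
    expect_lte(-sum(nz * log2(nz)), 4)
  }
})

test_that("statistics agree with the brute-force oracle on random windows", {
  set.seed(41)
  for (i in 1:60) {
    nl <- sample(c(4L, 8L, 16L), 1)
    win <- matrix(sample(0:(nl - 1), 49, replace = TRUE), 7, 7)
    th <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    got <- textureFeatures(computeGLCM(win, d = 1, theta = th, n_levels = nl,
                                       symmetric = sym))
    want <- glcmOracle(win, 1, th, nl, 2, sym)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("ASM respects its analytic bounds on random GLCMs", {
  set.seed(12)
  for (i in 1:50) {
    win <- matrix(sample(0:7, 49, replace = TRUE), 7, 7)
    g <- computeGLCM(win, d = 1, theta = 45, n_levels = 8)
    a <- textureFeatures(g)["asm"]
    expect_gte(a, 1 / 8^2)
    expect_lte(a, 1)
  }
})

test_that("feature maps match the per-window path and image structure", {
  set.seed(77)
  img <- matrix(stats::runif(30 * 30), 30, 30)
  cfg <- textureConfig()
  fm <- featureMap(img, cfg)
  expect_equal(dim(fm), c(30, 30, 20))

  q <- quantizeImage(img, cfg$n_levels)
  qp <- neuroSegReg:::padReflect(q, 3)
  for (i in 1:10) {
    r <- sample(30, 1); c <- sample(30, 1)
    win <- qp[r:(r + 6), c:(c + 6)]
    for (ti in seq_along(cfg$thetas)) {
      want <- textureFeatures(
        computeGLCM(win, cfg$d, cfg$thetas[ti], cfg$n_levels))
      expect_lt(max(abs(fm[r, c, (5 * ti - 4):(5 * ti)] - want)), 1e-10)
    }
  }

  # constant image: ASM 1, everything else 0, per orientation
  fc <- featureMap(matrix(1, 12, 12), cfg)
  expect_true(all(fc[, , seq(1, 20, by = 5)] == 1))
  expect_true(all(fc[, , -seq(1, 20, by = 5)] == 0))

  # vertical stripes of period 2: contrast across stripes exceeds along
  stripes <- matrix(rep(c(0, 1), 15), 30, 30, byrow = TRUE)[, 1:30]
  fs <- featureMap(stripes, textureConfig(thetas = c(0, 90), n_levels = 2))
  interior <- 5:26
  expect_true(all(fs[interior, interior, "contrast_t0"] >
                  fs[interior, interior, "contrast_t90"]))

  # rotating the image by 90 deg swaps the 0- and 90-deg planes (interior)
  rot <- t(img)[, nrow(img):1] # rot[i, j] = img[31 - j, i]
  f0 <- featureMap(img, textureConfig(thetas = c(0, 90)))
  f90 <- featureMap(rot, textureConfig(thetas = c(0, 90)))
  # pixel (r, c) maps to (c, 31 - r); horizontal pairs become vertical ones
  # (reversed direction, to which all five statistics are invariant)
  ok <- TRUE
  for (r in 8:22) for (c in 8:22) {
    a <- f0[r, c, 1:5]        # theta = 0 at original pixel
    b <- f90[c, 31 - r, 6:10] # theta = 90 at rotated pixel
    if (max(abs(a - b)) > 1e-10) ok <- FALSE
  }
  expect_true(ok)
})

test_that("texture config validation enforces the stated invariants", {
  expect_error(textureConfig(window = 4), "odd")
  expect_error(textureConfig(thetas = c(0, 30)), "subset")
  expect_error(textureConfig(n_levels = 1), ">= 2")
  expect_error(featureMap(matrix(1, 4, 4), textureConfig()), "smaller")
})
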