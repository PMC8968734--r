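test_that("rigid transforms compose, invert and map points consistently", {
  tf <- rigidTransform(3, -2, 5, c(10, 10))
  inv <- invertTransform(tf)
  idp <- composeTransforms(inv, tf)
  expect_lt(max(abs(transformParams(idp))), 1e-9)

  pts <- matrix(c(0, 0, 5, 3, 2, 8), ncol = 2, byrow = TRUE)
  back <- transformPoints(inv, transformPoints(tf, pts))
  expect_equal(back, pts)

  # resampling under the identity is exact
  img <- matrix(stats::runif(64), 8, 8)
  expect_identical(applyTransform(img, rigidTransform(0, 0, 0)), img)
})

test_that("mode-seeking clustering matches the blob fixtures", {
  one <- clusterFuzzyPixels(matrix(c(3, 3), 1, 2))
  expect_equal(nrow(clusterCenters(one)), 1L)
  expect_equal(as.vector(clusterCenters(one)), c(3, 3))

  set.seed(1)
  b1 <- cbind(stats::rnorm(40, 10), stats::rnorm(40, 10))
  b2 <- cbind(stats::rnorm(40, 40), stats::rnorm(40, 40))
  cl <- clusterFuzzyPixels(rbind(b1, b2), regParams(m_threshold = 5))
  expect_equal(nrow(clusterCenters(cl)), 2L)
  ctrs <- clusterCenters(cl)[order(clusterCenters(cl)[, 1]), ]
  expect_lt(max(abs(ctrs[1, ] - colMeans(b1))), 1)
  expect_lt(max(abs(ctrs[2, ] - colMeans(b2))), 1)
  expect_true(all(!is.na(clusterMemberships(cl))))

  # blobs 3 px apart merge under m_threshold = 5
  b3 <- cbind(stats::rnorm(40, 10), stats::rnorm(40, 13))
  cl2 <- clusterFuzzyPixels(rbind(b1, b3), regParams(m_threshold = 5))
  expect_equal(nrow(clusterCenters(cl2)), 1L)
})

test_that("clustering is stable under permutation of the input points", {
  set.seed(2)
  pts <- rbind(cbind(stats::rnorm(30, 5), stats::rnorm(30, 5)),
               cbind(stats::rnorm(30, 25), stats::rnorm(30, 30)))
  p <- regParams(m_threshold = 5, seed = 3)
  a <- clusterFuzzyPixels(pts, p)
  perm <- sample(nrow(pts))
  b <- clusterFuzzyPixels(pts[perm, ], p)
  ca <- clusterCenters(a)[order(clusterCenters(a)[, 1]), ]
  cb <- clusterCenters(b)[order(clusterCenters(b)[, 1]), ]
  expect_lt(max(abs(ca - cb)), p$tau)
})

test_that("recursive similarity follows its defining recursion and bound", {
  tr <- recursiveSimilarity(c(1, 1, 1), 0.5)
  expect_equal(tr@values, c(1, 1.5, 1.75))

  # phi -> 0 limit reduces to the increments
  tr0 <- recursiveSimilarity(c(2, 3, 4), 1e-12)
  expect_equal(tr0@values, c(2, 3, 4), tolerance = 1e-9)

  # constant increment converges to c / (1 - phi)
  trc <- recursiveSimilarity(rep(0.8, 60), 0.5)
  expect_lt(abs(utils::tail(trc@values, 1) - 0.8 / 0.5) / (0.8 / 0.5), 0.01)

  # boundedness for bounded increments
  set.seed(8)
  inc <- stats::runif(100, 0, 0.9)
  trb <- recursiveSimilarity(inc, 0.7)
  expect_true(all(trb@values <= 0.9 / (1 - 0.7) + 1e-12))
})

test_that("block matching recovers constructed shifts and degenerate cases", {
  ph <- makeBrainPhantom(phantomSpec(noise_fraction = 0, seed = 7))
  base <- intensity(ph)

  m0 <- blockMatch(base, base)
  expect_true(all(m0$dr == 0 & m0$dc == 0))
  expect_true(all(abs(m0$ncc - 1) < 1e-12))

  tf <- rigidTransform(2, 0, 0, gridCenter(base))
  mov <- applyTransform(base, tf, pad = 0.05)
  m <- blockMatch(base, mov)
  agree <- mean(abs(m$dr - 2) < 0.5 & abs(m$dc) < 0.5)
  expect_gte(agree, 0.9)

  flat <- blockMatch(matrix(1, 48, 48), matrix(1, 48, 48))
  expect_equal(nrow(flat), 0L)

  expect_error(blockMatch(base, base[1:90, ]), "share dimensions")
})

test_that("boosted weights separate corrupted from clean matches", {
  ph <- makeBrainPhantom(phantomSpec(noise_fraction = 0, seed = 7))
  base <- intensity(ph)
  mov <- applyTransform(base, rigidTransform(2, 1, 0, gridCenter(base)),
                        pad = 0.05)
  m <- blockMatch(base, mov)

  set.seed(3)
  idx <- sample(nrow(m), round(0.2 * nrow(m)))
  mc <- m
  mc$dr[idx] <- mc$dr[idx] + stats::runif(length(idx), 5, 8)
  mc$disagree <- sqrt((mc$dr - stats::median(mc$dr))^2 +
                      (mc$dc - stats::median(mc$dc))^2)
  w <- boostMatchWeights(mc)
  expect_true(all(w >= 0 & w <= 1))
  expect_lt(mean(w[idx]), mean(w[-idx]))

  # pure inlier field: every weight at least 0.5
  pure <- m[abs(m$dr - 2) < 0.5 & abs(m$dc - 1) < 0.5, ]
  pure$disagree <- 0
  expect_true(all(boostMatchWeights(pure) >= 0.5))

  # a single boosting round is exactly one stump's prediction
  w1 <- boostMatchWeights(mc, regParams(n_iters = 10L, iter_step = 10L))
  expect_true(all(w1 %in% c(0, 1)))

  expect_error(boostMatchWeights(m[1:5, ]), "at least 10")
})

test_that("rigid fits agree with the closed-form Procrustes oracle", {
  pts <- matrix(c(0, 0, 5, 3, 2, 8, 7, 1, 4, 6), ncol = 2, byrow = TRUE)

  # exact translation
  est <- estimateRigidTransform(pts, sweep(pts, 2, c(3, -2), "+"))
  expect_equal(transformParams(est), c(tx = 3, ty = -2, angle = 0),
               tolerance = 1e-9)

  # rotation + translation, against the oracle
  truth <- rigidTransform(1, 1, 5, c(10, 10))
  dst <- transformPoints(truth, pts)
  est2 <- estimateRigidTransform(pts, dst, center = c(10, 10))
  expect_lt(max(abs(transformParams(est2) - c(1, 1, 5))), 1e-8)
  orc <- procrustesOracle(pts, dst, center = c(10, 10))
  expect_lt(max(abs(transformParams(est2) -
                    c(orc$tx, orc$ty, orc$angle))), 1e-8)

  # weighted fits are invariant to weight scaling
  set.seed(5)
  w <- stats::runif(nrow(pts), 0.2, 1)
  a <- estimateRigidTransform(pts, dst, w, center = c(10, 10))
  b <- estimateRigidTransform(pts, dst, 2 * w, center = c(10, 10))
  expect_equal(transformParams(a), transformParams(b))

  # coincident source points cannot define a rotation
  same <- matrix(1, 4, 2)
  expect_error(estimateRigidTransform(same, same + 1), "degenerate")
})

test_that("time-series registration recovers motion parameters", {
  ph <- makeBrainPhantom(phantomSpec(noise_fraction = 0, seed = 7))

  # static series: identity within 1e-6
  st <- registerTimeSeries(list(intensity(ph), intensity(ph), intensity(ph)))
  for (tf in st$transforms[-1])
    expect_lt(max(abs(transformParams(tf))), 1e-6)

  # short seeded noiseless series: sub-quarter-pixel parameter recovery
  errT <- c(); errA <- c()
  for (s in 1:5) {
    ser <- makeMotionSeries(ph, n_frames = 4, max_shift_px = 3,
                            max_rot_deg = 2, noise_fraction = 0,
                            seed = 30 + s)
    res <- registerTimeSeries(ser)
    for (k in 2:4) {
      e <- transformParams(res$transforms[[k]]) -
        transformParams(truthTransforms(ser)[[k]])
      errT <- c(errT, abs(e[1:2])); errA <- c(errA, abs(e[3]))
    }
  }
  expect_lte(mean(errT), 0.25)
  expect_lte(mean(errA), 0.25)

  # per-frame diagnostics: 100 seeded pixels, cluster centers, polar output
  d <- res$diagnostics[[2]]
  expect_equal(nrow(d$sampledPixels), 100)
  expect_true(is.matrix(d$clusterCenters) && nrow(d$clusterCenters) >= 1)
  expect_s4_class(d$polar, "PolarOutput")
  expect_equal(d$polar@T,
               sqrt(sum(transformParams(res$transforms[[2]])[1:2]^2)))
  expect_s4_class(d$similarity, "SimilarityTrace")
})

test_that("registration is inverse-consistent on a noiseless pair", {
  ph <- makeBrainPhantom(phantomSpec(noise_fraction = 0, seed = 7))
  base <- intensity(ph)
  tf <- rigidTransform(2.2, -1.4, 1.2, gridCenter(base))
  mov <- applyTransform(base, tf, pad = 0.05)
  ab <- registerTimeSeries(list(base, mov))$transforms[[2]]
  ba <- registerTimeSeries(list(mov, base))$transforms[[2]]
  comp <- composeTransforms(ab, ba)
  probe <- as.matrix(expand.grid(seq(0, 95, length.out = 5),
                                 seq(0, 95, length.out = 5)))
  moved <- transformPoints(comp, probe)
  expect_lt(mean(sqrt(rowSums((moved - probe)^2))), 0.5)
})

test_that("polar output is a faithful spherical conversion", {
  p <- toPolarOutput(c(0, 0, 1))
  expect_equal(c(p@T, p@gammaDeg, p@phiDeg), c(1, 0, 0))
  expect_lt(max(abs(p@cartesian - c(0, 0, 1))), 1e-12)

  p2 <- toPolarOutput(c(1, 1, 0))
  expect_equal(c(p2@T, p2@gammaDeg, p2@phiDeg), c(sqrt(2), 90, 45))

  z <- toPolarOutput(c(0, 0))
  expect_equal(c(z@T, z@gammaDeg, z@phiDeg), c(0, 0, 0))
  expect_true(toPolarOutput(c(1, 2), gate_value = -0.1)@gate)
  expect_false(toPolarOutput(c(1, 2), gate_value = 0.4)@gate)

  set.seed(14)
  for (i in 1:100) {
    v <- stats::rnorm(3)
    expect_lt(max(abs(toPolarOutput(v)@cartesian - v)), 1e-9)
  }
})
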