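test_that("Dice coefficient matches its definition and conventions", {
  m <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(diceCoefficient(m, m), 1)
  expect_equal(diceCoefficient(m, !m), 0)
  expect_equal(diceCoefficient(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  a <- matrix(FALSE, 4, 4); a[1:2, ] <- TRUE   # |A| = 8
  b <- matrix(FALSE, 4, 4); b[2:3, ] <- TRUE   # |B| = 8, overlap 4
  expect_equal(diceCoefficient(a, b), 0.5)
})

test_that("accuracy, confusion and per-class Dice are mutually consistent", {
  set.seed(30)
  truth <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  met <- overallAccuracy(truth, truth)
  expect_equal(met@overallAccuracy, 1)
  expect_true(all(met@dice == 1))

  pred <- truth
  flip <- sample(100, 25)
  pred[flip] <- (pred[flip] + 1L) %% 4L
  met2 <- overallAccuracy(pred, truth)
  expect_equal(met2@overallAccuracy, 0.75)
  expect_equal(sum(met2@confusion), 100)
  expect_equal(unname(rowSums(met2@confusion)),
               as.vector(table(factor(truth, levels = 0:3))))
  expect_equal(met2@overallAccuracy,
               sum(diag(met2@confusion)) / sum(met2@confusion))

  expect_error(overallAccuracy(pred, truth, matrix(FALSE, 10, 10)), "empty")
})

test_that("target registration error matches uniform-displacement cases", {
  probe <- matrix(c(0, 0, 3, 4, 10, 2), ncol = 2, byrow = TRUE)
  id <- rigidTransform(0, 0, 0)
  expect_equal(targetRegistrationError(id, id, probe), 0)
  shift <- rigidTransform(1, 0, 0)
  expect_equal(targetRegistrationError(shift, id, probe), 1)
  # invariant to duplicated probe points
  expect_equal(targetRegistrationError(shift, id, rbind(probe, probe)), 1)
})

test_that("image, label, series, transform and config files round-trip", {
  td <- withr::local_tempdir()
  set.seed(20)
  g <- matrix(stats::runif(15 * 12), 15, 12)

  writeImageGrid(g, file.path(td, "g.nii"))
  expect_identical(readImageGrid(file.path(td, "g.nii")), g)
  writeImageGrid(g, file.path(td, "g.nii.gz"))
  expect_identical(readImageGrid(file.path(td, "g.nii.gz")), g)
  writeImageGrid(g, file.path(td, "g.tif"))
  expect_lt(max(abs(readImageGrid(file.path(td, "g.tif")) - g)), 1e-6)
  writeImageGrid(g, file.path(td, "g.png"))
  expect_lt(max(abs(readImageGrid(file.path(td, "g.png")) - g)), 1 / 255)

  lab <- matrix(sample(0:3, 180, replace = TRUE), 15, 12)
  writeLabelMap(lab, file.path(td, "l.png"))
  expect_identical(readLabelMap(file.path(td, "l.png")), lab)
  writeLabelMap(lab, file.path(td, "l.nii"))
  expect_identical(readLabelMap(file.path(td, "l.nii")), lab)

  ser <- list(g, g * 0.5, g * 0.25)
  writeSeries(ser, file.path(td, "s.nii"))
  expect_identical(readSeries(file.path(td, "s.nii")), ser)
  writeSeries(ser, file.path(td, "s.tif"))
  got <- readSeries(file.path(td, "s.tif"))
  expect_equal(length(got), 3)
  expect_lt(max(abs(got[[2]] - ser[[2]])), 1e-6)

  tfs <- list(rigidTransform(0, 0, 0, c(5, 5)),
              rigidTransform(1.5, -2, 3, c(5, 5)))
  writeTransforms(tfs, file.path(td, "t.json"))
  back <- readTransforms(file.path(td, "t.json"))
  expect_equal(transformParams(back[[2]]), transformParams(tfs[[2]]))
  expect_equal(back[[2]]@center, c(5, 5))

  cfg <- runConfig(seed = 42L, sigma = 0.7)
  writeRunConfig(cfg, file.path(td, "c.yaml"))
  expect_identical(unclass(readRunConfig(file.path(td, "c.yaml"))),
                   unclass(cfg))
  expect_error(runConfig(nonsense = 1), "unknown config keys")
})

test_that("unreadable or malformed inputs raise clear errors", {
  td <- withr::local_tempdir()
  writeLines("not an image", file.path(td, "bad.nii"))
  expect_error(suppressWarnings(readImageGrid(file.path(td, "bad.nii"))),
               "format error")
  expect_error(readImageGrid(file.path(td, "missing.png")), "no such file")
  writeLines("x", file.path(td, "img.xyz"))
  expect_error(readImageGrid(file.path(td, "img.xyz")), "unsupported format")
  bad <- matrix(1, 3, 3); bad[2, 3] <- NaN
  expect_error(writeImageGrid(bad, file.path(td, "nan.nii")),
               "non-finite pixel at \\(row 2, col 3\\)")
})

test_that("seeded CLI invocations are bit-reproducible", {
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.nii"); f2 <- file.path(td, "b.nii")
  l1 <- file.path(td, "a.png"); l2 <- file.path(td, "b.png")
  runCLI("phantom-gen", "--size", "48x48", "--noise", "0.02", "--bias",
         "0.30", "--seed", "5", "--out", f1, "--labels", l1)
  runCLI("phantom-gen", "--size", "48x48", "--noise", "0.02", "--bias",
         "0.30", "--seed", "5", "--out", f2, "--labels", l2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readBin(l1, "raw", file.size(l1)),
                   readBin(l2, "raw", file.size(l2)))

  s1 <- file.path(td, "s1.tif"); s2 <- file.path(td, "s2.tif")
  t1 <- file.path(td, "t1.json"); t2 <- file.path(td, "t2.json")
  runCLI("phantom-series", "--size", "48x48", "--frames", "3", "--seed",
         "9", "--out", s1, "--truth", t1)
  runCLI("phantom-series", "--size", "48x48", "--frames", "3", "--seed",
         "9", "--out", s2, "--truth", t2)
  expect_identical(readBin(s1, "raw", file.size(s1)),
                   readBin(s2, "raw", file.size(s2)))
  expect_identical(readLines(t1), readLines(t2))
})
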