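# Shared fixtures and independent oracles, built in code at test time.

# Noiseless two-phase fixture: bright disc (0.8) on dark background (0.1).
discFixture <- function(size = 96, radius = 28, fg = 0.8, bg = 0.1) {
  ctr <- (size - 1) / 2
  rr <- matrix(rep(0:(size - 1), size), size, size) - ctr
  cc <- t(rr)
  inside <- sqrt(rr^2 + cc^2) <= radius
  img <- matrix(bg, size, size)
  img[inside] <- fg
  list(image = img, truth = inside)
}

# 4x4 binary checkerboard (levels 0/1).
checkerboard4 <- function()
  matrix(c(0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0), 4, 4,
         byrow = TRUE)

# Independent brute-force GLCM oracle: explicit double loops over the window
# for the pair counts and over (i, j) for the five statistics, written
# directly from the defining formulas.
glcmOracle <- function(window, d, theta, nLevels, logBase = 2,
                       symmetric = FALSE) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, nLevels, nLevels)
  for (m in seq_len(nrow(window))) {
    for (n in seq_len(ncol(window))) {
      x <- m + off[1]; y <- n + off[2]
      if (x >= 1 && x <= nrow(window) && y >= 1 && y <= ncol(window)) {
        i <- window[m, n] + 1
        j <- window[x, y] + 1
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  p <- counts / sum(counts)
  px <- numeric(nLevels); py <- numeric(nLevels)
  for (i in 1:nLevels) for (j in 1:nLevels) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  muX <- 0; muY <- 0
  for (i in 1:nLevels) {
    muX <- muX + (i - 1) * px[i]
    muY <- muY + (i - 1) * py[i]
  }
  sX <- 0; sY <- 0
  for (i in 1:nLevels) {
    sX <- sX + (i - 1 - muX)^2 * px[i]
    sY <- sY + (i - 1 - muY)^2 * py[i]
  }
  sX <- sqrt(sX); sY <- sqrt(sY)
  asm <- 0; contrast <- 0; corrNum <- 0; variance <- 0; entropy <- 0
  for (i in 1:nLevels) for (j in 1:nLevels) {
    v <- p[i, j]
    asm <- asm + v^2
    contrast <- contrast + v * ((i - 1) - (j - 1))^2
    corrNum <- corrNum + (i - 1) * (j - 1) * v
    variance <- variance + ((i - 1) * (j - 1) - muX * muY) * v
    if (v > 0) entropy <- entropy - v * log(v, base = logBase)
  }
  correlation <- if (sX * sY > 0) (corrNum - muX * muY) / (sX * sY) else 0
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, entropy = entropy)
}

# Closed-form weighted orthogonal-Procrustes oracle for a 2D rigid fit:
# angle from the atan2 of the weighted cross/dot sums of centered points.
procrustesOracle <- function(src, dst, weights = NULL, center = c(0, 0)) {
  n <- nrow(src)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  sBar <- colSums(src * w); dBar <- colSums(dst * w)
  S <- sweep(src, 2, sBar); D <- sweep(dst, 2, dBar)
  num <- sum(w * (S[, 1] * D[, 2] - S[, 2] * D[, 1]))
  den <- sum(w * (S[, 1] * D[, 1] + S[, 2] * D[, 2]))
  a <- atan2(num, den)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t0 <- dBar - as.numeric(R %*% sBar)
  tt <- as.numeric(R %*% center) + t0 - center
  list(tx = tt[1], ty = tt[2], angle = a * 180 / pi)
}

# Default brain phantom used across tests.
defaultPhantom <- function(seed = 7) makeBrainPhantom(phantomSpec(seed = seed))

cliPath <- function() system.file("cli", "neurosegreg.R",
                                  package = "neuroSegReg")

runCLI <- function(...) {
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cliPath(), ...), stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", libs))
  invisible(out)
}
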