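# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(expr)
}

# Derive a child seed below 2^31 from a parent seed and a stream tag.
childSeed <- function(seed, tag) {
  as.integer((as.double(seed) * 48271 + tag * 1009 + 12345) %% 2147483647)
}

stopIfNotMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("'%s' has a non-finite pixel at (row %d, col %d) [0-based: (%d, %d)]",
                 name, bad[1], bad[2], bad[1] - 1L, bad[2] - 1L), call. = FALSE)
  }
  invisible(TRUE)
}

# Bilinear sampling at fractional 0-based (row, col) coordinates with
# constant padding outside the grid.
bilinearSample <- function(img, rows0, cols0, pad = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows0); c0 <- floor(cols0)
  fr <- rows0 - r0; fc <- cols0 - c0
  pick <- function(rr, cc) {
    ok <- rr >= 0 & rr <= h - 1 & cc >= 0 & cc <= w - 1
    out <- rep(pad, length(rr))
    if (any(ok)) out[ok] <- img[cbind(rr[ok] + 1, cc[ok] + 1)]
    out
  }
  v00 <- pick(r0, c0)
  v01 <- pick(r0, c0 + 1)
  v10 <- pick(r0 + 1, c0)
  v11 <- pick(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Reflection-pad a matrix by k pixels on every side.
padReflect <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  if (k >= h || k >= w)
    stop("padding exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(k) + 1), seq_len(h), h - seq_len(k))
  ci <- c(rev(seq_len(k) + 1), seq_len(w), w - seq_len(k))
  img[ri, ci, drop = FALSE]
}

# Mean over a centered (2k+1)x(2k+1) window at every pixel, reflection padding.
windowMean <- function(img, window) {
  k <- (window - 1L) %/% 2L
  p <- padReflect(img, k)
  cs <- rbind(0, apply(p, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  h <- nrow(img); w <- ncol(img)
  r2 <- (1:h) + 2L * k; c2 <- (1:w) + 2L * k
  r1 <- (1:h) - 1L;     c1 <- (1:w) - 1L
  s <- cs[r2 + 1, c2 + 1] - cs[r1 + 1, c2 + 1] - cs[r2 + 1, c1 + 1] + cs[r1 + 1, c1 + 1]
  s / (window * window)
}
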