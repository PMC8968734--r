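#' Texture extraction configuration
#'
#' Settings for sliding-window gray-level co-occurrence (GLCM) texture
#' extraction: window size (default the 7 x 7 used for brain MR slices),
#' inter-pixel distance `d = 1`, orientations {0, 45, 90, 135} degrees, and
#' quantization to `n_levels` gray levels (default 16; co-occurrence matrices
#' at full 8-bit depth are nearly empty in 7 x 7 windows).
#'
#' Orientation follows the Haralick offset convention for `d = 1`:
#' 0 degrees = (0, +1), 45 = (-1, +1), 90 = (-1, 0), 135 = (-1, -1) in
#' (row, col) steps, i.e. `(x, y) = (m, n) + (d cos(theta), d sin(theta))`
#' on the display axes.
#'
#' @param window odd window edge length >= 3 (default 7).
#' @param d inter-pixel distance (default 1).
#' @param thetas orientations in degrees, a subset of c(0, 45, 90, 135).
#' @param n_levels gray-level count after quantization (default 16).
#' @param log_base entropy logarithm base (default 2; entropies in bits).
#' @param symmetric accumulate the reverse pair direction too (default FALSE;
#'   the defining offset equation is one-directional).
#' @return a validated list of class `"TextureConfig"`.
#' @export
textureConfig <- function(window = 7L, d = 1L, thetas = c(0, 45, 90, 135),
                          n_levels = 16L, log_base = 2, symmetric = FALSE) {
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3", call. = FALSE)
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  if (!all(thetas %in% c(0, 45, 90, 135)))
    stop("thetas must be a subset of {0, 45, 90, 135}", call. = FALSE)
  structure(list(window = as.integer(window), d = as.integer(d),
                 thetas = as.numeric(thetas), n_levels = as.integer(n_levels),
                 log_base = log_base, symmetric = isTRUE(symmetric)),
            class = "TextureConfig")
}

#' Quantize an image to integer gray levels
#'
#' Uniform binning of `[min, max]` into `n_levels` bins, returning levels
#' 0..n_levels-1; a constant image maps to level 0.
#'
#' @param image numeric matrix.
#' @param n_levels number of gray levels (>= 2).
#' @return an integer matrix of levels.
#' @export
quantizeImage <- function(image, n_levels = 16L) {
  stopIfNotMatrix(image)
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  rng <- range(image)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * n_levels)
  q[q >= n_levels] <- n_levels - 1
  matrix(as.integer(q), nrow(image), ncol(image))
}

# (drow, dcol) pixel offset for a Haralick orientation at distance d.
thetaOffset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts co-occurrences of level pairs (i at (m, n), j at
#' (m, n) + offset(d, theta)) over all in-bounds pixel pairs of an integer
#' window, optionally accumulating the reverse direction, and normalizes the
#' counts to probabilities.
#'
#' @param window integer matrix of gray levels in 0..n_levels-1 (see
#'   [quantizeImage()]).
#' @param d inter-pixel distance.
#' @param theta orientation in degrees (0, 45, 90 or 135).
#' @param n_levels gray-level count (matrix dimension).
#' @param symmetric accumulate both pair directions.
#' @return a [GLCM-class].
#' @export
computeGLCM <- function(window, d = 1L, theta = 0, n_levels = 16L,
                        symmetric = FALSE) {
  if (!is.matrix(window)) stop("window must be a matrix", call. = FALSE)
  lv <- matrix(as.integer(window), nrow(window), ncol(window))
  if (any(lv < 0 | lv >= n_levels))
    stop("window levels must lie in 0..n_levels-1", call. = FALSE)
  off <- thetaOffset(theta, as.integer(d))
  h <- nrow(lv); w <- ncol(lv)
  rs <- seq_len(h); cs <- seq_len(w)
  rOk <- rs[rs + off[1] >= 1 & rs + off[1] <= h]
  cOk <- cs[cs + off[2] >= 1 & cs + off[2] <= w]
  if (length(rOk) == 0 || length(cOk) == 0)
    stop("empty GLCM: window has no valid pixel pair for this offset",
         call. = FALSE)
  i <- lv[rOk, cOk, drop = FALSE]
  j <- lv[rOk + off[1], cOk + off[2], drop = FALSE]
  counts <- matrix(0, n_levels, n_levels)
  tab <- table(factor(i, levels = 0:(n_levels - 1)),
               factor(j, levels = 0:(n_levels - 1)))
  counts <- counts + as.numeric(tab)
  if (symmetric) counts <- counts + t(matrix(as.numeric(tab), n_levels))
  counts <- matrix(counts, n_levels, n_levels)
  p <- counts / sum(counts)
  lev <- 0:(n_levels - 1)
  px <- rowSums(p); py <- colSums(p)
  muX <- sum(lev * px); muY <- sum(lev * py)
  new("GLCM", p = p, px = px, py = py, muX = muX, muY = muY,
      sigmaX = sqrt(sum((lev - muX)^2 * px)),
      sigmaY = sqrt(sum((lev - muY)^2 * py)),
      nLevels = as.integer(n_levels), d = as.integer(d),
      theta = as.numeric(theta), symmetric = isTRUE(symmetric))
}

#' The five GLCM texture statistics
#'
#' Computes, from a normalized co-occurrence matrix p(i, j) with 0-based
#' gray levels i, j:
#' \itemize{
#'   \item ASM (angular second moment) `sum p(i,j)^2`;
#'   \item Contrast `sum p(i,j) (i - j)^2`;
#'   \item Correlation `(sum i j p(i,j) - muX muY) / (sigmaX sigmaY)`,
#'     defined as 0 when `sigmaX * sigmaY = 0` (flat windows);
#'   \item Variance `sum (i j - muX muY) p(i,j)` — note this is the printed
#'     covariance-like form (identical to the correlation numerator), not the
#'     conventional GLCM variance `sum (i - mu)^2 p`; it is kept verbatim for
#'     fidelity to the defining statistic set;
#'   \item Entropy `-sum p log p` with `0 log 0 := 0`, base `log_base`.
#' }
#'
#' @param glcm a [GLCM-class] (normalized).
#' @param log_base entropy logarithm base (default 2).
#' @return named numeric: `asm`, `contrast`, `correlation`, `variance`,
#'   `entropy`.
#' @export
textureFeatures <- function(glcm, log_base = 2) {
  if (!is(glcm, "GLCM")) stop("glcm must be a GLCM object", call. = FALSE)
  if (abs(sum(glcm@p) - 1) > 1e-8)
    stop("glcm must be normalized", call. = FALSE)
  p <- glcm@p
  lev <- 0:(glcm@nLevels - 1)
  I <- matrix(lev, glcm@nLevels, glcm@nLevels)
  J <- t(I)
  asm <- sum(p^2)
  contrast <- sum(p * (I - J)^2)
  sxy <- glcm@sigmaX * glcm@sigmaY
  num <- sum(I * J * p) - glcm@muX * glcm@muY
  correlation <- if (sxy > 0) num / sxy else 0
  variance <- sum((I * J - glcm@muX * glcm@muY) * p)
  nz <- p[p > 0]
  entropy <- -sum(nz * log(nz)) / log(log_base)
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, entropy = entropy)
}

#' Per-pixel sliding-window texture feature map
#'
#' For every pixel (optionally restricted to a mask), quantizes the image
#' globally, extracts the centered `window x window` patch (reflection
#' padding at borders) and computes the five GLCM statistics per orientation,
#' yielding `5 * length(thetas)` feature planes (20 with the default four
#' orientations). Plane order: for each orientation in `config$thetas`, the
#' statistics asm, contrast, correlation, variance, entropy.
#'
#' @param image numeric matrix at least `window x window`.
#' @param config a [textureConfig()].
#' @param mask optional logical matrix; features are computed only where TRUE
#'   (other pixels are 0 in the output).
#' @return a numeric array `nrow x ncol x (5 * length(thetas))` with
#'   dimnames on the feature axis.
#' @export
featureMap <- function(image, config = textureConfig(), mask = NULL) {
  stopIfNotMatrix(image)
  k <- (config$window - 1L) %/% 2L
  if (nrow(image) < config$window || ncol(image) < config$window)
    stop("image smaller than the texture window", call. = FALSE)
  q <- quantizeImage(image, config$n_levels)
  qp <- padReflect(q, k)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  offs <- vapply(config$thetas, thetaOffset, integer(2), d = config$d)
  feats <- texture_map_cpp(qp, nrow(image), ncol(image), config$window,
                           offs, config$n_levels, config$log_base,
                           config$symmetric, mask)
  statNames <- c("asm", "contrast", "correlation", "variance", "entropy")
  dimnames(feats) <- list(NULL, NULL,
    as.vector(t(outer(config$thetas, statNames,
                      function(t, s) sprintf("%s_t%g", s, t)))))
  feats
}
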