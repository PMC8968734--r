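#' Chan-Vese evolution parameters
#'
#' Parameters of the two-phase Chan-Vese fitting energy
#' `alpha * Length(C) + beta * Area(inside(C)) +
#'  gamma1 * sum_inside (u - g0)^2 + gamma2 * sum_outside (u - g1)^2`
#' and of its level-set gradient descent.
#'
#' @param alpha length-term weight (default 0.2).
#' @param beta area-term weight (default 0; standard two-phase practice).
#' @param gamma1,gamma2 inside / outside fit weights (defaults 0.3 and 0.7).
#' @param time_step evolution step size.
#' @param heaviside_eps width of the smoothed Heaviside
#'   `H_eps(phi) = 1/2 (1 + (2/pi) atan(phi/eps))`.
#' @param max_iters iteration cap (default 500).
#' @param stop_tol relative energy-change tolerance over a 5-iteration window
#'   (default 1e-5).
#' @param reinit_every rebuild the level set as a signed distance every this
#'   many iterations (0 = never; default).
#' @return a validated list of class `"CVParams"`.
#' @export
cvParams <- function(alpha = 0.2, beta = 0, gamma1 = 0.3, gamma2 = 0.7,
                     time_step = 1, heaviside_eps = 1, max_iters = 500L,
                     stop_tol = 1e-5, reinit_every = 10L) {
  if (any(c(alpha, beta, gamma1, gamma2) < 0))
    stop("alpha, beta, gamma1, gamma2 must be >= 0", call. = FALSE)
  if (gamma1 + gamma2 <= 0) stop("gamma1 + gamma2 must be > 0", call. = FALSE)
  if (time_step <= 0) stop("time_step must be > 0", call. = FALSE)
  if (max_iters < 1) stop("max_iters must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma1 = gamma1,
                 gamma2 = gamma2, time_step = time_step,
                 heaviside_eps = heaviside_eps,
                 max_iters = as.integer(max_iters), stop_tol = stop_tol,
                 reinit_every = as.integer(reinit_every)),
            class = "CVParams")
}

#' Region means inside and outside a contour
#'
#' @param image numeric matrix.
#' @param inside_mask logical matrix of the same dimensions.
#' @return list with `g0` (mean inside), `g1` (mean outside) and logical
#'   flags `g0_defined`, `g1_defined`; an empty region yields `NA` with its
#'   flag `FALSE` rather than a number.
#' @export
regionMeans <- function(image, inside_mask) {
  stopIfNotMatrix(image)
  if (!all(dim(image) == dim(inside_mask)))
    stop("mask must match image dimensions", call. = FALSE)
  nIn <- sum(inside_mask)
  nOut <- length(inside_mask) - nIn
  list(g0 = if (nIn > 0) mean(image[inside_mask]) else NA_real_,
       g1 = if (nOut > 0) mean(image[!inside_mask]) else NA_real_,
       g0_defined = nIn > 0, g1_defined = nOut > 0)
}

#' Region fitting energy
#'
#' `gamma1 * sum_inside (u - g0)^2 + gamma2 * sum_outside (u - g1)^2`; an
#' empty region contributes 0.
#'
#' @inheritParams regionMeans
#' @param gamma1,gamma2 fit weights.
#' @return the scalar fitting energy.
#' @export
fitEnergy <- function(image, inside_mask, gamma1 = 0.3, gamma2 = 0.7) {
  m <- regionMeans(image, inside_mask)
  eIn <- if (m$g0_defined) sum((image[inside_mask] - m$g0)^2) else 0
  eOut <- if (m$g1_defined) sum((image[!inside_mask] - m$g1)^2) else 0
  gamma1 * eIn + gamma2 * eOut
}

# Contour length as the count of 4-neighbor inside/outside transitions,
# treating pixels beyond the image border as outside (so an isolated pixel
# has length 4).
maskPerimeter <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
}

#' Total Chan-Vese energy of a mask
#'
#' `alpha * Length(C) + beta * Area(inside) + fitEnergy(...)`, where the
#' length is the 4-neighbor boundary transition count and the area the inside
#' pixel count.
#'
#' @inheritParams regionMeans
#' @param params a [cvParams()] list.
#' @return the scalar total energy.
#' @export
totalEnergy <- function(image, inside_mask, params = cvParams()) {
  params$alpha * maskPerimeter(inside_mask) +
    params$beta * sum(inside_mask) +
    fitEnergy(image, inside_mask, params$gamma1, params$gamma2)
}

curvature <- function(phi) {
  h <- nrow(phi); w <- ncol(phi)
  ext <- function(p) p[c(1, 1:h, h), c(1, 1:w, w)]
  p <- ext(phi)
  ri <- 2:(h + 1); ci <- 2:(w + 1)
  px <- (p[ri, ci + 1] - p[ri, ci - 1]) / 2
  py <- (p[ri + 1, ci] - p[ri - 1, ci]) / 2
  pxx <- p[ri, ci + 1] - 2 * p[ri, ci] + p[ri, ci - 1]
  pyy <- p[ri + 1, ci] - 2 * p[ri, ci] + p[ri - 1, ci]
  pxy <- (p[ri + 1, ci + 1] - p[ri + 1, ci - 1] -
          p[ri - 1, ci + 1] + p[ri - 1, ci - 1]) / 4
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
    ((px^2 + py^2)^1.5 + 1e-8)
}

# Cheap signed distance rebuild: two-pass chamfer distance to the mask
# boundary on each side.
signedDistance <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  chamfer <- function(inside) {
    d <- matrix(ifelse(inside, Inf, 0), h, w)
    for (r in 1:h) for (c in 1:w) {
      if (d[r, c] > 0) {
        v <- d[r, c]
        if (r > 1) v <- min(v, d[r - 1, c] + 1)
        if (c > 1) v <- min(v, d[r, c - 1] + 1)
        if (r > 1 && c > 1) v <- min(v, d[r - 1, c - 1] + 1.4)
        d[r, c] <- v
      }
    }
    for (r in h:1) for (c in w:1) {
      v <- d[r, c]
      if (r < h) v <- min(v, d[r + 1, c] + 1)
      if (c < w) v <- min(v, d[r, c + 1] + 1)
      if (r < h && c < w) v <- min(v, d[r + 1, c + 1] + 1.4)
      d[r, c] <- v
    }
    d
  }
  chamfer(mask) - chamfer(!mask)
}

defaultInit <- function(image, kind = c("circle", "checkerboard")) {
  kind <- match.arg(kind)
  h <- nrow(image); w <- ncol(image)
  if (kind == "circle") {
    ctr <- gridCenter(image)
    rr <- matrix(rep(0:(h - 1), w), h, w) - ctr[1]
    cc <- matrix(rep(0:(w - 1), each = h), h, w) - ctr[2]
    min(h, w) / 3 - sqrt(rr^2 + cc^2)
  } else {
    rr <- matrix(rep(0:(h - 1), w), h, w)
    cc <- matrix(rep(0:(w - 1), each = h), h, w)
    sin(pi * rr / 5) * sin(pi * cc / 5)
  }
}

#' Two-phase Chan-Vese segmentation by level-set evolution
#'
#' Explicit gradient descent on the two-phase fitting energy with a smoothed
#' Heaviside/delta of width `heaviside_eps`. Each iteration updates the level
#' set along `delta_eps(phi) * (alpha * curvature - beta
#' - gamma1 (u - g0)^2 + gamma2 (u - g1)^2)`, the step normalized so
#' `time_step` is in level-set units (approximately pixels near the
#' interface); the level set is rebuilt as a signed distance every
#' `reinit_every` iterations, which keeps the interface advancing at a
#' consistent speed. Iteration stops when the relative change of the total
#' energy ([totalEnergy()], recorded per iteration in `energyTrace`) over a
#' 5-iteration window drops below `stop_tol`, or after `max_iters`
#' iterations.
#'
#' @param image numeric matrix with finite values.
#' @param params a [cvParams()] list.
#' @param init optional initialization: a logical mask, a numeric level-set
#'   field, or one of `"circle"` (default: centered circle of radius
#'   `min(H, W)/3`) / `"checkerboard"`.
#' @return a [CVResult-class].
#' @export
segmentCV <- function(image, params = cvParams(), init = "circle") {
  stopIfNotMatrix(image)
  phi <- if (is.character(init)) defaultInit(image, init)
         else if (is.logical(init)) signedDistance(init)
         else { stopifnot(all(dim(init) == dim(image))); init }
  u <- image
  eps <- params$heaviside_eps
  trace <- totalEnergy(u, phi > 0, params)
  if (!is.finite(trace))
    stop("Chan-Vese numerical failure at iteration 0: non-finite energy",
         call. = FALSE)
  it <- 0L
  for (it in seq_len(params$max_iters)) {
    mask <- phi > 0
    m <- regionMeans(u, mask)
    g0 <- if (m$g0_defined) m$g0 else 0
    g1 <- if (m$g1_defined) m$g1 else 0
    force_ <- params$alpha * curvature(phi) - params$beta -
      params$gamma1 * (u - g0)^2 + params$gamma2 * (u - g1)^2
    delta <- eps / (pi * (eps^2 + phi^2))
    # normalize the descent direction so time_step is in level-set units
    g <- delta * force_
    gmax <- max(abs(g))
    if (gmax > 0) g <- g / gmax
    phi <- phi + params$time_step * g
    if (params$reinit_every > 0 && it %% params$reinit_every == 0)
      phi <- signedDistance(phi > 0)
    e <- totalEnergy(u, phi > 0, params)
    if (!is.finite(e))
      stop(sprintf("Chan-Vese numerical failure at iteration %d", it),
           call. = FALSE)
    trace <- c(trace, e)
    n <- length(trace)
    if (n >= 6) {
      ref <- trace[n - 5]
      if (abs(trace[n] - ref) < params$stop_tol * max(abs(ref), 1e-12)) break
    }
  }
  mask <- phi > 0
  m <- regionMeans(u, mask)
  new("CVResult", insideMask = mask,
      g0 = if (m$g0_defined) m$g0 else NA_real_,
      g1 = if (m$g1_defined) m$g1 else NA_real_,
      energyTrace = trace, iterationsRun = it)
}
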