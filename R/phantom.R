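#' Specify a synthetic brain phantom
#'
#' Bundles the parameters of the seeded brain-like phantom generator:
#' piecewise-constant nested tissue regions (background, CSF, gray matter,
#' white matter, T1-like intensity ordering), a smooth multiplicative bias
#' field ("gray-level non-uniformity") and additive Gaussian noise.
#'
#' Tissue means must be strictly increasing in the order background < csf <
#' gm < wm so the classes are separable in the noiseless limit. The noise SD
#' is `noise_fraction * max(tissue_means)`; the bias field ranges over
#' `[1 - bias_fraction/2, 1 + bias_fraction/2]` with mean 1.
#'
#' @param height,width phantom dimensions in pixels.
#' @param tissue_means named numeric: intensities (in `[0, 1]`) for
#'   `background`, `csf`, `gm`, `wm`.
#' @param noise_fraction additive noise level (default 0.02, i.e. "2% noise").
#' @param bias_fraction bias-field amplitude (default 0.30, i.e. "30%
#'   non-uniformity").
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return a validated list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(height = 96, width = 96,
                        tissue_means = c(background = 0.05, csf = 0.40,
                                         gm = 0.62, wm = 0.84),
                        noise_fraction = 0.02, bias_fraction = 0.30,
                        seed = 1L) {
  if (height <= 0 || width <= 0)
    stop("invalid phantom spec: dimensions must be positive", call. = FALSE)
  need <- c("background", "csf", "gm", "wm")
  if (!all(need %in% names(tissue_means)))
    stop("tissue_means must name background, csf, gm, wm", call. = FALSE)
  tm <- as.numeric(tissue_means[need])
  if (any(diff(tm) <= 0))
    stop("tissue means must be strictly ordered: background < csf < gm < wm",
         call. = FALSE)
  if (noise_fraction < 0 || bias_fraction < 0)
    stop("noise_fraction and bias_fraction must be >= 0", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 tissue_means = stats::setNames(tm, need),
                 noise_fraction = noise_fraction,
                 bias_fraction = bias_fraction, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Smooth multiplicative bias field
#'
#' A sum of three seeded low-frequency cosine components, centered and
#' rescaled so the field lies in `[1 - bias_fraction/2, 1 + bias_fraction/2]`
#' with mean exactly 1. `bias_fraction = 0` returns a field of ones.
#'
#' @param height,width field dimensions.
#' @param bias_fraction peak-to-peak amplitude as a fraction of 1.
#' @param seed integer seed.
#' @return a height x width matrix.
#' @export
biasField <- function(height, width, bias_fraction, seed) {
  if (bias_fraction < 0) stop("bias_fraction must be >= 0", call. = FALSE)
  if (bias_fraction == 0) return(matrix(1, height, width))
  withSeed(seed, {
    r <- matrix(rep(seq_len(height) / height, width), height, width)
    c2 <- matrix(rep(seq_len(width) / width, each = height), height, width)
    f <- matrix(0, height, width)
    for (k in 1:3) {
      amp <- runif(1, 0.5, 1)
      fr <- runif(1, 0.4, 1.2)
      fc <- runif(1, 0.4, 1.2)
      ph <- runif(1, 0, 2 * pi)
      f <- f + amp * cos(2 * pi * (fr * r + fc * c2) + ph)
    }
    f <- f - mean(f)
    f <- f / max(abs(f))
    1 + (bias_fraction / 2) * f
  })
}

#' Multiply an image by a seeded smooth bias field
#'
#' @param image numeric matrix.
#' @inheritParams biasField
#' @return the image times the field generated by [biasField()];
#'   `bias_fraction = 0` returns the input unchanged.
#' @export
applyBiasField <- function(image, bias_fraction, seed) {
  stopIfNotMatrix(image)
  if (bias_fraction == 0) return(image)
  image * biasField(nrow(image), ncol(image), bias_fraction, seed)
}

# Normalized elliptical radius with seeded low-order angular perturbation;
# one perturbation per boundary keeps boundaries irregular but smooth.
phantomGeometry <- function(height, width) {
  cy <- (height - 1) / 2; cx <- (width - 1) / 2
  ry <- 0.40 * height; rx <- 0.36 * width
  rr <- matrix(rep(0:(height - 1), width), height, width) - cy
  cc <- matrix(rep(0:(width - 1), each = height), height, width) - cx
  list(rho = sqrt((rr / ry)^2 + (cc / rx)^2), theta = atan2(rr, cc))
}

#' Generate a synthetic brain phantom
#'
#' Builds a 2D brain-like slice: nested elliptical tissue regions (background
#' outside, then CSF, gray matter and white matter inward) with seeded
#' sinusoidal boundary perturbation, intensities
#' `tissue_mean * bias_field + noise`, and a label grid recording the
#' generating tissue of every pixel. Identical specs give bit-identical
#' output.
#'
#' @param spec a [phantomSpec()].
#' @return a [LabeledImage-class].
#' @export
makeBrainPhantom <- function(spec) {
  if (!inherits(spec, "PhantomSpec")) spec <- do.call(phantomSpec, spec)
  h <- spec$height; w <- spec$width
  geo <- phantomGeometry(h, w)
  bounds <- c(brain = 1.00, gmOuter = 0.88, wmOuter = 0.62)
  res <- withSeed(spec$seed, {
    pert <- lapply(1:3, function(b) {
      amp <- runif(3, 0, 0.03); ph <- runif(3, 0, 2 * pi)
      p <- matrix(0, h, w)
      for (k in 1:3) p <- p + amp[k] * sin((k + 1) * geo$theta + ph[k])
      p
    })
    bseed <- sample.int(2147483646L, 1)
    noise <- if (spec$noise_fraction > 0)
      matrix(rnorm(h * w, 0, spec$noise_fraction * max(spec$tissue_means)),
             h, w)
    else matrix(0, h, w)
    list(pert = pert, bseed = bseed, noise = noise)
  })
  labels <- matrix(0L, h, w)
  labels[geo$rho <= bounds["brain"] * (1 + res$pert[[1]])] <- 1L   # csf shell
  labels[geo$rho <= bounds["gmOuter"] * (1 + res$pert[[2]])] <- 2L # gm ring
  labels[geo$rho <= bounds["wmOuter"] * (1 + res$pert[[3]])] <- 3L # wm core
  means <- spec$tissue_means[labels + 1L]
  inten <- matrix(means, h, w)
  if (spec$bias_fraction > 0)
    inten <- inten * biasField(h, w, spec$bias_fraction, res$bseed)
  inten <- inten + res$noise
  new("LabeledImage", intensity = inten, labels = labels)
}

#' Generate a rigid-motion time series from a base image
#'
#' Frame 0 is the base image; frame k (k >= 1) is the base resampled under a
#' seeded rigid transform with `|tx|, |ty| <= max_shift_px` and
#' `|angle| <= max_rot_deg` (uniform draws), plus per-frame additive Gaussian
#' noise with SD `noise_fraction * max(base)`. The generating transforms are
#' stored as ground truth for parameter-recovery experiments.
#'
#' @param base a [LabeledImage-class] or intensity matrix.
#' @param n_frames number of frames (>= 1).
#' @param max_shift_px,max_rot_deg motion bounds.
#' @param noise_fraction per-frame noise level.
#' @param seed integer seed.
#' @param pad padding intensity used when resampling (defaults to the
#'   background mean estimated from the base's border pixels).
#' @return a [MotionSeries-class].
#' @export
makeMotionSeries <- function(base, n_frames = 20, max_shift_px = 3,
                             max_rot_deg = 2, noise_fraction = 0,
                             seed = 1L, pad = NULL) {
  if (is(base, "LabeledImage")) base <- intensity(base)
  stopIfNotMatrix(base)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  ctr <- gridCenter(base)
  if (is.null(pad))
    pad <- mean(c(base[1, ], base[nrow(base), ], base[, 1],
                  base[, ncol(base)]))
  nsd <- noise_fraction * max(base)
  withSeed(seed, {
    tfs <- vector("list", n_frames)
    frames <- vector("list", n_frames)
    tfs[[1]] <- rigidTransform(0, 0, 0, ctr)
    frames[[1]] <- base
    if (n_frames > 1) for (k in 2:n_frames) {
      tfs[[k]] <- rigidTransform(runif(1, -max_shift_px, max_shift_px),
                                 runif(1, -max_shift_px, max_shift_px),
                                 runif(1, -max_rot_deg, max_rot_deg), ctr)
      frames[[k]] <- applyTransform(base, tfs[[k]], pad = pad)
    }
    if (nsd > 0)
      frames <- lapply(frames, function(f)
        f + matrix(rnorm(length(f), 0, nsd), nrow(f), ncol(f)))
    new("MotionSeries", frames = frames, truthTransforms = tfs,
        seed = as.integer(seed))
  })
}
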