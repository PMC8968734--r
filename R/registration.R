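#' Registration parameters
#'
#' Parameters of the brain functional time-series registration pipeline:
#' fuzzy-pixel mode-seeking clustering, block matching with recursive
#' similarity accumulation, boosted match-reliability weighting and rigid
#' transform recovery.
#'
#' @param m_threshold merge threshold for cluster centers and clip on the
#'   mode-seeking shift, pixels (default 5).
#' @param tau convergence threshold on the shift magnitude (default 1e-3).
#' @param neighborhood_radius radius of the region around the shifted point
#'   used for density means and cluster marking, pixels (default 5).
#' @param block sub-block edge length for block matching (default 4).
#' @param search_radius block-match search extent, pixels (default 5).
#' @param phi_coeff recursive-similarity coefficient in (0, 1) (default 0.5).
#' @param n_iters iteration cap of the learning stage (default 100).
#' @param iter_step adaptive step size; boosting rounds are
#'   `n_iters / iter_step` (default 10, hence 10 rounds).
#' @param descent_rate damping factor applied to the residual transform in
#'   each refinement round (default 0.45).
#' @param edge_quant_coeff NCC acceptance floor for a block to enter the
#'   match set (default 0.62).
#' @param seed integer seed for all random choices (point selection order,
#'   diagnostic pixel sampling).
#' @return a validated list of class `"RegParams"`.
#' @export
regParams <- function(m_threshold = 5, tau = 1e-3, neighborhood_radius = 5,
                      block = 4L, search_radius = 5L, phi_coeff = 0.5,
                      n_iters = 100L, iter_step = 10L, descent_rate = 0.45,
                      edge_quant_coeff = 0.62, seed = 1L) {
  if (m_threshold <= 0 || tau <= 0) stop("m_threshold and tau must be > 0",
                                         call. = FALSE)
  if (block < 2) stop("block must be >= 2", call. = FALSE)
  if (search_radius < 1) stop("search_radius must be >= 1", call. = FALSE)
  if (phi_coeff <= 0 || phi_coeff >= 1)
    stop("phi_coeff must be in (0, 1)", call. = FALSE)
  structure(list(m_threshold = m_threshold, tau = tau,
                 neighborhood_radius = neighborhood_radius,
                 block = as.integer(block),
                 search_radius = as.integer(search_radius),
                 phi_coeff = phi_coeff, n_iters = as.integer(n_iters),
                 iter_step = as.integer(iter_step),
                 descent_rate = descent_rate,
                 edge_quant_coeff = edge_quant_coeff,
                 seed = as.integer(seed)),
            class = "RegParams")
}

#' Fuzzy-pixel mode-seeking clustering
#'
#' Seeded mode-seeking over 2D points: a randomly chosen unmarked point h is
#' repeatedly shifted toward the local density mean within
#' `neighborhood_radius` (shift clipped to magnitude `m_threshold`) until the
#' shift magnitude falls below `tau`; all points within the neighborhood of
#' the converged center are marked into that cluster. A new center closer
#' than `m_threshold` to an existing one is merged into it. Terminates when
#' every point is marked. The random point-selection stream operates on the
#' canonical (sorted-coordinate) point order, so clustering is stable under
#' permutation of the input.
#'
#' @param points n x 2 numeric matrix of (row, col) coordinates.
#' @param params a [regParams()].
#' @return a [ClusterSet-class].
#' @export
clusterFuzzyPixels <- function(points, params = regParams()) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n < 1) stop("at least one point required", call. = FALSE)
  canon <- order(points[, 1], points[, 2])
  marked <- rep(FALSE, n)
  membership <- rep(NA_integer_, n)
  centers <- matrix(numeric(0), 0, 2)
  trajectories <- list()
  withSeed(params$seed, {
    while (!all(marked)) {
      un <- canon[!marked[canon]]
      h <- points[if (length(un) == 1) un else un[sample.int(length(un), 1)], ]
      traj <- matrix(h, 1, 2)
      for (iter in seq_len(200L)) {
        d2 <- (points[, 1] - h[1])^2 + (points[, 2] - h[2])^2
        nb <- d2 <= params$neighborhood_radius^2
        tgt <- colMeans(points[nb, , drop = FALSE])
        shift <- tgt - h
        sm <- sqrt(sum(shift^2))
        if (sm > params$m_threshold)
          shift <- shift * params$m_threshold / sm
        h <- h + shift
        traj <- rbind(traj, h)
        if (sqrt(sum(shift^2)) < params$tau) break
      }
      trajectories[[length(trajectories) + 1]] <- traj
      # merge with an existing center or open a new cluster
      ci <- NA_integer_
      if (nrow(centers) > 0) {
        dc <- sqrt((centers[, 1] - h[1])^2 + (centers[, 2] - h[2])^2)
        if (min(dc) < params$m_threshold) ci <- which.min(dc)
      }
      if (is.na(ci)) {
        centers <- rbind(centers, h)
        ci <- nrow(centers)
      }
      d2 <- (points[, 1] - h[1])^2 + (points[, 2] - h[2])^2
      take <- !marked & d2 <= params$neighborhood_radius^2
      if (!any(take)) { # guarantee progress: claim the nearest unmarked point
        take <- rep(FALSE, n)
        take[which(!marked)[which.min(d2[!marked])]] <- TRUE
      }
      membership[take] <- ci
      marked <- marked | take
    }
  })
  rownames(centers) <- NULL
  new("ClusterSet", centers = centers, memberships = membership,
      fuzzySet = trajectories, mThreshold = params$m_threshold)
}

#' Recursive multi-level similarity accumulation
#'
#' `B(0) = d(0)`, `B(k) = phi * B(k-1) + d(k)`: a leaky accumulator of
#' per-level decomposition scores. For increments bounded by `c` the
#' accumulated values are bounded by `c / (1 - phi)`.
#'
#' @param increments numeric vector of per-level scores d(k).
#' @param phi_coeff accumulation coefficient in (0, 1).
#' @return a [SimilarityTrace-class].
#' @export
recursiveSimilarity <- function(increments, phi_coeff = 0.5) {
  if (length(increments) < 1)
    stop("increments must be non-empty", call. = FALSE)
  values <- numeric(length(increments))
  values[1] <- increments[1]
  if (length(increments) > 1)
    for (k in 2:length(increments))
      values[k] <- phi_coeff * values[k - 1] + increments[k]
  new("SimilarityTrace", values = values,
      increments = as.numeric(increments), phiCoeff = phi_coeff)
}

# Parabolic sub-pixel refinement from a 3-point NCC section. A perfect peak
# (NCC = 1) is already exact; refining it would only add parabola bias.
subpixelOffset <- function(nm1, n0, np1) {
  if (n0 >= 1 - 1e-12) return(0)
  if (any(is.na(c(nm1, n0, np1)))) return(0)
  den <- nm1 - 2 * n0 + np1
  if (abs(den) < 1e-12) return(0)
  delta <- 0.5 * (nm1 - np1) / den
  max(-0.5, min(0.5, delta))
}

#' Block matching between two frames
#'
#' Tiles the reference into `block x block` sub-blocks and finds, for each,
#' the integer displacement within `search_radius` (around an optional
#' per-block initial displacement) maximizing normalized cross-correlation
#' against the moving frame, followed by parabolic sub-pixel refinement of
#' the NCC peak. Flat (zero-variance) reference blocks are flagged and
#' excluded. Each block's similarity is the recursive accumulation
#' ([recursiveSimilarity()]) of its NCC scores across the coarse-to-fine
#' levels seen so far (a single level here).
#'
#' @param ref,moving numeric matrices of equal size, at least
#'   `block + 2 * search_radius` in each dimension.
#' @param params a [regParams()].
#' @param init optional list with integer matrices `dr`, `dc` of per-block
#'   initial displacements.
#' @param subpixel apply parabolic refinement (default TRUE).
#' @return a data.frame of non-flat block matches: block center (`row`,
#'   `col`, 0-based), displacement (`dr`, `dc`), `ncc`, reference block
#'   variance `refVar`, and local displacement disagreement `disagree`;
#'   attribute `"similarity"` holds the per-block accumulated similarity.
#' @export
blockMatch <- function(ref, moving, params = regParams(), init = NULL,
                       subpixel = TRUE) {
  stopIfNotMatrix(ref); stopIfNotMatrix(moving)
  if (!all(dim(ref) == dim(moving)))
    stop("ref and moving must share dimensions", call. = FALSE)
  b <- params$block
  if (min(dim(ref)) < b + 2 * params$search_radius)
    stop("grids must be at least block + 2 * search_radius", call. = FALSE)
  nbr <- nrow(ref) %/% b; nbc <- ncol(ref) %/% b
  if (is.null(init))
    init <- list(dr = matrix(0L, nbr, nbc), dc = matrix(0L, nbr, nbc))
  bm <- block_match_cpp(ref, moving, b, params$search_radius,
                        init$dr, init$dc)
  dr <- bm$dr; dc <- bm$dc
  if (subpixel) {
    for (bc in seq_len(nbc)) for (br in seq_len(nbr)) {
      if (bm$flat[br, bc]) next
      dr[br, bc] <- dr[br, bc] +
        subpixelOffset(bm$patch[br, bc, 2], bm$patch[br, bc, 5],
                       bm$patch[br, bc, 8])
      dc[br, bc] <- dc[br, bc] +
        subpixelOffset(bm$patch[br, bc, 4], bm$patch[br, bc, 5],
                       bm$patch[br, bc, 6])
    }
  }
  keep <- !bm$flat
  ctrR <- (rep(seq_len(nbr), nbc) - 1) * b + (b - 1) / 2
  ctrC <- (rep(seq_len(nbc), each = nbr) - 1) * b + (b - 1) / 2
  out <- data.frame(row = ctrR[keep], col = ctrC[keep],
                    dr = dr[keep], dc = dc[keep],
                    ncc = bm$ncc[keep], refVar = bm$refVar[keep])
  if (nrow(out) > 0) {
    medR <- median(out$dr); medC <- median(out$dc)
    out$disagree <- sqrt((out$dr - medR)^2 + (out$dc - medC)^2)
    sim <- vapply(out$ncc, function(v)
      tail(recursiveSimilarity(v, params$phi_coeff)@values, 1), numeric(1))
    attr(out, "similarity") <- sim
  } else attr(out, "similarity") <- numeric(0)
  out
}

# One Adaboost decision stump on weighted data: threshold + polarity over a
# single descriptor column minimizing weighted error.
fitStump <- function(X, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    xs <- X[, j]
    cand <- unique(quantile(xs, probs = seq(0, 1, length.out = 16),
                            names = FALSE, type = 1))
    thr <- c(cand - 1e-12, max(xs) + 1)
    above <- outer(xs, thr, ">")            # n x nthr: pol = +1 predictions
    # weighted error of predicting +1 above / -1 below, per threshold
    errPos <- colSums(w * (above != (y > 0)))
    errNeg <- sum(w) - errPos               # opposite polarity
    jp <- which.min(errPos); jn <- which.min(errNeg)
    if (errPos[jp] < best$err)
      best <- list(err = errPos[jp], j = j, t = thr[jp], pol = 1)
    if (errNeg[jn] < best$err)
      best <- list(err = errNeg[jn], j = j, t = thr[jn], pol = -1)
  }
  best
}

predictStump <- function(st, X)
  ifelse(st$pol * (X[, st$j] - st$t) > 0, 1, -1)

#' Boosted match-reliability weighting
#'
#' Scores block matches by an Adaboost ensemble of decision stumps over the
#' match descriptors (NCC score, reference block variance, displacement
#' disagreement with the field median). In unsupervised mode, pseudo-labels
#' mark matches whose displacement lies within 1 px of the field median as
#' inliers. Returns one weight in `[0, 1]` per match (the ensemble score
#' mapped affinely from `[-1, 1]`); ensemble size is
#' `n_iters / iter_step` rounds.
#'
#' @param matches data.frame from [blockMatch()] (>= 10 rows).
#' @param params a [regParams()].
#' @param labels optional +/-1 vector overriding the pseudo-labels.
#' @return numeric vector of per-match weights in `[0, 1]`.
#' @export
boostMatchWeights <- function(matches, params = regParams(), labels = NULL) {
  n <- nrow(matches)
  if (n < 10) stop("at least 10 matches required", call. = FALSE)
  X <- as.matrix(matches[, c("ncc", "refVar", "disagree")])
  if (is.null(labels)) labels <- ifelse(matches$disagree <= 1, 1, -1)
  y <- as.numeric(labels)
  if (all(duplicated(X)[-1])) return(rep(0.5 + 0.5 * (y[1] > 0), n))
  rounds <- max(1L, params$n_iters %/% params$iter_step)
  if (length(unique(y)) == 1) return(rep(if (y[1] > 0) 1 else 0.5, n))
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(rounds)) {
    st <- fitStump(X, y, w)
    err <- max(min(st$err, 1 - 1e-10), 1e-10)
    if (err >= 0.5 && r > 1) break
    alpha <- 0.5 * log((1 - err) / err)
    pred <- predictStump(st, X)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
  }
  score <- rep(0, n)
  for (i in seq_along(stumps))
    score <- score + alphas[i] * predictStump(stumps[[i]], X)
  score <- score / sum(abs(alphas))
  (score + 1) / 2
}

#' Weighted rigid transform from point correspondences
#'
#' Weighted least-squares fit of a 2D rigid transform (rotation +
#' translation) mapping source points to destination points, via the SVD
#' solution of the weighted orthogonal-Procrustes problem, re-expressed about
#' `center`.
#'
#' @param src,dst n x 2 matrices of corresponding (row, col) points.
#' @param weights per-correspondence non-negative weights (default equal).
#' @param center 0-based (row, col) rotation center of the returned
#'   transform.
#' @return a [RigidTransform2D-class].
#' @export
estimateRigidTransform <- function(src, dst, weights = NULL,
                                   center = c(0, 0)) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  if (n < 2 || nrow(dst) != n)
    stop("need >= 2 corresponding points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(weights) <= 0) stop("total weight must be positive", call. = FALSE)
  w <- weights / sum(weights)
  sBar <- colSums(src * w); dBar <- colSums(dst * w)
  S <- sweep(src, 2, sBar); D <- sweep(dst, 2, dBar)
  if (sum(w * rowSums(S^2)) < 1e-12)
    stop("degenerate fit: weighted source points are coincident",
         call. = FALSE)
  H <- t(S * w) %*% D
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) {
    V <- sv$v; V[, 2] <- -V[, 2]
    R <- V %*% t(sv$u)
  }
  t0 <- dBar - as.numeric(R %*% sBar)
  angle <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  # re-express x' = R x + t0 as rotation about `center` plus translation
  tt <- as.numeric(R %*% center) + t0 - center
  rigidTransform(tt[1], tt[2], angle, center)
}

# Fit a rigid transform to a weighted match set; NULL if too few matches.
fitFromMatches <- function(matches, weights, center, nccFloor) {
  keep <- matches$ncc >= nccFloor & weights > 0
  if (sum(keep) < 3) keep <- weights > 0
  if (sum(keep) < 2) return(NULL)
  src <- cbind(matches$row, matches$col)[keep, , drop = FALSE]
  dst <- src + cbind(matches$dr, matches$dc)[keep, , drop = FALSE]
  estimateRigidTransform(src, dst, weights[keep], center)
}

scaleTransform <- function(tf, s)
  rigidTransform(tf@tx * s, tf@ty * s, tf@angle * s, tf@center)

transformMagnitude <- function(tf, radius = 50)
  sqrt(tf@tx^2 + tf@ty^2) + abs(tf@angle) * pi / 180 * radius

# Register one frame to the reference: coarse block match at doubled block
# size, then damped residual refinement rounds at the native block size.
registerFrame <- function(ref, frame, params, pad) {
  ctr <- gridCenter(ref)
  coarse <- regParams(block = 2L * params$block,
                      search_radius = params$search_radius,
                      phi_coeff = params$phi_coeff,
                      edge_quant_coeff = params$edge_quant_coeff,
                      n_iters = params$n_iters, iter_step = params$iter_step,
                      descent_rate = params$descent_rate, seed = params$seed)
  m <- blockMatch(ref, frame, coarse)
  simTrace <- list(mean(attr(m, "similarity")))
  wts <- if (nrow(m) >= 10) boostMatchWeights(m, params)
         else rep(1, nrow(m))
  tf <- fitFromMatches(m, wts, ctr, params$edge_quant_coeff)
  if (is.null(tf)) tf <- rigidTransform(0, 0, 0, ctr)
  rounds <- max(1L, params$n_iters %/% params$iter_step)
  fine <- regParams(block = params$block, search_radius = 2L,
                    phi_coeff = params$phi_coeff,
                    edge_quant_coeff = params$edge_quant_coeff,
                    n_iters = params$n_iters, iter_step = params$iter_step,
                    descent_rate = params$descent_rate, seed = params$seed)
  meanW <- if (length(wts)) mean(wts) else NA_real_
  nccMean <- if (nrow(m)) mean(m$ncc) else NA_real_
  for (r in seq_len(rounds)) {
    warped <- applyTransform(frame, invertTransform(tf), pad = pad)
    mr <- blockMatch(ref, warped, fine)
    if (nrow(mr) < 2) break
    wr <- if (nrow(mr) >= 10) boostMatchWeights(mr, params)
          else rep(1, nrow(mr))
    resid <- fitFromMatches(mr, wr, ctr, params$edge_quant_coeff)
    if (is.null(resid)) break
    simTrace[[length(simTrace) + 1]] <- mean(attr(mr, "similarity"))
    step <- scaleTransform(resid, params$descent_rate)
    tf <- composeTransforms(tf, step)
    meanW <- mean(wr); nccMean <- mean(mr$ncc)
    if (transformMagnitude(resid, max(dim(ref)) / 2) < 1e-4) break
  }
  sims <- recursiveSimilarity(unlist(simTrace), params$phi_coeff)
  list(transform = tf, meanWeight = meanW, meanNCC = nccMean,
       similarity = sims)
}

#' Convert a displacement to the diagnostic polar output
#'
#' Verbatim spherical conversion of a (zero-padded if 2D) displacement
#' vector: `x = T sin(gamma) cos(phi)`, `y = T sin(gamma) sin(phi)`,
#' `z = T cos(gamma)`, with T the magnitude, gamma the inclination from +z
#' and phi the azimuth. The gate flag is set when `gate_value <= 0`.
#' Diagnostic only: never feeds back into the recovered transforms. A zero
#' vector yields T = 0 with both angles 0 by convention.
#'
#' @param displacement numeric vector of length 2 or 3.
#' @param gate_value scalar whose sign sets the gate flag (`F <= 0`).
#' @return a [PolarOutput-class].
#' @export
toPolarOutput <- function(displacement, gate_value = 1) {
  v <- as.numeric(displacement)
  if (length(v) == 2) v <- c(v, 0)
  if (length(v) != 3) stop("displacement must have length 2 or 3",
                           call. = FALSE)
  Tm <- sqrt(sum(v^2))
  if (Tm == 0) {
    gam <- 0; phi <- 0
  } else {
    gam <- acos(max(-1, min(1, v[3] / Tm))) * 180 / pi
    phi <- if (v[1] == 0 && v[2] == 0) 0 else atan2(v[2], v[1]) * 180 / pi
  }
  cart <- Tm * c(sin(gam * pi / 180) * cos(phi * pi / 180),
                 sin(gam * pi / 180) * sin(phi * pi / 180),
                 cos(gam * pi / 180))
  new("PolarOutput", T = Tm, gammaDeg = gam, phiDeg = phi,
      cartesian = cart, gate = gate_value <= 0)
}

#' Register a brain functional time series
#'
#' Frame 0 is the reference. Every later frame is registered by a
#' coarse-to-fine block-matching pass (coarse at doubled block size, then
#' damped residual refinement rounds), with boosted match-reliability
#' weighting feeding a weighted rigid fit. Also samples 100 seeded pixels per
#' frame for the diagnostic cluster / polar-output report, and, when ground
#' truth transforms are available, reports the per-frame target registration
#' error over a fixed probe grid.
#'
#' @param series a [MotionSeries-class], a list of matrices, or a 3D array
#'   (frames along the third dimension).
#' @param params a [regParams()].
#' @param truth optional list of [RigidTransform2D-class] ground-truth
#'   transforms (taken from the series when it is a [MotionSeries-class]).
#' @param n_sample_pixels diagnostic pixels sampled per frame (default 100).
#' @return list with `transforms` (per-frame [RigidTransform2D-class]),
#'   `aligned` (list of resampled frames), and `diagnostics` (per-frame mean
#'   match weight, mean NCC, similarity trace, sampled pixels, cluster
#'   centers of the sampled high-difference pixels, polar output, and `tre`
#'   when truth is available).
#' @export
registerTimeSeries <- function(series, params = regParams(), truth = NULL,
                               n_sample_pixels = 100L) {
  if (is(series, "MotionSeries")) {
    if (is.null(truth)) truth <- truthTransforms(series)
    series <- frames(series)
  }
  if (is.array(series) && length(dim(series)) == 3)
    series <- lapply(seq_len(dim(series)[3]), function(k) series[, , k])
  if (!is.list(series) || length(series) < 2)
    stop("at least two frames required", call. = FALSE)
  ref <- series[[1]]
  ctr <- gridCenter(ref)
  pad <- mean(c(ref[1, ], ref[nrow(ref), ], ref[, 1], ref[, ncol(ref)]))
  probe <- as.matrix(expand.grid(
    row = seq(0, nrow(ref) - 1, length.out = 5),
    col = seq(0, ncol(ref) - 1, length.out = 5)))
  nF <- length(series)
  transforms <- vector("list", nF)
  aligned <- vector("list", nF)
  diagnostics <- vector("list", nF)
  transforms[[1]] <- rigidTransform(0, 0, 0, ctr)
  aligned[[1]] <- ref
  sampleSeeds <- withSeed(params$seed,
                          sample.int(2147483646L, nF))
  diagnostics[[1]] <- list(meanWeight = NA_real_, meanNCC = NA_real_)
  for (k in 2:nF) {
    fit <- registerFrame(ref, series[[k]], params, pad)
    transforms[[k]] <- fit$transform
    aligned[[k]] <- applyTransform(series[[k]],
                                   invertTransform(fit$transform), pad = pad)
    px <- withSeed(sampleSeeds[k], {
      idx <- sample.int(length(ref), min(n_sample_pixels, length(ref)))
      cbind(row = (idx - 1) %% nrow(ref),
            col = (idx - 1) %/% nrow(ref))
    })
    dif <- abs(series[[k]] - ref)
    hot <- px[dif[px + 1] >= stats::quantile(dif, 0.5), , drop = FALSE]
    clu <- if (nrow(hot) >= 1)
      clusterFuzzyPixels(hot, regParams(m_threshold = params$m_threshold,
                                        tau = params$tau,
                                        neighborhood_radius =
                                          params$neighborhood_radius,
                                        seed = sampleSeeds[k]))
    else NULL
    polar <- toPolarOutput(c(fit$transform@tx, fit$transform@ty),
                           gate_value = fit$meanNCC -
                             params$edge_quant_coeff)
    diagnostics[[k]] <- list(
      meanWeight = fit$meanWeight, meanNCC = fit$meanNCC,
      similarity = fit$similarity, sampledPixels = px,
      clusterCenters = if (!is.null(clu)) clusterCenters(clu) else NULL,
      polar = polar)
    if (!is.null(truth))
      diagnostics[[k]]$tre <-
        targetRegistrationError(fit$transform, truth[[k]], probe)
  }
  list(transforms = transforms, aligned = aligned,
       diagnostics = diagnostics)
}
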