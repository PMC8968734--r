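#' @include utils.R
NULL

TISSUE_CODES <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L)

#' LabeledImage: intensity grid plus tissue-label grid
#'
#' The unit every pipeline stage consumes and produces: a real-valued 2D
#' intensity grid and an integer label grid with codes 0 = background,
#' 1 = CSF, 2 = gray matter, 3 = white matter.
#'
#' @slot intensity numeric matrix of intensities (nominally in `[0, 1]`).
#' @slot labels integer matrix of the same dimensions with values in 0:3.
#' @export
setClass("LabeledImage",
  representation(intensity = "matrix", labels = "matrix"),
  validity = function(object) {
    if (!all(dim(object@intensity) == dim(object@labels)))
      return("intensity and labels must have identical dimensions")
    if (!all(object@labels %in% TISSUE_CODES))
      return("labels must be in {0 (background), 1 (csf), 2 (gm), 3 (wm)}")
    if (any(!is.finite(object@intensity)))
      return("intensity must be finite")
    TRUE
  })

#' MotionSeries: frames plus ground-truth rigid transforms
#'
#' @slot frames list of intensity matrices sharing one dimension.
#' @slot truthTransforms list of [RigidTransform2D] objects, one per frame;
#'   the first is the identity.
#' @slot seed integer seed the series was generated from.
#' @export
setClass("MotionSeries",
  representation(frames = "list", truthTransforms = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@frames) < 1) return("at least one frame required")
    d <- dim(object@frames[[1]])
    if (!all(vapply(object@frames, function(f) all(dim(f) == d), logical(1))))
      return("all frames must share dimensions")
    if (length(object@truthTransforms) != length(object@frames))
      return("one truth transform per frame required")
    t0 <- object@truthTransforms[[1]]
    if (abs(t0@tx) > 1e-12 || abs(t0@ty) > 1e-12 || abs(t0@angle) > 1e-12)
      return("truth transform of frame 0 must be the identity")
    TRUE
  })

#' RigidTransform2D: in-plane rotation plus translation
#'
#' Coordinates are 0-based (row, col); the rotation acts about `center` and a
#' positive angle is counter-clockwise in the usual display convention
#' (x = col, y = -row). A point p maps to R (p - center) + center + (tx, ty).
#'
#' @slot tx,ty translation in pixels along rows (tx) and columns (ty).
#' @slot angle rotation in degrees.
#' @slot center length-2 numeric, 0-based (row, col) rotation center.
#' @export
setClass("RigidTransform2D",
  representation(tx = "numeric", ty = "numeric", angle = "numeric",
                 center = "numeric"),
  validity = function(object) {
    if (length(object@center) != 2) return("center must be length 2")
    if (!all(is.finite(c(object@tx, object@ty, object@angle, object@center))))
      return("transform parameters must be finite")
    TRUE
  })

#' CVResult: output of two-phase Chan-Vese segmentation
#'
#' @slot insideMask logical matrix: TRUE inside the final contour C.
#' @slot g0,g1 mean intensity inside / outside C (NA when a region is empty).
#' @slot energyTrace numeric vector of total energies per iteration.
#' @slot iterationsRun integer count of iterations performed.
#' @export
setClass("CVResult",
  representation(insideMask = "matrix", g0 = "numeric", g1 = "numeric",
                 energyTrace = "numeric", iterationsRun = "integer"),
  validity = function(object) {
    if (!is.logical(object@insideMask)) return("insideMask must be logical")
    if (any(!is.finite(object@energyTrace)))
      return("energy trace must be finite-valued")
    TRUE
  })

#' GLCM: normalized gray-level co-occurrence matrix
#'
#' Probability matrix p(i, j) over gray levels 0..nLevels-1 at offset
#' (d, theta), with marginals and marginal moments.
#'
#' @slot p nLevels x nLevels probability matrix (sums to 1).
#' @slot px,py marginal distributions over rows / columns of p.
#' @slot muX,muY,sigmaX,sigmaY means and SDs of the marginals (levels 0-based).
#' @slot nLevels integer gray-level count.
#' @slot d,theta generation offset (distance in pixels, orientation degrees).
#' @slot symmetric logical: whether the reverse direction was accumulated.
#' @export
setClass("GLCM",
  representation(p = "matrix", px = "numeric", py = "numeric",
                 muX = "numeric", muY = "numeric",
                 sigmaX = "numeric", sigmaY = "numeric",
                 nLevels = "integer", d = "integer", theta = "numeric",
                 symmetric = "logical"),
  validity = function(object) {
    if (any(object@p < 0)) return("GLCM entries must be non-negative")
    if (abs(sum(object@p) - 1) > 1e-8) return("GLCM entries must sum to 1")
    if (max(abs(rowSums(object@p) - object@px)) > 1e-10)
      return("px must equal row sums of p")
    if (max(abs(colSums(object@p) - object@py)) > 1e-10)
      return("py must equal column sums of p")
    TRUE
  })

#' TissueSVM: one-vs-one Gaussian-kernel SVM over tissue classes
#'
#' Stores, per class pair, the support vectors, dual coefficients and bias of
#' a soft-margin SVM, plus the z-scoring statistics applied to features.
#' Prediction is computed from these slots via [gaussianKernel()].
#'
#' @slot classifiers list of pairwise classifiers; each holds `classes`
#'   (integer pair), `sv` (support-vector matrix), `coefs` (dual coefficients
#'   times labels, bounded by the cost), `rho` (bias) and `positive` (the
#'   class a positive decision value votes for).
#' @slot kernel list with `sigma` and `c` (see [kernelParams()]).
#' @slot classes integer vector of tissue codes the model separates.
#' @slot center,scale per-feature z-scoring statistics from the training set.
#' @export
setClass("TissueSVM",
  representation(classifiers = "list", kernel = "list", classes = "integer",
                 center = "numeric", scale = "numeric"),
  validity = function(object) {
    cc <- object@kernel$c
    for (cl in object@classifiers) {
      if (any(abs(cl$coefs) > cc * (1 + 1e-8)))
        return("dual coefficients must satisfy 0 <= alpha_i <= c")
      if (nrow(cl$sv) != length(cl$coefs))
        return("one dual coefficient per support vector required")
    }
    TRUE
  })

#' TissueLabelMap: per-pixel tissue labels with provenance
#'
#' @slot labels integer matrix with tissue codes 0:3.
#' @slot provenance integer matrix: 0 = labeled background because outside the
#'   Chan-Vese contour, 1 = labeled by the SVM.
#' @export
setClass("TissueLabelMap",
  representation(labels = "matrix", provenance = "matrix"),
  validity = function(object) {
    if (!all(dim(object@labels) == dim(object@provenance)))
      return("labels and provenance must share dimensions")
    if (!all(object@labels %in% TISSUE_CODES)) return("invalid tissue code")
    if (any(object@labels[object@provenance == 0L] != 0L))
      return("pixels outside the contour must be labeled background")
    TRUE
  })

#' ClusterSet: result of fuzzy-pixel mode-seeking clustering
#'
#' @slot centers k x 2 matrix of cluster centers (row, col).
#' @slot memberships integer vector assigning every input point to a cluster.
#' @slot fuzzySet list of per-seed trajectories of the shifted point h.
#' @slot mThreshold the merge threshold used.
#' @export
setClass("ClusterSet",
  representation(centers = "matrix", memberships = "integer",
                 fuzzySet = "list", mThreshold = "numeric"),
  validity = function(object) {
    k <- nrow(object@centers)
    if (any(object@memberships < 1L | object@memberships > k))
      return("every point must be assigned to an existing cluster")
    if (k >= 2) {
      dmin <- min(dist(object@centers))
      if (dmin < object@mThreshold - 1e-9)
        return("pairwise center distances must be >= the merge threshold")
    }
    TRUE
  })

#' SimilarityTrace: recursively accumulated similarity scores
#'
#' B(0) = d(0), B(k) = phi * B(k-1) + d(k).
#'
#' @slot values accumulated scores B(k).
#' @slot increments per-level scores d(k).
#' @slot phiCoeff the accumulation coefficient phi in (0, 1).
#' @export
setClass("SimilarityTrace",
  representation(values = "numeric", increments = "numeric",
                 phiCoeff = "numeric"),
  validity = function(object) {
    if (length(object@values) != length(object@increments))
      return("values and increments must have equal length")
    TRUE
  })

#' PolarOutput: diagnostic spherical-coordinate view of a displacement
#'
#' Verbatim spherical conversion x = T sin(gamma) cos(phi),
#' y = T sin(gamma) sin(phi), z = T cos(gamma), with a gate flag raised when
#' the supplied gate value is <= 0. Diagnostic only; never feeds back into the
#' recovered transforms.
#'
#' @slot T magnitude (template-matching coefficient).
#' @slot gammaDeg inclination from the +z axis, degrees.
#' @slot phiDeg azimuth in the x-y plane, degrees.
#' @slot cartesian length-3 numeric reconstruction (x, y, z).
#' @slot gate logical; TRUE when gate value <= 0.
#' @export
setClass("PolarOutput",
  representation(T = "numeric", gammaDeg = "numeric", phiDeg = "numeric",
                 cartesian = "numeric", gate = "logical"),
  validity = function(object) {
    if (abs(sum(object@cartesian^2) - object@T^2) > 1e-9 * max(1, object@T^2))
      return("cartesian components must satisfy x^2+y^2+z^2 = T^2")
    TRUE
  })

#' SegmentationMetrics: accuracy, per-class Dice and confusion counts
#'
#' @slot overallAccuracy fraction of agreeing pixels in the evaluated region.
#' @slot dice named numeric of per-class Dice coefficients.
#' @slot confusion truth x predicted count table over the evaluated region.
#' @export
setClass("SegmentationMetrics",
  representation(overallAccuracy = "numeric", dice = "numeric",
                 confusion = "matrix"),
  validity = function(object) {
    n <- sum(object@confusion)
    if (n > 0 &&
        abs(object@overallAccuracy - sum(diag(object@confusion)) / n) > 1e-12)
      return("overall accuracy must equal the confusion-table trace / total")
    TRUE
  })
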