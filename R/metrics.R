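#' Dice coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined to have
#' Dice 1.
#'
#' @param pred_mask,truth_mask logical matrices of equal dimensions.
#' @return the Dice overlap in `[0, 1]`.
#' @export
diceCoefficient <- function(pred_mask, truth_mask) {
  if (!all(dim(pred_mask) == dim(truth_mask)))
    stop("masks must share dimensions", call. = FALSE)
  a <- sum(pred_mask); b <- sum(truth_mask)
  if (a + b == 0) return(1)
  2 * sum(pred_mask & truth_mask) / (a + b)
}

#' Overall pixel accuracy, per-class Dice and confusion table
#'
#' Computes the fraction of agreeing pixels within an optional region, the
#' truth x predicted confusion table, and per-class Dice coefficients.
#'
#' @param pred_labels,truth_labels integer label matrices of equal
#'   dimensions.
#' @param region_mask optional logical matrix restricting the evaluation
#'   (e.g. the ground-truth brain region).
#' @return a [SegmentationMetrics-class].
#' @export
overallAccuracy <- function(pred_labels, truth_labels, region_mask = NULL) {
  if (!all(dim(pred_labels) == dim(truth_labels)))
    stop("label maps must share dimensions", call. = FALSE)
  if (is.null(region_mask))
    region_mask <- matrix(TRUE, nrow(pred_labels), ncol(pred_labels))
  if (!any(region_mask)) stop("empty evaluation region", call. = FALSE)
  p <- pred_labels[region_mask]
  t <- truth_labels[region_mask]
  lev <- sort(unique(c(p, t)))
  conf <- table(factor(t, levels = lev), factor(p, levels = lev))
  conf <- matrix(as.numeric(conf), length(lev), length(lev),
                 dimnames = list(truth = lev, pred = lev))
  dice <- vapply(lev, function(k)
    diceCoefficient(matrix(p == k), matrix(t == k)), numeric(1))
  names(dice) <- lev
  new("SegmentationMetrics",
      overallAccuracy = sum(p == t) / length(p),
      dice = dice, confusion = conf)
}

#' Target registration error between two rigid transforms
#'
#' Mean Euclidean distance between probe points mapped by the estimated and
#' the true transform.
#'
#' @param est,truth [RigidTransform2D-class] objects.
#' @param probe_points n x 2 matrix of (row, col) probe points (>= 1).
#' @return the mean distance in pixels.
#' @export
targetRegistrationError <- function(est, truth, probe_points) {
  probe_points <- matrix(as.numeric(probe_points), ncol = 2)
  if (nrow(probe_points) < 1)
    stop("at least one probe point required", call. = FALSE)
  a <- transformPoints(est, probe_points)
  b <- transformPoints(truth, probe_points)
  mean(sqrt(rowSums((a - b)^2)))
}
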