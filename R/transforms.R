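#' Construct a 2D rigid transform
#'
#' A rigid transform is a rotation by `angle` degrees about `center` followed
#' by a translation of (`tx`, `ty`) pixels, in 0-based (row, col) coordinates.
#' A positive angle is counter-clockwise in display convention (x = col,
#' y = -row), i.e. the point map is
#' `r' = cos(a) (r - cr) - sin(a) (c - cc) + cr + tx`,
#' `c' = sin(a) (r - cr) + cos(a) (c - cc) + cc + ty`.
#'
#' @param tx,ty translation in pixels along rows / columns.
#' @param angle rotation in degrees.
#' @param center 0-based (row, col) rotation center; for an H x W image the
#'   grid center is `((H-1)/2, (W-1)/2)` (see [gridCenter()]).
#' @return a [RigidTransform2D-class] object.
#' @export
rigidTransform <- function(tx = 0, ty = 0, angle = 0, center = c(0, 0)) {
  new("RigidTransform2D", tx = as.numeric(tx), ty = as.numeric(ty),
      angle = as.numeric(angle), center = as.numeric(center))
}

#' Grid center of an image in 0-based coordinates
#' @param img a matrix (or object with dim) whose center is wanted.
#' @return numeric (row, col) center.
#' @export
gridCenter <- function(img) (dim(img)[1:2] - 1) / 2

rotMat <- function(angleDeg) {
  a <- angleDeg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param tf a [RigidTransform2D-class].
#' @param pts n x 2 matrix of 0-based (row, col) points.
#' @return n x 2 matrix of mapped points.
#' @export
transformPoints <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  R <- rotMat(tf@angle)
  sw <- sweep(pts, 2, tf@center)
  out <- sw %*% t(R)
  sweep(out, 2, tf@center + c(tf@tx, tf@ty), "+")
}

#' Invert a rigid transform
#' @param tf a [RigidTransform2D-class].
#' @return the inverse transform, sharing `tf`'s center.
#' @export
invertTransform <- function(tf) {
  R <- rotMat(-tf@angle)
  t2 <- -(R %*% c(tf@tx, tf@ty))
  rigidTransform(t2[1], t2[2], -tf@angle, tf@center)
}

#' Compose two rigid transforms
#'
#' Returns the transform mapping p to `second(first(p))`. Both transforms must
#' share the same rotation center (the composition is expressed about it).
#'
#' @param second,first [RigidTransform2D-class] objects.
#' @return the composed [RigidTransform2D-class].
#' @export
composeTransforms <- function(second, first) {
  if (max(abs(second@center - first@center)) > 1e-9)
    stop("transforms must share a rotation center to compose", call. = FALSE)
  R2 <- rotMat(second@angle)
  t <- as.numeric(R2 %*% c(first@tx, first@ty)) + c(second@tx, second@ty)
  rigidTransform(t[1], t[2], second@angle + first@angle, first@center)
}

#' Resample an image under a rigid transform
#'
#' Produces `out` with `out(x) = image(tf^{-1}(x))` (the image content moves
#' by `tf`), using bilinear interpolation and constant padding outside the
#' grid. If `tf`'s center is `c(0, 0)` and the image is larger than 1 x 1 in
#' both dimensions, the grid center is used unless `useCenterAsIs = TRUE`.
#'
#' @param image numeric matrix.
#' @param tf a [RigidTransform2D-class].
#' @param pad constant padding value (typically the background mean).
#' @param useCenterAsIs keep `tf@center` verbatim instead of defaulting to the
#'   grid center.
#' @return the resampled matrix.
#' @export
applyTransform <- function(image, tf, pad = 0, useCenterAsIs = FALSE) {
  stopIfNotMatrix(image)
  ctr <- tf@center
  if (!useCenterAsIs && all(ctr == 0)) ctr <- gridCenter(image)
  tfl <- rigidTransform(tf@tx, tf@ty, tf@angle, ctr)
  if (tfl@tx == 0 && tfl@ty == 0 && tfl@angle == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  grid <- cbind(rep(0:(h - 1), times = w), rep(0:(w - 1), each = h))
  src <- transformPoints(invertTransform(tfl), grid)
  matrix(bilinearSample(image, src[, 1], src[, 2], pad = pad), h, w)
}
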