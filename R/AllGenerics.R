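# Accessor generics and show methods.

#' Accessors for neuroSegReg objects
#'
#' Accessor functions for the package's S4 containers: `intensity()` and
#' `tissueLabels()` for [LabeledImage-class] / [TissueLabelMap-class],
#' `frames()` and `truthTransforms()` for [MotionSeries-class],
#' `insideMask()` and `energyTrace()` for [CVResult-class],
#' `glcmMatrix()` for [GLCM-class], `clusterCenters()` and
#' `clusterMemberships()` for [ClusterSet-class], and
#' `transformParams()` for [RigidTransform2D-class].
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
#' @aliases intensity tissueLabels frames truthTransforms insideMask
#'   energyTrace glcmMatrix clusterCenters clusterMemberships transformParams
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("truthTransforms", function(x) standardGeneric("truthTransforms"))
#' @rdname accessors
#' @export
setGeneric("insideMask", function(x) standardGeneric("insideMask"))
#' @rdname accessors
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))
#' @rdname accessors
#' @export
setGeneric("glcmMatrix", function(x) standardGeneric("glcmMatrix"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("clusterMemberships",
           function(x) standardGeneric("clusterMemberships"))
#' @rdname accessors
#' @export
setGeneric("transformParams", function(x) standardGeneric("transformParams"))

#' @rdname accessors
setMethod("intensity", "LabeledImage", function(x) x@intensity)
#' @rdname accessors
setMethod("tissueLabels", "LabeledImage", function(x) x@labels)
#' @rdname accessors
setMethod("tissueLabels", "TissueLabelMap", function(x) x@labels)
#' @rdname accessors
setMethod("frames", "MotionSeries", function(x) x@frames)
#' @rdname accessors
setMethod("truthTransforms", "MotionSeries", function(x) x@truthTransforms)
#' @rdname accessors
setMethod("insideMask", "CVResult", function(x) x@insideMask)
#' @rdname accessors
setMethod("energyTrace", "CVResult", function(x) x@energyTrace)
#' @rdname accessors
setMethod("glcmMatrix", "GLCM", function(x) x@p)
#' @rdname accessors
setMethod("clusterCenters", "ClusterSet", function(x) x@centers)
#' @rdname accessors
setMethod("clusterMemberships", "ClusterSet", function(x) x@memberships)
#' @rdname accessors
setMethod("transformParams", "RigidTransform2D", function(x)
  c(tx = x@tx, ty = x@ty, angle = x@angle))

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("LabeledImage %d x %d\n", d[1], d[2]))
  tab <- table(factor(object@labels, levels = TISSUE_CODES,
                      labels = names(TISSUE_CODES)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  intensity range: [%.4f, %.4f]\n",
              min(object@intensity), max(object@intensity)))
})

setMethod("show", "MotionSeries", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("MotionSeries: %d frames of %d x %d (seed %d)\n",
              length(object@frames), d[1], d[2], object@seed))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf(
    "RigidTransform2D: tx=%.4f ty=%.4f angle=%.4f deg (center %.1f, %.1f)\n",
    object@tx, object@ty, object@angle, object@center[1], object@center[2]))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d/%d pixels inside, g0=%.4f g1=%.4f, %d iterations, final energy %.6g\n",
    sum(object@insideMask), length(object@insideMask), object@g0, object@g1,
    object@iterationsRun, tail(object@energyTrace, 1)))
})

setMethod("show", "GLCM", function(object) {
  cat(sprintf("GLCM: %d levels, d=%d, theta=%g deg, %s\n",
              object@nLevels, object@d, object@theta,
              if (object@symmetric) "symmetric" else "asymmetric"))
})

setMethod("show", "TissueSVM", function(object) {
  nsv <- sum(vapply(object@classifiers, function(cl) nrow(cl$sv), integer(1)))
  cat(sprintf(
    "TissueSVM: %d pairwise classifiers over classes {%s}, %d support vectors, sigma=%g, c=%g\n",
    length(object@classifiers), paste(object@classes, collapse = ","),
    nsv, object@kernel$sigma, object@kernel$c))
})

setMethod("show", "TissueLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TissueLabelMap %d x %d (%d pixels labeled by SVM)\n",
              d[1], d[2], sum(object@provenance == 1L)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters over %d points\n",
              nrow(object@centers), length(object@memberships)))
})

setMethod("show", "SegmentationMetrics", function(object) {
  cat(sprintf("SegmentationMetrics: accuracy %.4f\n", object@overallAccuracy))
  cat("  Dice:", paste(sprintf("%s=%.4f", names(object@dice), object@dice),
                       collapse = " "), "\n")
})

#' @importFrom utils tail
NULL
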