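#' @include AllClasses.R
NULL

#' Rotation matrix of a rigid transform
#' @param x a [RigidTransform-class]
#' @return 3x3 matrix
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname rotation
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' Translation vector of a rigid transform
#' @param x a [RigidTransform-class]
#' @return length-3 numeric (mm)
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname translation
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' Vertex coordinates of a surface mesh
#' @param x a [SurfaceMesh-class]
#' @return n x 3 matrix (mm)
#' @export
setGeneric("meshPoints", function(x) standardGeneric("meshPoints"))

#' @rdname meshPoints
#' @export
setMethod("meshPoints", "SurfaceMesh", function(x) x@points)

#' Named landmarks of a surface mesh
#' @param x a [SurfaceMesh-class]
#' @return named list of length-3 points
#' @export
setGeneric("meshLandmarks", function(x) standardGeneric("meshLandmarks"))

#' @rdname meshLandmarks
#' @export
setMethod("meshLandmarks", "SurfaceMesh", function(x) x@landmarks)

#' Myocardium mask of a slice record
#'
#' The myocardium is the epicardial interior minus the endocardial blood
#' pool.
#' @param x a [SliceRecord-class]
#' @return binary matrix
#' @export
setGeneric("myocardiumMask", function(x) standardGeneric("myocardiumMask"))

#' @rdname myocardiumMask
#' @export
setMethod("myocardiumMask", "SliceRecord", function(x) {
  m <- x@epiMask * (1 - x@endoMask)
  m
})

#' Image of a slice record
#' @param x a [SliceRecord-class]
#' @return intensity matrix
#' @export
setGeneric("sliceImage", function(x) standardGeneric("sliceImage"))

#' @rdname sliceImage
#' @export
setMethod("sliceImage", "SliceRecord", function(x) x@image)

#' Per-region metric table of a metrics report
#' @param x a [MetricsReport-class]
#' @return data.frame
#' @export
setGeneric("perRegion", function(x) standardGeneric("perRegion"))

#' @rdname perRegion
#' @export
setMethod("perRegion", "MetricsReport", function(x) x@perRegion)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px, %d slices\n",
              object@imageSize, object@imageSize, object@nSlices))
  cat(sprintf("  epi radius %.0f-%.0f px, wall %.0f-%.0f px, RV arc %.0f deg\n",
              object@lvRadiusRange[1], object@lvRadiusRange[2],
              object@wallThicknessRange[1], object@wallThicknessRange[2],
              object@rvAttachmentArc))
  on <- .REGIONS[object@scarPresent]
  if (length(on))
    cat(sprintf("  scar: %s (burden %s), shift %+.0f, thinning %.2f\n",
                paste(on, collapse = "+"),
                paste(sprintf("%.2f", object@scarBurden[on]), collapse = "/"),
                object@scarIntensityShift, object@scarThinning))
  else cat("  scar: none\n")
  cat(sprintf("  noise sd %.1f, seed %d\n", object@noiseSd, object@seed))
})

setMethod("show", "SliceRecord", function(object) {
  d <- dim(object@image)
  cat(sprintf("SliceRecord %s/%d: %d x %d px, myo %d px, RV %d px, scar %d px\n",
              object@patientId, object@sliceIndex, d[1], d[2],
              sum(myocardiumMask(object)), sum(object@rvMask),
              sum(object@scarMask)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh <%s>: %d points, %d faces, landmarks: %s\n",
              object@label, nrow(object@points), nrow(object@faces),
              if (length(object@landmarks))
                paste(names(object@landmarks), collapse = ", ") else "none"))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig <%s>: input %dpx, latent %d, encoder [%s], branches %s [%s], dropout %.2f\n",
              object@variant, object@inputSize, object@latentDim,
              paste(object@encoderChannels, collapse = ","),
              paste(object@branches, collapse = "+"),
              paste(object@branchLayers, collapse = ","), object@dropout))
})

setMethod("show", "ScarNetwork", function(object) {
  np <- sum(vapply(as.list(object@params), length, 1L))
  show(object@config)
  cat(sprintf("  %d trainable parameters\n", np))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  pr <- object@perRegion
  for (i in seq_len(nrow(pr))) {
    cat(sprintf("  %-8s AUC %.3f [%.3f-%.3f]  sens %.2f  spec %.2f  (n=%d, pos=%d)\n",
                pr$region[i], pr$auc[i], pr$auc_ci_low[i], pr$auc_ci_high[i],
                pr$sensitivity[i], pr$specificity[i],
                pr$n_slices[i], pr$n_positive[i]))
  }
  cat(sprintf("  accuracy %.1f%%\n", 100 * object@accuracy))
})

setMethod("show", "RegionLabels", function(object) {
  if (object@excluded)
    cat(sprintf("RegionLabels: excluded (%s)\n", object@exclusionReason))
  else
    cat(sprintf("RegionLabels: septal %s (%.3f), lateral %s (%.3f)\n",
                object@septalScar, object@septalFraction,
                object@lateralScar, object@lateralFraction))
})
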