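#' @rdname InstanceMask-class
#' @param object an object.
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))

#' @rdname InstanceMask-class
#' @export
setGeneric("instanceLabel", function(object) standardGeneric("instanceLabel"))

#' @rdname InstanceMask-class
#' @export
setGeneric("instanceScore", function(object) standardGeneric("instanceScore"))

#' @rdname InstanceMask-class
#' @export
setGeneric("instanceId", function(object) standardGeneric("instanceId"))

#' @rdname Skeleton-class
#' @param object an object.
#' @export
setGeneric("skeletonPixels", function(object) standardGeneric("skeletonPixels"))

#' @rdname Skeleton-class
#' @export
setGeneric("endpoints", function(object) standardGeneric("endpoints"))

#' @rdname Skeleton-class
#' @export
setGeneric("branchpoints", function(object) standardGeneric("branchpoints"))

#' @rdname AnnotationDoc-class
#' @param object an object.
#' @export
setGeneric("docShapes", function(object) standardGeneric("docShapes"))

#' @rdname AnnotationDoc-class
#' @export
setGeneric("imageSize", function(object) standardGeneric("imageSize"))

setMethod("maskPixels", "InstanceMask", function(object) object@pixels)
setMethod("instanceLabel", "InstanceMask", function(object) object@label)
setMethod("instanceScore", "InstanceMask", function(object) object@score)
setMethod("instanceId", "InstanceMask", function(object) object@instanceId)
setMethod("skeletonPixels", "Skeleton", function(object) object@pixels)
setMethod("docShapes", "AnnotationDoc", function(object) object@shapes)

#' @describeIn AnnotationDoc-class image size as `c(height, width)` pixels.
setMethod("imageSize", "AnnotationDoc", function(object)
  c(height = object@imageHeight, width = object@imageWidth))

#' @describeIn Skeleton-class 0-based (x, y) coordinates of pixels with exactly
#'   one skeleton 8-neighbour.
setMethod("endpoints", "Skeleton", function(object) {
  deg <- neighborCount8(object@pixels)
  whichXY(object@pixels & deg == 1L)
})

#' @describeIn Skeleton-class 0-based (x, y) coordinates of pixels with three
#'   or more skeleton 8-neighbours.
setMethod("branchpoints", "Skeleton", function(object) {
  deg <- neighborCount8(object@pixels)
  whichXY(object@pixels & deg >= 3L)
})

setMethod("show", "AnnotationDoc", function(object) {
  cat(sprintf("AnnotationDoc: %s (%d x %d px), %d shape(s)%s\n",
              object@imagePath, object@imageWidth, object@imageHeight,
              length(object@shapes),
              if (length(object@imageData)) ", embedded image" else ""))
  labs <- vapply(object@shapes, function(s) s$label, character(1))
  if (length(labs)) {
    tab <- table(labs)
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "InstanceMask", function(object) {
  cat(sprintf("InstanceMask #%d '%s': %d x %d px, %d foreground px, score %s\n",
              object@instanceId, object@label,
              ncol(object@pixels), nrow(object@pixels), sum(object@pixels),
              ifelse(is.na(object@score), "NA", format(object@score))))
})

setMethod("show", "Skeleton", function(object) {
  ep <- endpoints(object)
  cat(sprintf("Skeleton (%s): %d px, %d endpoint(s), %d branchpoint(s)\n",
              object@method, sum(object@pixels), nrow(ep),
              nrow(branchpoints(object))))
})

setMethod("show", "ScaleModel", function(object) {
  cat(sprintf("ScaleModel: %g dpi (%.5f mm/px)\n", object@dpi, object@mmPerPx))
})

setMethod("show", "QuadraticFit", function(object) {
  cat(sprintf("QuadraticFit: y = %.5g x^2 + %.5g x + %.5g (rotated %.1f deg), rms %.3g px\n",
              object@a, object@b, object@c, object@rotation * 180 / pi, object@rms))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec '%s': %d graph nodes, heads at strides {%s}, %d classes\n",
              object@variant, length(object@layers),
              paste(object@headStrides, collapse = ", "), object@numClasses))
})
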