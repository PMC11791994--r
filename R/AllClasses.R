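#' Polygon annotation document
#'
#' In-memory model of a Labelme-dialect polygon annotation file: a list of
#' labelled polygons (`shapes`), the image file name, an optional embedded
#' base64 image payload, and the image dimensions. Top-level fields that the
#' model does not interpret are carried through untouched in `extra`, and the
#' original field order is retained so that a read/write round trip preserves
#' the document layout.
#'
#' @slot shapes list of shapes; each shape is a list with elements `label`
#'   (character), `points` (numeric matrix with columns x, y in 0-based
#'   pixels) and `extra` (named list of uninterpreted per-shape fields).
#' @slot imagePath character file name of the annotated image.
#' @slot imageData character base64 payload; `character(0)` encodes JSON null.
#' @slot imageHeight,imageWidth image dimensions in pixels.
#' @slot extra named list of uninterpreted top-level fields.
#' @slot fieldOrder character vector of top-level field names in file order.
#'
#' @seealso [readAnnotation()], [writeAnnotation()], [tileAnnotation()]
#' @export
setClass("AnnotationDoc",
  representation(
    shapes      = "list",
    imagePath   = "character",
    imageData   = "character",
    imageHeight = "numeric",
    imageWidth  = "numeric",
    extra       = "list",
    fieldOrder  = "character"
  ),
  prototype(
    shapes = list(), imagePath = "", imageData = character(0),
    imageHeight = 1, imageWidth = 1, extra = list(),
    fieldOrder = c("shapes", "imagePath", "imageData", "imageHeight", "imageWidth")
  )
)

setValidity("AnnotationDoc", function(object) {
  msg <- character(0)
  if (length(object@imageHeight) != 1 || object@imageHeight <= 0)
    msg <- c(msg, "imageHeight must be a single positive number")
  if (length(object@imageWidth) != 1 || object@imageWidth <= 0)
    msg <- c(msg, "imageWidth must be a single positive number")
  for (i in seq_along(object@shapes)) {
    sh <- object@shapes[[i]]
    if (!is.list(sh) || is.null(sh$label) || is.null(sh$points)) {
      msg <- c(msg, sprintf("shape %d must have 'label' and 'points'", i))
      next
    }
    if (!is.matrix(sh$points) || ncol(sh$points) != 2)
      msg <- c(msg, sprintf("shape %d points must be an n x 2 matrix", i))
  }
  if (length(msg)) msg else TRUE
})

#' Single-object instance mask
#'
#' One binary object mask as produced by an instance segmenter, together with
#' its detection metadata. Foreground pixels are `TRUE`; the matrix is indexed
#' `[y + 1, x + 1]` (row = image row).
#'
#' @slot pixels logical matrix, `TRUE` = object.
#' @slot label category string (e.g. `"primary root"`, `"lateral root"`).
#' @slot score detection confidence in `[0, 1]` (`NA` if unknown).
#' @slot bbox numeric `(x0, y0, x1, y1)` in 0-based pixels, or `numeric(0)`.
#' @slot sourceImage identifier of the image the mask came from.
#' @slot instanceId integer instance identifier.
#'
#' @seealso [largestComponent()], [thinMask()], [phenotypeInstance()]
#' @export
setClass("InstanceMask",
  representation(
    pixels      = "matrix",
    label       = "character",
    score       = "numeric",
    bbox        = "numeric",
    sourceImage = "character",
    instanceId  = "integer"
  ),
  prototype(
    pixels = matrix(FALSE, 1, 1), label = "root", score = NA_real_,
    bbox = numeric(0), sourceImage = "", instanceId = 1L
  )
)

setValidity("InstanceMask", function(object) {
  msg <- character(0)
  if (!is.logical(object@pixels))
    msg <- c(msg, "pixels must be a logical matrix")
  if (length(object@score) == 1 && !is.na(object@score) &&
      (object@score < 0 || object@score > 1))
    msg <- c(msg, "score must lie in [0, 1]")
  if (length(object@bbox) %in% c(0, 4) == FALSE)
    msg <- c(msg, "bbox must be numeric(0) or length 4 (x0, y0, x1, y1)")
  if (length(object@bbox) == 4 && any(object@pixels)) {
    b <- round(object@bbox)
    y <- (b[2] + 1):(b[4] + 1); x <- (b[1] + 1):(b[3] + 1)
    y <- y[y >= 1 & y <= nrow(object@pixels)]
    x <- x[x >= 1 & x <= ncol(object@pixels)]
    if (!length(y) || !length(x) || !any(object@pixels[y, x, drop = FALSE]))
      msg <- c(msg, "bbox must contain at least one foreground pixel")
  }
  if (length(msg)) msg else TRUE
})

#' One-pixel-wide medial skeleton
#'
#' Result of thinning a single-object mask: a subset of the mask foreground
#' that is (after successful thinning) one pixel wide and 8-connected, stored
#' on the same pixel grid as its source mask.
#'
#' @slot pixels logical matrix of skeleton pixels.
#' @slot method thinning method that produced the skeleton.
#'
#' @seealso [thinMask()], [pruneSpurs()], [toPolyline()]
#' @export
setClass("Skeleton",
  representation(pixels = "matrix", method = "character"),
  prototype(pixels = matrix(FALSE, 1, 1), method = "k3m")
)

setValidity("Skeleton", function(object) {
  if (!is.logical(object@pixels)) "pixels must be a logical matrix" else TRUE
})

#' Quadratic fit of a root polyline
#'
#' Least-squares fit of `y = a x^2 + b x + c` to an ordered polyline, in a
#' frame rotated so that the polyline's principal axis is horizontal (making
#' y(x) single-valued for elongated roots).
#'
#' @slot a,b,c polynomial coefficients in the rotated frame (pixel units).
#' @slot rotation rotation angle (radians) applied before fitting.
#' @slot center centroid subtracted before rotation (x, y pixels).
#' @slot domain fitted x-range `c(x_min, x_max)` in the rotated frame.
#' @slot rms residual root mean square of the fit (pixels).
#'
#' @seealso [fitQuadratic()], [curvatureFromFit()]
#' @export
setClass("QuadraticFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 rotation = "numeric", center = "numeric",
                 domain = "numeric", rms = "numeric"),
  prototype(a = 0, b = 0, c = 0, rotation = 0, center = c(0, 0),
            domain = c(0, 1), rms = 0)
)

setValidity("QuadraticFit", function(object) {
  msg <- character(0)
  if (!all(is.finite(c(object@a, object@b, object@c))))
    msg <- c(msg, "coefficients must be finite")
  if (length(object@domain) != 2 || diff(object@domain) < 0)
    msg <- c(msg, "domain must be c(x_min, x_max) with x_min <= x_max")
  if (length(msg)) msg else TRUE
})

#' Image scale model
#'
#' Physical scale of a scanned image: dots per inch and the derived
#' millimetres per pixel (`25.4 / dpi`).
#'
#' @slot dpi scanner resolution in dots per inch.
#' @slot mmPerPx millimetres per pixel.
#'
#' @seealso [scaleModel()]
#' @export
setClass("ScaleModel",
  representation(dpi = "numeric", mmPerPx = "numeric"),
  prototype(dpi = 1200, mmPerPx = 25.4 / 1200)
)

setValidity("ScaleModel", function(object) {
  msg <- character(0)
  if (object@dpi <= 0) msg <- c(msg, "dpi must be positive")
  if (abs(object@mmPerPx - 25.4 / object@dpi) > 1e-12)
    msg <- c(msg, "mmPerPx must equal 25.4 / dpi")
  if (length(msg)) msg else TRUE
})

#' Layer graph of a YoloV8seg-style network
#'
#' Ordered layer graph of an instance segmentation network variant, with
#' resolved channel counts and strides, sufficient for closed-form layer,
#' parameter and FLOP accounting. Base variants carry detection/segmentation
#' heads at strides 8/16/32; the elongated-target variant adds two coarser
#' strides (64/128).
#'
#' @slot variant one of `"n"`, `"s"`, `"m"`, `"l"`, `"x"`, `"improved_n"`.
#' @slot depthMult,widthMult,maxChannels family scaling factors.
#' @slot numClasses number of object classes the heads predict.
#' @slot layers ordered list of resolved layer descriptions.
#' @slot headStrides output strides of the detect/segment heads.
#'
#' @seealso [buildSpec()], [countParams()], [countLayers()], [countFlops()]
#' @export
setClass("ArchitectureSpec",
  representation(
    variant     = "character",
    depthMult   = "numeric",
    widthMult   = "numeric",
    maxChannels = "numeric",
    numClasses  = "numeric",
    layers      = "list",
    headStrides = "numeric"
  )
)

setValidity("ArchitectureSpec", function(object) {
  msg <- character(0)
  if (!length(object@layers)) msg <- c(msg, "layers must be nonempty")
  if (!length(object@headStrides)) msg <- c(msg, "headStrides must be nonempty")
  if (any(diff(object@headStrides) <= 0))
    msg <- c(msg, "headStrides must be strictly increasing")
  if (length(msg)) msg else TRUE
})
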