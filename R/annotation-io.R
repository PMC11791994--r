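#' Read a polygon annotation document
#'
#' Parses a Labelme-dialect JSON annotation file into an [AnnotationDoc].
#' The required fields are `shapes` (each with `label` and `points`),
#' `imagePath`, `imageData`, `imageHeight` and `imageWidth`; a missing field
#' raises an error naming it. Unknown top-level and per-shape fields are
#' preserved untouched, as is the field order, so that
#' `writeAnnotation(readAnnotation(p))` reproduces the document layout.
#'
#' @param path path to a JSON annotation file.
#' @return an [AnnotationDoc].
#' @examples
#' doc <- annotationDoc(
#'   shapes = list(shape("lateral root", cbind(c(0, 10, 10), c(0, 0, 10)))),
#'   imagePath = "scan.png", imageHeight = 64, imageWidth = 64)
#' f <- tempfile(fileext = ".json")
#' writeAnnotation(doc, f)
#' readAnnotation(f)
#' @seealso [writeAnnotation()], [tileAnnotation()]
#' @export
readAnnotation <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  annotationFromList(raw, source = path)
}

# build an AnnotationDoc from a parsed JSON list, checking required fields
annotationFromList <- function(raw, source = "annotation") {
  required <- c("shapes", "imagePath", "imageData", "imageHeight", "imageWidth")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(sprintf("malformed annotation '%s': missing field '%s'",
                 source, missing[1]), call. = FALSE)
  shapes <- lapply(seq_along(raw$shapes), function(i) {
    sh <- raw$shapes[[i]]
    for (fld in c("label", "points"))
      if (is.null(sh[[fld]]))
        stop(sprintf("malformed annotation '%s': shape %d missing field '%s'",
                     source, i, fld), call. = FALSE)
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
    if (ncol(pts) != 2)
      stop(sprintf("malformed annotation '%s': shape %d points are not (x, y) pairs",
                   source, i), call. = FALSE)
    list(label = as.character(sh$label), points = pts,
         extra = sh[setdiff(names(sh), c("label", "points"))])
  })
  extraNames <- setdiff(names(raw), required)
  new("AnnotationDoc",
      shapes = shapes,
      imagePath = as.character(raw$imagePath),
      imageData = if (is.null(raw$imageData)) character(0) else as.character(raw$imageData),
      imageHeight = as.numeric(raw$imageHeight),
      imageWidth = as.numeric(raw$imageWidth),
      extra = raw[extraNames],
      fieldOrder = names(raw))
}

#' Construct an annotation document in code
#'
#' @param shapes list of shapes, see [shape()].
#' @param imagePath image file name.
#' @param imageHeight,imageWidth image dimensions in pixels.
#' @param imageData optional base64 image payload (`NULL` for none).
#' @return an [AnnotationDoc].
#' @export
annotationDoc <- function(shapes, imagePath, imageHeight, imageWidth,
                          imageData = NULL) {
  new("AnnotationDoc", shapes = shapes, imagePath = imagePath,
      imageData = if (is.null(imageData)) character(0) else imageData,
      imageHeight = imageHeight, imageWidth = imageWidth,
      extra = list(version = "5.0.1", flags = structure(list(), names = character(0))),
      fieldOrder = c("version", "flags", "shapes", "imagePath", "imageData",
                     "imageHeight", "imageWidth"))
}

#' @rdname annotationDoc
#' @param label category string of the polygon.
#' @param points numeric n x 2 matrix of 0-based (x, y) pixel vertices.
#' @export
shape <- function(label, points) {
  list(label = label, points = points,
       extra = list(group_id = NULL, shape_type = "polygon",
                    flags = structure(list(), names = character(0))))
}

#' Write a polygon annotation document
#'
#' Serialises an [AnnotationDoc] back to the JSON dialect it was read from,
#' preserving field order and unknown fields. `imageData` of length zero is
#' written as JSON `null`.
#'
#' @param doc an [AnnotationDoc].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readAnnotation()]
#' @export
writeAnnotation <- function(doc, path) {
  validObject(doc)
  out <- annotationToList(doc)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

annotationToList <- function(doc) {
  shapes <- lapply(doc@shapes, function(sh) {
    c(list(label = sh$label,
           points = lapply(seq_len(nrow(sh$points)),
                           function(i) as.numeric(sh$points[i, ]))),
      asJsonDicts(sh$extra))
  })
  known <- list(shapes = shapes,
                imagePath = doc@imagePath,
                imageData = if (length(doc@imageData)) doc@imageData else NULL,
                imageHeight = doc@imageHeight,
                imageWidth = doc@imageWidth)
  all <- c(known, asJsonDicts(doc@extra))
  ord <- intersect(doc@fieldOrder, names(all))
  c(all[ord], all[setdiff(names(all), ord)])
}

# the annotation dialect writes empty dictionary fields (e.g. "flags") as {};
# a parsed empty list loses its names, so they are restored before writing
asJsonDicts <- function(x) {
  dictFields <- c("flags")
  for (nm in intersect(names(x), dictFields)) {
    if (is.list(x[[nm]]) && !length(x[[nm]]))
      x[[nm]] <- structure(list(), names = character(0))
  }
  x
}
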