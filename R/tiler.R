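#' Tile specification
#'
#' Position of one square tile in the tiling grid of a large scan. The tile's
#' top-left corner sits at `(col * s, row * s)` in source-image pixels.
#'
#' @param s tile side length in pixels (> 0).
#' @param row,col 0-based grid indices.
#' @return a list with elements `s`, `row`, `col` and `origin = c(ox, oy)`.
#' @export
tileSpec <- function(s, row = 0L, col = 0L) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("tile size 's' must be a single positive number", call. = FALSE)
  if (row < 0 || col < 0) stop("row and col must be >= 0", call. = FALSE)
  list(s = s, row = as.integer(row), col = as.integer(col),
       origin = c(ox = col * s, oy = row * s))
}

#' Restrict an annotation document to one tile
#'
#' Shifts every polygon vertex by minus the tile origin and restricts the
#' document to the `s` x `s` tile window. Two restriction modes are provided:
#'
#' * `"faithful"` reproduces the published splitting procedure verbatim:
#'   shifted vertices with `x > s` or `x < 0` or `y > s` or `y < 0` are
#'   deleted one by one (so `x = 0` and `x = s` are kept), and shapes left
#'   with two or fewer vertices are dropped. Boundary-crossing polygons are
#'   therefore distorted rather than clipped.
#' * `"clip"` intersects each polygon with the tile square
#'   (Sutherland-Hodgman clipping against the convex window), which keeps
#'   boundary geometry intact; degenerate results (fewer than three distinct
#'   vertices) are dropped.
#'
#' The output document has `imageHeight = imageWidth = s` and a `null`
#' `imageData` unless `imageData` is supplied (see [reencodeTileImage()]).
#'
#' @param doc an [AnnotationDoc].
#' @param tile a [tileSpec()].
#' @param mode `"faithful"` or `"clip"`.
#' @param imageData optional base64 string to embed in the tile document.
#' @return an [AnnotationDoc] for the tile.
#' @examples
#' sq <- shape("lateral root", cbind(c(2000, 2100, 2100, 2000),
#'                                   c(2000, 2000, 2100, 2100)))
#' doc <- annotationDoc(list(sq), "scan.png", 4096, 4096)
#' # two vertices fall outside x <= 2048, so the whole shape is dropped:
#' length(docShapes(tileAnnotation(doc, tileSpec(2048), "faithful")))
#' # clipping keeps the in-tile part of the square:
#' length(docShapes(tileAnnotation(doc, tileSpec(2048), "clip")))
#' @export
tileAnnotation <- function(doc, tile, mode = c("clip", "faithful"),
                           imageData = NULL) {
  mode <- match.arg(mode)
  validObject(doc)
  s <- tile$s
  shapes <- list()
  for (sh in doc@shapes) {
    pts <- sh$points
    pts[, 1] <- pts[, 1] - tile$origin[["ox"]]
    pts[, 2] <- pts[, 2] - tile$origin[["oy"]]
    if (mode == "faithful") {
      keep <- !(pts[, 1] > s | pts[, 1] < 0 | pts[, 2] > s | pts[, 2] < 0)
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) <= 2) next
      shapes[[length(shapes) + 1L]] <- list(label = sh$label, points = pts,
                                            extra = sh$extra)
    } else {
      clipped <- clipPolygonRect(pts, 0, 0, s, s)
      if (is.null(clipped) || nrow(unique(clipped)) < 3) next
      shapes[[length(shapes) + 1L]] <- list(label = sh$label, points = clipped,
                                            extra = sh$extra)
    }
  }
  new("AnnotationDoc", shapes = shapes,
      imagePath = doc@imagePath,
      imageData = if (is.null(imageData)) character(0) else imageData,
      imageHeight = s, imageWidth = s,
      extra = doc@extra, fieldOrder = doc@fieldOrder)
}

# Sutherland-Hodgman clipping of a polygon against the axis-aligned rectangle
# [x0,x1] x [y0,y1]. Returns NULL when nothing remains. The window is convex,
# so the result is a single (possibly degenerate) polygon; a subject polygon
# whose intersection is disconnected comes back with zero-width bridges along
# the window edge, which is acceptable for annotation purposes.
clipPolygonRect <- function(pts, x0, y0, x1, y1) {
  clipEdge <- function(poly, inside, intersect) {
    n <- nrow(poly)
    if (n == 0) return(poly)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- poly[i, ]
      prev <- poly[if (i == 1) n else i - 1, ]
      curIn <- inside(cur); prevIn <- inside(prev)
      if (curIn) {
        if (!prevIn) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prevIn) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, axis) {
    # intersection of segment pq with line axis = val
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  poly <- pts
  poly <- clipEdge(poly, function(p) p[1] >= x0, function(p, q) ix(p, q, x0, 1))
  poly <- clipEdge(poly, function(p) p[1] <= x1, function(p, q) ix(p, q, x1, 1))
  poly <- clipEdge(poly, function(p) p[2] >= y0, function(p, q) ix(p, q, y0, 2))
  poly <- clipEdge(poly, function(p) p[2] <= y1, function(p, q) ix(p, q, y1, 2))
  if (!nrow(poly)) return(NULL)
  colnames(poly) <- colnames(pts)
  poly
}

#' Tile a scan and its annotation document into a full grid
#'
#' Generalises single-tile splitting to the complete `ceiling(H/s) *
#' ceiling(W/s)` grid over the source image. Edge tiles are padded to
#' `s` x `s` with background (value 0). Tile names encode the grid position as
#' `<stem>_r<row>_c<col>` so that split annotation files correspond to split
#' images.
#'
#' @param doc an [AnnotationDoc].
#' @param image optional image to split alongside the annotations: a numeric
#'   matrix (grayscale, `[y, x]`) or 3-d array (`[y, x, channel]`) whose
#'   dimensions must match the document. With `image = NULL` only the
#'   annotation documents are produced.
#' @param s tile side length in pixels.
#' @param mode passed to [tileAnnotation()].
#' @param reencode if `TRUE` (and an image is given) each tile document embeds
#'   its tile image as base64 PNG; otherwise `imageData` is `null`.
#' @param keepEmpty keep tiles whose document has no shapes (default `TRUE`).
#' @return a list of tiles, each a list with elements `doc`, `image` (or
#'   `NULL`), `row`, `col`, `name`.
#' @examples
#' doc <- annotationDoc(list(shape("root", cbind(c(1, 50, 50), c(1, 1, 50)))),
#'                      "scan.png", 100, 100)
#' tiles <- tileGrid(doc, image = NULL, s = 50)
#' length(tiles)  # 2 x 2 grid
#' @export
tileGrid <- function(doc, image = NULL, s = 2048, mode = c("clip", "faithful"),
                     reencode = FALSE, keepEmpty = TRUE) {
  mode <- match.arg(mode)
  validObject(doc)
  if (!is.null(image)) {
    dims <- dim(image)
    if (dims[1] != doc@imageHeight || dims[2] != doc@imageWidth)
      stop(sprintf(
        "image size (%d x %d) does not match annotation (%g x %g)",
        dims[1], dims[2], doc@imageHeight, doc@imageWidth), call. = FALSE)
  }
  nRows <- ceiling(doc@imageHeight / s)
  nCols <- ceiling(doc@imageWidth / s)
  stem <- sub("\\.[^.]*$", "", basename(doc@imagePath))
  tiles <- vector("list", nRows * nCols)
  k <- 0L
  for (r in seq_len(nRows) - 1L) {
    for (cl in seq_len(nCols) - 1L) {
      tl <- tileSpec(s, row = r, col = cl)
      tileImg <- NULL
      if (!is.null(image)) {
        ys <- (r * s + 1):min((r + 1) * s, dim(image)[1])
        xs <- (cl * s + 1):min((cl + 1) * s, dim(image)[2])
        if (length(dim(image)) == 2) {
          tileImg <- matrix(0, s, s)
          tileImg[seq_along(ys), seq_along(xs)] <- image[ys, xs]
        } else {
          tileImg <- array(0, c(s, s, dim(image)[3]))
          tileImg[seq_along(ys), seq_along(xs), ] <- image[ys, xs, ]
        }
      }
      b64 <- if (reencode && !is.null(tileImg)) reencodeTileImage(tileImg) else NULL
      td <- tileAnnotation(doc, tl, mode, imageData = b64)
      name <- sprintf("%s_r%d_c%d", stem, r, cl)
      td@imagePath <- paste0(name, ".png")
      if (!keepEmpty && !length(td@shapes)) next
      k <- k + 1L
      tiles[[k]] <- list(doc = td, image = tileImg, row = r, col = cl, name = name)
    }
  }
  tiles[seq_len(k)]
}

#' Base64-encode a tile image
#'
#' Encodes an image (numeric matrix or array with values in `[0, 1]`) as a
#' base64 PNG string suitable for the `imageData` field of an annotation
#' document, so the tile opens self-contained in the annotation tool. The
#' encoding round-trips pixel-identically through [decodeTileImage()].
#'
#' @param image numeric matrix or `[y, x, channel]` array with values in
#'   `[0, 1]`.
#' @return a single base64 string (no newlines).
#' @export
reencodeTileImage <- function(image) {
  bytes <- png::writePNG(image)
  gsub("\n", "", jsonlite::base64_enc(bytes), fixed = TRUE)
}

#' @rdname reencodeTileImage
#' @param b64 base64 string produced by [reencodeTileImage()].
#' @export
decodeTileImage <- function(b64) {
  png::readPNG(jsonlite::base64_dec(b64))
}
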