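#' Construct an instance mask
#'
#' @param pixels logical matrix (`TRUE` = object), indexed `[y + 1, x + 1]`.
#' @param label category string.
#' @param score detection confidence in `[0, 1]`.
#' @param bbox numeric `(x0, y0, x1, y1)` in 0-based pixels, or `numeric(0)`
#'   to derive it from the foreground.
#' @param sourceImage identifier of the source image.
#' @param instanceId integer instance id.
#' @return an [InstanceMask].
#' @export
instanceMask <- function(pixels, label = "root", score = NA_real_,
                         bbox = numeric(0), sourceImage = "",
                         instanceId = 1L) {
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (!length(bbox) && any(pixels)) {
    xy <- whichXY(pixels)
    bbox <- c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  }
  new("InstanceMask", pixels = pixels, label = label, score = score,
      bbox = bbox, sourceImage = sourceImage, instanceId = as.integer(instanceId))
}

#' Keep only the largest connected domain of a mask
#'
#' Predicted masks of long roots occasionally swallow fragments of
#' neighbouring roots that fall inside the same detection box. This operation
#' enforces a one-to-one correspondence between detection and object by
#' retaining only the largest connected domain of the mask foreground.
#'
#' Two ranking criteria are available: `"area"` (foreground pixel count, the
#' default) and `"contour_length"` (number of boundary points of each
#' component, mirroring post-processing schemes that rank contours by their
#' point count). Ties are broken deterministically in favour of the component
#' whose first pixel comes earliest in row-major order.
#'
#' @param mask an [InstanceMask] or logical matrix.
#' @param connectivity pixel adjacency, 4 or 8 (default 8, so that thin
#'   diagonal root runs stay connected).
#' @param criterion `"area"` or `"contour_length"`.
#' @return an [InstanceMask] whose foreground has exactly one connected
#'   component (a subset of the input foreground); label, score and other
#'   metadata are untouched.
#' @examples
#' m <- matrix(FALSE, 10, 20)
#' m[2:7, 2:6] <- TRUE    # 30 px component
#' m[9, 12:16] <- TRUE    # 5 px fragment
#' sum(maskPixels(largestComponent(instanceMask(m))))
#' @seealso [postprocessDetections()]
#' @export
largestComponent <- function(mask, connectivity = 8,
                             criterion = c("area", "contour_length")) {
  criterion <- match.arg(criterion)
  isMaskObj <- is(mask, "InstanceMask")
  pix <- if (isMaskObj) mask@pixels else mask
  if (!any(pix)) stop("empty mask", call. = FALSE)
  lab <- labelComponents(pix, connectivity)
  n <- max(lab)
  if (n > 1L) {
    size <- if (criterion == "area") {
      tabulate(lab[lab > 0L], nbins = n)
    } else {
      contourPointCount(lab, n)
    }
    # which.max returns the first maximum; labels are ordered by the row-major
    # position of each component's first pixel, so ties resolve deterministically
    best <- which.max(size)
    pix <- lab == best
  }
  if (!isMaskObj) return(pix)
  out <- mask
  out@pixels <- pix
  xy <- whichXY(pix)
  out@bbox <- c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  out
}

# boundary point count per component of a labelled matrix (oriented contour)
contourPointCount <- function(lab, n) {
  oc <- EBImage::ocontour(EBImage::Image(lab))
  cnt <- integer(n)
  found <- as.integer(names(oc))
  if (is.null(found) || any(is.na(found))) found <- seq_along(oc)
  for (i in seq_along(oc)) cnt[found[i]] <- nrow(oc[[i]])
  cnt
}

#' Post-process a batch of detections
#'
#' Applies the confidence threshold used at prediction time and then
#' [largestComponent()] to every surviving mask. Masks that are empty (or
#' become empty) are dropped rather than raising an error, so batch runs never
#' crash on a degenerate detection. Instance ids are preserved.
#'
#' @param masks list of [InstanceMask] objects.
#' @param minScore detections with `score < minScore` are removed (default
#'   0.4, the prediction-time confidence threshold; masks with `NA` scores are
#'   kept).
#' @param connectivity,criterion passed to [largestComponent()].
#' @return list of post-processed [InstanceMask] objects.
#' @export
postprocessDetections <- function(masks, minScore = 0.4, connectivity = 8,
                                  criterion = c("area", "contour_length")) {
  criterion <- match.arg(criterion)
  out <- list()
  for (m in masks) {
    if (!is.na(m@score) && m@score < minScore) next
    if (!any(m@pixels)) next
    out[[length(out) + 1L]] <-
      largestComponent(m, connectivity = connectivity, criterion = criterion)
  }
  out
}
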