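#' Read and write instance masks as PNG with JSON sidecars
#'
#' Masks are stored as single-channel PNG files (0 = background, 255 =
#' object). Detection metadata (label, score, bbox, source image, instance
#' id) travels in a JSON sidecar named `<mask>.json`. A PNG that is not
#' binary raises an error suggesting thresholding, rather than silently
#' rounding.
#'
#' @param path PNG file path.
#' @return [readMask()] returns an [InstanceMask].
#' @export
readMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1)))
    stop(sprintf(
      "mask '%s' is not binary (values beyond {0, 255}); threshold it first",
      path), call. = FALSE)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::fromJSON(side, simplifyVector = TRUE)
  instanceMask(img == 1,
               label = meta$label %||% "root",
               score = meta$score %||% NA_real_,
               bbox = meta$bbox %||% numeric(0),
               sourceImage = meta$source_image %||% "",
               instanceId = meta$instance_id %||% 1L)
}

#' @rdname readMask
#' @param mask an [InstanceMask].
#' @param writeSidecar write the metadata sidecar (default `TRUE`).
#' @return [writeMask()] returns `path` invisibly.
#' @export
writeMask <- function(mask, path, writeSidecar = TRUE) {
  m <- matrix(0, nrow(mask@pixels), ncol(mask@pixels))
  m[mask@pixels] <- 1
  png::writePNG(m, path)
  if (writeSidecar) {
    meta <- list(label = mask@label, score = mask@score, bbox = mask@bbox,
                 source_image = mask@sourceImage, instance_id = mask@instanceId)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

# all single-object masks in a directory, ordered by file name
readMaskDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, readMask)
}

#' Write and read a trait table
#'
#' The trait CSV has the stable header documented in [phenotypeBatch()], one
#' row per instance.
#'
#' @param traits data.frame from [phenotypeBatch()].
#' @param path CSV file path.
#' @export
writeTraits <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraits
#' @export
readTraits <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise a pipeline configuration to YAML
#'
#' @param config a [rootgrainConfig()].
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @return [readConfig()] returns the [rootgrainConfig()].
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(rootgrainConfig, vals)
}

#' Write a skeleton as PNG and ordered coordinate CSV
#'
#' @param skel a [Skeleton].
#' @param pngPath optional output PNG (skeleton pixels white).
#' @param csvPath optional output CSV of the ordered polyline (`x,y` rows).
#' @export
writeSkeleton <- function(skel, pngPath = NULL, csvPath = NULL) {
  if (!is.null(pngPath)) {
    m <- matrix(0, nrow(skel@pixels), ncol(skel@pixels))
    m[skel@pixels] <- 1
    png::writePNG(m, pngPath)
  }
  if (!is.null(csvPath)) {
    write.csv(as.data.frame(toPolyline(skel)), csvPath, row.names = FALSE)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
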