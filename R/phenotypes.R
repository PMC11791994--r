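#' Scale model from scanner resolution
#'
#' @param dpi scanner resolution in dots per inch (default 1200, the
#'   resolution of high-quality flatbed root scans).
#' @return a [ScaleModel] with `mmPerPx = 25.4 / dpi`.
#' @export
scaleModel <- function(dpi = 1200) {
  new("ScaleModel", dpi = dpi, mmPerPx = 25.4 / dpi)
}

#' Root length of an ordered polyline
#'
#' Sums the Euclidean distance between consecutive polyline points and scales
#' to millimetres. On an adjacent-pixel polyline this is the classical chain
#' length: 1 per axial step and sqrt(2) per diagonal step. For smooth curves
#' the chain-step sum over raw pixel chains overestimates length at
#' intermediate orientations; resample the polyline first (see
#' [resamplePolyline()]) when accuracy matters.
#'
#' @param poly numeric matrix with columns x, y (pixels).
#' @param scale a [ScaleModel].
#' @return length in millimetres. A single-point polyline returns 0 with a
#'   warning.
#' @examples
#' p <- cbind(x = 0:100, y = rep(0, 101))
#' rootLength(p, scaleModel(1200))   # 100 px = 2.1167 mm
#' @export
rootLength <- function(poly, scale = scaleModel()) {
  if (nrow(poly) < 2) {
    warning("polyline has fewer than 2 points; length is 0")
    return(0)
  }
  steps <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  sum(steps) * scale@mmPerPx
}

#' Resample a pixel polyline at a coarser arc-length step
#'
#' Keeps every `step`-th point (by cumulative chain length) plus both
#' endpoints. Chord sums over the resampled polyline remove the staircase
#' bias of per-pixel chain codes and track the true arc length of smooth
#' curves to well under one percent.
#'
#' @param poly numeric matrix with columns x, y.
#' @param step resampling interval in pixels (default 5).
#' @return the resampled polyline.
#' @export
resamplePolyline <- function(poly, step = 5) {
  if (nrow(poly) <= 2 || step <= 1) return(poly)
  d <- c(0, cumsum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)))
  keep <- !duplicated(floor(d / step))
  keep[1] <- TRUE
  keep[length(keep)] <- TRUE
  poly[keep, , drop = FALSE]
}

#' Diameter statistics along the skeleton
#'
#' The local diameter at a skeleton pixel is estimated from the Euclidean
#' distance transform of the mask as `2 * EDT - 1` pixels (pixel-centre
#' convention: a width-1 line has EDT 1 and diameter 1). Statistics are taken
#' over all skeleton pixels and scaled to millimetres.
#'
#' @param mask an [InstanceMask] or logical matrix the skeleton was derived
#'   from.
#' @param skel a [Skeleton] (nonempty).
#' @param scale a [ScaleModel].
#' @param excludeTips drop skeleton pixels lying inside the rounded tip caps
#'   (closer to a curve endpoint, along the curve, than the local radius
#'   there): within a cap the local width is geometrically below the trunk
#'   diameter, so tip samples bias the statistics low. Ignored when the
#'   skeleton is too short to trim.
#' @return named numeric vector `c(avg, max, min)` of diameters in mm.
#' @export
rootDiameters <- function(mask, skel, scale = scaleModel(),
                          excludeTips = TRUE) {
  pix <- if (is(mask, "InstanceMask")) mask@pixels else mask
  sk <- skel@pixels
  if (!any(sk)) stop("empty skeleton", call. = FALSE)
  edt <- edtHalf(pix)
  use <- sk
  if (excludeTips && sum(sk) >= 5) {
    poly <- tryCatch(toPolyline(skel), error = function(e) NULL)
    if (!is.null(poly) && nrow(poly) >= 5) {
      pos <- c(0, cumsum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)))
      r1 <- edt[poly[1, 2] + 1, poly[1, 1] + 1]
      r2 <- edt[poly[nrow(poly), 2] + 1, poly[nrow(poly), 1] + 1]
      keep <- pos >= r1 & pos <= max(pos) - r2
      if (sum(keep) >= 3) {
        use <- matrix(FALSE, nrow(sk), ncol(sk))
        use[cbind(poly[keep, 2] + 1, poly[keep, 1] + 1)] <- TRUE
      }
    }
  }
  d <- 2 * edt[use] * scale@mmPerPx
  c(avg = mean(d), max = max(d), min = min(d))
}

# Euclidean distance transform: distance from each foreground pixel to the
# nearest background pixel (boundary foreground = 1)
edtMask <- function(pix) {
  m <- matrix(0, nrow(pix), ncol(pix))
  m[pix] <- 1
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

# half-pixel-resolution EDT: the distance transform of the 2x pixel-replicated
# mask, reduced per original pixel by the best quadrant and rescaled. On axial
# cross-sections 2 * edtHalf(pix) equals 2 * edtMask(pix) - 1 exactly; on
# oblique ones the half-grid quantisation loses far less width.
edtHalf <- function(pix) {
  nr <- nrow(pix); nc <- ncol(pix)
  up <- pix[rep(seq_len(nr), each = 2L), rep(seq_len(nc), each = 2L)]
  m <- matrix(0, 2L * nr, 2L * nc)
  m[up] <- 1
  d2 <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
  odd <- pmax(d2[seq(1L, 2L * nr, 2L), seq(1L, 2L * nc, 2L)],
              d2[seq(2L, 2L * nr, 2L), seq(1L, 2L * nc, 2L)])
  even <- pmax(d2[seq(1L, 2L * nr, 2L), seq(2L, 2L * nc, 2L)],
               d2[seq(2L, 2L * nr, 2L), seq(2L, 2L * nc, 2L)])
  pmax(odd, even) / 2
}

#' Projected and cylindrical surface area
#'
#' Projected area is the foreground pixel count scaled to mm^2; the
#' cylindrical surface models the root as a cylinder of the measured average
#' diameter: `pi * d * L`.
#'
#' @param mask an [InstanceMask] or logical matrix.
#' @param lengthMm root length in mm.
#' @param avgDiameterMm average diameter in mm.
#' @param scale a [ScaleModel].
#' @return named numeric vector `c(projected_mm2, cylindrical_mm2)`.
#' @export
rootAreas <- function(mask, lengthMm, avgDiameterMm, scale = scaleModel()) {
  pix <- if (is(mask, "InstanceMask")) mask@pixels else mask
  c(projected_mm2 = sum(pix) * scale@mmPerPx^2,
    cylindrical_mm2 = pi * avgDiameterMm * lengthMm)
}

#' Fit a quadratic to a root polyline
#'
#' Fits `y = a x^2 + b x + c` by least squares after rotating the points so
#' that their principal axis lies along x (near-vertical roots would make
#' y(x) multivalued in image coordinates). The rotation and centroid are
#' recorded in the fit for traceability; curvature derived from the fit is
#' invariant under this rigid motion.
#'
#' @param poly numeric matrix with columns x, y (at least 3 points, not all
#'   identical).
#' @param rotate set `FALSE` to fit in the raw frame.
#' @return a [QuadraticFit].
#' @examples
#' x <- seq(-10, 10, length.out = 50)
#' f <- fitQuadratic(cbind(x = x, y = 2 * x^2 + 3 * x + 1), rotate = FALSE)
#' c(f@a, f@b, f@c)
#' @export
fitQuadratic <- function(poly, rotate = TRUE) {
  if (nrow(poly) < 3) stop("need at least 3 points to fit a quadratic", call. = FALSE)
  if (nrow(unique(poly)) < 2) stop("degenerate polyline: all points identical", call. = FALSE)
  theta <- 0
  ctr <- c(0, 0)
  if (rotate) {
    ctr <- colMeans(poly)
    X <- sweep(poly, 2, ctr)
    cv <- crossprod(X) / nrow(X)
    ev <- eigen(cv, symmetric = TRUE)
    v1 <- ev$vectors[, 1]
    # orient the axis along the traversal direction for a reproducible frame
    dir <- poly[nrow(poly), ] - poly[1, ]
    if (sum(v1 * dir) < 0) v1 <- -v1
    theta <- atan2(v1[2], v1[1])
  } else {
    X <- poly
  }
  # rotate by -theta so the principal axis lies along x
  x <- X[, 1] * cos(theta) + X[, 2] * sin(theta)
  y <- -X[, 1] * sin(theta) + X[, 2] * cos(theta)
  if (diff(range(x)) < .Machine$double.eps^0.5)
    stop("degenerate polyline: no extent along the principal axis", call. = FALSE)
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  new("QuadraticFit",
      a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]),
      rotation = theta, center = unname(ctr),
      domain = range(x), rms = sqrt(mean(fit$residuals^2)))
}

#' Curvature and radius of curvature from a quadratic fit
#'
#' For the plane curve `y = a x^2 + b x + c` the curvature is
#' `K(x) = |y''| / (1 + y'^2)^(3/2)` with `y' = 2 a x + b`, `y'' = 2 a`, and
#' the radius of curvature is `rho = 1 / K`. The single-number summary is
#' taken at the domain midpoint by default; alternatives are the parabola
#' vertex (where K attains `|2 a|`) and the mean of `|K|` over the fitted
#' domain (closed-form integral). A negative-log transform of the summary is
#' reported for trend analysis of small curvatures.
#'
#' @param fit a [QuadraticFit] in pixel units.
#' @param where `"midpoint"`, `"vertex"` or `"mean_abs"`.
#' @param scale a [ScaleModel] used to express K in 1/mm and rho in mm; use
#'   `NULL` for pixel units.
#' @param logBase base of the negative-log transform (default `exp(1)`).
#' @return a list with elements `K` (1/mm), `rho` (mm; `Inf` for straight
#'   roots), `K_mean_abs`, `neg_log_K` (`NA` when K = 0), `straight`
#'   (logical), `where`.
#' @examples
#' f <- fitQuadratic(cbind(x = seq(-5, 5, 0.1),
#'                         y = 0.5 * seq(-5, 5, 0.1)^2), rotate = FALSE)
#' curvatureFromFit(f, "vertex", scale = NULL)$K   # 2a = 1 at the vertex
#' @export
curvatureFromFit <- function(fit, where = c("midpoint", "vertex", "mean_abs"),
                             scale = scaleModel(), logBase = exp(1)) {
  where <- match.arg(where)
  a <- fit@a; b <- fit@b
  perPx <- if (is.null(scale)) 1 else 1 / scale@mmPerPx
  Kfun <- function(x) abs(2 * a) / (1 + (2 * a * x + b)^2)^1.5
  meanAbs <- function() {
    # d/dx [ u / sqrt(1 + u^2) ] = 2a / (1 + u^2)^(3/2), u = 2ax + b
    u0 <- 2 * a * fit@domain[1] + b
    u1 <- 2 * a * fit@domain[2] + b
    wdt <- diff(fit@domain)
    if (wdt <= 0 || a == 0) return(0)
    abs(u1 / sqrt(1 + u1^2) - u0 / sqrt(1 + u0^2)) / wdt
  }
  straight <- abs(a) < .Machine$double.eps^0.5
  Kpx <- if (straight) 0 else switch(where,
    midpoint = Kfun(mean(fit@domain)),
    vertex   = abs(2 * a),
    mean_abs = meanAbs())
  K <- Kpx * perPx
  kma <- meanAbs() * perPx
  list(K = K,
       rho = if (K > 0) 1 / K else Inf,
       K_mean_abs = kma,
       neg_log_K = if (K > 0) -log(K, base = logBase) else NA_real_,
       straight = straight,
       where = where)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the phenotyping pipeline with their
#' defaults. A configuration serialises losslessly to YAML via
#' [writeConfig()] / [readConfig()].
#'
#' @param dpi scanner resolution (default 1200).
#' @param tileSize annotation tile side in pixels (default 2048).
#' @param minScore detection confidence threshold (default 0.4).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param criterion largest-component criterion (default `"area"`).
#' @param minBranchPx spur-pruning threshold in pixels (default 10).
#' @param curvatureAt curvature summary point (default `"midpoint"`).
#' @param logBase base of the negative-log curvature transform.
#' @param thinMethod thinning method (default `"k3m"`).
#' @param resamplePx polyline resampling step for length measurement.
#' @param tipCorrection extend the measured length by the distance-transform
#'   value at both skeleton tips, compensating the end retraction of thinning
#'   (default `TRUE`).
#' @param seed integer seed for stochastic helpers.
#' @return a named list with class `rootgrainConfig`.
#' @export
rootgrainConfig <- function(dpi = 1200, tileSize = 2048, minScore = 0.4,
                            connectivity = 8, criterion = "area",
                            minBranchPx = 10, curvatureAt = "midpoint",
                            logBase = exp(1), thinMethod = "k3m",
                            resamplePx = 5, tipCorrection = TRUE, seed = 1L) {
  structure(list(dpi = dpi, tileSize = tileSize, minScore = minScore,
                 connectivity = connectivity, criterion = criterion,
                 minBranchPx = minBranchPx, curvatureAt = curvatureAt,
                 logBase = logBase, thinMethod = thinMethod,
                 resamplePx = resamplePx, tipCorrection = tipCorrection,
                 seed = as.integer(seed)),
            class = "rootgrainConfig")
}

#' Phenotype a single root mask
#'
#' Full trait pipeline for one instance: largest-component selection, K3M
#' thinning, spur pruning, polyline ordering, then length (resampled chord
#' sum with tip correction), diameter statistics, areas and curvature.
#'
#' @param mask an [InstanceMask] or logical matrix.
#' @param scale a [ScaleModel].
#' @param config a [rootgrainConfig()].
#' @param timestamp optional acquisition day recorded in the result.
#' @return a list of class `RootPhenotype` with the trait fields.
#' @seealso [phenotypeBatch()]
#' @export
phenotypeInstance <- function(mask, scale = scaleModel(),
                              config = rootgrainConfig(), timestamp = NA) {
  m <- if (is(mask, "InstanceMask")) mask else instanceMask(mask)
  if (!any(m@pixels)) stop("empty mask", call. = FALSE)
  m <- largestComponent(m, connectivity = config$connectivity,
                        criterion = config$criterion)
  skel <- thinMask(m, method = config$thinMethod)
  skel <- pruneSpurs(skel, minBranchPx = config$minBranchPx)
  poly <- toPolyline(skel)
  rs <- resamplePolyline(poly, step = config$resamplePx)
  lengthMm <- rootLength(rs, scale)
  if (config$tipCorrection && nrow(poly) >= 2) {
    # the skeleton stops at the centre of each rounded tip; the remaining cap
    # extent is the local radius, EDT - 1 under the boundary-equals-1 EDT
    edt <- edtMask(m@pixels)
    tips <- poly[c(1, nrow(poly)), , drop = FALSE]
    lengthMm <- lengthMm +
      sum(pmax(edt[cbind(tips[, 2] + 1, tips[, 1] + 1)] - 1, 0)) * scale@mmPerPx
  }
  dia <- rootDiameters(m, skel, scale)
  ar <- rootAreas(m, lengthMm, dia[["avg"]], scale)
  curv <- if (nrow(poly) >= 3) {
    curvatureFromFit(fitQuadratic(poly), where = config$curvatureAt,
                     scale = scale, logBase = config$logBase)
  } else {
    list(K = 0, rho = Inf, K_mean_abs = 0, neg_log_K = NA_real_,
         straight = TRUE, where = config$curvatureAt)
  }
  structure(list(
    instance_id = m@instanceId, label = m@label, timestamp = timestamp,
    length_mm = lengthMm,
    avg_diameter_mm = dia[["avg"]], max_diameter_mm = dia[["max"]],
    min_diameter_mm = dia[["min"]],
    projected_area_mm2 = ar[["projected_mm2"]],
    cylindrical_surface_mm2 = ar[["cylindrical_mm2"]],
    curvature_per_mm = curv$K, radius_mm = curv$rho,
    curvature_mean_abs = curv$K_mean_abs, neg_log_curvature = curv$neg_log_K,
    straight = curv$straight), class = "RootPhenotype")
}

#' Phenotype a batch of root masks
#'
#' Runs [phenotypeInstance()] over a list of masks (or a directory of
#' single-object mask PNGs, see [readMask()]) and assembles one trait row per
#' instance. Per-instance failures are caught: the run continues and the
#' failed instance is recorded with `status` set to the error message.
#'
#' @param masks list of [InstanceMask] objects, or a directory path.
#' @param scale a [ScaleModel].
#' @param config a [rootgrainConfig()].
#' @param timestamps optional vector of acquisition days, recycled.
#' @return a data.frame with one row per instance and stable columns
#'   `instance_id, label, timestamp, length_mm, avg_diameter_mm,
#'   max_diameter_mm, min_diameter_mm, projected_area_mm2,
#'   cylindrical_surface_mm2, curvature_per_mm, radius_mm,
#'   curvature_mean_abs, neg_log_curvature, straight, status`.
#' @export
phenotypeBatch <- function(masks, scale = scaleModel(),
                           config = rootgrainConfig(), timestamps = NA) {
  if (is.character(masks) && length(masks) == 1) masks <- readMaskDir(masks)
  ts <- rep_len(timestamps, max(length(masks), 1L))
  cols <- c("instance_id", "label", "timestamp", "length_mm",
            "avg_diameter_mm", "max_diameter_mm", "min_diameter_mm",
            "projected_area_mm2", "cylindrical_surface_mm2",
            "curvature_per_mm", "radius_mm", "curvature_mean_abs",
            "neg_log_curvature", "straight", "status")
  rows <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    rows[[i]] <- tryCatch({
      ph <- phenotypeInstance(m, scale, config, timestamp = ts[i])
      cbind(as.data.frame(ph[setdiff(cols, "status")]), status = "ok")
    }, error = function(e) {
      data.frame(instance_id = if (is(m, "InstanceMask")) m@instanceId else i,
                 label = if (is(m, "InstanceMask")) m@label else NA_character_,
                 timestamp = ts[i], length_mm = NA_real_,
                 avg_diameter_mm = NA_real_, max_diameter_mm = NA_real_,
                 min_diameter_mm = NA_real_, projected_area_mm2 = NA_real_,
                 cylindrical_surface_mm2 = NA_real_, curvature_per_mm = NA_real_,
                 radius_mm = NA_real_, curvature_mean_abs = NA_real_,
                 neg_log_curvature = NA_real_, straight = NA,
                 status = conditionMessage(e))
    })
  }
  if (!length(rows)) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  do.call(rbind, rows)
}
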