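# Seeded generator of synthetic root scenes with analytic ground truth.
#
# The generator rasterises a parametric medial curve (straight segment,
# circular arc, or quadratic) at sub-pixel steps and dilates it with a disc
# brush to the requested diameter, so every instance carries exact ground
# truth: arc length of the medial curve, the realised (odd) brush diameter,
# and the analytic curvature of the curve. It emulates the geometry of
# scanned in situ root images - elongated, curved, possibly overlapping
# instances on a speckled soil-like background - not their photometric detail.

#' Parameters of one synthetic root
#'
#' @param curve a list describing the medial curve: `list(type = "straight")`,
#'   `list(type = "arc", radiusMm = 15)`, or
#'   `list(type = "quadratic", a = 0.02, b = 0, c = 0)` (coefficients in mm
#'   units, `y = a x^2 + b x + c`).
#' @param lengthMm arc length of the medial curve in mm.
#' @param diameterMm root diameter in mm (rounded to an odd pixel count when
#'   rasterised).
#' @param pattern `"curved"` or `"straight"` growth pattern tag.
#' @param seed integer seed fixing all randomness tied to this root.
#' @return a list of class `RootParams`.
#' @export
rootParams <- function(curve = list(type = "straight"), lengthMm = 10,
                       diameterMm = 0.5, pattern = "straight", seed = 1L) {
  stopifnot(lengthMm > 0, diameterMm > 0)
  structure(list(curve = curve, lengthMm = lengthMm, diameterMm = diameterMm,
                 pattern = pattern, seed = as.integer(seed)),
            class = "RootParams")
}

# medial curve as a function of arc length t in [0, L], in mm, plus the
# analytic curvature at the arc midpoint
medialCurve <- function(curve, lengthMm) {
  switch(curve$type,
    straight = list(
      f = function(t) cbind(t, 0),
      K = 0
    ),
    arc = {
      R <- curve$radiusMm
      stopifnot(R > 0)
      list(
        f = function(t) cbind(R * sin(t / R), R * (1 - cos(t / R))),
        K = 1 / R
      )
    },
    quadratic = {
      a <- curve$a
      b <- if (is.null(curve$b)) 0 else curve$b
      cc <- if (is.null(curve$c)) 0 else curve$c
      ds <- function(x) sqrt(1 + (2 * a * x + b)^2)
      arcLen <- function(x) integrate(ds, 0, x, rel.tol = 1e-10)$value
      # invert arc length numerically on a fine grid
      xmax <- lengthMm  # upper bound; refined below
      while (arcLen(xmax) < lengthMm) xmax <- xmax * 2
      xs <- seq(0, xmax, length.out = 4096)
      ss <- c(0, cumsum(ds((xs[-1] + xs[-length(xs)]) / 2) * diff(xs)))
      xOf <- function(t) approx(ss, xs, xout = pmin(t, max(ss)))$y
      xm <- xOf(lengthMm / 2)
      list(
        f = function(t) { x <- xOf(t); cbind(x, a * x^2 + b * x + cc) },
        K = abs(2 * a) / (1 + (2 * a * xm + b)^2)^1.5
      )
    },
    stop("unknown curve type: ", curve$type))
}

#' Rasterise one synthetic root
#'
#' Renders the root's medial curve onto a pixel canvas and dilates it to the
#' requested diameter. The returned ground truth carries the analytic medial
#' arc length, the realised diameter (odd pixel brush width in mm) and the
#' analytic curvature, against which the measurement pipeline can be
#' validated.
#'
#' @param params a [rootParams()].
#' @param scale a [ScaleModel].
#' @param canvas optional `c(height, width)` canvas in pixels; by default the
#'   canvas is sized to fit the root with a margin. A root that does not fit
#'   a supplied canvas is an error.
#' @param originPx 0-based (x, y) pixel position of the curve start.
#' @param angle rotation of the curve in radians (0 = growing along +x).
#' @return a list with elements `mask` ([InstanceMask]) and `truth` (list
#'   with `length_mm`, `diameter_mm`, `curvature_per_mm`, `pattern`).
#' @examples
#' r <- genRoot(rootParams(list(type = "arc", radiusMm = 20), lengthMm = 10),
#'              scaleModel(300))
#' r$truth$curvature_per_mm   # 1/20
#' @export
genRoot <- function(params, scale = scaleModel(), canvas = NULL,
                    originPx = NULL, angle = 0) {
  pxPerMm <- 1 / scale@mmPerPx
  # the stated length is tip-to-tip: the medial curve is trimmed by one cap
  # radius at each end so the dilated (rounded) tips land on the stated length
  if (params$lengthMm <= 2 * params$diameterMm)
    stop("root length must exceed twice its diameter", call. = FALSE)
  Lc <- params$lengthMm - params$diameterMm
  crv <- medialCurve(params$curve, Lc)
  step <- 0.25 * scale@mmPerPx           # ~0.25 px arc-length steps
  t <- seq(0, Lc, by = step)
  ptsMm <- crv$f(t)
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  ptsPx <- ptsMm %*% t(rot) * pxPerMm
  dPx <- max(1L, 2L * floor(params$diameterMm * pxPerMm / 2) + 1L)
  rad <- (dPx - 1L) / 2L
  if (is.null(originPx)) {
    originPx <- c(-min(ptsPx[, 1]) + rad + 2, -min(ptsPx[, 2]) + rad + 2)
  }
  ptsPx <- sweep(ptsPx, 2, -originPx)
  if (is.null(canvas)) {
    canvas <- c(ceiling(max(ptsPx[, 2]) + rad + 3),
                ceiling(max(ptsPx[, 1]) + rad + 3))
  }
  xs <- round(ptsPx[, 1]) + 1L
  ys <- round(ptsPx[, 2]) + 1L
  if (any(xs < rad + 1 | xs > canvas[2] - rad | ys < rad + 1 | ys > canvas[1] - rad))
    stop("root does not fit the canvas", call. = FALSE)
  # Isotropic band: threshold the distance to the medial curve at the cap
  # radius. The distance field is evaluated on a 2x supersampled grid so the
  # curve-rasterisation ripple stays well below half a pixel; the 0.75 px
  # margin keeps the axial cross-section at exactly dPx pixels while oblique
  # cross-sections realise the same width (a binary disc-brush dilation would
  # draw diagonals visibly too thin).
  if (dPx > 1) {
    ys2 <- pmax(1L, round(ptsPx[, 2] * 2) + 1L)
    xs2 <- pmax(1L, round(ptsPx[, 1] * 2) + 1L)
    notCurve <- matrix(1, 2L * canvas[1], 2L * canvas[2])
    notCurve[cbind(ys2, xs2)] <- 0
    distC <- as.matrix(EBImage::distmap(notCurve, metric = "euclidean"))
    sub <- distC[seq(1L, 2L * canvas[1], by = 2L),
                 seq(1L, 2L * canvas[2], by = 2L)] / 2
    m <- sub <= rad + 0.75
  } else {
    m <- matrix(FALSE, canvas[1], canvas[2])
    m[cbind(ys, xs)] <- TRUE
  }
  list(
    mask = instanceMask(m, label = "lateral root", instanceId = params$seed),
    truth = list(length_mm = params$lengthMm,
                 diameter_mm = dPx * scale@mmPerPx,
                 curvature_per_mm = crv$K,
                 pattern = params$pattern)
  )
}

# sample per-root parameters for a scene; placement is retried to respect the
# overlap setting
sceneRootParams <- function(pattern) {
  if (pattern == "curved") {
    R <- runif(1, 8, 25)
    L <- runif(1, 6, min(14, 1.2 * R))
    rootParams(list(type = "arc", radiusMm = R), lengthMm = L,
               diameterMm = runif(1, 0.35, 0.7), pattern = "curved")
  } else {
    rootParams(list(type = "straight"), lengthMm = runif(1, 4, 10),
               diameterMm = runif(1, 0.35, 0.7), pattern = "straight")
  }
}

#' Generate a synthetic root scene
#'
#' Composes several roots on a speckled soil-like background, with per-root
#' ground truth, per-instance masks, and a polygon annotation document (one
#' polygon per instance, traced from the mask contour). Overlapping
#' placements are admitted with probability `overlapProb`, emulating crossing
#' roots; overlap is resolved in favour of the later-drawn root in the
#' composite image only - instance masks stay separate.
#'
#' @param nRoots number of roots (>= 0).
#' @param patternMix probability that a root follows the curved pattern.
#' @param overlapProb probability that an overlapping placement is accepted.
#' @param noise speckle noise amplitude of the background in `[0, 1]`.
#' @param seed integer seed; fixes the whole scene.
#' @param scale a [ScaleModel]. The default desk-scale resolution (300 dpi)
#'   keeps canvases tractable while preserving the pixel-per-diameter regime
#'   of high-resolution scans.
#' @param canvasMm canvas size `c(height, width)` in mm.
#' @return a list of class `SceneGroundTruth` with elements `image` (numeric
#'   matrix in `[0, 1]`), `masks` (list of [InstanceMask]), `truth`
#'   (data.frame), `annotation` ([AnnotationDoc]), `dpi`, `seed`.
#' @export
genScene <- function(nRoots = 12, patternMix = 0.5, overlapProb = 0.2,
                     noise = 0.05, seed = 1L, scale = scaleModel(300),
                     canvasMm = c(40, 40)) {
  stopifnot(nRoots >= 0)
  set.seed(seed)
  pxPerMm <- 1 / scale@mmPerPx
  canvas <- round(canvasMm * pxPerMm)
  union <- matrix(FALSE, canvas[1], canvas[2])
  masks <- list()
  rows <- list()
  for (i in seq_len(nRoots)) {
    pattern <- if (runif(1) < patternMix) "curved" else "straight"
    pr <- sceneRootParams(pattern)
    pr$seed <- i
    placed <- NULL
    for (try in seq_len(60)) {
      ang <- runif(1, pi / 2 - 1.0, pi / 2 + 1.0)  # mostly downward growth
      org <- c(runif(1, 0.1, 0.9) * canvas[2], runif(1, 0.05, 0.6) * canvas[1])
      cand <- tryCatch(genRoot(pr, scale, canvas = canvas, originPx = org,
                               angle = ang),
                       error = function(e) NULL)
      if (is.null(cand)) next
      overlaps <- any(cand$mask@pixels & union)
      if (!overlaps || runif(1) < overlapProb) {
        placed <- cand
        break
      }
    }
    if (is.null(placed)) next
    id <- length(masks) + 1L
    placed$mask@instanceId <- id
    placed$mask@score <- round(runif(1, 0.5, 0.99), 3)
    masks[[id]] <- placed$mask
    union <- union | placed$mask@pixels
    rows[[id]] <- data.frame(instance_id = id,
                             label = placed$mask@label,
                             pattern = placed$truth$pattern,
                             length_mm = placed$truth$length_mm,
                             diameter_mm = placed$truth$diameter_mm,
                             curvature_per_mm = placed$truth$curvature_per_mm)
  }
  img <- matrix(pmin(pmax(0.15 + noise * rnorm(prod(canvas)), 0), 0.5),
                canvas[1], canvas[2])
  for (m in masks) img[m@pixels] <- 0.9
  shapes <- lapply(masks, function(m) shape(m@label, maskPolygon(m@pixels)))
  doc <- annotationDoc(shapes, imagePath = sprintf("scene_seed%d.png", seed),
                       imageHeight = canvas[1], imageWidth = canvas[2])
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(instance_id = integer(0), label = character(0),
               pattern = character(0), length_mm = numeric(0),
               diameter_mm = numeric(0), curvature_per_mm = numeric(0))
  structure(list(image = img, masks = masks, truth = truth, annotation = doc,
                 dpi = scale@dpi, seed = seed),
            class = "SceneGroundTruth")
}

# polygon outline of a mask: oriented contour, subsampled, 0-based (x, y)
maskPolygon <- function(pix, every = 4) {
  oc <- EBImage::ocontour(EBImage::Image(pix + 0))
  pts <- oc[[which.max(vapply(oc, nrow, numeric(1)))]]
  # EBImage images index dim1 = x; our matrices are [y, x], so swap back
  poly <- cbind(x = pts[, 2], y = pts[, 1])
  keep <- unique(c(seq(1, nrow(poly), by = every), nrow(poly)))
  poly[keep, , drop = FALSE]
}

#' Generate a synthetic time series of root growth
#'
#' Renders the same set of roots over consecutive acquisition days. Curved-
#' pattern roots elongate fast while their total bend angle grows slowly, so
#' the curvature `K = angle / length` decreases and `-log(K)` rises day by
#' day, matching the behaviour of roots that keep growing downward as they
#' bend. Straight-pattern roots elongate slowly at near-zero, near-constant
#' curvature. Per-day length increments are strictly larger for the curved
#' preset than the straight one.
#'
#' @param pattern `"curved"` or `"straight"`.
#' @param nDays number of acquisition days.
#' @param nRoots number of roots followed over time.
#' @param seed integer seed.
#' @param scale a [ScaleModel] (desk-scale default).
#' @return a list of per-day scenes; each element is a list with `day`,
#'   `masks`, `truth` (as in [genScene()], without the composite image).
#' @export
genTimeseries <- function(pattern = c("curved", "straight"), nDays = 8,
                          nRoots = 6, seed = 1L, scale = scaleModel(300)) {
  pattern <- match.arg(pattern)
  set.seed(seed + if (pattern == "curved") 0L else 10000L)
  curved <- pattern == "curved"
  L0 <- runif(nRoots, 3, 5)
  # curved roots elongate fast while their total bend angle grows slowly, so
  # K = angle/length falls and -log(K) rises; straight-pattern roots elongate
  # slowly (growth stagnates) at a fixed large bend radius, so their small
  # curvature barely changes
  rate <- if (curved) runif(nRoots, 2.5, 3.5) else runif(nRoots, 0.3, 0.7)
  phi0 <- if (curved) runif(nRoots, 0.5, 0.9) else rep(NA_real_, nRoots)
  dphi <- if (curved) runif(nRoots, 0.02, 0.06) else rep(0, nRoots)
  R0 <- if (curved) rep(NA_real_, nRoots) else runif(nRoots, 80, 200)
  dia0 <- runif(nRoots, 0.4, 0.6)
  drate <- if (curved) runif(nRoots, 0.01, 0.03) else runif(nRoots, -0.01, 0)
  out <- vector("list", nDays)
  for (d in seq_len(nDays)) {
    masks <- list(); rows <- list()
    for (i in seq_len(nRoots)) {
      L <- L0[i] + rate[i] * (d - 1)
      R <- if (curved) L / (phi0[i] + dphi[i] * (d - 1)) else R0[i]
      dia <- max(0.3, dia0[i] + drate[i] * (d - 1))
      pr <- rootParams(list(type = "arc", radiusMm = R), lengthMm = L,
                       diameterMm = dia,
                       pattern = if (curved) "curved" else "straight",
                       seed = i)
      g <- genRoot(pr, scale)
      g$mask@instanceId <- i
      masks[[i]] <- g$mask
      rows[[i]] <- data.frame(instance_id = i, day = d,
                              pattern = g$truth$pattern,
                              length_mm = g$truth$length_mm,
                              diameter_mm = g$truth$diameter_mm,
                              curvature_per_mm = g$truth$curvature_per_mm)
    }
    out[[d]] <- list(day = d, masks = masks, truth = do.call(rbind, rows))
  }
  out
}
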