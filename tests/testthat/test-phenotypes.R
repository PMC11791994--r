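# Per-root trait computation: length, diameter, area, curvature.

test_that("root length follows the chain-step convention and the dpi scale", {
  sc <- scaleModel(1200)
  horiz <- cbind(x = 0:100, y = rep(0, 101))
  expect_equal(rootLength(horiz, sc), 100 * 25.4 / 1200, tolerance = 1e-12)
  diag <- cbind(x = 0:10, y = 0:10)
  expect_equal(rootLength(diag, sc), 10 * sqrt(2) * 25.4 / 1200,
               tolerance = 1e-12)
  expect_warning(len1 <- rootLength(cbind(x = 1, y = 1), sc), "fewer than 2")
  expect_equal(len1, 0)
})

test_that("pipeline length tracks the analytic arc length of a parabolic root", {
  sc <- scaleModel(1200)
  a <- 0.02
  g <- genRoot(rootParams(list(type = "quadratic", a = a, b = 0, c = 0),
                          lengthMm = 12, diameterMm = 0.5, seed = 1), sc,
               angle = 0.4)
  ph <- phenotypeInstance(g$mask, sc)
  expect_lt(abs(ph$length_mm - g$truth$length_mm) / g$truth$length_mm, 0.02)
})

test_that("diameters follow the distance-transform convention", {
  sc1 <- scaleModel(25.4)   # 1 mm per px: diameters in px numerically
  # horizontal strip of height 5: interior diameter exactly 5 px
  strip <- matrix(FALSE, 11, 40); strip[4:8, 2:39] <- TRUE
  skl <- matrix(FALSE, 11, 40); skl[6, 4:37] <- TRUE
  dia <- rootDiameters(strip, new("Skeleton", pixels = skl, method = "k3m"),
                       sc1, excludeTips = FALSE)
  # compare against the brute-force nearest-background oracle on interior pixels
  edtOracle <- bruteEDT(strip)
  expect_equal(unname(dia[["max"]]), max(2 * edtOracle[skl] - 1))
  interior <- 2 * edtOracle[6, 10:30] - 1
  expect_true(all(interior == 5))
  expect_equal(unname(dia[["max"]]), 5)

  # width-1 line has diameter 1
  ln <- matrix(FALSE, 5, 15); ln[3, 3:13] <- TRUE
  sk1 <- matrix(FALSE, 5, 15); sk1[3, 5:11] <- TRUE
  d1 <- rootDiameters(ln, new("Skeleton", pixels = sk1, method = "k3m"), sc1,
                      excludeTips = FALSE)
  expect_equal(unname(d1[["avg"]]), 1)

  expect_error(rootDiameters(strip, new("Skeleton",
                                        pixels = matrix(FALSE, 11, 40),
                                        method = "k3m")), "empty skeleton")
})

test_that("synthetic constant-diameter roots are recovered within 5 percent", {
  sc <- scaleModel(1200)
  for (seed in 1:6) {
    set.seed(seed)
    g <- genRoot(rootParams(list(type = "straight"), lengthMm = 9,
                            diameterMm = runif(1, 0.4, 0.7), seed = seed),
                 sc, angle = runif(1, 0, pi))
    ph <- phenotypeInstance(g$mask, sc)
    expect_lt(abs(ph$avg_diameter_mm - g$truth$diameter_mm) /
                g$truth$diameter_mm, 0.05)
    # avg must sit between min and max
    expect_lte(ph$min_diameter_mm, ph$avg_diameter_mm)
    expect_lte(ph$avg_diameter_mm, ph$max_diameter_mm)
  }
})

test_that("dilating a mask never decreases the average diameter", {
  sc <- scaleModel(300)
  g <- genRoot(rootParams(list(type = "arc", radiusMm = 15), lengthMm = 10,
                          diameterMm = 0.8, seed = 1), sc)
  skel <- pruneSpurs(thinMask(g$mask))
  d0 <- rootDiameters(g$mask, skel, sc)[["avg"]]
  grown <- as.matrix(EBImage::dilate(maskPixels(g$mask) * 1,
                                     EBImage::makeBrush(3, "box"))) > 0
  d1 <- rootDiameters(grown, skel, sc)[["avg"]]
  expect_gte(d1, d0)
})

test_that("areas combine pixel counts and the cylinder model", {
  sc1 <- scaleModel(25.4)   # 1 mm per px
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  ar <- rootAreas(sq, lengthMm = 10, avgDiameterMm = 1, sc1)
  expect_equal(unname(ar[["projected_mm2"]]), 100)
  expect_equal(unname(ar[["cylindrical_mm2"]]), pi * 1 * 10)
  # projected area of a synthetic root is close to length x diameter
  sc <- scaleModel(1200)
  g <- genRoot(rootParams(list(type = "straight"), 10, 1, seed = 1), sc)
  expect_lt(abs(sum(maskPixels(g$mask)) -
                  (10 / sc@mmPerPx) * (1 / sc@mmPerPx)) /
              ((10 / sc@mmPerPx) * (1 / sc@mmPerPx)), 0.03)
})

test_that("quadratic fits recover exact and noisy coefficients", {
  x <- seq(-10, 10, length.out = 60)
  f <- fitQuadratic(cbind(x = x, y = 2 * x^2 + 3 * x + 1), rotate = FALSE)
  expect_equal(c(f@a, f@b, f@c), c(2, 3, 1), tolerance = 1e-9)

  # collinear points give a = 0
  g <- fitQuadratic(cbind(x = x, y = 0.5 * x + 2), rotate = FALSE)
  expect_equal(g@a, 0, tolerance = 1e-10)

  # noisy parabola matches an independently coded normal-equations solver
  set.seed(11)
  xn <- seq(-8, 8, length.out = 200)
  yn <- 1.5 * xn^2 - 2 * xn + 4 + rnorm(200, sd = 0.5)
  fit <- fitQuadratic(cbind(x = xn, y = yn), rotate = FALSE)
  ref <- normalEqFit(xn, yn)
  expect_equal(c(fit@c, fit@b, fit@a), unname(ref), tolerance = 1e-9)

  expect_error(fitQuadratic(cbind(x = rep(1, 5), y = rep(2, 5))), "degenerate")
  expect_error(fitQuadratic(cbind(x = 1:2, y = 1:2)), "at least 3")
})

test_that("curvature follows the plane-curve formula with rho = 1/K", {
  # straight line: K = 0, infinite radius, flagged straight, no crash
  f0 <- fitQuadratic(cbind(x = 1:20, y = rep(2, 20)), rotate = FALSE)
  c0 <- curvatureFromFit(f0, scale = NULL)
  expect_equal(c0$K, 0)
  expect_equal(c0$rho, Inf)
  expect_true(c0$straight)
  expect_true(is.na(c0$neg_log_K))

  # y = 0.5 x^2 at the vertex: K = 2a = 1, rho = 1
  x <- seq(-5, 5, by = 0.1)
  f1 <- fitQuadratic(cbind(x = x, y = 0.5 * x^2), rotate = FALSE)
  c1 <- curvatureFromFit(f1, "vertex", scale = NULL)
  expect_equal(c1$K, 1, tolerance = 1e-9)
  expect_equal(c1$rho, 1, tolerance = 1e-9)

  # circle of radius 50 px sampled on a 30-degree arc: K within 5% of 1/50
  th <- seq(-pi / 12, pi / 12, length.out = 200)
  circ <- cbind(x = 50 * sin(th), y = 50 * (1 - cos(th)))
  f2 <- fitQuadratic(circ)
  c2 <- curvatureFromFit(f2, "midpoint", scale = NULL)
  expect_lt(abs(c2$K - 1 / 50) / (1 / 50), 0.05)

  # rho * K = 1 holds exactly for every K > 0 output
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(1, 0.005, 0.1)   # elongated, root-like curves
    xx <- seq(-6, 6, length.out = 80)
    cf <- curvatureFromFit(fitQuadratic(cbind(x = xx, y = a * xx^2)),
                           sample(c("midpoint", "vertex", "mean_abs"), 1),
                           scale = NULL)
    expect_gt(cf$K, 0)
    expect_equal(cf$rho * cf$K, 1, tolerance = 1e-12)
  }
})

test_that("curvature is invariant under rigid motions of the polyline", {
  th <- seq(-pi / 8, pi / 8, length.out = 150)
  base <- cbind(x = 80 * sin(th), y = 80 * (1 - cos(th)))
  K0 <- curvatureFromFit(fitQuadratic(base), scale = NULL)$K
  for (seed in 1:10) {
    set.seed(seed)
    phi <- runif(1, 0, 2 * pi); tx <- runif(1, -500, 500); ty <- runif(1, -500, 500)
    Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    moved <- t(Rm %*% t(base)) + matrix(c(tx, ty), nrow(base), 2, byrow = TRUE)
    K1 <- curvatureFromFit(fitQuadratic(moved), scale = NULL)$K
    expect_equal(K1, K0, tolerance = 1e-6)
  }
})

test_that("mean absolute curvature agrees with numerical integration", {
  f <- fitQuadratic(cbind(x = seq(-4, 7, 0.05),
                          y = 0.3 * seq(-4, 7, 0.05)^2), rotate = FALSE)
  cm <- curvatureFromFit(f, "mean_abs", scale = NULL)
  Kf <- function(x) abs(2 * f@a) / (1 + (2 * f@a * x + f@b)^2)^1.5
  num <- integrate(Kf, f@domain[1], f@domain[2])$value / diff(f@domain)
  expect_equal(cm$K, num, tolerance = 1e-6)
})

test_that("batch phenotyping yields one stable row per instance", {
  emptyTab <- phenotypeBatch(list())
  expect_equal(nrow(emptyTab), 0)
  expect_true(all(c("instance_id", "length_mm", "curvature_per_mm", "status")
                  %in% names(emptyTab)))

  sc <- scaleModel(300)
  scn <- genScene(nRoots = 6, seed = 3, scale = sc)
  tab <- phenotypeBatch(scn$masks, sc)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$length_mm > 0))

  # a failing instance is recorded, the batch continues
  bad <- instanceMask(matrix(FALSE, 5, 5), instanceId = 99L)
  tab2 <- phenotypeBatch(c(scn$masks[1], list(bad)), sc)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$status[1], "ok")
  expect_match(tab2$status[2], "empty")
})
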