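# Thinning, spur pruning and polyline extraction.

skeletonPostconditions <- function(sk, mask) {
  pix <- skeletonPixels(sk)
  expect_false(hasThickSquare(pix))                    # one pixel wide
  expect_true(all(!pix | mask))                        # subset of foreground
  expect_equal(max(floodLabelOracle(pix, 8)),
               max(floodLabelOracle(mask, 8)))         # component conservation
}

test_that("thinning meets its postconditions on canonical shapes", {
  # a 1-pixel line is already thin: fixpoint
  l <- matrix(FALSE, 5, 15); l[3, 3:13] <- TRUE
  expect_identical(skeletonPixels(thinMask(l)), l)

  # empty mask -> empty skeleton
  expect_equal(sum(skeletonPixels(thinMask(matrix(FALSE, 4, 4)))), 0)

  # filled 20 x 5 rectangle -> single width-1 path along the long medial axis
  m <- matrix(FALSE, 9, 24); m[3:7, 3:22] <- TRUE
  for (method in c("k3m", "zhangsuen")) {
    sk <- thinMask(m, method = method)
    skeletonPostconditions(sk, m)
    ep <- endpoints(sk)
    expect_equal(nrow(ep), 2)
    rows <- which(skeletonPixels(sk), arr.ind = TRUE)[, 1]
    expect_true(all(abs(rows - 5) <= 1))   # on the long medial axis
    chain <- sum(sqrt(rowSums(diff(toPolyline(sk))^2)))
    expect_gte(chain, 14); expect_lte(chain, 20)
  }
})

test_that("thinning is idempotent and topology-preserving on random blobs", {
  for (seed in 1:12) {
    pix <- largestComponent(randomBlobMask(seed))
    sk <- thinMask(pix)
    skeletonPostconditions(sk, pix)
    again <- thinMask(skeletonPixels(sk))
    expect_identical(skeletonPixels(again), skeletonPixels(sk))
  }
  # a ring keeps its hole: skeleton stays cyclic with no endpoints
  r <- matrix(FALSE, 14, 14); r[3:11, 3:11] <- TRUE; r[6:8, 6:8] <- FALSE
  sk <- thinMask(r)
  expect_equal(nrow(endpoints(sk)), 0)
  expect_equal(max(floodLabelOracle(skeletonPixels(sk), 8)), 1)
})

test_that("multi-component masks are rejected with guidance", {
  m <- matrix(FALSE, 10, 10); m[2, 2] <- TRUE; m[8, 8] <- TRUE
  expect_error(thinMask(m), "largestComponent")
})

test_that("spur pruning removes short side branches only", {
  # T-shape: 15-px bar with a 3-px stub
  t <- matrix(FALSE, 10, 17)
  t[5, 2:16] <- TRUE
  t[6:8, 9] <- TRUE
  sk <- new("Skeleton", pixels = t, method = "k3m")
  pruned <- pruneSpurs(sk, minBranchPx = 5)
  expect_equal(nrow(endpoints(pruned)), 2)
  expect_equal(sum(skeletonPixels(pruned)), 15)

  # spur-free path unchanged; zero threshold is the identity
  p <- matrix(FALSE, 6, 12); p[3, 2:11] <- TRUE
  skp <- new("Skeleton", pixels = p, method = "k3m")
  expect_identical(skeletonPixels(pruneSpurs(skp, 5)), p)
  expect_identical(skeletonPixels(pruneSpurs(sk, 0)), t)

  # pruning never increases pixel count
  for (seed in 1:8) {
    pix <- largestComponent(randomBlobMask(seed))
    sk <- thinMask(pix)
    expect_lte(sum(skeletonPixels(pruneSpurs(sk, 6))),
               sum(skeletonPixels(sk)))
  }
})

test_that("polylines traverse the longest endpoint-to-endpoint geodesic", {
  # straight 10-pixel line: ordered, monotone in x
  l <- matrix(FALSE, 5, 14); l[3, 3:12] <- TRUE
  pl <- toPolyline(new("Skeleton", pixels = l, method = "k3m"))
  expect_equal(nrow(pl), 10)
  expect_true(all(diff(pl[, 1]) == 1) || all(diff(pl[, 1]) == -1))

  # L-shaped 15-pixel path: all pixels traversed endpoint to endpoint
  L <- matrix(FALSE, 12, 12)
  L[2:9, 3] <- TRUE; L[9, 4:10] <- TRUE
  pl <- toPolyline(new("Skeleton", pixels = L, method = "k3m"))
  expect_equal(nrow(pl), 15)
  expect_true(all(abs(diff(pl[, 1])) <= 1 & abs(diff(pl[, 2])) <= 1))
  expect_equal(nrow(unique(pl)), 15)

  # Y-shape, arms 12/12/4: the path covers the two long arms and ignores the
  # short one; cross-checked against the brute-force all-pairs oracle
  y <- matrix(FALSE, 30, 30)
  y[15, 2:14] <- TRUE                       # west arm
  for (i in 1:12) y[15 + i, 14 + i] <- TRUE # south-east arm
  for (i in 1:4) y[15 - i, 14 + i] <- TRUE  # short north-east arm
  y[15, 14] <- TRUE
  skY <- new("Skeleton", pixels = y, method = "k3m")
  pl <- toPolyline(skY)
  orc <- geodesicOracle(y)
  dEnds <- orc$D[orc$ends, orc$ends]
  expect_equal(sum(sqrt(rowSums(diff(pl)^2))), max(dEnds), tolerance = 1e-9)
  # short arm pixels are not on the path
  expect_false(any(pl[, 2] < 14 & pl[, 1] > 14))

  # closed loop -> explicit error
  ring <- matrix(FALSE, 14, 14); ring[3:11, 3:11] <- TRUE; ring[6:8, 6:8] <- FALSE
  skr <- thinMask(ring)
  expect_error(toPolyline(skr), "cyclic skeleton")
})

test_that("skeletons of synthetic roots stay within 1 px of the true curve", {
  sc <- scaleModel(300)
  pxPerMm <- 1 / sc@mmPerPx
  for (seed in 1:5) {
    set.seed(seed)
    R <- runif(1, 10, 25)
    ang <- runif(1, 0, pi / 2)
    org <- c(150, 150)
    g <- genRoot(rootParams(list(type = "arc", radiusMm = R), lengthMm = 10,
                            diameterMm = 0.8, seed = seed), sc,
                 canvas = c(400, 400), originPx = org, angle = ang)
    sk <- pruneSpurs(thinMask(g$mask))
    pl <- toPolyline(sk)
    # analytic medial curve in the same canvas frame
    tt <- seq(0, 10 - 0.8, length.out = 3000)
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    crv <- cbind(R * sin(tt / R), R * (1 - cos(tt / R))) %*% t(rot) * pxPerMm
    crv <- sweep(crv, 2, -org)
    dmin <- vapply(seq_len(nrow(pl)), function(i)
      sqrt(min((crv[, 1] - pl[i, 1])^2 + (crv[, 2] - pl[i, 2])^2)), numeric(1))
    expect_lt(mean(dmin), 1)
  }
})
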