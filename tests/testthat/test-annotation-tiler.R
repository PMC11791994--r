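# Tiling of polygon annotation documents.

test_that("faithful mode reproduces the published vertex-deletion trace", {
  # square at (2000,2000)-(2100,2100): after the (0,0)-origin shift with
  # s = 2048, the two x = 2100 vertices are outside, 2 vertices remain, and
  # the shape is deleted
  sq <- shape("lateral root", cbind(c(2000, 2100, 2100, 2000),
                                    c(2000, 2000, 2100, 2100)))
  doc <- annotationDoc(list(sq), "scan.png", 4096, 4096)
  out <- tileAnnotation(doc, tileSpec(2048), "faithful")
  expect_length(docShapes(out), 0)
  expect_equal(unname(imageSize(out)), c(2048, 2048))

  # a polygon fully inside the tile at origin (0,0) is untouched
  tri <- shape("primary root", cbind(c(10, 500, 300), c(10, 40, 900)))
  doc2 <- annotationDoc(list(tri), "scan.png", 1000, 1000)
  out2 <- tileAnnotation(doc2, tileSpec(2048), "faithful")
  expect_equal(docShapes(out2)[[1]]$points, tri$points)

  # the printed boundary test is strict: x = 0 and x = s survive
  edge <- shape("root", cbind(c(0, 2048, 1000), c(0, 0, 1000)))
  doc3 <- annotationDoc(list(edge), "scan.png", 4096, 4096)
  out3 <- tileAnnotation(doc3, tileSpec(2048), "faithful")
  expect_length(docShapes(out3), 1)

  # shapes left with <= 2 points are deleted even if partially inside
  two <- shape("root", cbind(c(10, 20, 3000), c(10, 20, 3000)))
  out4 <- tileAnnotation(annotationDoc(list(two), "s.png", 4096, 4096),
                         tileSpec(2048), "faithful")
  expect_length(docShapes(out4), 0)
})

test_that("faithful mode shifts points by the per-tile origin", {
  tri <- shape("root", cbind(c(2100, 2500, 2300), c(2100, 2150, 2600)))
  doc <- annotationDoc(list(tri), "scan.png", 4096, 4096)
  tl <- tileSpec(2048, row = 1, col = 1)
  out <- tileAnnotation(doc, tl, "faithful")
  expect_equal(docShapes(out)[[1]]$points,
               tri$points - rep(2048, each = 3))
})

test_that("faithful mode never gains vertices and yields an origin-shifted subset", {
  for (seed in 1:20) {
    doc <- randomPolyScene(seed)
    for (r in 0:1) for (cl in 0:1) {
      tl <- tileSpec(150, row = r, col = cl)
      out <- tileAnnotation(doc, tl, "faithful")
      inShapes <- docShapes(doc); outShapes <- docShapes(out)
      expect_lte(length(outShapes), length(inShapes))
      for (sh in outShapes) {
        expect_gte(nrow(sh$points), 3)
        # every output vertex, shifted back, is an input vertex of some shape
        restored <- sweep(sh$points, 2, -c(tl$origin[["ox"]], tl$origin[["oy"]]))
        allIn <- do.call(rbind, lapply(inShapes, `[[`, "points"))
        for (i in seq_len(nrow(restored))) {
          d <- abs(allIn[, 1] - restored[i, 1]) + abs(allIn[, 2] - restored[i, 2])
          expect_lt(min(d), 1e-9)
        }
      }
    }
  }
})

test_that("clip mode intersects polygons with the tile window", {
  sq <- shape("root", cbind(c(2000, 2100, 2100, 2000),
                            c(2000, 2000, 2100, 2100)))
  doc <- annotationDoc(list(sq), "scan.png", 4096, 4096)
  out <- tileAnnotation(doc, tileSpec(2048), "clip")
  expect_length(docShapes(out), 1)
  pts <- docShapes(out)[[1]]$points
  expect_true(all(pts >= 0 & pts <= 2048))
  # the clipped square is the 48 x 48 corner piece
  expect_equal(sort(unique(pts[, 1])), c(2000, 2048))

  for (seed in 1:15) {
    doc <- randomPolyScene(seed)
    out <- tileAnnotation(doc, tileSpec(150, 1, 1), "clip")
    for (sh in docShapes(out))
      expect_true(all(sh$points >= -1e-9 & sh$points <= 150 + 1e-9))
  }
})

test_that("tile grids cover the image with ceiling-division counts", {
  doc <- annotationDoc(list(shape("r", cbind(c(1, 50, 50), c(1, 1, 50)))),
                       "scan.png", 4096, 4096)
  expect_length(tileGrid(doc, NULL, s = 2048), 4)

  # full-scan geometry: 10200 x 14039 at s = 2048 -> 5 x 7 grid
  doc2 <- annotationDoc(list(shape("r", cbind(c(1, 50, 50), c(1, 1, 50)))),
                        "scan.png", 14039, 10200)
  expect_length(tileGrid(doc2, NULL, s = 2048), 35)

  # a polygon spanning two tiles appears in both tiles' documents
  span <- shape("root", cbind(c(100, 400, 400, 100), c(100, 100, 120, 120)))
  doc3 <- annotationDoc(list(span), "scan.png", 256, 512)
  tiles <- tileGrid(doc3, NULL, s = 256, mode = "clip")
  withShape <- vapply(tiles, function(t) length(docShapes(t$doc)) > 0, logical(1))
  expect_equal(sum(withShape), 2)

  # tile names encode the grid position
  expect_true(all(grepl("_r[0-9]+_c[0-9]+$", vapply(tiles, `[[`, "", "name"))))
})

test_that("edge tiles are padded to s x s with background", {
  img <- matrix(runif(100 * 80), 100, 80)
  doc <- annotationDoc(list(shape("r", cbind(c(1, 5, 5), c(1, 1, 5)))),
                       "x.png", 100, 80)
  tiles <- tileGrid(doc, img, s = 64)
  expect_length(tiles, 4)
  expect_equal(dim(tiles[[4]]$image), c(64, 64))
  expect_equal(tiles[[4]]$image[40, 20], 0)  # padded region
  expect_equal(tiles[[1]]$image, img[1:64, 1:64])
})

test_that("image re-encoding round-trips and defaults to null imageData", {
  img <- matrix(sample(0:255, 64, replace = TRUE) / 255, 8, 8)  # 8-bit exact
  b64 <- reencodeTileImage(img)
  expect_equal(decodeTileImage(b64), img, tolerance = 1e-9)
  expect_false(grepl("\n", b64))

  # frozen golden value for a deterministic 1x1 black PNG encoding
  expect_identical(
    reencodeTileImage(matrix(0, 1, 1)),
    "iVBORw0KGgoAAAANSUhEUgAAAAEAAAABCAAAAAA6fptVAAAACklEQVQImWNgAAAAAgAB9HFkpgAAAABJRU5ErkJggg==")

  doc <- annotationDoc(list(shape("r", cbind(c(1, 5, 5), c(1, 1, 5)))),
                       "x.png", 8, 8)
  plain <- tileAnnotation(doc, tileSpec(8), "faithful")
  expect_length(plain@imageData, 0)         # null unless re-encoding requested
  rich <- tileAnnotation(doc, tileSpec(8), "faithful", imageData = b64)
  expect_identical(rich@imageData, b64)
})

test_that("malformed inputs raise named errors", {
  f <- tempfile(fileext = ".json")
  writeLines('{"shapes": [], "imagePath": "x.png", "imageHeight": 10, "imageWidth": 10}', f)
  expect_error(readAnnotation(f), "imageData")
  expect_error(tileSpec(-5), "positive")
  doc <- annotationDoc(list(), "x.png", 10, 10)
  img <- matrix(0, 20, 10)
  expect_error(tileGrid(doc, img, s = 8), "does not match")
})
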