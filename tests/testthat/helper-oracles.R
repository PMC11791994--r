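# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (igraph, EBImage) used in R/.

# queue-based flood-fill component labelling
floodLabelOracle <- function(pix, connectivity = 8) {
  nr <- nrow(pix); nc <- ncol(pix)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!pix[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            pix[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# largest-component area by the flood-fill oracle
largestAreaOracle <- function(pix, connectivity = 8) {
  lab <- floodLabelOracle(pix, connectivity)
  if (max(lab) == 0L) return(0L)
  max(tabulate(lab[lab > 0L]))
}

# O(n^2) nearest-background distance (tiny fixtures only)
bruteEDT <- function(pix) {
  bg <- which(!pix, arr.ind = TRUE)
  fg <- which(pix, arr.ind = TRUE)
  out <- matrix(0, nrow(pix), ncol(pix))
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}

# all-pairs longest geodesic between endpoints of a tiny skeleton, by
# Dijkstra-style relaxation written out directly
geodesicOracle <- function(pix) {
  xy <- which(pix, arr.ind = TRUE)  # rows = (y, x)
  n <- nrow(xy)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dy <- abs(xy[i, 1] - xy[j, 1]); dx <- abs(xy[i, 2] - xy[j, 2])
    if (i == j) D[i, j] <- 0
    else if (dy <= 1 && dx <= 1) D[i, j] <- sqrt(dy + dx)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  deg <- sapply(seq_len(n), function(i)
    sum(abs(xy[, 1] - xy[i, 1]) <= 1 & abs(xy[, 2] - xy[i, 2]) <= 1) - 1)
  ends <- which(deg == 1)
  list(xy = xy, D = D, ends = ends)
}

# normal-equations least squares for y = a x^2 + b x + c
normalEqFit <- function(x, y) {
  X <- cbind(1, x, x^2)
  sol <- solve(crossprod(X), crossprod(X, y))
  c(cc = sol[1], b = sol[2], a = sol[3])
}

# random multi-blob mask for property tests
randomBlobMask <- function(seed, nr = 40, nc = 40, nBlobs = 3) {
  set.seed(seed)
  pix <- matrix(FALSE, nr, nc)
  for (b in seq_len(nBlobs)) {
    cy <- sample(5:(nr - 5), 1); cx <- sample(5:(nc - 5), 1)
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    pix[max(1, cy - h):min(nr, cy + h), max(1, cx - w):min(nc, cx + w)] <- TRUE
  }
  pix
}

# random polygon scene for tiler property tests
randomPolyScene <- function(seed, W = 300, H = 300, nShapes = 4) {
  set.seed(seed)
  shapes <- lapply(seq_len(nShapes), function(i) {
    n <- sample(3:8, 1)
    shape(sprintf("root%d", i),
          cbind(runif(n, -20, W + 20), runif(n, -20, H + 20)))
  })
  annotationDoc(shapes, "scene.png", H, W)
}

# no-2x2-square width check
hasThickSquare <- function(pix) {
  if (nrow(pix) < 2 || ncol(pix) < 2) return(FALSE)
  any(pix[-nrow(pix), -ncol(pix)] & pix[-1, -ncol(pix)] &
        pix[-nrow(pix), -1] & pix[-1, -1])
}
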