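# Low-level pixel-grid helpers shared by the mask, skeleton and generator code.
# Masks are logical matrices indexed [y + 1, x + 1]; exported coordinates are
# 0-based (x = column, y = row).

# 0-based (x, y) coordinates of TRUE cells, in row-major (reading) order
whichXY <- function(pix) {
  idx <- which(pix)
  if (!length(idx)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  y <- (idx - 1L) %% nrow(pix)
  x <- (idx - 1L) %/% nrow(pix)
  ord <- order(y, x)
  cbind(x = x[ord], y = y[ord])
}

# shift a matrix by (dy, dx), padding with `fill`
matShift <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  okY <- ys >= 1L & ys <= nr; okX <- xs >= 1L & xs <= nc
  out[okY, okX] <- m[ys[okY], xs[okX]]
  out
}

# 8-neighbour offsets in clockwise order starting north: N NE E SE S SW W NW
NEIGH8 <- cbind(dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# number of TRUE 8-neighbours of every cell
neighborCount8 <- function(pix) {
  acc <- matrix(0L, nrow(pix), ncol(pix))
  for (i in seq_len(8))
    acc <- acc + matShift(pix, NEIGH8[i, 1], NEIGH8[i, 2])
  acc
}

# deterministic connected-component labelling.
# Components are relabelled so that label 1 contains the foreground pixel that
# comes first in row-major (reading) order, label 2 the first remaining one,
# and so on; this fixes tie-breaks bit-stably across runs.
labelComponents <- function(pix, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(pix); nc <- ncol(pix)
  lab <- matrix(0L, nr, nc)
  fg <- which(pix)
  if (!length(fg)) return(lab)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pix[j]
    if (any(hit)) {
      from <- c(from, id[fg[ok][hit]])
      to <- c(to, id[j[hit]])
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # row-major rank of each component's first pixel
  key <- (r - 1L) * nc + (cc - 1L)
  firstKey <- tapply(key, memb, min)
  newLab <- integer(length(firstKey))
  newLab[order(firstKey)] <- seq_along(firstKey)
  lab[fg] <- newLab[memb]
  lab
}

# crop a logical matrix to its TRUE bounding box with a margin; returns the
# cropped matrix and the (row, col) offset needed to restore positions
cropToForeground <- function(pix, margin = 1L) {
  idx <- which(pix, arr.ind = TRUE)
  if (!nrow(idx)) return(list(pix = pix, offset = c(0L, 0L)))
  r0 <- max(1L, min(idx[, 1]) - margin); r1 <- min(nrow(pix), max(idx[, 1]) + margin)
  c0 <- max(1L, min(idx[, 2]) - margin); c1 <- min(ncol(pix), max(idx[, 2]) + margin)
  list(pix = pix[r0:r1, c0:c1, drop = FALSE], offset = c(r0 - 1L, c0 - 1L))
}

# paste a cropped matrix back into a full-size canvas
uncrop <- function(pix, offset, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  out[offset[1] + seq_len(nrow(pix)), offset[2] + seq_len(ncol(pix))] <- pix
  out
}
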