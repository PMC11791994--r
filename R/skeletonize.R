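# K3M-style phased thinning.
#
# Each foreground pixel is described by the weight of its 8-neighbourhood:
# neighbours are taken clockwise starting north with weights 1, 2, 4, 8, 16,
# 32, 64, 128, and the weight of a pixel is the sum over its foreground
# neighbours. The lookup sets below are rotation-closed: A0 marks border
# pixels (deletable candidates), A1..A5 the weights deletable with 3, 3-4,
# 3-5, 3-6 and 3-7 sticking neighbours, and A1PX the final one-pixel-width
# reduction set. Deletion is sequential in row-major scan order with weights
# recomputed on the fly, which preserves connectivity and makes the result
# bit-stable.
K3M_A0 <- c(3, 6, 7, 12, 14, 15, 24, 28, 30, 31, 48, 56, 60, 62, 63, 96, 112,
            120, 124, 126, 127, 129, 131, 135, 143, 159, 191, 192, 193, 195,
            199, 207, 223, 224, 225, 227, 231, 239, 240, 241, 243, 247, 248,
            249, 251, 252, 253, 254)
K3M_A1 <- c(7, 14, 28, 56, 112, 131, 193, 224)
K3M_A2 <- c(7, 14, 15, 28, 30, 56, 60, 112, 120, 131, 135, 193, 195, 224,
            225, 240)
K3M_A3 <- c(7, 14, 15, 28, 30, 31, 56, 60, 62, 112, 120, 124, 131, 135, 143,
            193, 195, 199, 224, 225, 227, 240, 241, 248)
K3M_A4 <- c(7, 14, 15, 28, 30, 31, 56, 60, 62, 63, 112, 120, 124, 126, 131,
            135, 143, 159, 193, 195, 199, 207, 224, 225, 227, 231, 240, 241,
            243, 248, 249, 252)
K3M_A5 <- c(7, 14, 15, 28, 30, 31, 56, 60, 62, 63, 112, 120, 124, 126, 131,
            135, 143, 159, 191, 193, 195, 199, 207, 224, 225, 227, 231, 239,
            240, 241, 243, 248, 249, 251, 252, 254)
K3M_A1PX <- K3M_A0

k3mLut <- function(vals) {
  lut <- logical(255)
  lut[vals] <- TRUE
  lut
}

# weight matrix of the full grid (vectorised over shifts)
k3mWeights <- function(pix) {
  w <- matrix(0L, nrow(pix), ncol(pix))
  pow <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  for (i in seq_len(8))
    w <- w + pow[i] * matShift(pix, NEIGH8[i, 1], NEIGH8[i, 2])
  w
}

# sequential deletion pass: visit candidate linear indices in row-major order,
# delete those whose current neighbourhood weight is in `lut`
k3mPass <- function(pix, cand, lut, noffs, pow) {
  changed <- FALSE
  nr <- nrow(pix)
  # row-major scan order: sort by (row, col) = ((i-1) %% nr, (i-1) %/% nr)
  cand <- cand[order((cand - 1L) %% nr, (cand - 1L) %/% nr)]
  for (i in cand) {
    if (!pix[i]) next
    w <- sum(pow[pix[i + noffs]])
    if (w > 0L && lut[w]) {
      pix[i] <- FALSE
      changed <- TRUE
    }
  }
  list(pix = pix, changed = changed)
}

k3mThin <- function(pix) {
  pow <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  luts <- lapply(list(K3M_A1, K3M_A2, K3M_A3, K3M_A4, K3M_A5), k3mLut)
  lutPx <- k3mLut(K3M_A1PX)
  nr <- nrow(pix)
  # linear-index offsets of the 8 neighbours (requires an empty 1-px border,
  # which thinMask guarantees by padding)
  noffs <- NEIGH8[, "dy"] + nr * NEIGH8[, "dx"]
  lutA0 <- k3mLut(K3M_A0)
  repeat {
    w <- k3mWeights(pix)
    isBorder <- pix & w > 0L
    isBorder[isBorder] <- lutA0[w[isBorder]]
    border <- which(isBorder)
    if (!length(border)) break
    changed <- FALSE
    for (k in seq_len(5)) {
      res <- k3mPass(pix, border, luts[[k]], noffs, pow)
      pix <- res$pix
      changed <- changed || res$changed
    }
    if (!changed) break
  }
  # final reduction to one-pixel width
  repeat {
    res <- k3mPass(pix, which(pix), lutPx, noffs, pow)
    pix <- res$pix
    if (!res$changed) break
  }
  pix
}

# Zhang-Suen two-subiteration parallel thinning (fallback method), followed by
# the same one-pixel-width reduction pass as K3M so both methods meet the
# width-1 postcondition.
zhangSuenThin <- function(pix) {
  nr <- nrow(pix)
  shifted <- function(p) lapply(seq_len(8), function(i)
    matShift(p, NEIGH8[i, 1], NEIGH8[i, 2]))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- shifted(pix)                      # P2..P9 = N, NE, E, SE, S, SW, W, NW
      B <- Reduce(`+`, nb)
      # A = number of 0 -> 1 transitions in the cyclic neighbour sequence
      A <- matrix(0L, nr, ncol(pix))
      for (i in seq_len(8)) {
        j <- if (i == 8) 1L else i + 1L
        A <- A + (!nb[[i]] & nb[[j]])
      }
      if (sub == 1) {
        cond <- !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- pix & B >= 2 & B <= 6 & A == 1L & cond
      if (any(del)) {
        pix[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pow <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  noffs <- NEIGH8[, "dy"] + nr * NEIGH8[, "dx"]
  lutPx <- k3mLut(K3M_A1PX)
  repeat {
    res <- k3mPass(pix, which(pix), lutPx, noffs, pow)
    pix <- res$pix
    if (!res$changed) break
  }
  pix
}

#' Thin a single-object mask to its medial skeleton
#'
#' Iteratively erodes a root mask to a one-pixel-wide, 8-connected,
#' topology-preserving medial curve. The default method is the phased
#' border-marking scheme of K3M (border pixels are marked via a 3x3
#' neighbourhood weight lookup, then deleted over five phases admitting 3 to 7
#' sticking neighbours, repeated to a fixpoint, with a final one-pixel-width
#' pass); `"zhangsuen"` is a classical two-subiteration parallel thinning that
#' meets the same postconditions and is kept as an alternative.
#'
#' The mask must contain at most one connected component - run
#' [largestComponent()] or [postprocessDetections()] first. An empty mask
#' yields an empty skeleton.
#'
#' @param mask an [InstanceMask] or logical matrix with one connected
#'   component.
#' @param method `"k3m"` (default) or `"zhangsuen"`.
#' @return a [Skeleton] on the same pixel grid.
#' @examples
#' m <- matrix(FALSE, 9, 24); m[3:7, 3:22] <- TRUE
#' sk <- thinMask(m)
#' sum(skeletonPixels(sk)); nrow(endpoints(sk))
#' @seealso [pruneSpurs()], [toPolyline()]
#' @export
thinMask <- function(mask, method = c("k3m", "zhangsuen")) {
  method <- match.arg(method)
  pix <- if (is(mask, "InstanceMask")) mask@pixels else mask
  if (!is.logical(pix)) storage.mode(pix) <- "logical"
  if (!any(pix))
    return(new("Skeleton", pixels = pix, method = method))
  lab <- labelComponents(pix, 8)
  if (max(lab) > 1L)
    stop("mask has ", max(lab), " connected components; apply ",
         "largestComponent()/postprocessDetections() before thinning",
         call. = FALSE)
  cr <- cropToForeground(pix, margin = 2L)
  work <- matrix(FALSE, nrow(cr$pix) + 2L, ncol(cr$pix) + 2L)
  work[2:(nrow(cr$pix) + 1L), 2:(ncol(cr$pix) + 1L)] <- cr$pix
  thin <- switch(method, k3m = k3mThin(work), zhangsuen = zhangSuenThin(work))
  thin <- thin[2:(nrow(cr$pix) + 1L), 2:(ncol(cr$pix) + 1L), drop = FALSE]
  new("Skeleton", pixels = uncrop(thin, cr$offset, dim(pix)), method = method)
}

#' Prune short skeleton side branches
#'
#' Thinning artefacts on a rough mask boundary appear as short spurs off the
#' main medial curve. This removes every branch that runs from a branchpoint
#' to an endpoint in fewer than `minBranchPx` pixels, repeating until no such
#' branch remains. A skeleton without branchpoints is returned unchanged.
#'
#' @param skel a [Skeleton].
#' @param minBranchPx minimum branch length to keep, in pixels. The default
#'   10 px corresponds to about 0.21 mm at 1200 dpi.
#' @return the pruned [Skeleton].
#' @export
pruneSpurs <- function(skel, minBranchPx = 10) {
  orig <- skel@pixels
  if (minBranchPx <= 0 || !any(orig)) return(skel)
  # pad with a 1-px background border so neighbour offsets never leave the grid
  pix <- matrix(FALSE, nrow(orig) + 2L, ncol(orig) + 2L)
  pix[2:(nrow(orig) + 1L), 2:(ncol(orig) + 1L)] <- orig
  nr <- nrow(pix)
  noffs <- NEIGH8[, "dy"] + nr * NEIGH8[, "dx"]
  repeat {
    deg <- neighborCount8(pix)
    if (!any(pix & deg >= 3L)) break
    ends <- which(pix & deg == 1L)
    # the two endpoints realising the longest geodesic are the main axis of
    # the root; their branches are never treated as spurs (a rounded tip can
    # thin into a short fork, and pruning both prongs would blunt the curve)
    if (length(ends) > 2) {
      sg <- skeletonGraph(pix)
      vEnds <- match(ends, sg$idx)
      d <- igraph::distances(sg$graph, v = vEnds, to = vEnds)
      best <- arrayInd(which.max(d), dim(d))
      ends <- setdiff(ends, ends[c(best[1], best[2])])
    } else {
      ends <- integer(0)
    }
    removed <- FALSE
    for (e in ends) {
      if (!pix[e]) next
      # walk from the endpoint towards the first branchpoint
      path <- e
      prev <- -1L
      repeat {
        cur <- path[length(path)]
        nbr <- cur + noffs
        nbr <- nbr[pix[nbr]]
        nbr <- setdiff(nbr, prev)
        if (length(nbr) != 1L) break          # branchpoint or isolated end
        prev <- cur
        path <- c(path, nbr)
        if (deg[nbr] >= 3L) break
        if (length(path) > minBranchPx + 1L) break
      }
      last <- path[length(path)]
      if (deg[last] >= 3L && (length(path) - 1L) < minBranchPx) {
        pix[path[-length(path)]] <- FALSE     # drop the spur, keep the branchpoint
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  # a junction can be left as a one-pixel protrusion once its spur is gone;
  # the same one-pixel-width pass used after thinning clears it
  pow <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  noffs2 <- NEIGH8[, "dy"] + nrow(pix) * NEIGH8[, "dx"]
  lutPx <- k3mLut(K3M_A1PX)
  repeat {
    res <- k3mPass(pix, which(pix), lutPx, noffs2, pow)
    pix <- res$pix
    if (!res$changed) break
  }
  out <- skel
  out@pixels <- pix[2:(nrow(orig) + 1L), 2:(ncol(orig) + 1L), drop = FALSE]
  out
}

# igraph over skeleton pixels: vertices = foreground pixels, edges between
# 8-adjacent pixels weighted by the Euclidean step (1 or sqrt 2). Diagonal
# edges that merely short-cut an existing axial corner (both pixels share a
# foreground axial neighbour) are dropped, so paths traverse the curve instead
# of cutting corners; connectivity is preserved through the corner pixel.
skeletonGraph <- function(pix) {
  idx <- which(pix)
  id <- matrix(0L, nrow(pix), ncol(pix))
  id[idx] <- seq_along(idx)
  nr <- nrow(pix)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  at <- function(rr, ccol) {
    ok <- rr >= 1L & rr <= nr & ccol >= 1L & ccol <= ncol(pix)
    out <- logical(length(rr))
    out[ok] <- pix[(ccol[ok] - 1L) * nr + rr[ok]]
    out
  }
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (o in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(pix)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pix[j]
    keep <- hit
    if (o[1] != 0L && o[2] != 0L) {
      # redundant diagonal: an axial stepping stone exists on either side
      stone <- at(r[ok], c2[ok]) | at(r2[ok], cc[ok])
      keep <- hit & !stone
    }
    if (any(keep)) {
      from <- c(from, id[idx[ok][keep]])
      to <- c(to, id[j[keep]])
      wt <- c(wt, rep(o[3], sum(keep)))
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- wt
  list(graph = g, idx = idx, x = cc - 1L, y = r - 1L)
}

#' Order a skeleton into an endpoint-to-endpoint polyline
#'
#' Returns the longest geodesic path between two endpoints of the skeleton,
#' as an ordered matrix of 0-based (x, y) pixel coordinates with consecutive
#' points 8-adjacent. Residual side branches (shorter than the pruning
#' threshold, or surviving it) are ignored: roots are analysed as single
#' curves, and the main axis is the longest endpoint-to-endpoint geodesic.
#'
#' @param skel a [Skeleton] (nonempty).
#' @return numeric matrix with columns `x`, `y`.
#' @section Errors:
#' A skeleton that is a single closed loop has no endpoints and signals
#' `"cyclic skeleton"`.
#' @export
toPolyline <- function(skel) {
  pix <- skel@pixels
  if (!any(pix)) stop("empty skeleton", call. = FALSE)
  if (sum(pix) == 1L) {
    xy <- whichXY(pix)
    return(cbind(x = xy[, 1], y = xy[, 2]))
  }
  sg <- skeletonGraph(pix)
  deg <- neighborCount8(pix)
  endIdx <- which(pix & deg == 1L)
  if (!length(endIdx)) stop("cyclic skeleton", call. = FALSE)
  vEnds <- match(endIdx, sg$idx)
  if (length(vEnds) == 1L) {
    # open curve with one free end (e.g. a spiral): farthest vertex is the other end
    d <- igraph::distances(sg$graph, v = vEnds)
    far <- which.max(d)
    pair <- c(vEnds, far)
  } else {
    d <- igraph::distances(sg$graph, v = vEnds, to = vEnds)
    best <- arrayInd(which.max(d), dim(d))
    pair <- c(vEnds[best[1]], vEnds[best[2]])
  }
  path <- igraph::shortest_paths(sg$graph, from = pair[1], to = pair[2],
                                 output = "vpath")$vpath[[1]]
  v <- as.integer(path)
  cbind(x = sg$x[v], y = sg$y[v])
}
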