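# Scattered-data piecewise-linear interpolation.
#
# A Delaunay triangulation of the target scatter is built once per
# configuration (Bowyer-Watson insertion with a strict in-circumcircle test,
# so exactly cocircular points -- the amplitude rings -- resolve to a valid
# triangulation) and interpolation reduces to a fixed grid x target weight
# matrix: in-hull grid bins get the barycentric weights of their containing
# triangle, out-of-hull bins get the nearest target's value and are flagged
# in the validity mask. Barycentric weights make the interpolant exact at
# the targets and exact on affine functions, independent of which valid
# triangulation the degenerate in-circle ties produce.

# Delaunay triangulation; returns matrix of vertex index triples.
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop_invalid("need at least 3 points to triangulate")
  if (anyDuplicated(cbind(x, y))) stop_invalid("duplicate points in triangulation")
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1e-8)
  # super-triangle comfortably containing everything
  big <- 64 * span
  px <- c(x, cx - big, cx + big, cx)
  py <- c(y, cy - big, cy - big, cy + big)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  circ <- matrix(circumcircle(px, py, tris[1, ]), nrow = 1)
  for (i in seq_len(n)) {
    d2 <- (px[i] - circ[, 1])^2 + (py[i] - circ[, 2])^2
    # inclusive containment so exactly-cocircular points (amplitude rings)
    # land in the cavity of their containing triangle as well
    bad <- which(d2 <= circ[, 3] * (1 + 1e-12))
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    newc <- t(apply(newt, 1, function(v) circumcircle(px, py, v)))
    tris <- rbind(tris, newt)
    circ <- rbind(circ, newc)
  }
  keep <- apply(tris <= n, 1, all)
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) stop_invalid("degenerate (collinear) point set")
  dimnames(tris) <- NULL
  tris
}

circumcircle <- function(px, py, v) {
  ax <- px[v[1]]; ay <- py[v[1]]
  bx <- px[v[2]]; by <- py[v[2]]
  cx <- px[v[3]]; cy <- py[v[3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(c(Inf, Inf, Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

# barycentric coordinates of point (qx, qy) in triangle rows of (x, y)
barycentric <- function(qx, qy, x, y) {
  d <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
  l1 <- ((y[2] - y[3]) * (qx - x[3]) + (x[3] - x[2]) * (qy - y[3])) / d
  l2 <- ((y[3] - y[1]) * (qx - x[3]) + (x[1] - x[3]) * (qy - y[3])) / d
  c(l1, l2, 1 - l1 - l2)
}

# Interpolation operator from scattered targets to grid bin centers.
# Returns list(W = nbins x ntargets weight matrix, mask = logical in-hull).
interp_operator <- function(tx, ty, gx, gy) {
  tris <- delaunay_triangulate(tx, ty)
  ntri <- nrow(tris)
  nb <- length(gx)
  W <- matrix(0, nb, length(tx))
  mask <- logical(nb)
  hull <- grDevices::chull(tx, ty)
  hx <- tx[hull]; hy <- ty[hull]
  for (g in seq_len(nb)) {
    best <- -Inf; bestw <- NULL; bestv <- NULL
    for (t in seq_len(ntri)) {
      v <- tris[t, ]
      b <- barycentric(gx[g], gy[g], tx[v], ty[v])
      m <- min(b)
      if (m > best) { best <- m; bestw <- b; bestv <- v }
      if (m >= -1e-12) break
    }
    if (best >= -1e-9) {
      W[g, bestv] <- bestw
      mask[g] <- TRUE
    } else {
      inside <- in_convex_polygon(gx[g], gy[g], hx, hy)
      if (inside) {
        # numerical sliver between triangles: extend the nearest triangle's
        # affine map (weights still sum to 1, affine exactness preserved)
        W[g, bestv] <- bestw
        mask[g] <- TRUE
      } else {
        nn <- which.min((tx - gx[g])^2 + (ty - gy[g])^2)
        W[g, nn] <- 1
        mask[g] <- FALSE
      }
    }
  }
  list(W = W, mask = mask)
}

in_convex_polygon <- function(qx, qy, hx, hy, tol = 1e-9) {
  n <- length(hx)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (qy - hy[i]) - (hy[j] - hy[i]) * (qx - hx[i])
    if (abs(cr) <= tol) next
    if (sgn == 0) sgn <- sign(cr)
    else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}
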