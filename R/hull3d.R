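# 3D convex hull by incremental insertion (quickhull-style visibility and
# horizon construction), plus exact plane-slice rasterization onto a voxel
# lattice. Written for voxel-centre point clouds: callers should pre-reduce
# the cloud to per-column extreme voxels (see hull_candidate_points), which
# keeps the insertion loop to a few thousand points.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Convex hull of a 3D point cloud
#'
#' Computes the convex hull of a set of points in physical coordinates.
#' Facets are oriented outward; the hull volume is obtained by summing
#' signed tetrahedra against an interior point.
#'
#' @param points Numeric matrix with 3 columns (one point per row), in any
#'   consistent physical unit.
#' @param tol Distance tolerance for classifying a point as on a facet
#'   plane; defaults to `1e-9` times the cloud diameter.
#' @return A list with `vertices` (coordinates of hull vertices), `facets`
#'   (m x 3 matrix of row indices into `vertices`), unit outward `normals`,
#'   plane `offsets` (a point p is inside iff `normals %*% p <= offsets`
#'   for all facets), and `volume` in the cube of the input unit.
#' @export
convex_hull_3d <- function(points, tol = NULL) {
  P <- as.matrix(points)
  if (ncol(P) != 3L) stop("`points` must be an n x 3 matrix")
  storage.mode(P) <- "double"
  P <- unique(P)
  n <- nrow(P)
  if (n < 4L)
    stop("convex hull needs at least 4 distinct points; 2D fallback is out of scope")
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate point cloud (all points identical)")
  if (is.null(tol)) tol <- 1e-9 * scale

  ## --- initial tetrahedron ---------------------------------------------
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) { i1 <- which.min(P[, 2]); i2 <- which.max(P[, 2]) }
  if (i1 == i2) { i1 <- which.min(P[, 3]); i2 <- which.max(P[, 3]) }
  d12 <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dline <- sqrt(rowSums(cr^2)) / sqrt(sum(d12^2))
  i3 <- which.max(dline)
  if (dline[i3] <= tol)
    stop("degenerate (collinear) point cloud; 2D fallback is out of scope")
  n0 <- cross3(d12, P[i3, ] - P[i1, ])
  n0 <- n0 / sqrt(sum(n0^2))
  dplane <- abs(rel %*% n0)
  i4 <- which.max(dplane)
  if (dplane[i4] <= tol)
    stop("degenerate (coplanar) point cloud; 2D fallback is out of scope")
  interior <- colMeans(P[c(i1, i2, i3, i4), ])

  ## --- facet store ------------------------------------------------------
  cap <- 1024L
  Fm <- matrix(0L, cap, 3)        # vertex indices (rows of P)
  Nm <- matrix(0, cap, 3)         # unit outward normals
  off <- numeric(cap)             # plane offsets
  alive <- logical(cap)
  nf <- 0L

  add_facet <- function(a, b, c) {
    nv <- cross3(P[b, ] - P[a, ], P[c, ] - P[a, ])
    len <- sqrt(sum(nv^2))
    if (len <= tol * scale * 1e-3) return(invisible(NULL)) # sliver facet
    nv <- nv / len
    d <- sum(nv * P[a, ])
    if (sum(nv * interior) > d) { nv <- -nv; d <- -d; tmp <- b; b <- c; c <- tmp }
    if (nf == nrow(Fm)) {  # grow
      Fm <<- rbind(Fm, matrix(0L, nrow(Fm), 3))
      Nm <<- rbind(Nm, matrix(0, nrow(Nm), 3))
      off <<- c(off, numeric(length(off)))
      alive <<- c(alive, logical(length(alive)))
    }
    nf <<- nf + 1L
    Fm[nf, ] <<- c(a, b, c)
    Nm[nf, ] <<- nv
    off[nf] <<- d
    alive[nf] <<- TRUE
    invisible(NULL)
  }

  add_facet(i1, i2, i3)
  add_facet(i1, i2, i4)
  add_facet(i1, i3, i4)
  add_facet(i2, i3, i4)

  ## --- insert remaining points, farthest-from-centroid first ------------
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  ord <- rest[order(-rowSums(sweep(P[rest, , drop = FALSE], 2, interior)^2))]

  for (ip in ord) {
    p <- P[ip, ]
    live <- which(alive[seq_len(nf)])
    dist <- Nm[live, , drop = FALSE] %*% p - off[live]
    vis <- live[dist > tol]
    if (length(vis) == 0L) next
    ## horizon = directed edges of visible facets whose reverse is not visible
    vf <- Fm[vis, , drop = FALSE]
    eu <- c(vf[, 1], vf[, 2], vf[, 3])
    ev <- c(vf[, 2], vf[, 3], vf[, 1])
    key_fwd <- paste(eu, ev)
    key_rev <- paste(ev, eu)
    horizon <- !(key_rev %in% key_fwd)
    alive[vis] <- FALSE
    hu <- eu[horizon]; hv <- ev[horizon]
    for (k in seq_along(hu)) add_facet(hu[k], hv[k], ip)
  }

  live <- which(alive[seq_len(nf)])
  Fl <- Fm[live, , drop = FALSE]
  vidx <- sort(unique(as.vector(Fl)))
  remap <- match(Fl, vidx)
  facets <- matrix(remap, ncol = 3)
  V <- P[vidx, , drop = FALSE]

  ## volume: sum of tetrahedra (interior, facet) -- facets outward so det > 0
  a <- P[Fl[, 1], , drop = FALSE]
  b <- P[Fl[, 2], , drop = FALSE]
  cc <- P[Fl[, 3], , drop = FALSE]
  a <- sweep(a, 2, interior); b <- sweep(b, 2, interior); cc <- sweep(cc, 2, interior)
  dets <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(dets) / 6

  list(vertices = V, facets = facets,
       normals = Nm[live, , drop = FALSE], offsets = off[live],
       volume = vol, interior = interior, tol = tol)
}

# Unique undirected vertex-index edges of a hull (rows into hull$vertices).
hull_edges <- function(hull) {
  f <- hull$facets
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  e <- t(apply(e, 1, sort))
  unique(e)
}

# Rasterize a convex hull onto a voxel lattice by exact plane slicing:
# the cross-section of the polytope at each z voxel-centre plane is a
# convex polygon (hull vertices on the plane plus edge/plane crossings);
# each polygon is scan-converted row by row into x-index intervals.
# Returns a logical array of the requested dims marking voxels whose
# centres lie inside or on the hull (within `eps` physical units).
#
# coords: list(z =, y =, x =) voxel-centre physical coordinates.
rasterize_hull <- function(hull, coords, eps = NULL) {
  V <- hull$vertices
  if (is.null(eps)) eps <- 1e-6 * max(apply(V, 2, function(v) diff(range(v))))
  E <- hull_edges(hull)
  zc <- coords$z; yc <- coords$y; xc <- coords$x
  nz <- length(zc); ny <- length(yc); nx <- length(xc)
  out <- array(FALSE, dim = c(nz, ny, nx))
  vz <- V[, 1]
  zmin <- min(vz) - eps; zmax <- max(vz) + eps
  ez1 <- vz[E[, 1]]; ez2 <- vz[E[, 2]]
  sx <- if (nx > 1) xc[2] - xc[1] else 1
  sy <- if (ny > 1) yc[2] - yc[1] else 1

  for (iz in seq_len(nz)) {
    z0 <- zc[iz]
    if (z0 < zmin || z0 > zmax) next
    ## section points (y, x)
    on <- abs(vz - z0) <= eps
    pts <- V[on, c(2, 3), drop = FALSE]
    lo <- pmin(ez1, ez2); hi <- pmax(ez1, ez2)
    crossing <- which(lo < z0 - eps & hi > z0 + eps)
    if (length(crossing)) {
      t <- (z0 - ez1[crossing]) / (ez2[crossing] - ez1[crossing])
      py <- V[E[crossing, 1], 2] + t * (V[E[crossing, 2], 2] - V[E[crossing, 1], 2])
      px <- V[E[crossing, 1], 3] + t * (V[E[crossing, 2], 3] - V[E[crossing, 1], 3])
      pts <- rbind(pts, cbind(py, px))
    }
    if (nrow(pts) == 0L) next
    ymin <- min(pts[, 1]) - eps; ymax <- max(pts[, 1]) + eps
    iy_lo <- max(1L, ceiling((ymin - yc[1]) / sy + 1))
    iy_hi <- min(ny, floor((ymax - yc[1]) / sy + 1))
    if (iy_lo > iy_hi) next
    ## convex polygon in (y, x); may be degenerate (point or segment)
    h2 <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]), error = function(e) integer())
    poly <- if (length(h2) >= 3) pts[h2, , drop = FALSE] else pts
    np <- nrow(poly)
    for (iy in iy_lo:iy_hi) {
      y0 <- yc[iy]
      if (np >= 3) {
        ## intersect polygon edges with the line y = y0
        ya <- poly[, 1]; yb <- poly[c(2:np, 1), 1]
        xa <- poly[, 2]; xb <- poly[c(2:np, 1), 2]
        xs <- numeric(0)
        onv <- abs(ya - y0) <= eps
        if (any(onv)) xs <- xa[onv]
        cross <- which((ya < y0 - eps & yb > y0 + eps) | (yb < y0 - eps & ya > y0 + eps))
        if (length(cross)) {
          tt <- (y0 - ya[cross]) / (yb[cross] - ya[cross])
          xs <- c(xs, xa[cross] + tt * (xb[cross] - xa[cross]))
        }
        if (!length(xs)) next
        xlo <- min(xs) - eps; xhi <- max(xs) + eps
      } else {
        sel <- abs(poly[, 1] - y0) <= eps  # degenerate section (point/segment)
        if (!any(sel)) next
        xlo <- min(poly[sel, 2]) - eps; xhi <- max(poly[sel, 2]) + eps
      }
      ix_lo <- max(1L, ceiling((xlo - xc[1]) / sx + 1))
      ix_hi <- min(nx, floor((xhi - xc[1]) / sx + 1))
      if (ix_lo <= ix_hi) out[iz, iy, ix_lo:ix_hi] <- TRUE
    }
  }
  out
}

# Candidate hull points of a voxel mask: per-column extreme foreground
# voxels along each of the three axes. Every hull vertex of the full
# voxel-centre cloud is among these.
hull_candidate_points <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(numeric(0), 0, 3))
  ai <- arrayInd(idx, d)
  z <- ai[, 1]; y <- ai[, 2]; x <- ai[, 3]
  keep <- logical(length(idx))
  mark_extremes <- function(val, key) {
    o <- order(key, val)
    first <- !duplicated(key[o])
    last <- !duplicated(key[o], fromLast = TRUE)
    sel <- logical(length(val)); sel[o] <- first | last
    sel
  }
  keep <- keep | mark_extremes(z, y + x * (d[2] + 1))
  keep <- keep | mark_extremes(y, z + x * (d[1] + 1))
  keep <- keep | mark_extremes(x, z + y * (d[1] + 1))
  cbind(z = z[keep], y = y[keep], x = x[keep])
}
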