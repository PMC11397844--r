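# Convex-hull geometry for trajectory features: polygon area of 2-D
# projections and surface area of the 3-D hull of a kinematic trajectory.

#' Convex hull area of a 2-D point cloud
#'
#' @param xy two-column matrix of points
#' @return polygon area of the convex hull (0 for degenerate clouds)
#' @export
hull_area_2d <- function(xy) {
  xy <- as.matrix(xy)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3) return(0)
  idx <- grDevices::chull(xy)
  if (length(idx) < 3) return(0)
  h <- xy[idx, , drop = FALSE]
  x <- h[, 1]; y <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convex hull surface area of a 3-D point cloud
#'
#' Quickhull with outside-point sets; returns the total area of the hull's
#' triangular facets. Degenerate (coplanar or collinear) clouds return 0.
#'
#' @param xyz three-column matrix of points
#' @param tol degeneracy tolerance relative to the cloud scale
#' @return hull surface area
#' @export
hull_surface_area_3d <- function(xyz, tol = 1e-10) {
  p <- as.matrix(xyz)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  p <- unique(p)
  n <- nrow(p)
  if (n < 4) return(0)
  scale <- max(apply(p, 2, function(v) diff(range(v))), 1e-300)
  eps <- tol * scale

  # initial simplex: extremes along x, farthest point from that segment,
  # farthest point from that plane
  i1 <- which.min(p[, 1]); i2 <- which.max(p[, 1])
  if (i1 == i2) return(0)
  d12 <- p[i2, ] - p[i1, ]
  rel <- sweep(p, 2, p[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dseg <- sqrt(rowSums(cr^2))
  i3 <- which.max(dseg)
  if (dseg[i3] <= eps) return(0)
  nrm <- crossp(p[i2, ] - p[i1, ], p[i3, ] - p[i1, ])
  dpl <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dpl)
  if (dpl[i4] <= eps) return(0)

  verts <- c(i1, i2, i3, i4)
  centroid <- colMeans(p[verts, ])
  faces <- list()
  combs <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  for (f in combs) faces[[length(faces) + 1]] <- make_face(p, f, centroid)

  # assign points to the first face they are outside of
  remaining <- setdiff(seq_len(n), verts)
  for (fi in seq_along(faces)) {
    if (length(remaining) == 0) break
    d <- p[remaining, , drop = FALSE] %*% faces[[fi]]$normal - faces[[fi]]$offset
    out <- remaining[d > eps]
    faces[[fi]]$outside <- out
    remaining <- setdiff(remaining, out)
  }

  repeat {
    fi <- which(vapply(faces, function(f) length(f$outside) > 0, logical(1)))[1]
    if (is.na(fi)) break
    f <- faces[[fi]]
    d <- p[f$outside, , drop = FALSE] %*% f$normal - f$offset
    apex <- f$outside[which.max(d)]
    # visible faces from apex
    vis <- vapply(faces, function(g) {
      sum(p[apex, ] * g$normal) - g$offset > eps
    }, logical(1))
    # horizon edges: edges of visible faces shared with a hidden face
    edges <- list()
    for (g in faces[vis]) {
      v <- g$v
      for (e in list(v[c(1, 2)], v[c(2, 3)], v[c(3, 1)])) {
        edges[[length(edges) + 1]] <- sort(e)
      }
    }
    ek <- vapply(edges, paste, character(1), collapse = "-")
    horizon <- edges[ek %in% names(which(table(ek) == 1))]
    orphan <- unique(unlist(lapply(faces[vis], `[[`, "outside")))
    orphan <- setdiff(orphan, apex)
    faces <- faces[!vis]
    new_faces <- lapply(horizon, function(e) make_face(p, c(e, apex), centroid))
    for (nf_i in seq_along(new_faces)) {
      if (length(orphan) == 0) break
      nf <- new_faces[[nf_i]]
      d <- p[orphan, , drop = FALSE] %*% nf$normal - nf$offset
      out <- orphan[d > eps]
      new_faces[[nf_i]]$outside <- out
      orphan <- setdiff(orphan, out)
    }
    faces <- c(faces, new_faces)
  }

  sum(vapply(faces, function(f) triangle_area(p[f$v, ]), numeric(1)))
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

triangle_area <- function(tri) {
  sqrt(sum(crossp(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2)) / 2
}

make_face <- function(p, v, interior) {
  nrm <- crossp(p[v[2], ] - p[v[1], ], p[v[3], ] - p[v[1], ])
  nn <- sqrt(sum(nrm^2))
  if (nn > 0) nrm <- nrm / nn
  off <- sum(nrm * p[v[1], ])
  if (sum(interior * nrm) - off > 0) { # orient outward
    nrm <- -nrm; off <- -off; v <- v[c(1, 3, 2)]
  }
  list(v = v, normal = nrm, offset = off, outside = integer(0))
}
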