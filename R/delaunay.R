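#' Delaunay triangulation (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation of a 2-D point set.  A tiny
#' deterministic symbolic perturbation (1e-9 of the point spread) is applied
#' before triangulating so that cocircular or collinear configurations
#' resolve deterministically; returned edges refer to the original points.
#'
#' @param x,y point coordinates.
#' @return list with \code{edges} (2-column matrix of point indices,
#'   \code{u < v}) and \code{triangles} (3-column matrix of point indices).
#' @examples
#' pts <- expand.grid(x = 0:2, y = 0:2)
#' tri <- delaunayTriangulation(pts$x, pts$y)
#' nrow(tri$edges)
#' @export
delaunayTriangulation <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  scale <- max(diff(range(x)), diff(range(y)), 1)
  # deterministic symbolic perturbation against degenerate configurations
  x <- x + 1e-9 * scale * sin(1e4 * seq_len(n) + 0.7)
  y <- y + 1e-9 * scale * cos(7e3 * seq_len(n) + 1.3)

  cx0 <- mean(range(x)); cy0 <- mean(range(y))
  # the enclosing triangle must be far enough that its vertices behave like
  # points at infinity for every circumcircle test near the hull
  M <- 1e5 * scale
  px <- c(x, cx0 - 2 * M, cx0 + 2 * M, cx0)
  py <- c(y, cy0 - M, cy0 - M, cy0 + 2 * M)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  circum <- function(a, b, c) {
    ax <- px[a]; ay <- py[a]; bx <- px[b]; by <- py[b]
    cxx <- px[c]; cyy <- py[c]
    d <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
    if (abs(d) < 1e-12 * scale^2) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
           (cxx^2 + cyy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
           (cxx^2 + cyy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  cap <- max(64L, 4L * n)
  tri <- matrix(NA_integer_, cap, 3)
  cc <- matrix(NA_real_, cap, 3)  # cx, cy, r2
  alive <- logical(cap)
  tri[1, ] <- c(s1, s2, s3); cc[1, ] <- circum(s1, s2, s3); alive[1] <- TRUE
  nt <- 1L

  for (p in seq_len(n)) {
    ai <- which(alive)
    bad <- ai[(px[p] - cc[ai, 1])^2 + (py[p] - cc[ai, 2])^2 <= cc[ai, 3]]
    if (length(bad) == 0) next  # numerically outside everything; skip
    # boundary = edges of bad triangles occurring exactly once
    eds <- rbind(tri[bad, c(1, 2), drop = FALSE],
                 tri[bad, c(2, 3), drop = FALSE],
                 tri[bad, c(3, 1), drop = FALSE])
    eds <- t(apply(eds, 1, sort))
    key <- paste(eds[, 1], eds[, 2])
    keep <- eds[key %in% names(which(table(key) == 1)), , drop = FALSE]
    alive[bad] <- FALSE
    for (e in seq_len(nrow(keep))) {
      nt <- nt + 1L
      if (nt > cap) {
        tri <- rbind(tri, matrix(NA_integer_, cap, 3))
        cc <- rbind(cc, matrix(NA_real_, cap, 3))
        alive <- c(alive, logical(cap)); cap <- 2L * cap
      }
      tri[nt, ] <- c(keep[e, 1], keep[e, 2], p)
      cc[nt, ] <- circum(keep[e, 1], keep[e, 2], p)
      alive[nt] <- TRUE
    }
  }

  fin <- tri[alive, , drop = FALSE]
  fin <- fin[rowSums(fin > n) == 0, , drop = FALSE]
  if (nrow(fin) == 0) return(list(edges = matrix(integer(), 0, 2),
                                  triangles = fin))
  eds <- rbind(fin[, c(1, 2)], fin[, c(2, 3)], fin[, c(3, 1)])
  eds <- t(apply(eds, 1, sort))
  eds <- unique(eds)
  # convex hull edges are always Delaunay; restore any lost to the finite
  # enclosing-triangle approximation.  chull() drops collinear boundary
  # points, so each hull side is subdivided through any points lying on it.
  hull <- grDevices::chull(x, y)
  hullE <- NULL
  for (i in seq_along(hull)) {
    a <- hull[i]; b <- hull[if (i == length(hull)) 1L else i + 1L]
    ex <- x[b] - x[a]; ey <- y[b] - y[a]
    len2 <- ex^2 + ey^2
    t0 <- (ex * (x - x[a]) + ey * (y - y[a])) / len2
    cross <- abs(ex * (y - y[a]) - ey * (x - x[a])) / sqrt(len2)
    on <- which(cross < 1e-7 * scale & t0 > 1e-9 & t0 < 1 - 1e-9)
    chain <- c(a, on[order(t0[on])], b)
    hullE <- rbind(hullE, cbind(chain[-length(chain)], chain[-1]))
  }
  hullE <- unique(t(apply(hullE, 1, sort)))
  key <- paste(eds[, 1], eds[, 2])
  add <- hullE[!(paste(hullE[, 1], hullE[, 2]) %in% key), , drop = FALSE]
  if (nrow(add)) eds <- rbind(eds, add)
  eds <- eds[order(eds[, 1], eds[, 2]), , drop = FALSE]
  list(edges = eds, triangles = fin)
}

#' Bellman-Ford shortest path
#'
#' Textbook Bellman-Ford over an undirected weighted graph: up to |V| - 1
#' relaxation rounds with early exit.  Ties in path weight are broken by
#' fewer path nodes, then by the lower predecessor id, so results are
#' deterministic.  With the nonnegative kernel-distance weights used here no
#' negative cycles can occur.
#'
#' @param nNodes number of nodes.
#' @param edges data.frame or matrix with columns \code{u}, \code{v},
#'   \code{w} (undirected edges, nonnegative weights).
#' @param source source node id.
#' @return list of vectors \code{dist}, \code{hops} and \code{pred}
#'   (NA at the source / unreachable nodes).
#' @export
bellmanFord <- function(nNodes, edges, source) {
  u <- c(edges[, 1], edges[, 2]); v <- c(edges[, 2], edges[, 1])
  w <- c(edges[, 3], edges[, 3])
  if (any(w < 0)) stop("negative edge weight")
  dist <- rep(Inf, nNodes); hops <- rep(Inf, nNodes)
  pred <- rep(NA_integer_, nNodes)
  dist[source] <- 0; hops[source] <- 0
  eps <- 1e-9
  for (round in seq_len(max(1L, nNodes - 1L))) {
    nd <- dist[u] + w
    nh <- hops[u] + 1
    better <- nd < dist[v] - eps |
      (nd < dist[v] + eps & (nh < hops[v] |
         (nh == hops[v] & !is.na(pred[v]) & u < pred[v])))
    if (!any(better, na.rm = TRUE)) break
    changed <- FALSE
    # process sequentially within the round to keep updates consistent
    for (k in which(better)) {
      nd_k <- dist[u[k]] + w[k]
      nh_k <- hops[u[k]] + 1
      if (nd_k < dist[v[k]] - eps ||
          (nd_k < dist[v[k]] + eps &&
           (nh_k < hops[v[k]] ||
            (nh_k == hops[v[k]] && !is.na(pred[v[k]]) && u[k] < pred[v[k]])))) {
        dist[v[k]] <- min(dist[v[k]], nd_k)
        hops[v[k]] <- nh_k
        pred[v[k]] <- u[k]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(dist = dist, hops = hops, pred = pred)
}

.tracePath <- function(pred, source, target) {
  path <- target
  while (path[1] != source) {
    p <- pred[path[1]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}
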