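# valid-kernel coordinates in unwrapped circumferential coordinates
.kernelCoords <- function(kmap, ids = NULL) {
  k <- kmap@kernels[kmap@kernels$valid, , drop = FALSE]
  if (!is.null(ids)) k <- k[k$id %in% ids, , drop = FALSE]
  H <- nrow(kmap@labels)
  data.frame(kernelId = k$id, x = k$x,
             yu = (k$y - kmap@wrapOrigin - 1) %% H)
}

.medianSpacing <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  diag(d2) <- Inf
  stats::median(sqrt(apply(d2, 1, min)))
}

#' Build the kernel Delaunay graph
#'
#' Triangulates the valid kernel centroids together with start and end
#' terminal groups placed one lattice spacing beyond the kernel hull on both
#' sides along the counting direction, spaced \code{terminalSpacing} across
#' it.  Edge weights are Euclidean pixel distances; edges longer than
#' \code{pruneFactor} times the median edge length are dropped to prevent
#' cross-row shortcuts (terminal edges are kept).  With fewer than 3 usable
#' kernels (or a collinear set) a nearest-neighbor chain graph is returned
#' with a warning.
#'
#' @param kmap a \code{\linkS4class{KernelMap}}.
#' @param direction \code{"axial"} (paths along the ear axis, x) or
#'   \code{"transverse"} (paths around the circumference, y).
#' @param terminalSpacing spacing of terminal nodes across the direction,
#'   px; default: the observed median nearest-neighbor kernel spacing.
#' @param ids optional subset of kernel ids to include.
#' @param terminalIds optional subset of \code{ids} whose extent anchors the
#'   terminal groups.  Kernels in \code{ids} but not here act as a guard
#'   ring: they take part in the triangulation (blocking spurious hull
#'   shortcut edges, whose circumcircles would otherwise be empty beyond
#'   the band boundary) without attracting terminals.
#' @return a \code{\linkS4class{KernelGraph}}.
#' @export
buildKernelGraph <- function(kmap, direction = c("axial", "transverse"),
                             terminalSpacing = NULL, ids = NULL,
                             terminalIds = NULL, pruneFactor = 3,
                             wrapGuard = FALSE) {
  direction <- match.arg(direction)
  kc <- .kernelCoords(kmap, ids)
  if (nrow(kc) == 0) stop("no valid kernels")
  kt <- if (is.null(terminalIds)) kc else
    kc[kc$kernelId %in% terminalIds, , drop = FALSE]
  if (nrow(kt) == 0) kt <- kc
  if (wrapGuard && nrow(kc) >= 3) {
    # ghost copies across the circumferential seam: they join the
    # triangulation (blocking hull shortcut edges at the seam-side rows)
    # but carry kernelId 0 so they never enter kernel counts
    H <- nrow(kmap@labels)
    sp0 <- .medianSpacing(kc$x, kc$yu)
    gl <- kc[kc$yu < 3 * sp0, , drop = FALSE];  gl$yu <- gl$yu + H
    gh <- kc[kc$yu > H - 3 * sp0, , drop = FALSE]; gh$yu <- gh$yu - H
    ghosts <- rbind(gl, gh)
    if (nrow(ghosts)) {
      ghosts$kernelId <- 0L
      kc <- rbind(kc, ghosts)
    }
  }
  # work in (along, across) coordinates for terminal placement
  along <- if (direction == "axial") kt$x else kt$yu
  across <- if (direction == "axial") kt$yu else kt$x
  spacing <- .medianSpacing(kc$x, kc$yu)
  if (!is.finite(spacing) || spacing <= 0) spacing <- 1
  if (is.null(terminalSpacing)) terminalSpacing <- spacing

  acrossPos <- if (diff(range(across)) < terminalSpacing / 2) {
    mean(range(across))
  } else {
    seq(min(across), max(across), by = terminalSpacing)
  }
  allAlong <- if (direction == "axial") kc$x else kc$yu
  sAlong <- min(allAlong) - spacing
  eAlong <- max(allAlong) + spacing
  term <- rbind(
    data.frame(along = sAlong, across = acrossPos, type = "start"),
    data.frame(along = eAlong, across = acrossPos, type = "end"))

  nodes <- data.frame(
    id = seq_len(nrow(kc) + nrow(term)),
    x = c(kc$x, if (direction == "axial") term$along else term$across),
    y = c(kc$yu, if (direction == "axial") term$across else term$along),
    type = c(ifelse(kc$kernelId == 0L, "guard", "kernel"), term$type),
    kernelId = c(kc$kernelId, rep(0L, nrow(term))))

  n <- nrow(nodes)
  collinear <- FALSE
  if (nrow(kc) >= 3) {
    xs <- nodes$x - mean(nodes$x); ys <- nodes$y - mean(nodes$y)
    cv <- matrix(c(mean(xs^2), mean(xs * ys), mean(xs * ys), mean(ys^2)), 2)
    collinear <- min(eigen(cv, symmetric = TRUE)$values) < 1e-9 * max(cv)
  }
  if (nrow(kc) < 3 || collinear) {
    warning("fewer than 3 (or collinear) kernels: nearest-neighbor chain graph")
    # connect consecutively along the direction
    ord <- order(if (direction == "axial") nodes$x else nodes$y)
    edges <- data.frame(u = ord[-n], v = ord[-1])
  } else {
    tri <- delaunayTriangulation(nodes$x, nodes$y)
    edges <- data.frame(u = tri$edges[, 1], v = tri$edges[, 2])
  }
  edges$w <- sqrt((nodes$x[edges$u] - nodes$x[edges$v])^2 +
                  (nodes$y[edges$u] - nodes$y[edges$v])^2)
  if (nrow(edges) > 2 && is.finite(pruneFactor)) {
    medW <- stats::median(edges$w)
    terminal <- !(nodes$type %in% c("kernel", "guard"))
    drop <- edges$w > pruneFactor * medW &
      !(terminal[edges$u] | terminal[edges$v])
    edges <- edges[!drop, , drop = FALSE]
  }
  edges <- .pruneBypasses(nodes, edges)
  rownames(edges) <- NULL
  new("KernelGraph", nodes = nodes, edges = edges, direction = direction)
}

# Drop near-collinear shortcut edges: on strongly anisotropic kernel
# lattices the Delaunay triangulation can contain an edge that hops over an
# intermediate kernel (the empty circumcircle fits between rows).  Such an
# edge is geometrically a path "through" the middle kernel, so it is removed
# whenever some third node w gives d(u,w) + d(w,v) within (1 + delta) of the
# edge length; the two-leg path keeps connectivity and nearly the same
# weight, and shortest paths then enumerate every kernel they pass through.
.pruneBypasses <- function(nodes, edges, delta = 0.12) {
  m <- nrow(edges)
  if (m == 0) return(edges)
  xs <- nodes$x; ys <- nodes$y
  n <- length(xs)
  du <- sqrt(outer(xs, xs[edges$u], "-")^2 + outer(ys, ys[edges$u], "-")^2)
  dv <- sqrt(outer(xs, xs[edges$v], "-")^2 + outer(ys, ys[edges$v], "-")^2)
  tot <- du + dv  # n x m: via-w length for each edge
  idx <- cbind(edges$u, seq_len(m))
  tot[idx] <- Inf; tot[cbind(edges$v, seq_len(m))] <- Inf
  best <- apply(tot, 2, min)
  edges[best > (1 + delta) * edges$w, , drop = FALSE]
}

#' Bellman-Ford shortest kernel path
#'
#' Minimal-weight path between a start and an end terminal; the kernel count
#' is the number of path nodes excluding all terminals.
#'
#' @param graph a \code{\linkS4class{KernelGraph}}.
#' @param s,e node ids of a start and an end terminal.
#' @return list with \code{path} (node ids), \code{weight} and
#'   \code{kernelCount}.
#' @export
shortestKernelPath <- function(graph, s, e) {
  nodes <- graph@nodes
  if (nodes$type[s] != "start") stop("s must be a start terminal")
  if (nodes$type[e] != "end") stop("e must be an end terminal")
  bf <- bellmanFord(nrow(nodes), as.matrix(graph@edges), s)
  if (!is.finite(bf$dist[e])) {
    comp <- .components(nrow(nodes), graph@edges)
    stop(sprintf("end terminal unreachable: start in component %d, end in component %d",
                 comp[s], comp[e]))
  }
  path <- .tracePath(bf$pred, s, e)
  list(path = path, weight = bf$dist[e],
       kernelCount = sum(nodes$type[path] == "kernel"))
}

.components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    c2 <- comp
    c2[edges$v] <- pmin(c2[edges$v], comp[edges$u])
    c2[edges$u] <- pmin(c2[edges$u], comp[edges$v])
    c2 <- c2[c2]
    if (identical(c2, comp)) break
    comp <- c2
  }
  match(comp, unique(comp))
}

# best (minimum-weight) start-to-end path over the terminal groups
.bestGroupPath <- function(graph) {
  nodes <- graph@nodes
  ss <- nodes$id[nodes$type == "start"]
  ee <- nodes$id[nodes$type == "end"]
  best <- NULL
  for (s in ss) {
    bf <- bellmanFord(nrow(nodes), as.matrix(graph@edges), s)
    reach <- ee[is.finite(bf$dist[ee])]
    if (length(reach) == 0) next
    e <- reach[order(bf$dist[reach], bf$hops[reach], reach)][1]
    cand <- list(path = .tracePath(bf$pred, s, e), weight = bf$dist[e],
                 hops = bf$hops[e])
    if (is.null(best) || cand$weight < best$weight - 1e-9 ||
        (cand$weight < best$weight + 1e-9 && cand$hops < best$hops))
      best <- cand
  }
  if (is.null(best)) stop("no start terminal reaches any end terminal")
  best$kernelCount <- sum(nodes$type[best$path] == "kernel")
  best
}

#' Count kernel rows (RNE)
#'
#' Builds transverse kernel graphs at three axial stations (by default 30,
#' 50 and 70% of the kernel-bearing span, each over the kernels within one
#' median spacing of the station) and reports the mean of the three
#' transverse shortest-path kernel counts, unrounded.
#'
#' @param kmap a \code{\linkS4class{KernelMap}}.
#' @param stations axial station positions as fractions of the
#'   kernel-bearing span.
#' @param bandHalfWidth station band half-width in units of the median
#'   kernel spacing.
#' @return RNE, the (possibly fractional) kernel row count.
#' @export
countRows <- function(kmap, stations = c(0.3, 0.5, 0.7),
                      bandHalfWidth = 1) {
  kc <- .kernelCoords(kmap)
  if (nrow(kc) == 0) stop("no valid kernels")
  if (nrow(kc) == 1) return(1)
  spacing <- .medianSpacing(kc$x, kc$yu)
  span <- range(kc$x)
  counts <- numeric(0)
  for (f in stations) {
    xs <- span[1] + f * diff(span)
    ids <- kc$kernelId[abs(kc$x - xs) <= bandHalfWidth * spacing]
    if (length(ids) == 0) {
      warning(sprintf("station at %.0f%% of the span has no kernels; skipped",
                      100 * f))
      next
    }
    if (length(ids) == 1) { counts <- c(counts, 1); next }
    # one extra guard column on each side blocks hull shortcut edges
    guard <- kc$kernelId[abs(kc$x - xs) <= (bandHalfWidth + 1.2) * spacing]
    g <- buildKernelGraph(kmap, "transverse", ids = guard, terminalIds = ids)
    counts <- c(counts, .bestGroupPath(g)$kernelCount)
  }
  if (length(counts) == 0) stop("all stations empty")
  mean(counts)
}

#' Count kernels per row (KNR)
#'
#' Builds the axial kernel graph over the central band of the circumference
#' (default: the central 50%) and reports the maximum Bellman-Ford
#' shortest-path kernel count over the start terminals - the highest kernel
#' count along a row path in the central area.
#'
#' @param kmap a \code{\linkS4class{KernelMap}}.
#' @param centralFraction fraction of the circumference forming the central
#'   band.
#' @return KNR, an integer count.
#' @export
countKernelsPerRow <- function(kmap, centralFraction = 0.5) {
  kc <- .kernelCoords(kmap)
  if (nrow(kc) == 0) stop("no valid kernels")
  if (nrow(kc) == 1) return(1L)
  H <- nrow(kmap@labels)
  lo <- H * (1 - centralFraction) / 2
  ids <- kc$kernelId[kc$yu >= lo & kc$yu <= H - lo]
  if (length(ids) == 0) stop("central band empty")
  if (length(ids) == 1) return(1L)
  # a guard row on each side of the band blocks hull shortcut edges
  spacing <- .medianSpacing(kc$x, kc$yu)
  guard <- kc$kernelId[kc$yu >= lo - 3 * spacing & kc$yu <= H - lo + 3 * spacing]
  g <- buildKernelGraph(kmap, "axial", ids = guard, terminalIds = ids)
  nodes <- g@nodes
  ss <- nodes$id[nodes$type == "start"]
  ee <- nodes$id[nodes$type == "end"]
  best <- 0L
  for (s in ss) {
    bf <- bellmanFord(nrow(nodes), as.matrix(g@edges), s)
    reach <- ee[is.finite(bf$dist[ee])]
    if (length(reach) == 0) next
    e <- reach[which.min(bf$dist[reach])]
    path <- .tracePath(bf$pred, s, e)
    best <- max(best, sum(nodes$type[path] == "kernel"))
  }
  as.integer(best)
}

#' Count total kernels (KNE)
#'
#' @param kmap a \code{\linkS4class{KernelMap}}.
#' @return number of valid kernels.
#' @export
countTotal <- function(kmap) sum(kmap@kernels$valid)
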