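# Shared fixtures and independent oracles.

# small, fast reference ear used across tests
cleanCylinderModel <- function(seed = 1L, jitter = 0) {
  dy <- 15 / 30; dv <- 2 * pi * 2.5 / 14
  buildEarModel(earLength = 15, maxRadius = 2.5, profile = "cylinder",
                nRows = 14L, kernelsPerRow = 30L, barrenTipFraction = 0,
                centroidJitterSd = jitter * min(dy, dv), seed = seed)
}

# masks of a model rendered at a few rotations (no noise)
modelMasks <- function(model, nFrames = 4L) {
  sq <- renderSequence(model, nFrames = nFrames,
                       rotationPerFrame = 360 / nFrames, nLead = 0L,
                       nTrail = 0L)
  ref <- list(background = model@backgroundColor, roller = model@rollerColor)
  lapply(sq@frames, function(f)
    normalizeOrientation(f, segmentEar(f, ref))$mask)
}

# --- independent oracles ---------------------------------------------------

# O(n^4) empty-circumcircle Delaunay graph: edge (i, j) is admitted when
# some circle through i and j contains no other point strictly inside.
# For points in general position this equals the Delaunay edge set.
bruteDelaunayEdges <- function(x, y) {
  n <- length(x)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- FALSE
    # candidate circles: circumcircles of (i, j, k) plus the diametral circle
    for (k in c(0, setdiff(seq_len(n), c(i, j)))) {
      if (k == 0) {
        cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
        r2 <- ((x[i] - x[j])^2 + (y[i] - y[j])^2) / 4
      } else {
        ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]
        cxx <- x[k]; cyy <- y[k]
        d <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
        if (abs(d) < 1e-12) next
        cx <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
               (cxx^2 + cyy^2) * (ay - by)) / d
        cy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
               (cxx^2 + cyy^2) * (bx - ax)) / d
        r2 <- (cx - ax)^2 + (cy - ay)^2
      }
      others <- setdiff(seq_len(n), c(i, j, if (k > 0) k else NULL))
      inside <- (x[others] - cx)^2 + (y[others] - cy)^2 < r2 * (1 - 1e-12)
      kIn <- if (k > 0)
        (x[k] - cx)^2 + (y[k] - cy)^2 < r2 * (1 - 1e-12) else FALSE
      if (!any(inside) && !kIn) { ok <- TRUE; break }
    }
    if (ok) edges <- rbind(edges, c(i, j))
  }
  edges
}

# textbook Dijkstra with the same (weight, hops) tie preference
dijkstraOracle <- function(nNodes, edges, source) {
  u <- c(edges[, 1], edges[, 2]); v <- c(edges[, 2], edges[, 1])
  w <- c(edges[, 3], edges[, 3])
  dist <- rep(Inf, nNodes); done <- rep(FALSE, nNodes)
  dist[source] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    cur <- cand[which.min(dist[cand])]
    done[cur] <- TRUE
    sel <- u == cur
    nd <- dist[cur] + w[sel]
    tgt <- v[sel]
    upd <- nd < dist[tgt]
    dist[tgt[upd]] <- nd[upd]
  }
  dist
}

# exhaustive enumeration of simple paths; returns the minimal total weight
exhaustiveShortest <- function(nNodes, edges, source, target) {
  adj <- vector("list", nNodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]; w <- edges[r, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- Inf
  recurse <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == target) { best <<- acc; return() }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb)))
      if (!visited[nb[r, 1]])
        recurse(nb[r, 1], `[<-`(visited, nb[r, 1], TRUE), acc + nb[r, 2])
  }
  recurse(source, `[<-`(logical(nNodes), source, TRUE), 0)
  best
}

# step-down Holm by its definition
bruteHolm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# 10^6-step trapezoid quadrature of the revolution integrals
quadratureOracle <- function(rfun, L, n = 1e6) {
  y <- seq(0, L, length.out = n + 1)
  r <- rfun(y)
  dy <- diff(y); dr <- diff(r)
  list(EV = sum(pi * (r[-length(r)]^2 + r[-1]^2) / 2 * dy),
       ESA = sum(pi * (r[-length(r)] + r[-1]) * sqrt(dy^2 + dr^2)))
}

ncc <- function(a, b) stats::cor(as.vector(a), as.vector(b))

# all permutations of 1..m as a list of index vectors
combinat_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(m - 1)) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1L]] <- append(sub, m, after = pos - 1L)
    }
  }
  out
}

# KernelMap built directly from a label raster with contiguous ids 1..n
# (for constructed fixtures)
kernelMapFromLabels <- function(labels, pixelSize = 3.126e-2,
                                wrapOrigin = 0) {
  st <- EarPheno:::.regionStats(labels)
  stopifnot(identical(st$id, seq_len(nrow(st))))
  st$valid <- TRUE
  rownames(st) <- NULL
  methods::new("KernelMap", labels = labels, kernels = st,
               wrapOrigin = wrapOrigin, pixelSize = pixelSize)
}
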