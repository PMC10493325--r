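test_that("Delaunay triangulation matches the empty-circumcircle oracle", {
  # random general-position point sets, n <= 12
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:12, 1)
    x <- runif(n) * 10; y <- runif(n) * 10
    tri <- delaunayTriangulation(x, y)
    got <- tri$edges[order(tri$edges[, 1], tri$edges[, 2]), , drop = FALSE]
    exp <- bruteDelaunayEdges(x, y)
    exp <- exp[order(exp[, 1], exp[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(exp), info = paste("seed", seed))
  }

  # 3x3 unit grid (degenerate cocircular squares): every produced edge is
  # admissible under the empty-circumcircle test, and all unambiguous
  # (strictly Delaunay) edges are present
  g <- expand.grid(x = 0:2, y = 0:2)
  tri <- delaunayTriangulation(g$x, g$y)
  adm <- bruteDelaunayEdges(g$x, g$y)
  keyG <- paste(tri$edges[, 1], tri$edges[, 2])
  keyA <- paste(adm[, 1], adm[, 2])
  expect_true(all(keyG %in% keyA))
  # the 12 axis-aligned unit edges are strictly Delaunay
  expect_true(all(c("1 2", "2 3", "4 5", "5 6", "7 8", "8 9",
                    "1 4", "4 7", "2 5", "5 8", "3 6", "6 9") %in% keyG))
})

test_that("Bellman-Ford agrees with Dijkstra and exhaustive enumeration", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    n <- sample(5:10, 1)
    x <- runif(n) * 10; y <- runif(n) * 10
    tri <- delaunayTriangulation(x, y)
    e <- tri$edges
    edges <- cbind(e, sqrt((x[e[, 1]] - x[e[, 2]])^2 +
                           (y[e[, 1]] - y[e[, 2]])^2))
    bf <- bellmanFord(n, edges, 1)
    expect_equal(bf$dist, dijkstraOracle(n, edges, 1), tolerance = 1e-9)
    tgt <- n
    expect_equal(bf$dist[tgt], exhaustiveShortest(n, edges, 1, tgt),
                 tolerance = 1e-9)
    # path weight equals the sum of its edge weights
    path <- EarPheno:::.tracePath(bf$pred, 1, tgt)
    wsum <- 0
    for (i in seq_len(length(path) - 1)) {
      sel <- (edges[, 1] == path[i] & edges[, 2] == path[i + 1]) |
             (edges[, 2] == path[i] & edges[, 1] == path[i + 1])
      wsum <- wsum + edges[sel, 3][1]
    }
    expect_equal(wsum, bf$dist[tgt], tolerance = 1e-9)
  }
  expect_error(bellmanFord(3, cbind(1, 2, -1), 1), "negative")
})

test_that("kernel segmentation recovers clean synthetic kernels one-to-one", {
  m <- cleanCylinderModel()
  rp <- renderPanorama(m)
  km <- segmentKernels(rp$panorama)
  expect_equal(nrow(kernelTable(km)), 420)
  # each region contains exactly one true label
  lab <- km@labels
  cross <- table(lab[lab > 0 & rp$labels > 0],
                 rp$labels[lab > 0 & rp$labels > 0])
  major <- apply(cross, 1, function(r) max(r) / sum(r))
  expect_true(all(major > 0.95))
  expect_equal(length(unique(apply(cross, 1, which.max))), 420)

  # pure cob-colored panorama: nothing to segment
  cob <- array(0L, dim = c(60, 80, 3))
  for (ch in 1:3) cob[, , ch] <- m@cobColor[ch]
  cobPano <- new("Panorama", rgb = cob, pixelSize = 3.126e-2,
                 provenance = list())
  expect_error(segmentKernels(cobPano), "no kernels detected")

  # two-kernel toy image with a 2-px groove
  toy <- array(0, dim = c(40, 60, 3))
  for (ch in 1:3) toy[, , ch] <- m@cobColor[ch]
  for (ch in 1:3) {
    toy[10:30, 10:28, ch] <- m@kernelColor[ch]
    toy[10:30, 31:49, ch] <- m@kernelColor[ch]
  }
  toyPano <- new("Panorama", rgb = toy, pixelSize = 3.126e-2,
                 provenance = list())
  km2 <- segmentKernels(toyPano, smoothSigma = 0.8)
  expect_equal(nrow(kernelTable(km2)), 2)
})

test_that("validity marking applies area and border rules", {
  labels <- matrix(0L, 60, 80)
  labels[20:29, 20:29] <- 1L   # 100 px kernel
  labels[40:49, 40:49] <- 2L   # 100 px kernel
  labels[10:12, 60] <- 3L      # 3 px speck
  labels[25:34, 78:80] <- 4L   # clipped at the right border
  km <- kernelMapFromLabels(labels)

  km1 <- markValid(km, aMin = 25, aMax = 400)
  expect_equal(kernelTable(km1)$valid, c(TRUE, TRUE, FALSE, TRUE))

  km2 <- markValid(km, aMin = 25, aMax = 400, borderMargin = 2L)
  expect_equal(kernelTable(km2)$valid, c(TRUE, TRUE, FALSE, FALSE))

  km3 <- markValid(km)  # defaults relative to the median area
  expect_false(kernelTable(km3)$valid[3])
})

test_that("kernel graphs connect terminals through the lattice", {
  # 2 kernels: chain fallback with terminals
  labels <- matrix(0L, 50, 60)
  labels[20:25, 10:15] <- 1L
  labels[20:25, 30:35] <- 2L
  km <- kernelMapFromLabels(labels)
  expect_warning(g <- buildKernelGraph(km, "axial"), "chain")
  expect_equal(nrow(graphNodes(g)), 4)  # 2 kernels + 2 terminals
  expect_equal(nrow(graphEdges(g)), 3)

  # jittered grids stay connected start-to-end over seeds
  for (seed in 1:10) {
    m <- cleanCylinderModel(seed = seed, jitter = 0.1)
    rp <- renderPanorama(m)
    km <- markValid(segmentKernels(rp$panorama))
    g <- buildKernelGraph(km, "transverse")
    nodes <- graphNodes(g)
    s <- nodes$id[nodes$type == "start"][1]
    e <- nodes$id[nodes$type == "end"][1]
    res <- shortestKernelPath(g, s, e)
    expect_true(is.finite(res$weight))
  }
})

test_that("shortest-path counting reads rows and kernels off the lattice", {
  # 1 x 5 collinear centroids, axial terminals: kernel count 5
  labels <- matrix(0L, 40, 120)
  for (i in 1:5) labels[18:22, (i * 20):(i * 20 + 4)] <- as.integer(i)
  km <- kernelMapFromLabels(labels)
  suppressWarnings(g <- buildKernelGraph(km, "axial"))
  nodes <- graphNodes(g)
  s <- nodes$id[nodes$type == "start"][1]
  e <- nodes$id[nodes$type == "end"][1]
  expect_equal(shortestKernelPath(g, s, e)$kernelCount, 5)

  # 4 x 4 unit grid, transverse direction: kernel count 4, cross-checked
  # against exhaustive enumeration over the same graph
  labels <- matrix(0L, 140, 140)
  for (i in 1:4) for (j in 1:4)
    labels[(j * 25):(j * 25 + 4), (i * 25):(i * 25 + 4)] <-
      as.integer((j - 1) * 4 + i)
  km <- kernelMapFromLabels(labels)
  g <- buildKernelGraph(km, "transverse")
  nodes <- graphNodes(g); edges <- as.matrix(graphEdges(g))
  s <- nodes$id[nodes$type == "start"][1]
  ee <- nodes$id[nodes$type == "end"]
  res <- lapply(ee, function(e) shortestKernelPath(g, s, e))
  wts <- vapply(res, `[[`, 1, "weight")
  best <- res[[which.min(wts)]]
  expect_equal(best$kernelCount, 4)
  expect_equal(unname(best$weight),
               unname(exhaustiveShortest(nrow(nodes), edges, s,
                                         ee[which.min(wts)])),
               tolerance = 1e-9)
})

test_that("row, per-row and total counts recover generator truth", {
  skipBig <- FALSE
  for (seed in 1:5) {
    m <- benchmarkEarModel(seed, jitterFraction = 0.05)
    rp <- renderPanorama(m)
    km <- markValid(segmentKernels(rp$panorama))
    expect_equal(countTotal(km), m@nRows * m@kernelsPerRow)
    expect_equal(countRows(km), m@nRows)
    expect_equal(countKernelsPerRow(km), m@kernelsPerRow)
    expect_gte(countTotal(km), countKernelsPerRow(km))
  }

  # degenerate single-row ear
  labels <- matrix(0L, 40, 200)
  for (i in 1:6) labels[18:22, (i * 25):(i * 25 + 4)] <- as.integer(i)
  km1 <- kernelMapFromLabels(labels)
  expect_equal(suppressWarnings(countRows(km1)), 1)

  # a barren tip shortens rows: KNR decreases at equal pitch
  mFull <- buildEarModel(15, 2.5, "cylinder", 14L, 30L,
                         barrenTipFraction = 0, seed = 3L)
  mBare <- buildEarModel(12, 2.5, "cylinder", 14L, 24L,
                         barrenTipFraction = 0.2, seed = 3L)
  kmF <- markValid(segmentKernels(renderPanorama(mFull)$panorama))
  kmB <- markValid(segmentKernels(renderPanorama(mBare)$panorama))
  expect_lt(countKernelsPerRow(kmB), countKernelsPerRow(kmF))

  # empty map counts zero
  kmE <- new("KernelMap", labels = matrix(0L, 5, 5),
             kernels = data.frame(id = integer(), x = numeric(),
                                  y = numeric(), area = integer(),
                                  xmin = integer(), xmax = integer(),
                                  ymin = integer(), ymax = integer(),
                                  valid = logical()),
             wrapOrigin = 0, pixelSize = 3.126e-2)
  expect_equal(countTotal(kmE), 0)
})

test_that("row counting tolerates heavy jitter on most ears", {
  # jitter sd = 0.15 lattice spacings: the reported row number (rounded to
  # an integer, as row counts are read in the field) is exact for at least
  # 19 of 20 ears; heavily jittered ears can leave one station off by one
  # row when two same-row kernels land nearly on top of each other
  ok <- 0L
  for (seed in 1:20) {
    m <- benchmarkEarModel(seed, jitterFraction = 0.15)
    rp <- renderPanorama(m)
    km <- markValid(segmentKernels(rp$panorama))
    rne <- tryCatch(countRows(km), error = function(e) NA)
    ok <- ok + as.integer(isTRUE(round(rne) == m@nRows))
  }
  expect_gte(ok, 19)
})
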