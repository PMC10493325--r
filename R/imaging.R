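#' Euclidean RGB distance raster
#' @param rgb H x W x 3 array.
#' @param ref RGB triple.
#' @return H x W matrix of distances.
#' @keywords internal
.colorDistance <- function(rgb, ref) {
  sqrt((rgb[, , 1] - ref[1])^2 + (rgb[, , 2] - ref[2])^2 +
       (rgb[, , 3] - ref[3])^2)
}

.luminance <- function(rgb)
  0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]

#' Estimate background and roller reference colors
#'
#' Derives the two dominant scene colors from an ear-free frame by coarse
#' RGB histogram binning: the most frequent bin is the background, the most
#' frequent remaining distinct bin the roller chain.
#'
#' @param frame H x W x 3 array (an ear-free frame).
#' @return list with RGB triples \code{background} and \code{roller}.
#' @export
estimateReference <- function(frame) {
  q <- 24
  bins <- (frame[, , 1] %/% q) * 10000 + (frame[, , 2] %/% q) * 100 +
    (frame[, , 3] %/% q)
  tab <- sort(table(bins), decreasing = TRUE)
  binMean <- function(b) {
    sel <- bins == as.numeric(b)
    c(mean(frame[, , 1][sel]), mean(frame[, , 2][sel]), mean(frame[, , 3][sel]))
  }
  bg <- binMean(names(tab)[1])
  roller <- bg
  for (nm in names(tab)[-1]) {
    cand <- binMean(nm)
    if (sqrt(sum((cand - bg)^2)) > 30) { roller <- cand; break }
  }
  list(background = bg, roller = roller)
}

#' Detect whether a frame contains an ear
#'
#' A frame is declared to contain an ear when the fraction of pixels whose
#' RGB distance from both the background and the roller reference colors
#' exceeds \code{tauColor} is above \code{tauArea}.
#'
#' @param frame H x W x 3 array.
#' @param reference list with \code{background} and \code{roller} RGB
#'   triples, e.g. from \code{\link{estimateReference}}.
#' @param tauColor color distance threshold (default 40).
#' @param tauArea area fraction threshold (default 0.02).
#' @return logical.
#' @export
detectEarPresent <- function(frame, reference, tauColor = 40,
                             tauArea = 0.02) {
  if (missing(reference) || is.null(reference))
    stop("no background reference available: calibrate with estimateReference() on an ear-free frame or supply reference colors")
  far <- .colorDistance(frame, reference$background) > tauColor &
         .colorDistance(frame, reference$roller) > tauColor
  mean(far) > tauArea
}

#' Segment the ear from a frame
#'
#' Color-distance thresholding against the background and roller references,
#' morphological closing then opening with a disk brush, and selection of
#' the largest connected component.
#'
#' @inheritParams detectEarPresent
#' @param morphRadius disk radius (px) of the closing/opening brush.
#' @return binary mask matrix (\code{TRUE} = ear).
#' @export
segmentEar <- function(frame, reference, tauColor = 40, morphRadius = 3) {
  cand <- .colorDistance(frame, reference$background) > tauColor &
          .colorDistance(frame, reference$roller) > tauColor
  kern <- EBImage::makeBrush(2L * morphRadius + 1L, shape = "disc")
  m <- EBImage::opening(EBImage::closing(cand * 1, kern), kern)
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) stop("no ear found")
  areas <- tabulate(lab[lab > 0])
  mask <- lab == which.max(areas)
  mask
}

#' Normalize ear orientation
#'
#' Rotates frame and mask so the mask's principal axis is horizontal, then
#' flips horizontally if needed so the butt (the wider end: larger mean
#' radius over the outer 20% of the mask's axial extent) sits at x = 0.
#' Near-circular masks (axis ratio below 1.1) are left unrotated with a
#' warning.
#'
#' @param frame H x W x 3 array.
#' @param mask binary matrix from \code{\link{segmentEar}}.
#' @param minAngle rotations smaller than this (degrees) are skipped.
#' @return list with rotated/flipped \code{frame} and \code{mask}, and the
#'   applied \code{angle} (degrees) and \code{flipped} flag.
#' @export
normalizeOrientation <- function(frame, mask, minAngle = 0.5) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  ym <- idx[, 1] - mean(idx[, 1]); xm <- idx[, 2] - mean(idx[, 2])
  mxx <- mean(xm^2); myy <- mean(ym^2); mxy <- mean(xm * ym)
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)$values
  angle <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (sqrt(ev[1] / max(ev[2], 1e-12)) < 1.1) {
    warning("near-circular mask: orientation left unchanged")
    angle <- 0
  }
  if (abs(angle) >= minAngle) {
    bg <- c(frame[1, 1, 1], frame[1, 1, 2], frame[1, 1, 3])
    img <- EBImage::Image(aperm(frame, c(2, 1, 3)) / 255, colormode = "Color")
    rot <- EBImage::rotate(img, -angle, bg.col = grDevices::rgb(
      bg[1] / 255, bg[2] / 255, bg[3] / 255))
    frame <- aperm(EBImage::imageData(rot), c(2, 1, 3)) * 255
    mrot <- EBImage::rotate(EBImage::Image(t(mask * 1)), -angle, bg.col = 0)
    mask <- t(EBImage::imageData(mrot)) > 0.5
  } else angle <- 0
  cols <- which(colSums(mask) > 0)
  outer20 <- max(1L, round(0.2 * length(cols)))
  leftR <- mean(colSums(mask)[cols[seq_len(outer20)]])
  rightR <- mean(colSums(mask)[cols[length(cols) - seq_len(outer20) + 1L]])
  flipped <- rightR > leftR
  if (flipped) {
    frame <- frame[, rev(seq_len(ncol(frame))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  list(frame = frame, mask = mask, angle = angle, flipped = flipped)
}

#' Extract the low-distortion central strip
#'
#' Returns the band of rows within \code{halfWidth} pixels of the mask's
#' central axis (the per-column midpoint of the mask), resampled into a
#' straight band over the mask's axial extent.
#'
#' @param frame H x W x 3 array with normalized orientation.
#' @param mask aligned binary mask.
#' @param halfWidth half band width in pixels.
#' @return (2 halfWidth + 1) x W' x 3 array with attribute \code{xrange},
#'   the frame column range it covers.
#' @export
centralStrip <- function(frame, mask, halfWidth = 20L) {
  cols <- which(colSums(mask) > 0)
  if (length(cols) == 0) stop("empty mask")
  heights <- colSums(mask)[cols]
  if (2L * halfWidth + 1L > max(heights))
    stop("strip wider than mask")
  H <- nrow(frame)
  strip <- array(0, dim = c(2L * halfWidth + 1L, length(cols), 3))
  for (ii in seq_along(cols)) {
    u <- cols[ii]
    rows <- which(mask[, u])
    mid <- round((min(rows) + max(rows)) / 2)
    sel <- pmin(pmax(mid + (-halfWidth:halfWidth), 1L), H)
    strip[, ii, ] <- frame[sel, u, ]
  }
  attr(strip, "xrange") <- range(cols)
  strip
}

#' Stitch central strips into a panorama
#'
#' Estimates the circumferential offset between consecutive strips by
#' maximizing normalized cross-correlation of their luminance within a
#' search window around the expected offset, composites the strips with
#' linear blending in the overlaps, and (optionally) folds the canvas onto
#' one full circumference.
#'
#' The circumferential scan direction is unknown a priori; the offset sign
#' is fixed from the first pair's best correlation and reused for the rest.
#'
#' @param strips list of equally sized strip arrays from
#'   \code{\link{centralStrip}}.
#' @param expectedOverlap expected row overlap between consecutive strips,
#'   px.
#' @param pixelSize cm per pixel of the source frames.
#' @param searchWindow half-width of the offset search window, px.
#' @param nWrap if not \code{NULL}, the number of strips spanning one full
#'   rotation; the canvas is folded at the cumulative offset of the first
#'   \code{nWrap} strips, yielding a one-circumference panorama.
#' @param minCor minimum acceptable pairwise correlation.
#' @return a \code{\linkS4class{Panorama}}; provenance records per-pair
#'   offsets and correlations.
#' @export
stitchStrips <- function(strips, expectedOverlap, pixelSize = 3.126e-2,
                         searchWindow = 8L, nWrap = NULL, minCor = 0.5) {
  nS <- length(strips)
  if (nS < 2) stop("need at least 2 strips to stitch")
  sh <- nrow(strips[[1]])
  dExp <- sh - round(expectedOverlap)
  if (dExp < 1) dExp <- 1L
  lums <- lapply(strips, .luminance)

  bestOffset <- function(a, b, signs) {
    cand <- unlist(lapply(signs, function(s)
      s * pmax(1L, pmin(sh - 2L, dExp + (-searchWindow:searchWindow)))))
    cand <- unique(cand)
    best <- c(cor = -Inf, d = NA)
    for (d in cand) {
      if (d > 0) { ov1 <- a[(d + 1):sh, ]; ov2 <- b[1:(sh - d), ] }
      else { ov1 <- a[1:(sh + d), ]; ov2 <- b[(1 - d):sh, ] }
      cc <- suppressWarnings(stats::cor(as.vector(ov1), as.vector(ov2)))
      if (is.finite(cc) && cc > best["cor"]) best <- c(cor = cc, d = d)
    }
    best
  }

  offsets <- numeric(nS - 1); cors <- numeric(nS - 1)
  sgn <- NULL
  for (i in seq_len(nS - 1)) {
    b <- bestOffset(lums[[i]], lums[[i + 1]],
                    signs = if (is.null(sgn)) c(1, -1) else sgn)
    if (!is.finite(b["cor"]) || b["cor"] < minCor)
      stop(sprintf("stitching failure between strips %d and %d (best correlation %.2f)",
                   i, i + 1, b["cor"]))
    if (is.null(sgn)) sgn <- if (b["d"] >= 0) 1 else -1
    offsets[i] <- abs(b["d"]); cors[i] <- b["cor"]
  }

  pos <- c(0, cumsum(offsets))  # top row (0-based) of each strip
  Hc <- max(pos) + sh
  Wc <- ncol(strips[[1]])
  Hpan <- if (!is.null(nWrap)) {
    if (nWrap >= nS) Hc else max(2L, round(pos[nWrap + 1]))
  } else Hc
  acc <- array(0, dim = c(Hpan, Wc, 3))
  wacc <- matrix(0, Hpan, Wc)
  rampBase <- pmin(seq_len(sh), rev(seq_len(sh)))
  for (i in seq_len(nS)) {
    rows <- (pos[i] + seq_len(sh) - 1L) %% Hpan + 1L
    s <- strips[[i]]
    if (sgn < 0) {
      s <- s[rev(seq_len(sh)), , , drop = FALSE]
    }
    w <- rampBase
    for (ch in 1:3)
      acc[rows, , ch] <- acc[rows, , ch] + s[, , ch] * w
    wacc[rows, ] <- wacc[rows, ] + w
  }
  wacc[wacc == 0] <- 1
  out <- array(0L, dim = c(Hpan, Wc, 3))
  for (ch in 1:3)
    out[, , ch] <- as.integer(round(pmin(pmax(acc[, , ch] / wacc, 0), 255)))
  new("Panorama", rgb = out, pixelSize = pixelSize,
      provenance = list(source = "stitch", offsets = offsets, cors = cors,
                        sign = sgn, nStrips = nS))
}
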