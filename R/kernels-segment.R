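#' Segment kernels on a panorama
#'
#' Kernel candidate pixels are separated from the cob by Otsu thresholding
#' of the smoothed luminance; individual kernels are then recovered by a
#' watershed of the smoothed luminance restricted to the candidate mask -
#' flooding grows regions from the bright kernel crowns down to the dark
#' groove valleys between kernels.  The circumferential axis is periodic:
#' segmentation runs on a vertically doubled raster and regions are deduped
#' into a one-circumference window opened at the groove line with the least
#' kernel occupancy, so kernels crossing the seam are recovered whole.
#'
#' @param panorama a \code{\linkS4class{Panorama}}.
#' @param earMask optional binary matrix restricting the ear region
#'   (default: the whole panorama is ear surface).
#' @param smoothSigma Gaussian smoothing sigma (px) for the luminance.
#' @param tolerance watershed tolerance in luminance units; maxima closer
#'   than this merge into one kernel.
#' @param minArea regions below this pixel area are discarded as specks.
#' @return a \code{\linkS4class{KernelMap}} (all kernels initially marked
#'   valid; see \code{\link{markValid}}).
#' @export
segmentKernels <- function(panorama, earMask = NULL, smoothSigma = 1.5,
                           tolerance = 5.5, minArea = 5L) {
  rgb <- panorama@rgb
  H <- nrow(rgb); W <- ncol(rgb)
  lum <- .luminance(rgb)
  lumS <- EBImage::gblur(lum, sigma = smoothSigma)
  if (is.null(earMask)) earMask <- matrix(TRUE, H, W)
  # threshold the raw luminance so kernel rims are not eroded by smoothing;
  # the smoothed relief is used only to seed/flood the watershed
  thr <- .otsu(lum[earMask])
  cand <- lum > thr & earMask
  if (!any(cand)) stop("no kernels detected")

  # open the circular axis at the least-occupied groove line
  occ <- rowSums(cand)
  v0 <- which.min(occ) - 1L  # 0-based wrap origin

  dbl <- rbind(lumS, lumS)
  cdbl <- rbind(cand, cand)
  relief <- dbl - min(dbl)
  relief[!cdbl] <- 0
  labDbl <- EBImage::watershed(relief, tolerance = tolerance, ext = 1)
  labDbl[!cdbl] <- 0L

  st <- .regionStats(labDbl, w = pmax(dbl - thr, 0)^2)
  if (nrow(st) == 0) stop("no kernels detected")
  # each kernel appears twice (at v and v + H); exactly one copy has its
  # centroid in the window (v0, v0 + H], and since v0 is a groove line no
  # kept region straddles the window cut, so the kept copy is never clipped
  keep <- st$y > v0 & st$y <= v0 + H & st$area >= minArea
  st <- st[keep, , drop = FALSE]
  if (nrow(st) == 0) stop("no kernels detected")
  st <- st[order(st$y, st$x), , drop = FALSE]
  oldIds <- st$id
  st$id <- seq_len(nrow(st))

  labels <- matrix(0L, H, W)
  pix <- which(labDbl %in% oldIds)
  plab <- labDbl[pix]
  prow <- (pix - 1L) %% (2L * H) + 1L
  pcol <- (pix - 1L) %/% (2L * H) + 1L
  newId <- integer(max(oldIds)); newId[oldIds] <- st$id
  rw <- (prow - 1L) %% H + 1L
  labels[rw + (pcol - 1L) * H] <- newId[plab]

  # regions fully in the upper copy move down one circumference; regions
  # crossing the seam keep continuous coordinates (y may exceed H there)
  shift <- ifelse(st$ymin > H, H, 0)
  st$y <- st$y - shift
  st$ymin <- st$ymin - shift
  st$ymax <- st$ymax - shift
  st$valid <- TRUE
  rownames(st) <- NULL
  new("KernelMap", labels = labels, kernels = st,
      wrapOrigin = as.numeric(v0), pixelSize = panorama@pixelSize)
}

# Otsu threshold on a numeric vector
.otsu <- function(v, nBins = 256L) {
  br <- seq(min(v), max(v), length.out = nBins + 1L)
  if (br[1] == br[length(br)]) return(br[1])
  w <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = nBins)
  m <- (br[-1] + br[-length(br)]) / 2
  tot <- sum(w)
  best <- -Inf; thr <- m[1]
  csum <- cumsum(w); cmean <- cumsum(w * m)
  mu <- cmean[length(cmean)] / tot
  for (k in seq_len(nBins - 1L)) {
    w0 <- csum[k] / tot; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- cmean[k] / csum[k]
    mu1 <- (cmean[length(cmean)] - cmean[k]) / (tot - csum[k])
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; thr <- m[k] }
  }
  thr
}

# per-label area, centroid, bbox from a label matrix; when an intensity
# weight raster is given the centroid is weighted by it (anchoring the
# centroid on the bright kernel crown, which is robust to boundary-pixel
# allocation when touching kernels are split)
.regionStats <- function(lab, w = NULL) {
  pix <- which(lab > 0)
  if (length(pix) == 0)
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      area = integer(), xmin = integer(), xmax = integer(),
                      ymin = integer(), ymax = integer()))
  H <- nrow(lab)
  ids <- lab[pix]
  rw <- (pix - 1L) %% H + 1L
  cl <- (pix - 1L) %/% H + 1L
  area <- tabulate(ids)
  present <- which(area > 0)
  wt <- if (is.null(w)) rep(1, length(pix)) else w[pix] + 1e-9
  sw <- rowsum(wt, ids)[, 1]
  sx <- rowsum(as.numeric(cl) * wt, ids)[, 1]
  sy <- rowsum(as.numeric(rw) * wt, ids)[, 1]
  xmin <- tapply(cl, ids, min); xmax <- tapply(cl, ids, max)
  ymin <- tapply(rw, ids, min); ymax <- tapply(rw, ids, max)
  data.frame(id = present, x = sx / sw, y = sy / sw,
             area = area[present],
             xmin = as.integer(xmin), xmax = as.integer(xmax),
             ymin = as.integer(ymin), ymax = as.integer(ymax))
}

#' Flag valid kernels
#'
#' A kernel is valid when its pixel area lies within \code{[aMin, aMax]} and
#' its bounding box keeps at least \code{borderMargin} pixels from the
#' axial (left/right) panorama borders.  The area defaults are relative to
#' the median kernel area.  The circumferential axis is periodic, so no
#' vertical border rule applies.
#'
#' @param kmap a \code{\linkS4class{KernelMap}}.
#' @param aMin,aMax area bounds in px (defaults: 0.25 and 4 times the
#'   median area).
#' @param borderMargin minimum distance (px) of the bounding box from the
#'   left/right borders; 0 disables the rule.
#' @return the map with the \code{valid} column updated.
#' @export
markValid <- function(kmap, aMin = NULL, aMax = NULL, borderMargin = 0L) {
  k <- kmap@kernels
  if (nrow(k) == 0) return(kmap)
  med <- stats::median(k$area)
  if (is.null(aMin)) aMin <- 0.25 * med
  if (is.null(aMax)) aMax <- 4 * med
  W <- ncol(kmap@labels)
  ok <- k$area >= aMin & k$area <= aMax
  if (borderMargin > 0)
    ok <- ok & k$xmin > borderMargin & k$xmax <= W - borderMargin
  kmap@kernels$valid <- ok
  kmap
}
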