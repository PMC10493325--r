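#' Render the ideal unrolled surface panorama of an ear model
#'
#' Emits the generator-side ground-truth panorama directly: the lateral
#' surface unrolled at constant circumferential scale (one full circumference
#' \eqn{2\pi R} maps to the raster height), butt at x = 0.  Kernels are drawn
#' as crowned ellipses over the cob background - a brighter core and a darker
#' rim whose shading is zero-mean over the ellipse, so the mean rendered
#' kernel color equals the configured color while grooves between kernels
#' remain segmentable valleys.  A 16-bit-style label raster records the true
#' kernel id under every kernel pixel.
#'
#' @param model an \code{\linkS4class{EarModel}}.
#' @param pixelSize cm per pixel (default 3.126e-2).
#' @param noiseSd optional additive Gaussian pixel noise sd (0-255 units).
#' @param illumGradient optional peak-to-peak axial illumination gradient
#'   (0-255 units, additive, zero mean).
#' @return list with elements \code{panorama}
#'   (\code{\linkS4class{Panorama}}), \code{labels} (integer matrix) and
#'   \code{truth} (named trait vector, see \code{\link{trueTraits}}).
#' @export
renderPanorama <- function(model, pixelSize = 3.126e-2, noiseSd = 0,
                           illumGradient = 0) {
  validObject(model)
  L <- model@earLength
  circ <- 2 * pi * model@maxRadius
  W <- round(L / pixelSize)
  H <- round(circ / pixelSize)
  if (W < 2 || H < 2) stop("degenerate model: panorama smaller than 2 px")
  prof <- profileRadius(model, (seq_len(W) - 0.5) * pixelSize)
  if (all(prof <= 0)) stop("degenerate model: zero radius everywhere")

  rgb <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) rgb[, , ch] <- model@cobColor[ch]
  labels <- matrix(0L, H, W)

  lat <- model@lattice
  aPx <- model@kernelAxialSemi / pixelSize
  bPx <- model@kernelArcSemi / pixelSize
  crownUp <- 36
  crownDown <- crownUp * 0.25 / 0.36  # zero area-weighted mean shading
  for (k in seq_len(nrow(lat))) {
    uc <- lat$y[k] / pixelSize + 0.5
    vc <- lat$s[k] / pixelSize + 0.5
    us <- max(1L, floor(uc - aPx)):min(W, ceiling(uc + aPx))
    vs <- floor(vc - bPx):ceiling(vc + bPx)  # may wrap
    du <- (us - uc) / aPx
    dv <- (vs - vc) / bPx
    rho2 <- outer(dv^2, du^2, "+")
    inside <- rho2 <= 1
    if (!any(inside)) next
    vw <- ((vs - 1L) %% H) + 1L
    shade <- matrix(0, length(vs), length(us))
    shade[rho2 <= 0.25] <- crownUp
    shade[rho2 >= 0.64 & inside] <- -crownDown
    idx <- which(inside, arr.ind = TRUE)
    rows <- vw[idx[, 1]]; cols <- us[idx[, 2]]
    lin <- rows + (cols - 1L) * H
    col <- c(lat$r[k], lat$g[k], lat$b[k])
    for (ch in 1:3)
      rgb[lin + (ch - 1L) * H * W] <- col[ch] + shade[idx]
    labels[lin] <- k
  }

  rgb <- .finishRaster(rgb, model@seed, offset = 1L,
                       noiseSd = noiseSd, illumGradient = illumGradient)
  pano <- new("Panorama", rgb = rgb, pixelSize = pixelSize,
              provenance = list(source = "render", seed = model@seed,
                                noiseSd = noiseSd))
  list(panorama = pano, labels = labels, truth = trueTraits(model))
}

# clamp/round to 0..255 integers, adding seeded noise and illumination
.finishRaster <- function(rgb, seed, offset, noiseSd = 0, illumGradient = 0) {
  d <- dim(rgb)
  if (illumGradient > 0) {
    grad <- illumGradient * (2 * (seq_len(d[2]) - 0.5) / d[2] - 1) / 2
    rgb <- rgb + rep(matrix(grad, d[1], d[2], byrow = TRUE), d[3])
  }
  if (noiseSd > 0) {
    nseed <- as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
    withr::with_seed(nseed, {
      rgb <- rgb + stats::rnorm(length(rgb), 0, noiseSd)
    })
  }
  out <- round(pmin(pmax(rgb, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Render a rotating frame sequence of an ear model
#'
#' Orthographic views of the textured ear rotating about its axis on a
#' roller conveyor, butt to the left, over a dark background with a
#' roller-colored band along the bottom of each frame.  Texture comes from
#' the model's noiseless panorama, sampled through the cylindrical mapping
#' \eqn{h = r(y)\,\sin\psi} (so the limb is foreshortened and only the
#' central strip is distortion-free, as for a real ear).  Leading and
#' trailing frames contain no ear, for ear-state detection.
#'
#' @param model an \code{\linkS4class{EarModel}}.
#' @param nFrames number of ear frames; \code{nFrames * rotationPerFrame}
#'   must reach at least 360 degrees.
#' @param rotationPerFrame rotation between frames, degrees.
#' @param pixelSize cm per pixel.
#' @param noiseSd optional additive Gaussian pixel noise sd.
#' @param nLead,nTrail number of empty frames before/after the ear.
#' @return an \code{\linkS4class{EarImageSequence}}.
#' @export
renderSequence <- function(model, nFrames = 28L, rotationPerFrame = 15,
                           pixelSize = 3.126e-2, noiseSd = 0,
                           nLead = 2L, nTrail = 2L) {
  validObject(model)
  if (nFrames * rotationPerFrame < 360)
    stop("insufficient total rotation: nFrames * rotationPerFrame must be >= 360 degrees")
  tex <- renderPanorama(model, pixelSize)$panorama@rgb
  Ht <- nrow(tex); Wt <- ncol(tex)
  maxRpx <- model@maxRadius / pixelSize
  margin <- 20L
  rollerBand <- 36L
  W <- Wt + 2L * margin
  H <- 2L * ceiling(maxRpx) + 2L * margin + rollerBand
  vc <- ceiling(maxRpx) + margin
  rpx <- profileRadius(model, (seq_len(Wt) - 0.5) * pixelSize) / pixelSize

  blank <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    blank[, , ch] <- model@backgroundColor[ch]
    blank[(H - rollerBand + 1L):H, , ch] <- model@rollerColor[ch]
  }

  # precompute per-pixel surface mapping of the ear bounding box
  hh <- seq_len(2L * ceiling(maxRpx) + 1L) - (ceiling(maxRpx) + 1L)  # v - vc
  hmat <- matrix(hh, length(hh), Wt)
  rmat <- matrix(rpx, length(hh), Wt, byrow = TRUE)
  visible <- abs(hmat) < rmat & rmat > 0.5

  frames <- vector("list", nLead + nFrames + nTrail)
  psi <- matrix(NA_real_, length(hh), Wt)
  psi[visible] <- asin(hmat[visible] / rmat[visible])
  ucol <- matrix(rep(seq_len(Wt), each = length(hh)), length(hh), Wt)
  earRows <- vc + hh
  for (f in seq_len(nFrames)) {
    phi <- (f - 1) * rotationPerFrame * pi / 180
    fr <- blank
    theta <- (phi + psi[visible]) %% (2 * pi)
    vtex <- pmin(Ht, floor(theta / (2 * pi) * Ht) + 1L)
    lin <- vtex + (ucol[visible] - 1L) * Ht
    rows <- earRows[row(hmat)[visible]]
    cols <- margin + ucol[visible]
    dst <- rows + (cols - 1L) * H
    for (ch in 1:3)
      fr[dst + (ch - 1L) * H * W] <- tex[lin + (ch - 1L) * Ht * Wt]
    frames[[nLead + f]] <- .finishRaster(fr, model@seed, offset = 100L + f,
                                         noiseSd = noiseSd)
  }
  for (f in c(seq_len(nLead), nLead + nFrames + seq_len(nTrail)))
    frames[[f]] <- .finishRaster(blank, model@seed, offset = 1000L + f,
                                 noiseSd = noiseSd)

  new("EarImageSequence", frames = frames, pixelSize = pixelSize,
      rotationPerFrame = rotationPerFrame,
      earFrames = as.integer(nLead + seq_len(nFrames)))
}
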