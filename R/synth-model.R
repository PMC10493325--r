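#' Build a parametric ear model
#'
#' Resolves a fully deterministic \code{\linkS4class{EarModel}}: the taper
#' profile, the kernel lattice (axial pitch spanning the kernel-bearing part
#' of the ear, circumferential pitch \eqn{2\pi R / nRows}), jittered kernel
#' centroids and per-kernel color draws.  The kernel lattice covers axial
#' positions \code{[0, (1 - barrenTipFraction) * earLength]}; kernel ellipse
#' semi-axes are fixed fractions (0.46 axial, 0.44 circumferential) of the
#' lattice pitches so that kernels are separated by narrow grooves.
#'
#' Centroid jitter is drawn from an isotropic Gaussian (sd
#' \code{centroidJitterSd}, cm) and clamped at 0.4 of the smaller lattice
#' pitch, so rows and columns never cross and the ground-truth counts remain
#' well defined.  Identical parameters and seed give a bit-identical model.
#'
#' @param earLength ear length, cm.
#' @param maxRadius maximum profile radius, cm.
#' @param profile one of \code{"spindle"}, \code{"cylinder"},
#'   \code{"sphere"}, \code{"sine"}; see \code{\linkS4class{EarModel}}.
#' @param nRows kernel rows around the circumference.
#' @param kernelsPerRow kernels per row.
#' @param barrenTipFraction fraction of the length at the tip with no
#'   kernels, in [0, 1).
#' @param kernelColor,cobColor,backgroundColor,rollerColor RGB triples
#'   (0-255).
#' @param kernelColorSd per-kernel color channel standard deviation.
#' @param centroidJitterSd centroid jitter, cm.
#' @param seed integer seed.
#' @return an \code{\linkS4class{EarModel}}.
#' @examples
#' m <- buildEarModel(earLength = 15, maxRadius = 2.5, profile = "cylinder",
#'                    nRows = 14, kernelsPerRow = 30, seed = 1)
#' nrow(earLattice(m))  # 420 kernel sites
#' @export
buildEarModel <- function(earLength, maxRadius = 2.5,
                          profile = c("spindle", "cylinder", "sphere", "sine"),
                          nRows = 14L, kernelsPerRow = 30L,
                          barrenTipFraction = 0.1,
                          kernelColor = c(210, 180, 60), kernelColorSd = 0,
                          cobColor = c(150, 80, 60),
                          backgroundColor = c(30, 30, 34),
                          rollerColor = c(90, 95, 110),
                          centroidJitterSd = 0, seed = 1L) {
  profile <- match.arg(profile)
  .checkScalar(earLength, "earLength", positive = TRUE)
  .checkScalar(maxRadius, "maxRadius", positive = TRUE)
  .checkScalar(barrenTipFraction, "barrenTipFraction")
  if (barrenTipFraction < 0 || barrenTipFraction >= 1)
    stop("barrenTipFraction must be in [0, 1)")
  nRows <- as.integer(nRows); kernelsPerRow <- as.integer(kernelsPerRow)
  if (nRows < 1L) stop("nRows must be >= 1")
  if (kernelsPerRow < 1L) stop("kernelsPerRow must be >= 1")
  for (nm in c("kernelColor", "cobColor", "backgroundColor", "rollerColor")) {
    v <- get(nm)
    if (!.validColor(v)) stop(nm, " must be an RGB triple in [0, 255]")
  }
  if (kernelColorSd < 0) stop("kernelColorSd must be >= 0")
  if (centroidJitterSd < 0) stop("centroidJitterSd must be >= 0")
  seed <- as.integer(seed)

  span <- (1 - barrenTipFraction) * earLength
  dy <- span / kernelsPerRow
  dv <- 2 * pi * maxRadius / nRows
  lat <- expand.grid(i = seq_len(kernelsPerRow), j = seq_len(nRows))
  y0 <- (lat$i - 0.5) * dy
  s0 <- (lat$j - 0.5) * dv
  lim <- 0.4 * min(dy, dv)
  n <- nrow(lat)
  withr::with_seed(seed, {
    jy <- pmin(pmax(stats::rnorm(n, 0, centroidJitterSd), -lim), lim)
    js <- pmin(pmax(stats::rnorm(n, 0, centroidJitterSd), -lim), lim)
    colJit <- matrix(stats::rnorm(3 * n, 0, kernelColorSd), ncol = 3)
  })
  lat$y <- y0 + jy
  lat$s <- (s0 + js) %% (2 * pi * maxRadius)
  lat$r <- pmin(pmax(kernelColor[1] + colJit[, 1], 0), 255)
  lat$g <- pmin(pmax(kernelColor[2] + colJit[, 2], 0), 255)
  lat$b <- pmin(pmax(kernelColor[3] + colJit[, 3], 0), 255)

  new("EarModel", earLength = earLength, maxRadius = maxRadius,
      profile = profile, nRows = nRows, kernelsPerRow = kernelsPerRow,
      barrenTipFraction = barrenTipFraction, kernelColor = kernelColor,
      kernelColorSd = kernelColorSd, cobColor = cobColor,
      backgroundColor = backgroundColor, rollerColor = rollerColor,
      centroidJitterSd = centroidJitterSd, seed = seed, lattice = lat,
      kernelAxialSemi = 0.46 * dy, kernelArcSemi = 0.44 * dv,
      pitchAxial = dy, pitchArc = dv)
}

.checkScalar <- function(x, name, positive = FALSE) {
  if (!(is.numeric(x) && length(x) == 1 && is.finite(x)))
    stop(name, " must be a single finite number")
  if (positive && x <= 0) stop(name, " must be positive")
}

#' Radius of the revolution profile
#'
#' Evaluates \eqn{r(y)} of an ear model at axial positions \code{y} (cm,
#' butt at 0).  Values outside \code{[0, earLength]} give 0.
#'
#' @param model an \code{\linkS4class{EarModel}}.
#' @param y numeric vector of axial positions, cm.
#' @return radii in cm.
#' @export
profileRadius <- function(model, y) {
  L <- model@earLength; R <- model@maxRadius
  t <- y / L
  s <- switch(model@profile,
    cylinder = rep(1, length(t)),
    sphere = sqrt(pmax(0, 1 - (2 * t - 1)^2)),
    sine = sin(pi * pmin(pmax(t, 0), 1)),
    spindle = {
      tb <- 0.15; tt <- 0.70
      v <- numeric(length(t))
      bl <- t < tb
      v[bl] <- sqrt(pmax(0, 1 - ((tb - t[bl]) / tb)^2))
      v[t >= tb & t <= tt] <- 1
      tp <- t > tt
      v[tp] <- cos(pi / 2 * (t[tp] - tt) / (1 - tt))
      v
    })
  out <- R * s
  out[t < 0 | t > 1] <- 0
  pmax(out, 0)
}

#' Sample the profile as a RadiusProfile table
#'
#' @param model an \code{\linkS4class{EarModel}}.
#' @param step axial sampling step, cm.
#' @return data.frame with columns \code{y} (cm, strictly increasing from the
#'   butt) and \code{r} (cm).
#' @export
modelProfile <- function(model, step = 0.05) {
  y <- seq(0, model@earLength, by = step)
  if (y[length(y)] < model@earLength) y <- c(y, model@earLength)
  data.frame(y = y, r = profileRadius(model, y))
}

#' Analytic ground-truth traits of an ear model
#'
#' Computes all twenty traits implied by the model, using the same trait
#' definitions as the measurement layer: surface area and volume by
#' fine-step frustum quadrature of the revolution profile (step
#' \code{1e-4 * earLength}), ear width as the mean diameter over the profile
#' region with \eqn{r \ge 0.25 \max r}, the non-sphericity shape index
#' \eqn{ES = ESA / (\pi^{1/3} (6 EV)^{2/3})}, exact lattice counts, and
#' color means (the ear color is the area-weighted kernel/cob mixture on the
#' unrolled surface).
#'
#' @param model an \code{\linkS4class{EarModel}}.
#' @return named numeric vector over \code{\link{TRAIT_NAMES}}.
#' @export
trueTraits <- function(model) {
  validObject(model)
  L <- model@earLength
  prof <- modelProfile(model, step = 1e-4 * L)
  sv <- surfaceVolume(prof)
  wp <- earWidthPerimeter(prof)
  es <- earShape(sv[["ESA"]], sv[["EV"]])
  a <- model@kernelAxialSemi; b <- model@kernelArcSemi
  lat <- model@lattice
  # the furthest kernel surface point of the resolved (jittered) lattice
  btl <- max(0, L - (max(lat$y) + a))
  bta <- if (btl > 0) {
    keep <- prof$y >= L - btl
    surfaceVolume(prof[keep, , drop = FALSE])[["ESA"]]
  } else 0
  # mean consecutive-centroid distance along the rows of the lattice
  ord <- order(lat$j, lat$i)
  dy <- diff(lat$y[ord]); ds <- diff(lat$s[ord])
  within <- diff(lat$j[ord]) == 0
  kt <- if (any(within)) mean(sqrt(dy[within]^2 + ds[within]^2)) else
    model@pitchAxial
  kne <- model@nRows * model@kernelsPerRow
  aka <- pi * a * b
  circ <- 2 * pi * model@maxRadius
  f <- kne * aka / (L * circ)  # kernel cover fraction of the unrolled surface
  earCol <- f * model@kernelColor + (1 - f) * model@cobColor
  out <- c(BTL = btl, EL = L, EP = wp[["EP"]], EW = wp[["EW"]],
           KNE = kne, KNR = model@kernelsPerRow, RNE = model@nRows,
           AKA = aka, BTA = bta,
           EB = earCol[3], EG = earCol[2], ER = earCol[1],
           ES = es, ESA = sv[["ESA"]], EV = sv[["EV"]],
           KB = model@kernelColor[3], KG = model@kernelColor[2],
           KR = model@kernelColor[1],
           KT = kt, KW = 2 * b)
  out[TRAIT_NAMES]
}

#' Randomized ear model under the benchmark study conditions
#'
#' Draws one ear from the benchmark population used throughout the accuracy
#' studies: length uniform on 12-20 cm, maximum radius uniform on
#' 2.2-2.6 cm, row number uniform on \{8, 10, 12, 14, 16, 18\}, axial kernel
#' pitch near 0.45 cm, barren tip fraction uniform on 0.05-0.15, centroid
#' jitter sd = 0.1 lattice spacings.  All draws derive from \code{seed}.
#'
#' @param seed integer seed (also the model seed).
#' @param jitterFraction centroid jitter sd as a fraction of the smaller
#'   lattice pitch.
#' @return an \code{\linkS4class{EarModel}}.
#' @export
benchmarkEarModel <- function(seed, jitterFraction = 0.1) {
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    len <- stats::runif(1, 12, 20)
    maxR <- stats::runif(1, 2.2, 2.6)
    rows <- sample(c(8L, 10L, 12L, 14L, 16L, 18L), 1)
    btf <- stats::runif(1, 0.05, 0.15)
  })
  kpr <- max(1L, as.integer(round((1 - btf) * len / 0.45)))
  dy <- (1 - btf) * len / kpr
  dv <- 2 * pi * maxR / rows
  buildEarModel(earLength = len, maxRadius = maxR, profile = "spindle",
                nRows = rows, kernelsPerRow = kpr, barrenTipFraction = btf,
                centroidJitterSd = jitterFraction * min(dy, dv), seed = seed)
}

#' @describeIn buildEarModel resolved kernel lattice of a model.
#' @param model an \code{\linkS4class{EarModel}}.
#' @export
earLattice <- function(model) model@lattice

setMethod("show", "EarModel", function(object) {
  cat(sprintf(
    "EarModel: %.1f cm x r%.2f cm (%s), %d rows x %d kernels, barren tip %.0f%%, seed %d\n",
    object@earLength, object@maxRadius, object@profile, object@nRows,
    object@kernelsPerRow, 100 * object@barrenTipFraction, object@seed))
})

setMethod("show", "Panorama", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("Panorama: %d x %d px (%.4f cm/px), %.1f x %.1f cm\n",
              d[1], d[2], object@pixelSize,
              d[2] * object@pixelSize, d[1] * object@pixelSize))
})

setMethod("show", "KernelMap", function(object) {
  cat(sprintf("KernelMap: %d kernels (%d valid), raster %d x %d\n",
              nrow(object@kernels), sum(object@kernels$valid),
              nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "KernelGraph", function(object) {
  tb <- table(object@nodes$type)
  cat(sprintf("KernelGraph (%s): %d kernels, %d start, %d end terminals, %d edges\n",
              object@direction, tb[["kernel"]], tb[["start"]], tb[["end"]],
              nrow(object@edges)))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: Vg = %.4g, Vgl = %.4g, Ve = %.4g (L = %d, R = %d, %d EM iterations%s)\n",
    object@Vg, object@Vgl, object@Ve, object@L, object@R, object@iterations,
    if (object@converged) "" else ", NOT converged"))
})

setMethod("show", "EarImageSequence", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("EarImageSequence: %d frames (%d with ear), %d x %d px, %.1f deg/frame\n",
              length(object@frames), length(object@earFrames), d[1], d[2],
              object@rotationPerFrame))
})

#' Accessors for image containers
#'
#' \code{panoramaImage} returns the H x W x 3 RGB array of a panorama,
#' \code{pixelSize} the cm-per-pixel scale, \code{kernelTable} the per-kernel
#' record table, \code{graphNodes}/\code{graphEdges} the graph tables, and
#' \code{sequenceFrames} the frame list of a sequence.
#'
#' @param x a package object.
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
panoramaImage <- function(x) x@rgb

#' @rdname accessors
#' @export
pixelSize <- function(x) x@pixelSize

#' @rdname accessors
#' @export
kernelTable <- function(x) x@kernels

#' @rdname accessors
#' @export
graphNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
graphEdges <- function(x) x@edges

#' @rdname accessors
#' @export
sequenceFrames <- function(x) x@frames

#' @rdname accessors
#' @export
varianceComponents <- function(x)
  c(Vg = x@Vg, Vgl = x@Vgl, Ve = x@Ve, L = x@L, R = x@R)
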