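#' Radius profile from a mask sequence
#'
#' Half the transverse mask extent at each axial column, averaged across
#' frames and converted to cm.  Masks must be orientation-normalized (ear
#' horizontal, butt left).
#'
#' @param masks list of binary mask matrices (or a single matrix).
#' @param pixelSize cm per pixel.
#' @param smoothWindow odd width (in samples) of a centered running mean
#'   applied to the radii; 1 (default) leaves them raw.  A small window
#'   suppresses the staircase quantization of the mask boundary, which
#'   otherwise inflates the frustum slant lengths on tapered spans.
#' @return data.frame with columns \code{y} (cm from the butt) and \code{r}
#'   (cm); one row per axial sample.
#' @export
radiusProfile <- function(masks, pixelSize = 3.126e-2, smoothWindow = 1L) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) == 0) stop("empty mask sequence")
  profs <- lapply(masks, function(m) {
    cols <- which(colSums(m) > 0)
    if (length(cols) == 0) stop("empty mask")
    h <- colSums(m)[cols]
    list(cols = cols - min(cols), h = h)
  })
  W <- max(vapply(profs, function(p) max(p$cols) + 1L, 1L))
  acc <- numeric(W); cnt <- numeric(W)
  for (p in profs) {
    acc[p$cols + 1L] <- acc[p$cols + 1L] + p$h
    cnt[p$cols + 1L] <- cnt[p$cols + 1L] + 1
  }
  cnt[cnt == 0] <- 1
  r <- acc / cnt / 2 * pixelSize
  if (smoothWindow > 1L) {
    k <- as.integer(smoothWindow) %/% 2L * 2L + 1L
    rs <- stats::filter(r, rep(1 / k, k), sides = 2)
    r <- ifelse(is.na(rs), r, as.numeric(rs))
  }
  data.frame(y = (seq_len(W) - 0.5) * pixelSize, r = r)
}

#' Ear length (EL)
#'
#' Mean over frames of the corrected axial mask extent, in cm.  The axial
#' distortion correction factor defaults to the identity; when the camera
#' view half-angle is known, the chord-to-arc factor
#' \eqn{\theta / \sin\theta} can be supplied.
#'
#' @param masks list of normalized binary masks (or one matrix).
#' @param pixelSize cm per pixel.
#' @param cameraTheta camera view half-angle in radians; 0 (default) applies
#'   no correction.
#' @return EL in cm.
#' @export
earLength <- function(masks, pixelSize = 3.126e-2, cameraTheta = 0) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) == 0) stop("empty mask sequence")
  corr <- if (cameraTheta > 0) cameraTheta / sin(cameraTheta) else 1
  ext <- vapply(masks, function(m) {
    cols <- which(colSums(m) > 0)
    if (length(cols) == 0) stop("empty mask")
    diff(range(cols)) + 1
  }, 1)
  mean(ext) * pixelSize * corr
}

#' Ear width and perimeter (EW, EP)
#'
#' EW is the mean diameter over the profile samples with radius at least a
#' quarter of the maximum (excluding the tapered ends from the average);
#' EP = pi * EW.
#'
#' @param profile data.frame with columns \code{y}, \code{r} (cm).
#' @param taperCutoff radius fraction below which samples are excluded.
#' @return named vector \code{c(EW, EP)} in cm.
#' @export
earWidthPerimeter <- function(profile, taperCutoff = 0.25) {
  r <- profile$r
  if (all(r <= 0)) stop("all-zero radius profile")
  keep <- r >= taperCutoff * max(r)
  ew <- mean(2 * r[keep])
  c(EW = ew, EP = pi * ew)
}

#' Surface area and volume by frustum quadrature (ESA, EV)
#'
#' Composite trapezoid / frustum rule over the radius profile of the solid
#' of revolution: \eqn{EV = \sum \pi (r_i^2 + r_{i+1}^2)/2\, \Delta y} and
#' \eqn{ESA = \sum \pi (r_i + r_{i+1}) \sqrt{\Delta y^2 + \Delta r^2}}
#' (frustum lateral areas; end caps excluded, as real ears taper to near
#' zero radius).
#'
#' @param profile data.frame with columns \code{y} (strictly increasing,
#'   cm) and \code{r} (cm).
#' @return named vector \code{c(ESA, EV)} in cm^2 and cm^3.
#' @export
surfaceVolume <- function(profile) {
  y <- profile$y; r <- profile$r
  if (length(y) < 2) stop("need at least 2 profile samples")
  if (any(diff(y) <= 0)) stop("profile y must be strictly increasing")
  dy <- diff(y); dr <- diff(r)
  ev <- sum(pi * (r[-length(r)]^2 + r[-1]^2) / 2 * dy)
  esa <- sum(pi * (r[-length(r)] + r[-1]) * sqrt(dy^2 + dr^2))
  c(ESA = esa, EV = ev)
}

#' Non-sphericity ear shape index (ES)
#'
#' Surface area relative to the sphere of equal volume:
#' \eqn{ES = ESA / (\pi^{1/3} (6 EV)^{2/3})}.  Equals 1 for a sphere and
#' exceeds 1 for any other shape.
#'
#' @param ESA surface area, cm^2.
#' @param EV volume, cm^3.
#' @return ES (unitless).
#' @export
earShape <- function(ESA, EV) {
  if (EV <= 0) stop("EV must be positive")
  ESA / (pi^(1 / 3) * (6 * EV)^(2 / 3))
}

#' Barren tip length and area (BTL, BTA)
#'
#' BTL is the axial distance from the tip end of the radius profile to the
#' tip-most valid-kernel pixel; BTA is the frustum lateral area of the
#' profile over that barren span.
#'
#' @param kmap a \code{\linkS4class{KernelMap}} aligned to the profile
#'   (butt at x = 0, same pixel size).
#' @param profile radius profile data.frame (cm).
#' @return named vector \code{c(BTL, BTA)}.
#' @export
barrenTip <- function(kmap, profile) {
  tipY <- .tipPosition(profile)
  k <- kmap@kernels[kmap@kernels$valid, , drop = FALSE]
  if (nrow(k) == 0) {
    warning("no valid kernels: barren tip spans the whole ear")
    btl <- tipY
  } else {
    # the barren span starts at the right edge of the furthest kernel pixel
    btl <- max(0, tipY - max(k$xmax) * kmap@pixelSize)
  }
  bta <- 0
  if (btl > 0) {
    piece <- profile[profile$y >= tipY - btl & profile$r > 0, , drop = FALSE]
    if (max(piece$y) < tipY)  # extrapolated tip closes the profile at r = 0
      piece <- rbind(piece, data.frame(y = tipY, r = 0))
    if (nrow(piece) >= 2) bta <- surfaceVolume(piece)[["ESA"]]
  }
  c(BTL = btl, BTA = bta)
}

# The true tip of a tapering ear extends a few pixels past the last mask
# column (the silhouette there is thinner than the morphological brush), so
# the tip position is recovered by extrapolating the taper flank to r = 0.
.tipPosition <- function(profile) {
  pos <- profile[profile$r > 0, , drop = FALSE]
  yEnd <- max(pos$y)
  rmax <- max(pos$r)
  flank <- pos[pos$y > yEnd - 0.25 * diff(range(pos$y)) &
               pos$r < 0.35 * rmax, , drop = FALSE]
  if (nrow(flank) >= 3 && stats::sd(flank$r) > 0) {
    fit <- stats::lm(y ~ r, data = flank)
    tipY <- unname(stats::predict(fit, data.frame(r = 0)))
    if (is.finite(tipY) && tipY > yEnd && tipY < yEnd + 0.05 * diff(range(pos$y)))
      return(tipY)
  }
  yEnd
}

#' Kernel geometry traits (AKA, KT, KW)
#'
#' AKA is the mean valid-kernel pixel area in cm^2; KT (kernel thickness,
#' the stacking pitch along a row) is the mean consecutive-centroid
#' distance along the axial shortest paths; KW (crown width) is the mean
#' valid-kernel bounding extent along the transverse axis.
#'
#' @param kmap a \code{\linkS4class{KernelMap}}.
#' @param graph optional \code{\linkS4class{KernelGraph}} in the requested
#'   \code{ktDirection}; built from all valid kernels when omitted.
#' @param ktDirection direction of the kernel-thickness path: \code{"axial"}
#'   (default; thickness is the stacking pitch along a row) or
#'   \code{"transverse"}.
#' @param kwMethod kernel width as the transverse bounding extent of the
#'   crown (\code{"extent"}, default) or as the mean consecutive-centroid
#'   spacing along the transverse paths (\code{"spacing"}).
#' @return named vector \code{c(AKA, KT, KW)} (cm^2, cm, cm).
#' @export
kernelGeometry <- function(kmap, graph = NULL,
                           ktDirection = c("axial", "transverse"),
                           kwMethod = c("extent", "spacing")) {
  ktDirection <- match.arg(ktDirection)
  kwMethod <- match.arg(kwMethod)
  k <- kmap@kernels[kmap@kernels$valid, , drop = FALSE]
  if (nrow(k) == 0) stop("no valid kernels")
  px <- kmap@pixelSize
  aka <- mean(k$area) * px^2
  kw <- mean(k$ymax - k$ymin + 1) * px
  if (kwMethod == "spacing" && nrow(k) >= 2) {
    gT <- buildKernelGraph(kmap, "transverse")
    sp <- .pathGaps(gT)
    if (length(sp)) kw <- mean(sp) * px
  }
  kt <- NA_real_
  if (nrow(k) >= 2) {
    if (is.null(graph)) graph <- buildKernelGraph(kmap, ktDirection,
                                                  wrapGuard =
                                                    ktDirection == "axial")
    gaps <- .pathGaps(graph)
    if (length(gaps)) kt <- mean(gaps) * px
  }
  c(AKA = aka, KT = kt, KW = kw)
}

# consecutive kernel-kernel distances (px) along the best shortest path
# from each start terminal of a kernel graph
.pathGaps <- function(graph) {
  nodes <- graph@nodes
  ss <- nodes$id[nodes$type == "start"]
  ee <- nodes$id[nodes$type == "end"]
  gaps <- numeric(0)
  for (s in ss) {
    bf <- bellmanFord(nrow(nodes), as.matrix(graph@edges), s)
    reach <- ee[is.finite(bf$dist[ee])]
    if (length(reach) == 0) next
    e <- reach[which.min(bf$dist[reach])]
    path <- .tracePath(bf$pred, s, e)
    kp <- path[nodes$type[path] %in% c("kernel", "guard")]
    if (length(kp) >= 2) {
      dx <- diff(nodes$x[kp]); dyy <- diff(nodes$y[kp])
      gaps <- c(gaps, sqrt(dx^2 + dyy^2))
    }
  }
  gaps
}

#' Ear and kernel color traits (ER, EG, EB, KR, KG, KB)
#'
#' Ear channels are averaged over the full ear region (kernels, exposed cob
#' and barren tip alike); kernel channels are averaged over valid kernel
#' regions only.
#'
#' @param panorama a \code{\linkS4class{Panorama}}.
#' @param kmap a \code{\linkS4class{KernelMap}} aligned to it.
#' @param earMask optional binary matrix; default: the whole panorama.
#' @return named vector \code{c(ER, EG, EB, KR, KG, KB)}, values 0-255.
#' @export
colorTraits <- function(panorama, kmap, earMask = NULL) {
  rgb <- panorama@rgb
  if (is.null(earMask)) earMask <- matrix(TRUE, nrow(rgb), ncol(rgb))
  if (!any(earMask)) stop("empty ear region")
  validIds <- kmap@kernels$id[kmap@kernels$valid]
  kmask <- matrix(kmap@labels %in% validIds, nrow(rgb), ncol(rgb))
  if (!any(kmask)) stop("no valid kernel region")
  ear <- vapply(1:3, function(ch) mean(rgb[, , ch][earMask]), 1)
  ker <- vapply(1:3, function(ch) mean(rgb[, , ch][kmask]), 1)
  c(ER = ear[1], EG = ear[2], EB = ear[3],
    KR = ker[1], KG = ker[2], KB = ker[3])
}

#' Measure the twenty traits from a panorama and mask sequence
#'
#' Computes every requested trait from an already-assembled panorama (ideal
#' or stitched) and the orientation-normalized per-frame ear masks: lengths
#' and solid-of-revolution geometry from the radius profile, counts from the
#' kernel Delaunay graph, colors from the panorama.
#'
#' @param panorama a \code{\linkS4class{Panorama}}.
#' @param masks list of normalized binary ear masks (or one matrix).
#' @param traits \code{"all"} or a subset of \code{\link{TRAIT_NAMES}};
#'   stages not needed for the request are skipped.
#' @param kmap optional precomputed \code{\linkS4class{KernelMap}}.
#' @return list with \code{traits} (named vector over
#'   \code{\link{TRAIT_NAMES}}), \code{kmap} and \code{profile}.
#' @export
measureEar <- function(panorama, masks, traits = "all", kmap = NULL) {
  want <- function(x) identical(traits, "all") || any(x %in% traits)
  px <- panorama@pixelSize
  prof <- radiusProfile(masks, px, smoothWindow = 5L)
  out <- rep(NA_real_, length(TRAIT_NAMES))
  names(out) <- TRAIT_NAMES
  out["EL"] <- earLength(masks, px)
  wp <- earWidthPerimeter(prof)
  out["EW"] <- wp[["EW"]]; out["EP"] <- wp[["EP"]]
  sv <- surfaceVolume(prof)
  out["ESA"] <- sv[["ESA"]]; out["EV"] <- sv[["EV"]]
  out["ES"] <- earShape(sv[["ESA"]], sv[["EV"]])
  if (want(c("KNE", "KNR", "RNE", "AKA", "KT", "KW", "BTL", "BTA",
             "ER", "EG", "EB", "KR", "KG", "KB"))) {
    if (is.null(kmap)) kmap <- markValid(segmentKernels(panorama))
    if (want("KNE")) out["KNE"] <- countTotal(kmap)
    if (want("RNE")) out["RNE"] <- countRows(kmap)
    if (want("KNR")) out["KNR"] <- countKernelsPerRow(kmap)
    if (want(c("AKA", "KT", "KW"))) {
      kg <- kernelGeometry(kmap)
      out["AKA"] <- kg[["AKA"]]; out["KT"] <- kg[["KT"]]
      out["KW"] <- kg[["KW"]]
    }
    if (want(c("BTL", "BTA"))) {
      bt <- barrenTip(kmap, prof)
      out["BTL"] <- bt[["BTL"]]; out["BTA"] <- bt[["BTA"]]
    }
    if (want(c("ER", "EG", "EB", "KR", "KG", "KB"))) {
      ct <- colorTraits(panorama, kmap)
      out[names(ct)] <- ct
    }
  }
  list(traits = out, kmap = kmap, profile = prof)
}

#' Measure the twenty traits of one ear
#'
#' Runs the full measurement pipeline on a rotating frame sequence:
#' ear-state detection, color segmentation, orientation normalization,
#' radius profiling, central-strip stitching into a panorama, kernel
#' segmentation and validity marking, Delaunay/Bellman-Ford counting, and
#' the geometric and color traits.
#'
#' @param seq an \code{\linkS4class{EarImageSequence}} (or any list of
#'   frames with the same metadata slots).
#' @param reference background/roller reference colors; estimated from the
#'   first frame when omitted (the sequence is expected to lead with an
#'   ear-free frame).
#' @param stripHalfWidth central strip half-width, px.
#' @param traits which traits to compute: \code{"all"} or a subset of
#'   \code{\link{TRAIT_NAMES}} (counting and color stages are skipped when
#'   not requested).
#' @param tauColor,tauArea,morphRadius segmentation thresholds, see
#'   \code{\link{detectEarPresent}} and \code{\link{segmentEar}}.
#' @return list with \code{traits} (named vector), \code{panorama},
#'   \code{kmap}, \code{profile} and \code{masks}.
#' @export
phenotypeEar <- function(seq, reference = NULL, stripHalfWidth = 20L,
                         traits = "all", tauColor = 40, tauArea = 0.02,
                         morphRadius = 3) {
  want <- function(x) identical(traits, "all") || any(x %in% traits)
  px <- seq@pixelSize
  frames <- seq@frames
  if (is.null(reference)) reference <- estimateReference(frames[[1]])
  present <- vapply(frames, detectEarPresent, TRUE, reference = reference,
                    tauColor = tauColor, tauArea = tauArea)
  if (!any(present)) stop("no ear found in sequence")
  earIdx <- which(present)

  norm <- lapply(earIdx, function(i) {
    m <- segmentEar(frames[[i]], reference, tauColor, morphRadius)
    normalizeOrientation(frames[[i]], m)
  })
  masks <- lapply(norm, `[[`, "mask")

  pano <- NULL
  needPano <- want(c("KNE", "KNR", "RNE", "AKA", "KT", "KW", "BTL", "BTA",
                     "ER", "EG", "EB", "KR", "KG", "KB"))
  if (needPano) {
    strips <- lapply(seq_along(norm), function(i)
      centralStrip(norm[[i]]$frame, masks[[i]], stripHalfWidth))
    prof0 <- radiusProfile(masks, px)
    maxRpx <- max(prof0$r) / px
    dExp <- maxRpx * seq@rotationPerFrame * pi / 180
    nWrap <- ceiling(360 / seq@rotationPerFrame)
    pano <- stitchStrips(strips, expectedOverlap = nrow(strips[[1]]) - dExp,
                         pixelSize = px, nWrap = nWrap)
  } else {
    # profile-only placeholder panorama; kernel stages are skipped
    pano <- new("Panorama", rgb = array(0L, c(2, 2, 3)), pixelSize = px,
                provenance = list(source = "none"))
  }
  me <- measureEar(pano, masks, traits = traits)
  list(traits = me$traits, panorama = if (needPano) pano else NULL,
       kmap = me$kmap, profile = me$profile, masks = masks)
}

#' Write a trait table CSV
#'
#' One row per ear, trait columns in the canonical alphabetical header
#' order.
#'
#' @param traitList list of named trait vectors (or a single vector).
#' @param path output file.
#' @param ids optional ear identifiers for a leading \code{ear} column.
#' @return the written data.frame, invisibly.
#' @export
writeTraitCSV <- function(traitList, path, ids = NULL) {
  if (!is.list(traitList)) traitList <- list(traitList)
  hdr <- TRAIT_NAMES
  df <- as.data.frame(do.call(rbind, lapply(traitList, function(x) x[hdr])))
  names(df) <- hdr
  if (!is.null(ids)) df <- cbind(ear = ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
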