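#' @import methods
NULL

#' Parametric maize ear model
#'
#' An \code{EarModel} describes a maize ear as a tapered solid of revolution
#' carrying kernels on a jittered axial lattice: \code{nRows} longitudinal
#' rows around the circumference, \code{kernelsPerRow} kernels per row, and a
#' kernel-free (barren) span at the tip.  The model is fully deterministic
#' given its parameters and \code{seed}; all downstream renders are
#' bit-identical for identical models.
#'
#' @slot earLength ear length in cm (butt at axial position 0).
#' @slot maxRadius maximum radius of the revolution profile, cm.
#' @slot profile profile name: \code{"spindle"} (rounded elliptic butt,
#'   cylindrical body, cosine-tapered tip), \code{"cylinder"},
#'   \code{"sphere"} (half-circle profile; a true sphere when
#'   \code{earLength == 2 * maxRadius}) or \code{"sine"}
#'   (\eqn{r(y) = R \sin(\pi y / L)}).
#' @slot nRows number of kernel rows around the circumference.
#' @slot kernelsPerRow number of kernels in each row.
#' @slot barrenTipFraction fraction of the ear length at the tip bearing no
#'   kernels, in [0, 1).
#' @slot kernelColor mean kernel RGB, 0-255.
#' @slot kernelColorSd per-kernel standard deviation added to each channel.
#' @slot cobColor,backgroundColor,rollerColor RGB triples, 0-255.
#' @slot centroidJitterSd isotropic Gaussian jitter (cm) applied to kernel
#'   centroids, clamped at 0.4 lattice spacings so rows never cross.
#' @slot seed integer seed driving the jitter and per-kernel color streams.
#' @slot lattice data.frame of resolved kernel sites: axial index \code{i},
#'   row index \code{j}, jittered axial position \code{y} (cm) and
#'   circumferential arc position \code{s} (cm, at radius \code{maxRadius}).
#' @slot kernelAxialSemi,kernelArcSemi kernel ellipse semi-axes, cm.
#' @slot pitchAxial,pitchArc lattice pitches, cm.
#'
#' @seealso \code{\link{buildEarModel}}, \code{\link{trueTraits}},
#'   \code{\link{renderPanorama}}, \code{\link{renderSequence}}
#' @exportClass EarModel
setClass("EarModel", representation(
  earLength = "numeric",
  maxRadius = "numeric",
  profile = "character",
  nRows = "integer",
  kernelsPerRow = "integer",
  barrenTipFraction = "numeric",
  kernelColor = "numeric",
  kernelColorSd = "numeric",
  cobColor = "numeric",
  backgroundColor = "numeric",
  rollerColor = "numeric",
  centroidJitterSd = "numeric",
  seed = "integer",
  lattice = "data.frame",
  kernelAxialSemi = "numeric",
  kernelArcSemi = "numeric",
  pitchAxial = "numeric",
  pitchArc = "numeric"
))

.validColor <- function(x) length(x) == 3 && all(is.finite(x)) &&
  all(x >= 0) && all(x <= 255)

setValidity("EarModel", function(object) {
  msg <- character()
  if (!(length(object@earLength) == 1 && object@earLength > 0))
    msg <- c(msg, "earLength must be a single positive number")
  if (!(length(object@maxRadius) == 1 && object@maxRadius > 0))
    msg <- c(msg, "maxRadius must be a single positive number")
  if (!object@profile %in% c("spindle", "cylinder", "sphere", "sine"))
    msg <- c(msg, "profile must be one of spindle/cylinder/sphere/sine")
  if (object@nRows < 1L)
    msg <- c(msg, "nRows must be >= 1")
  if (object@kernelsPerRow < 1L)
    msg <- c(msg, "kernelsPerRow must be >= 1")
  if (object@barrenTipFraction < 0 || object@barrenTipFraction >= 1)
    msg <- c(msg, "barrenTipFraction must be in [0, 1)")
  for (slot in c("kernelColor", "cobColor", "backgroundColor", "rollerColor"))
    if (!.validColor(slot(object, slot)))
      msg <- c(msg, paste(slot, "must be an RGB triple in [0, 255]"))
  if (object@kernelColorSd < 0)
    msg <- c(msg, "kernelColorSd must be >= 0")
  if (object@centroidJitterSd < 0)
    msg <- c(msg, "centroidJitterSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Panoramic ear surface image
#'
#' The ear's lateral surface unrolled into a flat 8-bit RGB raster: the axial
#' axis is horizontal (butt at x = 0), the circumferential axis vertical and
#' periodic (one full circumference).  Panoramas come from
#' \code{\link{renderPanorama}} (ideal, generator-side) or from
#' \code{\link{stitchStrips}} (reconstructed from a frame sequence).
#'
#' @slot rgb integer array H x W x 3, values 0-255.
#' @slot pixelSize cm per pixel.
#' @slot provenance list of assembly metadata (strip offsets, correlations).
#' @exportClass Panorama
setClass("Panorama", representation(
  rgb = "array", pixelSize = "numeric", provenance = "list"
))

setValidity("Panorama", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3 || d[3] != 3) return("rgb must be an H x W x 3 array")
  if (min(object@rgb) < 0 || max(object@rgb) > 255)
    return("rgb values must lie in [0, 255]")
  if (!(length(object@pixelSize) == 1 && object@pixelSize > 0))
    return("pixelSize must be a single positive number")
  TRUE
})

#' Labeled kernel map
#'
#' Segmented kernel regions on a \code{\linkS4class{Panorama}}: a label
#' raster plus one record per kernel (pixel area, centroid, bounding box and
#' a validity flag).  The circumferential axis is periodic; \code{wrapOrigin}
#' records the raster row at which the one-circumference window was opened
#' (a groove line free of kernels), so that graph construction can work in
#' unwrapped coordinates.
#'
#' @slot labels integer matrix aligned to the panorama; 0 = no kernel.
#' @slot kernels data.frame with columns \code{id}, \code{x}, \code{y}
#'   (centroid, px), \code{area} (px), \code{xmin}, \code{xmax}, \code{ymin},
#'   \code{ymax} (bounding box, 1-based inclusive) and \code{valid}.
#' @slot wrapOrigin raster row (0-based offset) where the circular window
#'   starts.
#' @slot pixelSize cm per pixel.
#' @exportClass KernelMap
setClass("KernelMap", representation(
  labels = "matrix", kernels = "data.frame", wrapOrigin = "numeric",
  pixelSize = "numeric"
))

setValidity("KernelMap", function(object) {
  k <- object@kernels
  need <- c("id", "x", "y", "area", "xmin", "xmax", "ymin", "ymax", "valid")
  if (!all(need %in% names(k))) return("kernels lacks required columns")
  if (nrow(k) && !identical(k$id, seq_len(nrow(k))))
    return("kernel ids must be contiguous from 1")
  if (nrow(k) && any(k$x < k$xmin - 0.5 | k$x > k$xmax + 0.5 |
                     k$y < k$ymin - 0.5 | k$y > k$ymax + 0.5))
    return("each centroid must lie inside its bounding box")
  TRUE
})

#' Kernel adjacency graph
#'
#' Delaunay triangulation over valid kernel centroids plus two terminal node
#' groups (start \code{S} and end \code{E}) placed beyond the kernel hull
#' along the counting direction.  Edge weights are Euclidean pixel distances
#' (nonnegative, hence no negative cycles); Bellman-Ford shortest paths
#' between the groups count kernel rows or kernels per row.
#'
#' @slot nodes data.frame: \code{id}, \code{x}, \code{y} (px, unwrapped
#'   circumferential coordinate), \code{type} in \code{kernel}/\code{start}/
#'   \code{end}, \code{kernelId} (0 for terminals).
#' @slot edges data.frame: \code{u}, \code{v}, \code{w}.
#' @slot direction \code{"axial"} or \code{"transverse"}.
#' @exportClass KernelGraph
setClass("KernelGraph", representation(
  nodes = "data.frame", edges = "data.frame", direction = "character"
))

setValidity("KernelGraph", function(object) {
  if (nrow(object@edges) && any(object@edges$w < 0))
    return("edge weights must be nonnegative")
  if (!any(object@nodes$type == "start") || !any(object@nodes$type == "end"))
    return("start and end terminal groups must be nonempty")
  TRUE
})

#' Rotating-ear frame sequence
#'
#' Ordered orthographic views of a rotating textured ear over a background
#' with a roller-colored band, as produced by an inspection line camera.
#' Leading and trailing frames contain no ear (for ear-state detection).
#'
#' @slot frames list of H x W x 3 integer arrays (0-255).
#' @slot pixelSize cm per pixel.
#' @slot rotationPerFrame rotation between consecutive ear frames, degrees.
#' @slot earFrames indices of the frames that contain the ear.
#' @exportClass EarImageSequence
setClass("EarImageSequence", representation(
  frames = "list", pixelSize = "numeric", rotationPerFrame = "numeric",
  earFrames = "integer"
))

#' REML variance components
#'
#' Genotypic (\code{Vg}), genotype-by-site (\code{Vgl}) and residual
#' (\code{Ve}) variance components of the multi-environment mixed model,
#' together with the site count \code{L} and replication count \code{R} used
#' for broad-sense heritability.
#'
#' @slot Vg,Vgl,Ve nonnegative variance components.
#' @slot L number of sites.
#' @slot R number of replications (explicit input, never inferred).
#' @slot iterations EM iterations used.
#' @slot converged logical.
#' @exportClass VarianceComponents
setClass("VarianceComponents", representation(
  Vg = "numeric", Vgl = "numeric", Ve = "numeric",
  L = "integer", R = "integer", iterations = "integer", converged = "logical"
))

setValidity("VarianceComponents", function(object) {
  v <- c(object@Vg, object@Vgl, object@Ve)
  if (any(!is.finite(v)) || any(v < 0))
    return("variance components must be finite and nonnegative")
  if (object@L < 1L || object@R < 1L) return("L and R must be >= 1")
  TRUE
})

#' Mixed-model BLUP result
#'
#' Fixed-effect estimates and best linear unbiased predictions of genotype
#' effects from the converged mixed-model equations.
#'
#' @slot blup data.frame: \code{genotype}, random effect \code{u}, and
#'   \code{blup} = grand mean + u.
#' @slot beta named numeric vector of fixed-effect estimates (site effects).
#' @slot grandMean mean fitted fixed-effect value.
#' @slot trait trait name.
#' @exportClass BlupResult
setClass("BlupResult", representation(
  blup = "data.frame", beta = "numeric", grandMean = "numeric",
  trait = "character"
))

#' The twenty ear and kernel traits
#'
#' Canonical trait abbreviations, in the column order used by trait CSV
#' output: barren tip length/area (BTL, BTA), ear length (EL), perimeter
#' (EP), width (EW), kernel counts (KNE total, KNR per row, RNE rows),
#' average kernel area (AKA), ear colors (ER, EG, EB), non-sphericity shape
#' (ES), surface area (ESA), volume (EV), kernel colors (KR, KG, KB), kernel
#' thickness (KT) and kernel width (KW).
#'
#' @export
TRAIT_NAMES <- c("BTL", "EL", "EP", "EW", "KNE", "KNR", "RNE", "AKA", "BTA",
                 "EB", "EG", "ER", "ES", "ESA", "EV", "KB", "KG", "KR",
                 "KT", "KW")
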