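#' Write an RGB raster as PNG
#'
#' Lossless 8-bit PNG output for frames and panoramas.
#'
#' @param rgb H x W x 3 array (0-255) or a \code{\linkS4class{Panorama}}.
#' @param path output file.
#' @export
writeImagePNG <- function(rgb, path) {
  if (is(rgb, "Panorama")) rgb <- rgb@rgb
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Read a PNG frame as 0-255 RGB array
#'
#' @param path PNG file.
#' @return H x W x 3 numeric array, 0-255.
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' Write a kernel label raster as 16-bit PNG
#'
#' @param labels integer matrix of kernel ids (0 = none).
#' @param path output file.
#' @export
writeLabelPNG <- function(labels, path) {
  png::writePNG(labels / 65535, path)
  invisible(path)
}

#' Simulate one ear dataset to disk
#'
#' Renders an ear model's panorama, label raster and rotating frame
#' sequence into a directory, together with the ground-truth trait values
#' as JSON (keys are the canonical trait abbreviations).
#'
#' @param model an \code{\linkS4class{EarModel}}.
#' @param outDir output directory (created if needed).
#' @param pixelSize cm per pixel.
#' @param noiseSd additive pixel noise sd.
#' @param nFrames,rotationPerFrame sequence geometry.
#' @return the ground-truth trait vector, invisibly.
#' @export
simulateEarDataset <- function(model, outDir, pixelSize = 3.126e-2,
                               noiseSd = 0, nFrames = 28L,
                               rotationPerFrame = 15) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rp <- renderPanorama(model, pixelSize, noiseSd = noiseSd)
  writeImagePNG(rp$panorama, file.path(outDir, "panorama.png"))
  writeLabelPNG(rp$labels, file.path(outDir, "labels.png"))
  sq <- renderSequence(model, nFrames, rotationPerFrame, pixelSize,
                       noiseSd = noiseSd)
  for (i in seq_along(sq@frames))
    writeImagePNG(sq@frames[[i]],
                  file.path(outDir, sprintf("frame_%03d.png", i)))
  tr <- rp$truth
  json <- paste0("{", paste(sprintf('"%s": %.10g', names(tr), tr),
                            collapse = ", "), "}")
  writeLines(json, file.path(outDir, "truth.json"))
  invisible(tr)
}
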