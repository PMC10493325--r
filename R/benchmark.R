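#' Run the ear-measurement accuracy benchmark
#'
#' Generates benchmark ears (see \code{\link{benchmarkEarModel}}: lengths
#' uniform on 12-20 cm, row numbers in \{8..18\}, centroid jitter sd 0.1
#' lattice spacings), renders each as a rotating frame sequence with
#' additive pixel noise, runs the full measurement pipeline (ear detection,
#' segmentation, central-strip stitching, kernel counting), and scores the
#' estimates against each ear's ground truth.
#'
#' @param seeds integer vector of ear seeds (one ear per seed).
#' @param noiseSd additive Gaussian pixel noise sd (default 5).
#' @param jitterFraction centroid jitter sd in lattice spacings.
#' @param verbose print one line per ear.
#' @return data.frame with one row per ear: \code{seed}, \code{elTrue},
#'   \code{elEst}, \code{rneTrue}, \code{rneEst}, and the derived
#'   \code{elRelErr} and \code{rneExact} (rounded row count correct).
#' @examples
#' \donttest{
#' bench <- benchmarkAccuracy(1:3)
#' 100 * (1 - mean(bench$elRelErr))  # mean ear-length accuracy, %
#' }
#' @export
benchmarkAccuracy <- function(seeds, noiseSd = 5, jitterFraction = 0.1,
                              verbose = FALSE) {
  rows <- lapply(seeds, function(seed) {
    m <- benchmarkEarModel(seed, jitterFraction = jitterFraction)
    tt <- trueTraits(m)
    sq <- renderSequence(m, noiseSd = noiseSd)
    res <- tryCatch(phenotypeEar(sq, traits = c("EL", "RNE")),
                    error = function(e) NULL)
    out <- data.frame(seed = seed, elTrue = tt[["EL"]],
                      elEst = if (is.null(res)) NA_real_ else
                        res$traits[["EL"]],
                      rneTrue = tt[["RNE"]],
                      rneEst = if (is.null(res)) NA_real_ else
                        res$traits[["RNE"]])
    if (verbose)
      message(sprintf("ear %d: EL %.2f/%.2f cm, RNE %.2f/%d", seed,
                      out$elEst, out$elTrue, out$rneEst, out$rneTrue))
    out
  })
  df <- do.call(rbind, rows)
  df$elRelErr <- abs(df$elEst - df$elTrue) / df$elTrue
  df$rneExact <- !is.na(df$rneEst) & round(df$rneEst) == df$rneTrue
  df
}
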