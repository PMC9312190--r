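# Bundled amino-acid composition tables.
#
# `backgroundAAFreq` approximates average human proteome composition with the
# methionine entry pinned at 0.02, the background rate the spatial statistic
# is calibrated around. `prionAAFreq` is a prion-like compositional
# preference table, strongly enriched in Q/N/S/G (and mildly in M), in the
# spirit of yeast-prion-domain composition. Both are package constants,
# normalised at load time; neither is fitted to any particular dataset.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.backgroundRaw <- c(
  A = 0.071, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
  Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
  L = 0.100, K = 0.057, M = 0.020, F = 0.037, P = 0.063,
  S = 0.083, T = 0.053, W = 0.012, Y = 0.027, V = 0.060
)

.prionRaw <- c(
  A = 0.050, R = 0.020, N = 0.180, D = 0.005, C = 0.002,
  Q = 0.200, E = 0.005, G = 0.130, H = 0.020, I = 0.010,
  L = 0.020, K = 0.005, M = 0.030, F = 0.015, P = 0.060,
  S = 0.150, T = 0.040, W = 0.003, Y = 0.050, V = 0.005
)

#' Bundled amino-acid emission tables
#'
#' Returns one of the two composition tables shipped with the package:
#' \code{"background"}, an approximation of average proteome composition
#' (methionine 0.02), or \code{"prion"}, a prion-like preference table
#' enriched in Q/N/S/G. Frequencies are normalised to sum to 1 and ordered
#' over the 20 standard residues.
#'
#' @param table which table, \code{"background"} or \code{"prion"}.
#' @param metWeight optional override for the methionine weight; the other 19
#'   entries are rescaled so the table still sums to 1.
#' @return named numeric vector of length 20.
#' @examples
#' aminoAcidTable("background")[["M"]]
#' @export
aminoAcidTable <- function(table = c("background", "prion"), metWeight = NULL) {
  table <- match.arg(table)
  w <- switch(table, background = .backgroundRaw, prion = .prionRaw)
  w <- w[.AA20]
  w <- w / sum(w)
  if (!is.null(metWeight)) {
    checkProb(metWeight, "metWeight")
    others <- setdiff(.AA20, "M")
    w[others] <- w[others] * (1 - metWeight) / sum(w[others])
    w["M"] <- metWeight
  }
  w
}
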