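# Transect-based spatial statistics for methionine clustering.
#
# The primary structure is cut into consecutive segments (default 50
# residues), methionines are counted per segment, and the coefficient of
# variation q = population SD / mean of the per-segment counts is the
# aggregation index: q near 1 for random (Poisson-like) placement, q >> 1
# for clustering, q << 1 for dispersion. Significance comes from a
# per-protein empirical null that fixes the protein length and Met count
# and randomises the positions.

#' Per-segment methionine counts
#'
#' Counts positions falling in consecutive windows \code{[1-50]},
#' \code{[51-100]}, ... of the effective (initiator-stripped) sequence.
#' Two dialects handle a length not divisible by the segment length:
#' \code{"ceil"} (default) keeps a final short segment holding the
#' remainder; \code{"merge"} folds the remainder into the last full segment.
#'
#' @param positions integer vector of 1-based positions (already shifted to
#'   effective coordinates, initiator removed).
#' @param effectiveLength length of the effective sequence.
#' @param segmentLen segment (transect) length in residues, default 50.
#' @param tail tail-segment rule, \code{"ceil"} or \code{"merge"}.
#' @return integer vector of per-segment counts; \code{sum(counts)} equals
#'   \code{length(positions)}.
#' @examples
#' segmentCounts(c(3, 55, 118), 120)  # 1 1 1
#' @export
segmentCounts <- function(positions, effectiveLength, segmentLen = 50,
                          tail = c("ceil", "merge")) {
  tail <- match.arg(tail)
  checkCount(effectiveLength, "effectiveLength", min = 1)
  checkCount(segmentLen, "segmentLen", min = 1)
  positions <- as.integer(positions)
  if (length(positions) && (min(positions) < 1L || max(positions) > effectiveLength))
    stop("positions out of range [1, effectiveLength]")
  nSeg <- as.integer(if (tail == "ceil") ceiling(effectiveLength / segmentLen)
                     else max(1L, floor(effectiveLength / segmentLen)))
  idx <- ceiling(positions / segmentLen)
  if (tail == "merge") idx <- pmin(idx, nSeg)
  tabulate(idx, nbins = nSeg)
}

#' Coefficient of variation of segment counts (aggregation index q)
#'
#' \code{q = sqrt(N * sum((x_i - mean)^2)) / sum(x_i)}, i.e. the population
#' standard deviation of the per-segment counts divided by their mean.
#' Returns \code{NA} (not evaluable) when the counts are all zero or there
#' are fewer than two segments, never a division-by-zero.
#'
#' @param counts integer vector of per-segment methionine counts.
#' @return q >= 0, or \code{NA_real_} when not evaluable.
#' @examples
#' qStatistic(c(2, 0))          # 1
#' qStatistic(c(5, 0, 0, 0, 0)) # 2
#' @export
qStatistic <- function(counts) {
  if (length(counts) < 2L || sum(counts) == 0) return(NA_real_)
  n <- length(counts)
  s <- sum(counts)
  sqrt(n * sum(counts^2) - s^2) / s
}

#' Empirical null distribution of q for one protein
#'
#' Places \code{m} methionines uniformly at random without replacement among
#' \code{effectiveLength} positions, recomputes q, and repeats \code{B}
#' times. The null conditions on the protein's own length and Met count, so
#' size and abundance effects on q are absorbed.
#'
#' @param m methionine count (initiator excluded); must be > 0.
#' @param effectiveLength initiator-stripped protein length.
#' @param B number of replicates (default 10000).
#' @param segmentLen,tail passed to \code{\link{segmentCounts}}.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return numeric vector of \code{B} null q values.
#' @export
nullQ <- function(m, effectiveLength, B = 10000, segmentLen = 50,
                  tail = c("ceil", "merge"), seed = NULL) {
  tail <- match.arg(tail)
  m <- checkCount(m, "m", min = 1)
  checkCount(effectiveLength, "effectiveLength", min = m)
  B <- checkCount(B, "B", min = 1)
  nSeg <- as.integer(if (tail == "ceil") ceiling(effectiveLength / segmentLen)
                     else max(1L, floor(effectiveLength / segmentLen)))
  withSeed(seed, {
    segIdx <- vapply(seq_len(B), function(i) {
      idx <- as.integer(ceiling(sample.int(effectiveLength, m) / segmentLen))
      if (tail == "merge") idx <- pmin(idx, nSeg)
      idx
    }, integer(m))
    segIdx <- matrix(segIdx, nrow = m)  # guard m == 1 simplification
    offs <- rep((seq_len(B) - 1L) * nSeg, each = m)
    counts <- matrix(tabulate(as.vector(segIdx) + offs, nbins = nSeg * B),
                     nrow = nSeg)
    # q = sqrt(N * sum(x^2) - m^2) / m, since counts always sum to m
    sqrt(pmax(nSeg * colSums(counts^2) - m^2, 0)) / m
  })
}

#' Classify one q value against its empirical null
#'
#' Empirical tail fractions use the plug-in estimator r/B with inclusive
#' ties: \code{pHigh} is the fraction of null q at or above the observed
#' value, \code{pLow} at or below. The protein is called
#' \code{"aggregation"} when \code{pHigh < alpha}, \code{"dispersion"} when
#' \code{pLow < alpha}, otherwise \code{"random"}. With B = 10000 and
#' alpha = 1e-4 a call requires the observed q to fall strictly outside the
#' whole null sample; the plug-in estimator is anti-conservative but is the
#' only one for which that alpha is attainable at that B.
#'
#' @param qObs observed q.
#' @param nullSamples numeric vector of null q values.
#' @param alpha significance level (default 1e-4).
#' @return list: \code{class}, \code{pHigh}, \code{pLow}.
#' @export
classifySpatial <- function(qObs, nullSamples, alpha = 1e-4) {
  checkProb(alpha, "alpha", open = TRUE)
  if (is.na(qObs) || !length(nullSamples))
    return(list(class = "not_evaluable", pHigh = NA_real_, pLow = NA_real_))
  pHigh <- mean(nullSamples >= qObs)
  pLow  <- mean(nullSamples <= qObs)
  cls <- if (pHigh < alpha) "aggregation"
         else if (pLow < alpha) "dispersion"
         else "random"
  list(class = cls, pHigh = pHigh, pLow = pLow)
}

#' Spatially classify every protein of a proteome
#'
#' Runs the full per-protein procedure: initiator-stripped Met positions,
#' segment counts, q, an empirical null of \code{B} random placements
#' conditioned on the protein's length and Met count, and the
#' aggregation / dispersion / random call at level \code{alpha}. Proteins
#' with no methionine (beyond an initiator) or fewer than two segments are
#' \code{not_evaluable}. Per-protein seeds are derived from \code{seed} and
#' the accession, so results do not depend on processing order.
#'
#' @param proteome a \code{\linkS4class{MetProteome}}.
#' @param segmentLen transect length (default 50).
#' @param tail tail-segment rule (see \code{\link{segmentCounts}}).
#' @param B null replicates per protein (default 10000).
#' @param alpha significance level (default 1e-4).
#' @param seed global integer seed.
#' @return data.frame: accession, m, nSeg, q, pHigh, pLow, class.
#' @export
spatialClassify <- function(proteome, segmentLen = 50,
                            tail = c("ceil", "merge"),
                            B = 10000, alpha = 1e-4, seed = 1) {
  stopifnot(is(proteome, "MetProteome"))
  tail <- match.arg(tail)
  info <- proteome@info
  posList <- proteome@metPositions
  n <- nrow(info)
  out <- data.frame(
    accession = info$accession, m = info$metCount, nSeg = NA_integer_,
    q = NA_real_, pHigh = NA_real_, pLow = NA_real_,
    class = rep("not_evaluable", n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    eff <- effectiveMetLayout(posList[[i]], info$length[i],
                              info$initiatorIsMet[i])
    if (eff$m == 0L) next
    counts <- segmentCounts(eff$positions, eff$length, segmentLen, tail)
    if (length(counts) < 2L) next
    qObs <- qStatistic(counts)
    nul <- nullQ(eff$m, eff$length, B = B, segmentLen = segmentLen,
                 tail = tail, seed = deriveSeed(seed, info$accession[i]))
    cl <- classifySpatial(qObs, nul, alpha)
    out$nSeg[i] <- length(counts)
    out$q[i] <- qObs
    out$pHigh[i] <- cl$pHigh
    out$pLow[i] <- cl$pLow
    out$class[i] <- cl$class
  }
  out
}

# Initiator-stripped layout: effective length and shifted Met positions.
effectiveMetLayout <- function(positions, length, initiatorIsMet) {
  if (initiatorIsMet) {
    list(positions = positions[positions > 1L] - 1L,
         length = length - 1L,
         m = sum(positions > 1L))
  } else {
    list(positions = positions, length = length, m = length(positions))
  }
}
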