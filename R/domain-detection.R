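# MR-PrLD calling.
#
# A methionine-rich prion-like domain is called when four criteria meet:
# (i) the host protein belongs to the spatial "aggregation" class;
# (ii) the stretch is a methionine-contributed low-complexity region (a
#      compositional-bias scan at a binomial-tail threshold);
# (iii) the stretch matches a prion-like domain (two-state HMM posterior at
#      a 0.9 threshold over a minimum core length);
# (iv) the stretch contains at least 5 methionines.
# Called domains are scored by the exact binomial upper tail of their Met
# count given the whole-protein Met frequency and ranked by that p-value.

#' Methionine compositional-bias regions
#'
#' Lowest-probability-subsequence scan: every candidate window delimited by
#' two methionines is scored by the binomial upper tail
#' \code{P[X >= k]}, \code{X ~ Bin(n, backgroundP)}, with \code{n} the
#' window length and \code{k} its methionine count. The globally
#' lowest-probability window is emitted when its tail probability is below
#' \code{threshold}, its methionines are masked, and the scan repeats on
#' the flanking stretches until nothing passes. Emitted regions start and
#' end on a methionine and never overlap. Window lengths are constrained to
#' \code{[minLen, maxLen]}; a methionine span shorter than \code{minLen} is
#' scored at \code{n = minLen} (its shortest admissible containing window)
#' while its reported coordinates remain methionine-trimmed.
#'
#' @param sequence residue string (canonical, full sequence).
#' @param backgroundP background methionine probability; typically the
#'   proteome-wide Met frequency.
#' @param threshold binomial-tail acceptance threshold (default 1e-5).
#' @param minLen,maxLen allowed region lengths (defaults 10 and 1000).
#' @return data.frame: start, end (1-based inclusive canonical), metCount,
#'   biasP; zero rows when nothing passes.
#' @export
metBiasRegions <- function(sequence, backgroundP, threshold = 1e-5,
                           minLen = 10, maxLen = 1000) {
  checkProb(backgroundP, "backgroundP", open = TRUE)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  pos <- which(strsplit(sequence, "")[[1]] == "M")
  empty <- data.frame(start = integer(), end = integer(),
                      metCount = integer(), biasP = numeric())
  if (!length(pos)) return(empty)

  bestInGap <- function(p) {
    # p: sorted Met positions within one unmasked stretch. A Met span
    # shorter than minLen is evaluated at n = minLen (the shortest legal
    # window containing it), so the minimum over candidates equals the
    # minimum over all length-constrained windows; coordinates stay
    # Met-trimmed.
    m <- length(p)
    best <- NULL
    for (i in seq_len(m)) {
      span <- p[i:m] - p[i] + 1L
      keep <- which(span <= maxLen)
      if (!length(keep)) next
      j <- i + keep - 1L
      k <- j - i + 1L
      pv <- stats::pbinom(k - 1, pmax(span[keep], minLen), backgroundP,
                          lower.tail = FALSE)
      w <- which.min(pv)
      if (is.null(best) || pv[w] < best$biasP)
        best <- list(start = p[i], end = p[j[w]], metCount = k[w],
                     biasP = pv[w])
    }
    best
  }

  out <- empty
  gaps <- list(pos)
  while (length(gaps)) {
    gap <- gaps[[1]]
    gaps <- gaps[-1]
    if (length(gap) == 0L) next
    best <- bestInGap(gap)
    if (is.null(best) || best$biasP >= threshold) next
    out <- rbind(out, as.data.frame(best))
    gaps <- c(gaps, list(gap[gap < best$start], gap[gap > best$end]))
  }
  out[order(out$start), , drop = FALSE]
}

#' Prion-likeness posterior by two-state HMM forward-backward decoding
#'
#' Hidden states are "background" and "prion-like", each emitting residues
#' i.i.d. from a composition table (bundled defaults:
#' \code{aminoAcidTable("background")} and \code{aminoAcidTable("prion")}).
#' Transition probabilities are parameterised by expected state segment
#' lengths; the chain is initialised at its stationary distribution.
#' Posteriors are computed by the scaled forward-backward algorithm and the
#' two states' posteriors sum to one at every residue. Residues absent from
#' the tables (ambiguity codes) emit uniformly in both states.
#'
#' @param sequence residue string.
#' @param prionTable,backgroundTable named emission tables over the 20
#'   residues (need not be the bundled ones).
#' @param expectedPrionLen,expectedBackgroundLen expected segment lengths in
#'   residues (defaults 100 and 1000); the exit probability of each state is
#'   their reciprocal.
#' @return numeric vector: per-residue posterior probability of the
#'   prion-like state.
#' @export
prldPosterior <- function(sequence,
                          prionTable = aminoAcidTable("prion"),
                          backgroundTable = aminoAcidTable("background"),
                          expectedPrionLen = 100,
                          expectedBackgroundLen = 1000) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  stopifnot(all(.AA20 %in% names(prionTable)),
            all(.AA20 %in% names(backgroundTable)))
  aPB <- 1 / expectedPrionLen       # prion -> background
  aBP <- 1 / expectedBackgroundLen  # background -> prion
  stopifnot(aPB > 0, aPB < 1, aBP > 0, aBP < 1)
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  eB <- unname(backgroundTable[ch])
  eP <- unname(prionTable[ch])
  unknown <- is.na(eB) | is.na(eP)
  if (any(unknown)) {
    message(sum(unknown), " residue(s) absent from emission tables; ",
            "treated as uniform emission")
    eB[unknown] <- 1 / 20
    eP[unknown] <- 1 / 20
  }
  # states: 1 = background, 2 = prion
  trans <- rbind(c(1 - aBP, aBP), c(aPB, 1 - aPB))
  init <- c(aPB, aBP) / (aPB + aBP)  # stationary distribution
  fwd <- matrix(0, L, 2)
  scale <- numeric(L)
  f <- init * c(eB[1], eP[1])
  scale[1] <- sum(f)
  fwd[1, ] <- f / scale[1]
  for (t in seq_len(L - 1) + 1) {
    f <- (fwd[t - 1, ] %*% trans) * c(eB[t], eP[t])
    scale[t] <- sum(f)
    fwd[t, ] <- f / scale[t]
  }
  bwd <- matrix(0, L, 2)
  bwd[L, ] <- 1
  for (t in rev(seq_len(L - 1))) {
    b <- trans %*% (c(eB[t + 1], eP[t + 1]) * bwd[t + 1, ])
    bwd[t, ] <- b / scale[t + 1]
  }
  post <- fwd * bwd
  post[, 2] / rowSums(post)
}

#' Prion-like regions from a posterior profile
#'
#' Maximal runs of consecutive residues with posterior at or above
#' \code{threshold}; runs shorter than \code{minCore} are discarded.
#'
#' @param posterior per-residue posterior of the prion-like state.
#' @param threshold posterior threshold (default 0.9).
#' @param minCore minimum run length retained (default 60 residues).
#' @return data.frame: start, end (1-based inclusive).
#' @export
prldRegions <- function(posterior, threshold = 0.9, minCore = 60) {
  stopifnot(is.numeric(posterior), all(posterior >= 0 & posterior <= 1))
  r <- rle(posterior >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minCore
  data.frame(start = starts[keep], end = ends[keep])
}

#' Exact binomial upper-tail score for a candidate domain
#'
#' \code{P[X >= x]} with \code{X ~ Bin(n, pBg)}: the probability of seeing
#' at least as many methionines as observed in a stretch of length \code{n}
#' if methionines occurred at the whole-protein rate \code{pBg}. Equals 1
#' at \code{x = 0} and is strictly decreasing in \code{x}.
#'
#' @param n region length (residues).
#' @param x methionine count in the region.
#' @param pBg whole-protein methionine relative frequency
#'   (initiator-stripped by package convention).
#' @return the tail probability in (0, 1]. Vectorised over all arguments.
#' @examples
#' scoreMrPrld(10, 10, 0.5)  # 0.5^10
#' @export
scoreMrPrld <- function(n, x, pBg) {
  stopifnot(all(x >= 0), all(x <= n), all(pBg > 0), all(pBg < 1))
  stats::pbinom(x - 1, n, pBg, lower.tail = FALSE)
}

#' Call MR-PrLDs for one protein
#'
#' Applies the four criteria. Criterion (i) is enforced here: a protein not
#' in the spatial \code{"aggregation"} class yields no calls. For each
#' bias-region / prion-region pair with positional overlap the emitted span
#' is, by default, their intersection (\code{"union"} and
#' \code{"containment"} — bias region fully inside the prion region — are
#' alternatives). Spans with fewer than \code{minMet} methionines are
#' dropped and duplicate spans merged.
#'
#' @param accession protein accession.
#' @param sequence canonical residue string.
#' @param spatialClass the protein's spatial class string.
#' @param biasRegions data.frame from \code{\link{metBiasRegions}}.
#' @param prionRegions data.frame from \code{\link{prldRegions}}.
#' @param pBg whole-protein Met frequency used for scoring.
#' @param minMet minimum methionine count (default 5).
#' @param match overlap rule: \code{"intersection"} (default),
#'   \code{"union"}, or \code{"containment"}.
#' @return data.frame: accession, start, end, n, x, pBg, pValue, sequence
#'   (the domain string); zero rows when nothing qualifies.
#' @export
callMrPrlds <- function(accession, sequence, spatialClass, biasRegions,
                        prionRegions, pBg, minMet = 5,
                        match = c("intersection", "union", "containment")) {
  match <- match.arg(match)
  empty <- data.frame(accession = character(), start = integer(),
                      end = integer(), n = integer(), x = integer(),
                      pBg = numeric(), pValue = numeric(),
                      sequence = character())
  if (!identical(spatialClass, "aggregation") ||
      !nrow(biasRegions) || !nrow(prionRegions)) return(empty)
  ch <- strsplit(sequence, "")[[1]]
  spans <- list()
  for (i in seq_len(nrow(biasRegions))) {
    for (j in seq_len(nrow(prionRegions))) {
      bs <- biasRegions$start[i]; be <- biasRegions$end[i]
      ps <- prionRegions$start[j]; pe <- prionRegions$end[j]
      if (be < ps || pe < bs) next
      if (match == "containment" && !(bs >= ps && be <= pe)) next
      span <- switch(match,
        intersection = c(max(bs, ps), min(be, pe)),
        union        = c(min(bs, ps), max(be, pe)),
        containment  = c(bs, be))
      spans[[length(spans) + 1L]] <- span
    }
  }
  if (!length(spans)) return(empty)
  spans <- unique(spans)
  rows <- lapply(spans, function(sp) {
    x <- sum(ch[sp[1]:sp[2]] == "M")
    if (x < minMet) return(NULL)
    n <- sp[2] - sp[1] + 1L
    data.frame(accession = accession, start = sp[1], end = sp[2],
               n = n, x = x, pBg = pBg,
               pValue = scoreMrPrld(n, x, pBg),
               sequence = paste(ch[sp[1]:sp[2]], collapse = ""))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Rank a census table by p-value
#'
#' Ascending in \code{pValue}; ties broken by accession, then start.
#'
#' @param census data.frame with columns \code{pValue}, \code{accession},
#'   \code{start}.
#' @return the reordered data.frame.
#' @export
rankCensus <- function(census) {
  if (!nrow(census)) return(census)
  census[order(census$pValue, census$accession, census$start), ,
         drop = FALSE]
}

#' Run the full MR-PrLD census on a proteome
#'
#' End-to-end pipeline: spatial classification (unless supplied), the
#' methionine bias scan and HMM prion posterior on every
#' \code{"aggregation"} protein, domain calling under the four criteria,
#' binomial scoring, and ranking.
#'
#' @param proteome a \code{\linkS4class{MetProteome}}.
#' @param classification optional precomputed \code{\link{spatialClassify}}
#'   table.
#' @param backgroundP Met probability for the bias scan; default the pooled
#'   initiator-stripped Met frequency of the input proteome.
#' @param biasThreshold,minLen,maxLen bias-scan parameters.
#' @param prldThreshold,minCore prion-region parameters.
#' @param minMet criterion-(iv) threshold (default 5).
#' @param match overlap rule passed to \code{\link{callMrPrlds}}.
#' @param B,alpha,segmentLen,tail,seed spatial-classification parameters,
#'   used only when \code{classification} is NULL.
#' @return ranked census data.frame (Table-1-style schema: accession,
#'   start, end, n, x, pBg, pValue, sequence).
#' @export
runCensus <- function(proteome, classification = NULL, backgroundP = NULL,
                      biasThreshold = 1e-5, minLen = 10, maxLen = 1000,
                      prldThreshold = 0.9, minCore = 60, minMet = 5,
                      match = "intersection",
                      B = 10000, alpha = 1e-4, segmentLen = 50,
                      tail = "ceil", seed = 1) {
  stopifnot(is(proteome, "MetProteome"))
  if (is.null(classification))
    classification <- spatialClassify(proteome, segmentLen = segmentLen,
                                      tail = tail, B = B, alpha = alpha,
                                      seed = seed)
  info <- proteome@info
  if (is.null(backgroundP)) {
    effLen <- info$length - as.integer(info$initiatorIsMet)
    backgroundP <- sum(info$metCount) / sum(effLen)
  }
  agg <- classification$accession[classification$class == "aggregation"]
  res <- list()
  for (acc in agg) {
    i <- base::match(acc, info$accession)
    seqStr <- as.character(proteome@sequences[[i]])
    bias <- metBiasRegions(seqStr, backgroundP, threshold = biasThreshold,
                           minLen = minLen, maxLen = maxLen)
    if (!nrow(bias)) next
    post <- prldPosterior(seqStr)
    prld <- prldRegions(post, threshold = prldThreshold, minCore = minCore)
    if (!nrow(prld)) next
    res[[acc]] <- callMrPrlds(acc, seqStr, "aggregation", bias, prld,
                              pBg = info$metFreq[i], minMet = minMet,
                              match = match)
  }
  res <- res[vapply(res, nrow, integer(1)) > 0]
  census <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
            else data.frame(accession = character(), start = integer(),
                            end = integer(), n = integer(), x = integer(),
                            pBg = numeric(), pValue = numeric(),
                            sequence = character())
  rankCensus(census)
}

# ---- adapters for external scan outputs ------------------------------------

#' Read biased regions from an fLPS-style output table
#'
#' Drop-in replacement for \code{\link{metBiasRegions}} when an external
#' low-complexity scan has already been run. Expects a whitespace- or
#' tab-delimited table whose columns include (in order) sequence name,
#' bias type, start, end, residue count, binomial p-value and the biased
#' residue signature (e.g. \code{\{M\}}); lines starting with \code{#} are
#' skipped. Only rows whose signature contains \code{residue} and whose
#' p-value is below \code{threshold} are returned.
#'
#' @param path file path.
#' @param accession keep rows for this sequence name (NULL keeps all).
#' @param residue biased residue of interest (default "M").
#' @param threshold p-value cutoff (default 1e-5).
#' @return data.frame: accession, start, end, metCount, biasP.
#' @export
readFlpsRegions <- function(path, accession = NULL, residue = "M",
                            threshold = 1e-5) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE)
  stopifnot(ncol(tab) >= 7)
  out <- data.frame(accession = as.character(tab[[1]]),
                    start = as.integer(tab[[3]]),
                    end = as.integer(tab[[4]]),
                    metCount = as.integer(tab[[5]]),
                    biasP = as.numeric(tab[[6]]),
                    signature = as.character(tab[[7]]))
  if (!is.null(accession)) out <- out[out$accession == accession, ]
  out <- out[grepl(residue, out$signature, fixed = TRUE) &
               out$biasP < threshold, ]
  out$signature <- NULL
  rownames(out) <- NULL
  out
}

#' Read a per-residue prion-likeness profile from an external score file
#'
#' Drop-in replacement for \code{\link{prldPosterior}}: a delimited table
#' with one row per residue holding the position and the prion-state
#' probability (column indices configurable; header lines starting with
#' \code{#} skipped). Returns the probabilities ordered by position.
#'
#' @param path file path.
#' @param posCol,probCol column indices of the residue position and the
#'   probability (defaults 1 and 2).
#' @return numeric posterior vector usable with \code{\link{prldRegions}}.
#' @export
readPlaacPosterior <- function(path, posCol = 1, probCol = 2) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  p <- as.numeric(tab[[probCol]])[order(as.integer(tab[[posCol]]))]
  stopifnot(all(p >= 0 & p <= 1))
  p
}
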