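# Synthetic data generators.
#
# These emulate the statistical structure the census pipeline assumes:
# proteomes with ~2% i.i.d. background methionine, a subpopulation with a
# locally planted methionine cluster or a planted Met-rich prion-composition
# segment, and a subpopulation with no methionine beyond the initiator;
# alpha-carbon-only structures for the compactness index; and two-group GO
# annotation tables with controlled within/between term overlap for the
# assortativity analysis. All generators are seed-deterministic
# (byte-identical outputs under an identical specification).

#' Generate a synthetic proteome
#'
#' Each sequence starts with an initiator methionine. Every later position
#' is methionine independently with probability \code{metFreq}; other
#' residues are drawn from the bundled background composition table. A
#' fraction of proteins additionally receives a planted feature at a
#' uniformly placed window that never covers position 1:
#' \describe{
#'   \item{\code{"cluster"}}{exactly \code{clusterMet} methionines inside a
#'     \code{clusterWindow}-residue window (non-Met window positions drawn
#'     from the background table).}
#'   \item{\code{"prld"}}{a \code{prldLength}-residue segment drawn i.i.d.
#'     from the prion composition table with the methionine weight raised to
#'     \code{prldMetWeight} — a planted MR-PrLD. The default weight of 1/3
#'     matches the methionine density of the strongest reported MR-PrLDs
#'     (about one methionine in three residues); reported domains range
#'     from roughly 19 to 33 percent methionine.}
#' }
#' An independent fraction of proteins carries no methionine after position
#' 1 (the zero-Met subpopulation).
#'
#' @param nProteins number of proteins.
#' @param lengthLaw \code{"lognormal"} (default; meanlog 6.1, sdlog 0.6,
#'   truncated to [100, 5000], roughly human-proteome-like) or
#'   \code{"fixed"}.
#' @param fixedLength length used when \code{lengthLaw = "fixed"}.
#' @param meanLog,sdLog lognormal parameters.
#' @param metFreq background per-position methionine probability (default
#'   0.02, the average proteome rate).
#' @param plantedFraction fraction of proteins receiving a planted feature
#'   (default 0.02).
#' @param plantType \code{"cluster"} or \code{"prld"}.
#' @param clusterWindow,clusterMet cluster plant geometry (default 30
#'   residues, 10 methionines).
#' @param prldLength,prldMetWeight prion-segment plant geometry (default 60
#'   residues, Met weight 1/3).
#' @param zeroMetFraction fraction of proteins with no Met after position 1
#'   (default 0.025, matching the conspicuous zero-Met subpopulation size
#'   relative to a full proteome).
#' @param seed integer seed.
#' @return a \code{\linkS4class{MetProteome}}; the per-protein table gains
#'   columns \code{planted}, \code{plantStart}, \code{plantEnd} (canonical
#'   coordinates of the planted window, NA when absent).
#' @examples
#' p <- generateProteome(20, lengthLaw = "fixed", fixedLength = 200, seed = 1)
#' proteinInfo(p)[1:3, c("accession", "length", "metCount")]
#' @export
generateProteome <- function(nProteins,
                             lengthLaw = c("lognormal", "fixed"),
                             fixedLength = 1000, meanLog = 6.1, sdLog = 0.6,
                             metFreq = 0.02,
                             plantedFraction = 0.02,
                             plantType = c("cluster", "prld"),
                             clusterWindow = 30, clusterMet = 10,
                             prldLength = 60, prldMetWeight = 1/3,
                             zeroMetFraction = 0.025,
                             seed = 1) {
  nProteins <- checkCount(nProteins, "nProteins", min = 1)
  lengthLaw <- match.arg(lengthLaw)
  plantType <- match.arg(plantType)
  checkProb(metFreq, "metFreq")
  checkProb(plantedFraction, "plantedFraction")
  checkProb(zeroMetFraction, "zeroMetFraction")
  checkCount(clusterWindow, "clusterWindow", min = 1)
  checkCount(clusterMet, "clusterMet", min = 0)
  if (clusterMet > clusterWindow)
    stop("'clusterMet' cannot exceed 'clusterWindow'")
  checkCount(prldLength, "prldLength", min = 1)
  checkProb(prldMetWeight, "prldMetWeight")
  bg <- aminoAcidTable("background")
  bgNoMet <- bg[setdiff(names(bg), "M")]
  bgNoMet <- bgNoMet / sum(bgNoMet)
  prionTab <- aminoAcidTable("prion", metWeight = prldMetWeight)

  withSeed(seed, {
    lens <- if (lengthLaw == "fixed") rep(checkCount(fixedLength,
                                                     "fixedLength", min = 100),
                                          nProteins)
            else {
              l <- round(stats::rlnorm(nProteins, meanLog, sdLog))
              as.integer(pmin(pmax(l, 100), 5000))
            }
    nPlant <- round(plantedFraction * nProteins)
    nZero <- round(zeroMetFraction * nProteins)
    roles <- rep("background", nProteins)
    if (nPlant + nZero > nProteins) stop("planted + zero-Met fractions exceed 1")
    pick <- sample.int(nProteins, nPlant + nZero)
    roles[pick[seq_len(nPlant)]] <- "planted"
    if (nZero > 0) roles[pick[nPlant + seq_len(nZero)]] <- "zeromet"

    seqs <- character(nProteins)
    plantStart <- rep(NA_integer_, nProteins)
    plantEnd <- rep(NA_integer_, nProteins)
    plantLen <- if (plantType == "cluster") clusterWindow else prldLength
    for (i in seq_len(nProteins)) {
      L <- lens[i]
      body <- sample(names(bgNoMet), L - 1L, replace = TRUE, prob = bgNoMet)
      if (roles[i] != "zeromet" && metFreq > 0) {
        isMet <- stats::runif(L - 1L) < metFreq
        body[isMet] <- "M"
      }
      if (roles[i] == "planted" && L - 1L >= plantLen) {
        # window in body coordinates (body position k = canonical k + 1)
        ws <- sample.int(L - plantLen, 1L)
        idx <- ws:(ws + plantLen - 1L)
        if (plantType == "cluster") {
          win <- sample(names(bgNoMet), plantLen, replace = TRUE,
                        prob = bgNoMet)
          win[sample.int(plantLen, clusterMet)] <- "M"
        } else {
          win <- sample(names(prionTab), plantLen, replace = TRUE,
                        prob = prionTab)
        }
        body[idx] <- win
        plantStart[i] <- ws + 1L
        plantEnd[i] <- ws + plantLen
      }
      seqs[i] <- paste0("M", paste(body, collapse = ""))
    }
    names(seqs) <- sprintf("SYN%05d", seq_len(nProteins))
    prot <- MetProteome(seqs)
    prot@info$planted <- roles == "planted"
    prot@info$plantStart <- plantStart
    prot@info$plantEnd <- plantEnd
    prot
  })
}

#' Generate an i.i.d. segment from a bundled composition table
#'
#' @param length segment length (0 gives an empty string).
#' @param table \code{"background"} or \code{"prion"}.
#' @param metWeight optional methionine weight override (others rescaled).
#' @param seed integer seed.
#' @return a residue string.
#' @examples
#' generatePrldSegment(60, "prion", metWeight = 0.2, seed = 3)
#' @export
generatePrldSegment <- function(length, table = c("background", "prion"),
                                metWeight = NULL, seed = NULL) {
  length <- checkCount(length, "length", min = 0)
  w <- aminoAcidTable(match.arg(table), metWeight = metWeight)
  if (length == 0L) return("")
  withSeed(seed,
    paste(sample(names(w), length, replace = TRUE, prob = w), collapse = ""))
}

#' Generate a synthetic alpha-carbon-only structure
#'
#' Writes a valid single-model, single-chain PDB file with one CA atom per
#' residue. \code{"extended"} places atoms collinearly at \code{bondLen}
#' spacing (terminal distance exactly \code{bondLen * (n - 1)});
#' \code{"random_walk"} places each successive atom at \code{bondLen} in a
#' uniformly random direction (freely jointed chain, mean squared
#' end-to-end distance \code{(n - 1) * bondLen^2}).
#'
#' @param nResidues number of residues (>= 2).
#' @param mode \code{"extended"} or \code{"random_walk"}.
#' @param bondLen CA-CA spacing in Angstrom (default 3.8).
#' @param path output PDB path (default a tempfile).
#' @param seed integer seed (random_walk mode).
#' @return the PDB path, invisibly; attribute \code{"coords"} carries the
#'   n x 3 coordinate matrix.
#' @export
generateStructure <- function(nResidues, mode = c("extended", "random_walk"),
                              bondLen = 3.8, path = tempfile(fileext = ".pdb"),
                              seed = NULL) {
  nResidues <- checkCount(nResidues, "nResidues", min = 2)
  mode <- match.arg(mode)
  stopifnot(is.numeric(bondLen), bondLen > 0)
  xyz <- withSeed(seed, {
    if (mode == "extended") {
      cbind((seq_len(nResidues) - 1) * bondLen, 0, 0)
    } else {
      # uniform directions on the sphere
      z <- stats::runif(nResidues - 1, -1, 1)
      phi <- stats::runif(nResidues - 1, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      steps <- bondLen * cbind(r * cos(phi), r * sin(phi), z)
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    }
  })
  xyz <- matrix(xyz, ncol = 3)
  lines <- c(
    "HEADER    SYNTHETIC CA TRACE",
    sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nResidues), seq_len(nResidues), xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("TER   %5d      ALA A%4d", nResidues + 1L, nResidues),
    "END"
  )
  writeLines(lines, path)
  structure(invisible(path), coords = xyz)
}

#' Generate synthetic GO annotations for two labeled groups
#'
#' Builds a "red" (MR) and a "blue" (NonMR) protein group whose GO term sets
#' are drawn from group-specific term pools. Pool sizes control the expected
#' within-group Jaccard similarity (\code{withinOverlap} = terms per protein
#' over pool size; a pool equal to the set size makes same-group sets
#' identical), and the two pools share \code{betweenOverlap} of their terms,
#' controlling cross-group similarity. Writes a GAF 2.2 file and a
#' two-column label table.
#'
#' @param nRed,nBlue group sizes.
#' @param termsPerProtein terms drawn per protein (without replacement).
#' @param withinOverlap target within-group overlap in (0, 1]; the
#'   group-pool size is \code{round(termsPerProtein / withinOverlap)}.
#' @param betweenOverlap fraction of each group pool shared with the other
#'   group, in [0, 1]; must not exceed \code{withinOverlap}.
#' @param gafPath,labelPath output paths (default tempfiles).
#' @param seed integer seed.
#' @return list: \code{annotations} (named list of term-set character
#'   vectors), \code{labels} (named character, \code{"MR"}/\code{"NonMR"}),
#'   \code{gafPath}, \code{labelPath}.
#' @export
generateGoAnnotations <- function(nRed, nBlue, termsPerProtein,
                                  withinOverlap = 0.5, betweenOverlap = 0.05,
                                  gafPath = tempfile(fileext = ".gaf"),
                                  labelPath = tempfile(fileext = ".tsv"),
                                  seed = 1) {
  nRed <- checkCount(nRed, "nRed", min = 1)
  nBlue <- checkCount(nBlue, "nBlue", min = 1)
  termsPerProtein <- checkCount(termsPerProtein, "termsPerProtein", min = 0)
  checkProb(withinOverlap, "withinOverlap")
  checkProb(betweenOverlap, "betweenOverlap")
  if (withinOverlap < betweenOverlap)
    stop("withinOverlap must be >= betweenOverlap")
  if (termsPerProtein > 0 && withinOverlap <= 0)
    stop("withinOverlap must be > 0 when termsPerProtein > 0")
  poolSize <- if (termsPerProtein == 0) 0L
              else max(termsPerProtein, round(termsPerProtein / withinOverlap))
  nShared <- round(betweenOverlap * poolSize)
  acc <- c(sprintf("RED%04d", seq_len(nRed)), sprintf("BLU%04d", seq_len(nBlue)))
  labels <- stats::setNames(rep(c("MR", "NonMR"), c(nRed, nBlue)), acc)
  withSeed(seed, {
    shared <- if (nShared > 0) sprintf("GO:%07d", seq_len(nShared)) else character()
    own <- poolSize - nShared
    redPool <- c(shared, sprintf("GO:1%06d", seq_len(own)))
    bluePool <- c(shared, sprintf("GO:2%06d", seq_len(own)))
    annotations <- lapply(seq_along(acc), function(i) {
      pool <- if (labels[i] == "MR") redPool else bluePool
      if (termsPerProtein == 0) character()
      else sort(sample(pool, termsPerProtein))
    })
    names(annotations) <- acc
    writeGaf(annotations, gafPath)
    utils::write.table(
      data.frame(accession = acc, label = unname(labels)),
      labelPath, sep = "\t", quote = FALSE, row.names = FALSE)
    list(annotations = annotations, labels = labels,
         gafPath = gafPath, labelPath = labelPath)
  })
}

#' Write annotations as GAF 2.2
#'
#' @param annotations named list mapping accession to a character vector of
#'   GO term identifiers.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGaf <- function(annotations, path) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (acc in names(annotations)) {
    terms <- annotations[[acc]]
    if (!length(terms)) next
    writeLines(paste(
      "UniProtKB", acc, acc, "involved_in", terms, "GO_REF:0000000", "IEA",
      "", "P", "", "", "protein", "taxon:9606", "20220629", "metcensus",
      "", "", sep = "\t"), con)
  }
  invisible(path)
}
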