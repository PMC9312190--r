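#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setOldClass("igraph")

#' MetProteome: a proteome annotated with methionine statistics
#'
#' Container for a set of protein sequences together with the per-protein
#' methionine bookkeeping the census pipeline relies on: 1-based methionine
#' positions, the methionine count \code{m} excluding an initiator methionine
#' at position 1, relative frequencies with and without the initiator, and
#' membrane / zero-methionine flags.
#'
#' The initiator convention used throughout the package: when position 1 is a
#' methionine it is treated as the translation-initiator and excluded from all
#' spatial statistics; the \emph{effective} sequence for clustering analysis
#' is the sequence with position 1 removed. Reported domain coordinates are
#' always in canonical full-sequence 1-based numbering.
#'
#' @slot sequences an \code{\link[Biostrings]{AAStringSet}} of uppercase
#'   residue strings, named by accession.
#' @slot info a \code{\link[S4Vectors]{DataFrame}} with one row per sequence:
#'   \code{accession}, \code{length}, \code{initiatorIsMet}, \code{metCount}
#'   (the count \code{m}, initiator excluded), \code{metFreq}
#'   (initiator-stripped relative frequency \code{m / (length - 1)} when the
#'   initiator is Met, else \code{m / length}), \code{metFreqRaw}
#'   (all methionines over full length), \code{isMembrane}, \code{zeroMet}.
#' @slot metPositions an \code{\link[IRanges]{IntegerList}} of canonical
#'   1-based methionine positions per protein (initiator included).
#'
#' @seealso \code{\link{readProteome}}, \code{\link{generateProteome}},
#'   \code{\link{spatialClassify}}, \code{\link{runCensus}}
#' @export
setClass("MetProteome",
  representation(
    sequences    = "AAStringSet",
    info         = "DataFrame",
    metPositions = "IntegerList"
  )
)

setValidity("MetProteome", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (nrow(object@info) != n)
    msg <- c(msg, "info must have one row per sequence")
  if (length(object@metPositions) != n)
    msg <- c(msg, "metPositions must have one element per sequence")
  need <- c("accession", "length", "initiatorIsMet", "metCount", "metFreq",
            "metFreqRaw", "isMembrane", "zeroMet")
  miss <- setdiff(need, colnames(object@info))
  if (length(miss))
    msg <- c(msg, paste0("info lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (!identical(object@info$length, Biostrings::width(object@sequences)))
      msg <- c(msg, "info$length disagrees with sequence widths")
    if (any(object@info$metFreq < 0 | object@info$metFreq > 1))
      msg <- c(msg, "metFreq must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' GoGraph: a GO-similarity protein network with group labels
#'
#' Undirected graph whose nodes are proteins and whose edges join pairs with
#' Jaccard similarity of GO term sets at or above a threshold. Isolated nodes
#' are retained. Each node carries a categorical label (e.g. \code{"MR"} vs
#' \code{"NonMR"}) used by the assortativity analysis.
#'
#' @slot graph an \code{igraph} undirected graph; vertex attribute
#'   \code{label} holds the group label.
#' @slot threshold the Jaccard threshold (inclusive) used to build the edges.
#'
#' @seealso \code{\link{buildGoGraph}}, \code{\link{assortativityCoefficient}}
#' @export
setClass("GoGraph",
  representation(graph = "igraph", threshold = "numeric")
)

setValidity("GoGraph", function(object) {
  msg <- character()
  g <- object@graph
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (is.null(igraph::vertex_attr(g, "label")))
    msg <- c(msg, "vertices must carry a 'label' attribute")
  if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must be a single value in [0, 1]")
  if (igraph::any_loop(g)) msg <- c(msg, "graph must not contain self-loops")
  if (length(msg)) msg else TRUE
})
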