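# GO-similarity network and assortativity analysis.
#
# Proteins are nodes labeled MR / NonMR; two nodes are joined when the
# Jaccard similarity of their GO term sets is at or above a threshold
# (default 0.25, inclusive). Whether like-labeled nodes preferentially
# connect is measured by Newman's nominal assortativity coefficient, with
# two permutation controls: random relabeling on the fixed topology, and
# rebuilding the graph from random samples of an annotation pool.

#' Jaccard similarity of two term sets
#'
#' \code{|A intersect B| / |A union B|}. When both sets are empty the index
#' is undefined; it is returned as 0 (no edge) with a message, guarding the
#' division by zero.
#'
#' @param setA,setB character vectors (treated as sets).
#' @return similarity in [0, 1].
#' @export
jaccardIndex <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- length(union(setA, setB))
  if (u == 0L) {
    message("Jaccard of two empty sets is undefined; returning 0")
    return(0)
  }
  length(intersect(setA, setB)) / u
}

#' Read GO annotations from a GAF 2.x file
#'
#' Parses the tab-delimited Gene Association File format (comment lines
#' start with \code{!}), returning the mapping from protein accession
#' (column 2) to its set of GO term identifiers (column 5), duplicates
#' removed.
#'
#' @param path GAF file path.
#' @param aspect optional filter on the ontology aspect column
#'   (\code{"P"}, \code{"F"}, \code{"C"}); NULL keeps all.
#' @return named list of character term-set vectors.
#' @export
readGaf <- function(path, aspect = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 9
  if (any(!ok)) warning(sum(!ok), " malformed GAF row(s) skipped")
  parts <- parts[ok]
  acc <- vapply(parts, `[`, character(1), 2)
  term <- vapply(parts, `[`, character(1), 5)
  if (!is.null(aspect)) {
    keep <- vapply(parts, `[`, character(1), 9) == aspect
    acc <- acc[keep]; term <- term[keep]
  }
  lapply(split(term, acc), unique)
}

#' Read a two-column accession/label table
#'
#' @param path TSV with header columns \code{accession} and \code{label}.
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "label") %in% colnames(tab)))
  stats::setNames(tab$label, tab$accession)
}

#' Build the GO-Jaccard protein graph
#'
#' Tests all unordered pairs of labeled proteins and joins those whose
#' Jaccard similarity meets the threshold (inclusive). Proteins without an
#' annotation entry get an empty term set; isolated nodes are retained.
#'
#' @param annotations named list mapping accession to a term-set vector.
#' @param labels named character vector of group labels; its names define
#'   the node set.
#' @param threshold Jaccard threshold (default 0.25).
#' @return a \code{\linkS4class{GoGraph}}.
#' @export
buildGoGraph <- function(annotations, labels, threshold = 0.25) {
  checkProb(threshold, "threshold")
  acc <- names(labels)
  stopifnot(!is.null(acc), !anyDuplicated(acc))
  sets <- lapply(acc, function(a) unique(annotations[[a]]))
  n <- length(acc)
  from <- integer(0); to <- integer(0)
  emptyPairs <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0L) { emptyPairs <- emptyPairs + 1L; next }
      if (length(intersect(sets[[i]], sets[[j]])) / u >= threshold) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  if (emptyPairs > 0L)
    message(emptyPairs, " pair(s) with two empty term sets treated as unrelated")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = acc)
  g <- igraph::set_vertex_attr(g, "label", value = unname(labels))
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  new("GoGraph", graph = g, threshold = threshold)
}

setMethod("show", "GoGraph", function(object) {
  g <- object@graph
  cat("GoGraph:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      "edges (Jaccard >=", object@threshold, ")\n")
  print(table(igraph::vertex_attr(g, "label")))
})

# Nominal assortativity from the labels at the two ends of each edge.
# Each undirected edge contributes both orientations to the mixing matrix.
.assortFromEnds <- function(endA, endB, levels) {
  la <- factor(c(endA, endB), levels = levels)
  lb <- factor(c(endB, endA), levels = levels)
  e <- table(la, lb) / (2 * length(endA))
  a <- rowSums(e)
  denom <- 1 - sum(a * a)
  if (denom == 0) return(NA_real_)  # single label class: undefined
  (sum(diag(e)) - sum(a * a)) / denom
}

#' Newman's nominal assortativity coefficient
#'
#' Computed from the edge mixing matrix over label categories:
#' \code{r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)}, where
#' \code{e_ij} is the fraction of edge ends joining categories i and j and
#' \code{a}, \code{b} its margins. \code{r = 1} for perfectly assortative
#' mixing (edges only within categories), \code{r = -1} for a balanced
#' perfectly disassortative network, near 0 when labels do not influence
#' edges. Only edges contribute; isolated nodes are ignored.
#'
#' @param graph a \code{\linkS4class{GoGraph}}, or an \code{igraph} object
#'   with a \code{label} vertex attribute.
#' @param labels optional label vector overriding the stored attribute.
#' @return r in [-1, 1]; \code{NA} (not evaluable) for an edgeless graph or
#'   when every edge end carries the same single label.
#' @export
assortativityCoefficient <- function(graph, labels = NULL) {
  g <- if (is(graph, "GoGraph")) graph@graph else graph
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "label")
  stopifnot(length(labels) == igraph::vcount(g))
  if (igraph::ecount(g) == 0L) return(NA_real_)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  .assortFromEnds(labels[ends[, 1]], labels[ends[, 2]],
                  levels = sort(unique(labels)))
}

#' Relabeling permutation test for assortativity
#'
#' Keeps the network topology and the label proportions fixed, randomly
#' permutes the node labels, and recomputes r. The p-value is the plug-in
#' fraction of permutations with r at or above the observed value (upper
#' tail: positive assortativity is the claim under test).
#'
#' @param graph a \code{\linkS4class{GoGraph}} (or igraph with labels).
#' @param reps permutation replicates (default 1e5).
#' @param seed integer seed.
#' @return list: observed r, p, reps, nullR (the permutation sample).
#' @export
relabelTest <- function(graph, reps = 100000, seed = 1) {
  g <- if (is(graph, "GoGraph")) graph@graph else graph
  labels <- igraph::vertex_attr(g, "label")
  rObs <- assortativityCoefficient(g, labels)
  if (is.na(rObs)) stop("observed assortativity is not evaluable")
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  lv <- sort(unique(labels))
  nullR <- withSeed(seed, vapply(seq_len(reps), function(i) {
    perm <- sample(labels)
    .assortFromEnds(perm[ends[, 1]], perm[ends[, 2]], lv)
  }, numeric(1)))
  list(observed = rObs, p = mean(nullR >= rObs, na.rm = TRUE),
       reps = reps, nullR = nullR)
}

#' Resampling control for assortativity
#'
#' Per replicate: sample \code{nNodes} proteins from an annotation pool,
#' build the graph under the same Jaccard rule, assign labels at random at
#' the observed proportion, and compute r. Replicates whose graph is not
#' evaluable (edgeless) are skipped with a message. The p-value is the
#' fraction of evaluable replicates with r at or above the observed value.
#'
#' @param annotationPool named list of term sets to sample nodes from.
#' @param nNodes nodes per replicate (the observed network's node count).
#' @param labelProportion fraction of nodes given the first label.
#' @param observedR the observed assortativity to compare against.
#' @param threshold Jaccard edge threshold (default 0.25).
#' @param reps replicates (default 1000).
#' @param labelLevels the two label strings (default MR / NonMR).
#' @param seed integer seed.
#' @return list: p, reps, used (evaluable replicates), nullR.
#' @export
resampleTest <- function(annotationPool, nNodes, labelProportion, observedR,
                         threshold = 0.25, reps = 1000,
                         labelLevels = c("MR", "NonMR"), seed = 1) {
  stopifnot(length(annotationPool) >= nNodes, nNodes >= 2)
  checkProb(labelProportion, "labelProportion")
  nFirst <- round(labelProportion * nNodes)
  nullR <- withSeed(seed, vapply(seq_len(reps), function(i) {
    acc <- sample(names(annotationPool), nNodes)
    lab <- stats::setNames(
      sample(rep(labelLevels, c(nFirst, nNodes - nFirst))), acc)
    gg <- suppressMessages(
      buildGoGraph(annotationPool[acc], lab, threshold = threshold))
    assortativityCoefficient(gg)
  }, numeric(1)))
  skipped <- sum(is.na(nullR))
  if (skipped > 0)
    message(skipped, " replicate(s) with non-evaluable graphs skipped")
  list(p = mean(nullR >= observedR, na.rm = TRUE), reps = reps,
       used = sum(!is.na(nullR)), nullR = nullR)
}

#' Hypergeometric GO term enrichment with Bonferroni correction
#'
#' For each term annotated in the reference set: \code{k} of the \code{n}
#' test proteins and \code{K} of the \code{N} reference proteins carry the
#' term; the upper-tail hypergeometric p-value is Bonferroni-multiplied by
#' the number of tested terms (capped at 1). Fold enrichment is the ratio
#' of proportions \code{(k/n) / (K/N)}.
#'
#' @param testSet accessions of the test group (must be a subset of
#'   \code{referenceSet}).
#' @param referenceSet accessions of the reference (background) group.
#' @param annotations named list of term sets.
#' @return data.frame: term, k, K, n, N, p, pAdj, fold, sorted by p.
#' @export
goEnrichment <- function(testSet, referenceSet, annotations) {
  stopifnot(all(testSet %in% referenceSet))
  refSets <- lapply(referenceSet, function(a) unique(annotations[[a]]))
  names(refSets) <- referenceSet
  terms <- sort(unique(unlist(refSets)))
  missing <- setdiff(unique(unlist(lapply(testSet, function(a)
    annotations[[a]]))), terms)
  if (length(missing))
    message(length(missing), " term(s) absent from the reference skipped")
  N <- length(referenceSet)
  n <- length(testSet)
  inTest <- referenceSet %in% testSet
  rows <- lapply(terms, function(tm) {
    has <- vapply(refSets, function(s) tm %in% s, logical(1))
    K <- sum(has)
    k <- sum(has & inTest)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               fold = if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- pmin(out$p * length(terms), 1)
  out <- out[order(out$p, out$term), c("term", "k", "K", "n", "N", "p",
                                       "pAdj", "fold")]
  rownames(out) <- NULL
  out
}
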