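#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#'   vmatchPattern
#' @importFrom IRanges IntegerList
NULL

# Build the per-protein info table and Met-position list for a set of
# uppercase sequences. Ambiguous residues (X, U, B, Z, ...) are retained in
# the sequence but never counted as methionine.
.annotateProteome <- function(seqs) {
  acc <- names(seqs)
  pos <- Biostrings::vmatchPattern("M", seqs)
  posList <- IRanges::IntegerList(lapply(pos, IRanges::start))
  len <- Biostrings::width(seqs)
  nMetAll <- unname(lengths(posList))
  initIsMet <- vapply(posList, function(p) length(p) > 0L && p[1L] == 1L,
                      logical(1), USE.NAMES = FALSE)
  m <- nMetAll - as.integer(initIsMet)
  effLen <- len - as.integer(initIsMet)
  info <- S4Vectors::DataFrame(
    accession      = acc,
    length         = len,
    initiatorIsMet = initIsMet,
    metCount       = as.integer(m),
    metFreq        = ifelse(effLen > 0, m / effLen, 0),
    metFreqRaw     = nMetAll / len,
    isMembrane     = logical(length(seqs)),
    zeroMet        = m == 0L,
    row.names      = acc
  )
  new("MetProteome", sequences = seqs, info = info, metPositions = posList)
}

#' Construct a MetProteome from sequences
#'
#' @param sequences named character vector or \code{AAStringSet} of uppercase
#'   residue strings; names are taken as accessions.
#' @return a \code{\linkS4class{MetProteome}}.
#' @export
MetProteome <- function(sequences) {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names (accessions)")
  .annotateProteome(sequences)
}

#' Read and filter a proteome from FASTA
#'
#' Reads protein sequences, parses accessions from UniProt-style headers
#' (\code{sp|ACC|NAME} or \code{tr|ACC|NAME}; otherwise the first
#' whitespace-delimited token), and drops every sequence shorter than
#' \code{minLength} residues. Records containing characters outside the
#' amino-acid alphabet (including ambiguity codes) are kept; truly
#' non-residue characters cause the record to be skipped with a warning.
#'
#' @param fastaPath path to a FASTA file.
#' @param minLength minimum sequence length retained (default 100).
#' @return a \code{\linkS4class{MetProteome}} with records in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">sp|P00001|TEST", strrep("ACDM", 30)), fa)
#' p <- readProteome(fa)
#' accessions(p)
#' @export
readProteome <- function(fastaPath, minLength = 100) {
  if (!file.exists(fastaPath)) stop("cannot read FASTA file: ", fastaPath)
  seqs <- Biostrings::readAAStringSet(fastaPath)
  if (length(seqs) == 0L) stop("no sequences found in ", fastaPath)
  hdr <- names(seqs)
  acc <- vapply(hdr, function(h) {
    tok <- strsplit(h, "[[:space:]]+")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && parts[1] %in% c("sp", "tr")) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(seqs) <- acc
  bad <- grepl("[^ABCDEFGHIKLMNPQRSTUVWXYZ*]", as.character(seqs)) |
    Biostrings::width(seqs) == 0L
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped (empty or non-residue characters): ",
            paste(utils::head(acc[bad], 5), collapse = ", "))
    seqs <- seqs[!bad]
  }
  seqs <- seqs[Biostrings::width(seqs) >= minLength]
  if (anyDuplicated(names(seqs))) {
    warning("duplicated accessions; keeping first occurrence")
    seqs <- seqs[!duplicated(names(seqs))]
  }
  .annotateProteome(seqs)
}

#' Write a proteome to FASTA
#'
#' Uppercase residues, 60-column line wrap, headers are bare accessions.
#'
#' @param proteome a \code{\linkS4class{MetProteome}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  stopifnot(is(proteome, "MetProteome"))
  Biostrings::writeXStringSet(proteome@sequences, path, width = 60L)
  invisible(path)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn MetProteome-accessors accessions, in order
#' @export
accessions <- function(x) x@info$accession

#' Accessors for MetProteome
#'
#' @param x a \code{\linkS4class{MetProteome}}.
#' @name MetProteome-accessors
#' @return \code{accessions}: character vector; \code{proteinInfo}: the
#'   per-protein \code{DataFrame}; \code{metPositions}: an
#'   \code{IntegerList} of canonical 1-based Met positions;
#'   \code{sequences}: the \code{AAStringSet}.
NULL

#' @describeIn MetProteome-accessors per-protein annotation table
#' @export
proteinInfo <- function(x) x@info

#' @describeIn MetProteome-accessors Met positions (canonical coordinates)
#' @export
metPositions <- function(x) x@metPositions

#' @describeIn MetProteome-accessors the sequences
#' @export
sequences <- function(x) x@sequences

setMethod("show", "MetProteome", function(object) {
  info <- object@info
  cat("MetProteome with", nrow(info), "proteins\n")
  cat(sprintf("  length: %d-%d; mean Met frequency (initiator-stripped): %.4f\n",
              min(info$length), max(info$length), mean(info$metFreq)))
  cat(sprintf("  zero-Met: %d; membrane-flagged: %d\n",
              sum(info$zeroMet), sum(info$isMembrane)))
})

#' @export
setMethod("length", "MetProteome", function(x) length(x@sequences))

#' @export
setMethod("[", "MetProteome", function(x, i, j, ..., drop = TRUE) {
  new("MetProteome", sequences = x@sequences[i], info = x@info[i, ],
      metPositions = x@metPositions[i])
})

# ---- composition ------------------------------------------------------------

#' Methionine relative frequency of one sequence
#'
#' With \code{stripInitiator = TRUE} (the package convention) a methionine at
#' position 1 is dropped from both the count and the length: the frequency is
#' \code{m / (length - 1)}. Without stripping, it is the raw fraction of
#' methionines over the full length.
#'
#' @param sequence a single residue string.
#' @param stripInitiator drop a position-1 methionine from numerator and
#'   denominator (default TRUE).
#' @return relative frequency in [0, 1].
#' @examples
#' metContent("MAAAM")                        # 1/4
#' metContent("MAAAM", stripInitiator = FALSE) # 2/5
#' @export
metContent <- function(sequence, stripInitiator = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  ch <- strsplit(sequence, "")[[1]]
  nMet <- sum(ch == "M")
  if (stripInitiator && ch[1] == "M") {
    if (length(ch) == 1L) return(0)
    (nMet - 1L) / (length(ch) - 1L)
  } else nMet / length(ch)
}

#' Proteome-level methionine composition summary
#'
#' @param proteome a \code{\linkS4class{MetProteome}}.
#' @return a list: \code{perProtein} (data.frame with accession, frequency
#'   with and without initiator), \code{mean}, \code{median} (both on the
#'   initiator-stripped frequency), and \code{zeroMet} (accessions with no
#'   methionine beyond an initiator).
#' @export
metCompositionSummary <- function(proteome) {
  stopifnot(is(proteome, "MetProteome"))
  info <- proteome@info
  list(
    perProtein = data.frame(
      accession  = info$accession,
      metFreq    = info$metFreq,
      metFreqRaw = info$metFreqRaw
    ),
    mean    = mean(info$metFreq),
    median  = stats::median(info$metFreq),
    zeroMet = info$accession[info$zeroMet]
  )
}

# ---- membrane partition and enrichment --------------------------------------

#' Flag membrane proteins from an accession list
#'
#' @param proteome a \code{\linkS4class{MetProteome}}.
#' @param membraneAccessions character vector (or path to a one-per-line
#'   text file) of membrane protein accessions. Accessions absent from the
#'   proteome are reported and ignored.
#' @return the proteome with \code{isMembrane} set.
#' @export
splitMembrane <- function(proteome, membraneAccessions) {
  stopifnot(is(proteome, "MetProteome"))
  if (length(membraneAccessions) == 1L && file.exists(membraneAccessions))
    membraneAccessions <- readLines(membraneAccessions)
  membraneAccessions <- membraneAccessions[nzchar(membraneAccessions)]
  unknown <- setdiff(membraneAccessions, proteome@info$accession)
  if (length(unknown))
    message(length(unknown), " membrane accession(s) not in proteome; ignored")
  proteome@info$isMembrane <- proteome@info$accession %in% membraneAccessions
  proteome
}

#' Fisher's exact test on a 2x2 property contingency table
#'
#' Cross-tabulates two binary protein properties (e.g. membrane status vs a
#' spatial class) and returns the two-sided Fisher exact p-value.
#'
#' @param flagA,flagB logical vectors of equal length.
#' @return list with \code{table} (2x2) and \code{p.value}.
#' @examples
#' contingencyFisher(rep(c(TRUE, FALSE), each = 10),
#'                   rep(c(TRUE, FALSE), each = 10))
#' @export
contingencyFisher <- function(flagA, flagB) {
  stopifnot(is.logical(flagA), is.logical(flagB),
            length(flagA) == length(flagB))
  tab <- table(factor(flagA, levels = c(TRUE, FALSE)),
               factor(flagB, levels = c(TRUE, FALSE)))
  list(table = tab, p.value = stats::fisher.test(tab)$p.value)
}
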