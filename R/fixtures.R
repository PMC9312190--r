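#' Bundled worked example: the six top-ranking MR-PrLDs
#'
#' The published six highest-ranking MR-PrLD records (accession, canonical
#' 1-based inclusive start/end, length, methionine count x, reported
#' p-value, and domain sequence), shipped as a plain-text fixture. Used in
#' worked examples and consistency checks: the printed length equals
#' \code{end - start + 1} and \code{x} equals the methionine count of the
#' printed sequence.
#'
#' @return data.frame with columns accession, start, end, length, x,
#'   pValue, sequence.
#' @examples
#' tab <- mrprldTop6()
#' all(tab$length == tab$end - tab$start + 1)
#' @export
mrprldTop6 <- function() {
  utils::read.table(
    system.file("extdata", "mrprld_top6.tsv", package = "metcensus",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
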