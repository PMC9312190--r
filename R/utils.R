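# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-protein seed from a global seed and an accession
#'
#' Proteome-scale runs draw one empirical null per protein. Deriving each
#' protein's seed deterministically from a single global seed and its
#' accession makes results reproducible and independent of processing order.
#' The accession is hashed with a 31-ary polynomial rolling hash modulo
#' 2^31 - 1 and combined with the global seed.
#'
#' @param seed global integer seed.
#' @param accession character accession string.
#' @return an integer in [0, 2^31 - 2] usable with \code{set.seed}.
#' @export
deriveSeed <- function(seed, accession) {
  stopifnot(length(accession) == 1L, is.character(accession))
  p <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (v in utf8ToInt(accession)) h <- (h * 31 + v) %% p
  as.integer((h + (as.numeric(seed) %% p) * 48271) %% p)
}

# Validate a probability argument.
checkProb <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("'%s' must be a probability%s", name,
                        if (open) " strictly inside (0, 1)" else " in [0, 1]"),
                call. = FALSE)
  invisible(x)
}

checkCount <- function(x, name, min = 0) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
  if (!ok) stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
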