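# Independent oracles used to validate the package's implementations.
# Each is deliberately naive (two-pass arithmetic, term-by-term summation,
# exhaustive enumeration) and shares no code with the functions it checks.

# Naive two-pass coefficient of variation: population SD over mean.
naiveCV <- function(counts) {
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  sqrt(mean((counts - m)^2)) / m
}

# Binomial upper tail P[X >= x] by log-space term accumulation
# (log-sum-exp so the sum is stable far into the tail).
binomTailOracle <- function(n, x, p) {
  if (x <= 0) return(1)
  ks <- x:n
  lt <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

# Hypergeometric upper tail P[X >= k] by direct summation.
hyperTailOracle <- function(N, K, n, k) {
  ks <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Exhaustive lowest-binomial-tail subsequence: scans every O(L^2) window
# with length in [minLen, maxLen], Met-trimmed endpoints implicit in that
# only windows starting/ending on a Met can minimise the tail.
exhaustiveBiasOracle <- function(sequence, p, minLen = 10, maxLen = 1000) {
  ch <- strsplit(sequence, "")[[1]]
  isM <- ch == "M"
  cum <- c(0L, cumsum(isM))
  L <- length(ch)
  best <- list(p = Inf, start = NA, end = NA, k = NA)
  for (s in seq_len(L)) {
    for (e in s:min(L, s + maxLen - 1)) {
      n <- e - s + 1
      if (n < minLen) next
      k <- cum[e + 1] - cum[s]
      if (k == 0) next
      pv <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
      if (pv < best$p) best <- list(p = pv, start = s, end = e, k = k)
    }
  }
  if (is.finite(best$p)) {
    # Met-trimmed coordinates of the minimising window
    mets <- which(isM)
    inside <- mets[mets >= best$start & mets <= best$end]
    best$tstart <- inside[1]
    best$tend <- inside[length(inside)]
  }
  best
}

# Naive empirical null for q: plain loop, no shared code with nullQ.
naiveNullQ <- function(m, len, B, segmentLen = 50, seed = 1) {
  set.seed(seed)
  vapply(seq_len(B), function(i) {
    pos <- sample.int(len, m)
    counts <- tabulate(ceiling(pos / segmentLen),
                       nbins = ceiling(len / segmentLen))
    naiveCV(counts)
  }, numeric(1))
}

# Random labeled graph for assortativity cross-checks.
randomLabeledGraph <- function(n, pEdge, labels = NULL) {
  g <- igraph::sample_gnp(n, pEdge, directed = FALSE)
  if (is.null(labels)) labels <- sample(c("MR", "NonMR"), n, replace = TRUE)
  igraph::set_vertex_attr(g, "label", value = labels)
}

# Jaccard of two integer intervals [s1,e1], [s2,e2].
intervalJaccard <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  un <- max(e1, e2) - min(s1, s2) + 1
  ov / un
}

countMet <- function(s) sum(strsplit(s, "")[[1]] == "M")
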