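test_that("bias scan finds planted Met-rich windows and agrees with the exhaustive oracle", {
  expect_equal(nrow(metBiasRegions(strrep("A", 200), 0.02)), 0)

  # planted: 10 Met inside residues 91-120, none elsewhere
  set.seed(2)
  ch <- rep("A", 200)
  ch[sort(sample(91:120, 10))] <- "M"
  reg <- metBiasRegions(paste(ch, collapse = ""), 0.02)
  expect_equal(nrow(reg), 1)
  expect_gte(reg$start, 91)
  expect_lte(reg$end, 120)
  expect_equal(reg$metCount, 10)

  # oracle agreement on random sequences <= 300 residues: same minimising
  # window and same acceptance decision
  set.seed(77)
  for (i in 1:25) {
    L <- sample(120:300, 1)
    dens <- runif(1, 0.02, 0.2)
    s <- paste(sample(c("M", "A", "G", "S"), L, replace = TRUE,
                      prob = c(dens, rep((1 - dens) / 3, 3))),
               collapse = "")
    oracle <- exhaustiveBiasOracle(s, 0.02)
    got <- metBiasRegions(s, 0.02)
    if (is.finite(oracle$p) && oracle$p < 1e-5) {
      expect_gte(nrow(got), 1)
      top <- got[which.min(got$biasP), ]
      expect_equal(top$start, oracle$tstart)
      expect_equal(top$end, oracle$tend)
      expect_equal(top$biasP, oracle$p, tolerance = 1e-12)
    } else {
      expect_equal(nrow(got), 0)
    }
  }

  # emitted regions never overlap and always start/end on a Met; blocks are
  # spaced far enough apart that merging them is less surprising than each
  # block alone
  s <- paste(rep(c(strrep("M", 8), strrep("A", 300)), 4), collapse = "")
  multi <- metBiasRegions(s, 0.02)
  expect_gt(nrow(multi), 1)
  ch <- strsplit(s, "")[[1]]
  expect_true(all(ch[multi$start] == "M" & ch[multi$end] == "M"))
  if (nrow(multi) > 1)
    expect_true(all(multi$start[-1] > multi$end[-nrow(multi)]))
})

test_that("bias scan false-positive rate on background sequences is small", {
  hits <- vapply(1:400, function(i) {
    s <- generatePrldSegment(300, "background", seed = 4000 + i)
    nrow(metBiasRegions(s, 0.02)) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.04)  # ~2% expected; 3 SE slack at 400 seeds
})

test_that("HMM posterior decodes planted prion segments and degenerate cases", {
  # background-only sequence: low prion posterior on average
  s <- generatePrldSegment(500, "background", seed = 1)
  expect_lt(mean(prldPosterior(s)), 0.1)

  # identical emission tables: posterior equals the stationary probability
  tab <- aminoAcidTable("background")
  post <- prldPosterior(generatePrldSegment(200, "background", seed = 2),
                        prionTable = tab, backgroundTable = tab,
                        expectedPrionLen = 100, expectedBackgroundLen = 1000)
  stationary <- (1 / 1000) / (1 / 1000 + 1 / 100)
  expect_equal(post, rep(stationary, 200), tolerance = 1e-9)

  # posterior is a proper probability and sums to 1 with the background state
  expect_true(all(post >= 0 & post <= 1))

  # planted segment: the maximal >=0.9 run overlaps the plant midpoint
  hit <- vapply(1:100, function(i) {
    sq <- paste0(generatePrldSegment(200, "background", seed = 3 * i),
                 generatePrldSegment(80, "prion", seed = 3 * i + 1),
                 generatePrldSegment(200, "background", seed = 3 * i + 2))
    runs <- prldRegions(prldPosterior(sq), 0.9, minCore = 1)
    if (!nrow(runs)) return(FALSE)
    len <- runs$end - runs$start + 1
    top <- runs[which.max(len), ]
    top$start <= 240 && top$end >= 240
  }, logical(1))
  expect_gt(mean(hit), 0.95)
})

test_that("prion regions are maximal runs over the core-length filter", {
  expect_equal(nrow(prldRegions(rep(0, 100))), 0)
  expect_equal(prldRegions(rep(1, 100)), data.frame(start = 1L, end = 100L))
  expect_equal(nrow(prldRegions(c(rep(0, 10), rep(0.95, 59), rep(0, 10)))), 0)
  got <- prldRegions(c(rep(0.95, 60), rep(0, 5), rep(0.95, 70)), minCore = 60)
  expect_equal(got$start, c(1L, 66L))
  expect_equal(got$end, c(60L, 135L))
})

test_that("binomial domain score matches the direct-summation oracle", {
  expect_equal(scoreMrPrld(10, 0, 0.3), 1)
  expect_equal(scoreMrPrld(10, 10, 0.5), 0.5^10, tolerance = 1e-15)
  # strictly decreasing in x
  expect_true(all(diff(scoreMrPrld(57, 0:57, 42 / 956)) < 0))
  # 500 random triples within the normally-representable double range
  # (tails below ~1e-290 only exist as subnormals, where relative error is
  # representation granularity, not arithmetic)
  set.seed(8)
  done <- 0
  while (done < 500) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    p <- runif(1, 0.005, 0.5)
    o <- binomTailOracle(n, x, p)
    if (o < 1e-290) next
    expect_equal(scoreMrPrld(n, x, p) / o, 1, tolerance = 1e-10)
    done <- done + 1
  }
})

test_that("domain calling enforces the four criteria and the overlap rule", {
  seqStr <- paste0(strrep("A", 64), strrep("MA", 29), strrep("A", 100))
  bias <- data.frame(start = 65, end = 121, metCount = 19, biasP = 1e-9)
  prld <- data.frame(start = 60, end = 130)

  # criterion i: non-aggregation proteins yield nothing
  expect_equal(nrow(callMrPrlds("X", seqStr, "dispersion", bias, prld, 0.04)), 0)
  expect_equal(nrow(callMrPrlds("X", seqStr, "random", bias, prld, 0.04)), 0)

  # intersection span with canonical coordinates
  got <- callMrPrlds("X", seqStr, "aggregation", bias, prld, 0.04)
  expect_equal(got$start, 65)
  expect_equal(got$end, 121)
  expect_equal(got$n, 57)
  expect_equal(got$x, countMet(substring(seqStr, 65, 121)))
  expect_equal(got$pValue, scoreMrPrld(got$n, got$x, 0.04))

  # criterion iv: fewer than 5 Met filtered out
  seq4 <- paste0(strrep("A", 64), "MAMAMAMA", strrep("A", 130))
  bias4 <- data.frame(start = 65, end = 72, metCount = 4, biasP = 1e-9)
  expect_equal(nrow(callMrPrlds("X", seq4, "aggregation", bias4, prld, 0.02)), 0)

  # no positional overlap -> no call
  far <- data.frame(start = 150, end = 220)
  expect_equal(nrow(callMrPrlds("X", seqStr, "aggregation", bias, far, 0.04)), 0)

  # union and containment dialects
  u <- callMrPrlds("X", seqStr, "aggregation", bias, prld, 0.04, match = "union")
  expect_equal(c(u$start, u$end), c(60, 130))
  ct <- callMrPrlds("X", seqStr, "aggregation", bias, prld, 0.04,
                    match = "containment")
  expect_equal(c(ct$start, ct$end), c(65, 121))
})

test_that("census ranking is ascending in p with documented tie-breaks", {
  tab <- data.frame(accession = c("B", "A", "C"), start = c(1, 5, 2),
                    pValue = c(1e-3, 1e-13, 1e-9))
  expect_equal(rankCensus(tab)$pValue, c(1e-13, 1e-9, 1e-3))
  ties <- data.frame(accession = c("B", "A", "A"), start = c(7, 9, 2),
                     pValue = rep(1e-5, 3))
  expect_equal(rankCensus(ties)$accession, c("A", "A", "B"))
  expect_equal(rankCensus(ties)$start, c(2, 9, 7))
  expect_equal(nrow(rankCensus(tab[0, ])), 0)
})

test_that("published top-six table is internally consistent with the call machinery", {
  tab <- mrprldTop6()
  # Met counts of the printed sequences equal the printed x column
  expect_equal(vapply(tab$sequence, countMet, numeric(1), USE.NAMES = FALSE),
               c(19, 21, 18, 8, 12, 14))
  # printed lengths match 1-based inclusive coordinates
  expect_equal(tab$end - tab$start + 1, tab$length)
  expect_equal(nchar(tab$sequence), tab$length)
  # scored at any common background, the (57, 19) domain outranks (28, 8)
  pv <- scoreMrPrld(tab$length, tab$x, 42 / 956)
  expect_lt(pv[tab$accession == "O75400"], pv[tab$accession == "Q96JP2"])
})

test_that("external-scan adapters parse drop-in region and posterior files", {
  flps <- tempfile()
  writeLines(c(
    "# fLPS-style output",
    paste("O75400", "SINGLE", "65", "121", "19", "3.1e-12", "{M}", sep = "\t"),
    paste("O75400", "SINGLE", "200", "240", "6", "2.0e-03", "{M}", sep = "\t"),
    paste("O75400", "SINGLE", "300", "340", "12", "1.0e-09", "{Q}", sep = "\t")
  ), flps)
  reg <- readFlpsRegions(flps, accession = "O75400")
  expect_equal(nrow(reg), 1)  # {Q} signature and sub-threshold row dropped
  expect_equal(reg$start, 65)
  expect_equal(reg$metCount, 19)

  plaac <- tempfile()
  writeLines(c("# pos prob", paste(3:1, c(0.2, 0.9, 0.4))), plaac)
  post <- readPlaacPosterior(plaac)
  expect_equal(post, c(0.4, 0.9, 0.2))
})
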