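test_that("Jaccard similarity handles standard and degenerate sets", {
  expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccardIndex(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccardIndex(c("a"), c("a", "b", "c", "d")), 0.25)
  expect_message(z <- jaccardIndex(character(), character()), "undefined")
  expect_equal(z, 0)
})

test_that("graph construction applies the inclusive threshold and keeps isolates", {
  ann <- list(P1 = c("a", "b", "c", "d"), P2 = c("a", "b", "c", "e"),
              P3 = "x")
  lab <- c(P1 = "MR", P2 = "MR", P3 = "NonMR")
  g <- buildGoGraph(ann, lab, threshold = 0.25)
  expect_equal(igraph::vcount(g@graph), 3)
  expect_equal(igraph::ecount(g@graph), 1)  # J(P1,P2) = 3/5
  expect_true(igraph::are_adjacent(g@graph, "P1", "P2"))

  # J exactly at the threshold forms an edge (inclusive rule)
  ann2 <- list(A = c("t1"), B = c("t1", "t2", "t3", "t4"))
  g2 <- buildGoGraph(ann2, c(A = "MR", B = "NonMR"), threshold = 0.25)
  expect_equal(igraph::ecount(g2@graph), 1)

  # identical sets: complete graph; disjoint sets: edgeless
  annC <- setNames(rep(list(c("a", "b")), 4), paste0("P", 1:4))
  gC <- buildGoGraph(annC, setNames(rep("MR", 4), names(annC)))
  expect_equal(igraph::ecount(gC@graph), choose(4, 2))
  annD <- setNames(lapply(1:4, function(i) paste0("t", i)), paste0("P", 1:4))
  gD <- buildGoGraph(annD, setNames(rep("MR", 4), names(annD)))
  expect_equal(igraph::ecount(gD@graph), 0)
})

test_that("nominal assortativity reproduces closed forms and the igraph oracle", {
  # two disconnected monochromatic cliques: r = 1 exactly
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(5))
  g <- igraph::set_vertex_attr(g, "label",
                               value = rep(c("MR", "NonMR"), c(4, 5)))
  expect_identical(assortativityCoefficient(g), 1)

  # balanced complete bipartite with edges only across: r = -1 exactly
  gb <- igraph::make_full_bipartite_graph(5, 5)
  gb <- igraph::set_vertex_attr(gb, "label",
                                value = rep(c("MR", "NonMR"), each = 5))
  expect_identical(assortativityCoefficient(gb), -1)

  # edgeless graph: not evaluable
  ge <- igraph::make_empty_graph(3, directed = FALSE)
  ge <- igraph::set_vertex_attr(ge, "label", value = rep("MR", 3))
  expect_true(is.na(assortativityCoefficient(ge)))

  # agreement with igraph's implementation on random labeled graphs
  set.seed(23)
  checked <- 0
  while (checked < 200) {
    g <- randomLabeledGraph(sample(6:25, 1), runif(1, 0.15, 0.6))
    if (igraph::ecount(g) == 0) next
    lab <- igraph::vertex_attr(g, "label")
    if (length(unique(lab)) < 2) next
    ref <- igraph::assortativity_nominal(g, as.integer(factor(lab)))
    mine <- assortativityCoefficient(g)
    if (is.nan(ref)) expect_true(is.na(mine) || is.nan(mine))
    else expect_equal(mine, ref, tolerance = 1e-10)
    checked <- checked + 1
  }

  # random labels on a fixed graph: mean r near 0 (the permutation null
  # carries a small negative O(1/n) bias from the random margins, so "near"
  # means within 0.05 here, not within Monte Carlo error of exactly 0)
  set.seed(31)
  gfix <- randomLabeledGraph(30, 0.3,
                             labels = rep(c("MR", "NonMR"), each = 15))
  rs <- vapply(seq_len(2000), function(i)
    assortativityCoefficient(gfix, sample(igraph::vertex_attr(gfix, "label"))),
    numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("relabeling test is deterministic, monotone and detects planted structure", {
  set.seed(7)
  ga <- generateGoAnnotations(15, 15, 6, withinOverlap = 0.6,
                              betweenOverlap = 0.05, seed = 41)
  g <- buildGoGraph(ga$annotations, ga$labels)
  t1 <- relabelTest(g, reps = 2000, seed = 3)
  t2 <- relabelTest(g, reps = 2000, seed = 3)
  expect_identical(t1$p, t2$p)
  expect_gt(t1$observed, 0)

  # p is monotone decreasing in the observed statistic on a fixed null
  ps <- vapply(c(-0.5, 0, 0.2, 0.8),
               function(r) mean(t1$nullR >= r), numeric(1))
  expect_true(all(diff(ps) <= 0))

  # strongly assortative planted annotations: p below alpha in most seeds
  hits <- vapply(1:20, function(i) {
    gg <- generateGoAnnotations(12, 12, 6, withinOverlap = 0.75,
                                betweenOverlap = 0.05, seed = 500 + i)
    gr <- buildGoGraph(gg$annotations, gg$labels)
    r <- assortativityCoefficient(gr)
    if (is.na(r)) return(NA)
    relabelTest(gr, reps = 500, seed = i)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.9)
})

test_that("resampling control rebuilds graphs and yields valid p-values", {
  ga <- generateGoAnnotations(25, 25, 6, withinOverlap = 0.7,
                              betweenOverlap = 0.05, seed = 11)
  g <- buildGoGraph(ga$annotations, ga$labels)
  rObs <- assortativityCoefficient(g)
  # pool without group structure: labels are random, so extreme observed r
  # is rarely matched
  pool <- ga$annotations
  rt <- resampleTest(pool, nNodes = 30, labelProportion = 0.5,
                     observedR = rObs, reps = 100, seed = 13)
  expect_true(rt$p >= 0 && rt$p <= 1)
  expect_identical(
    rt$p, resampleTest(pool, 30, 0.5, rObs, reps = 100, seed = 13)$p)

  # identically annotated pool: every replicate is a complete graph with
  # random labels; null r concentrates near 0 and an extreme observed r
  # gives a small p
  same <- setNames(rep(list(c("a", "b", "c")), 60), sprintf("P%02d", 1:60))
  rs <- resampleTest(same, nNodes = 20, labelProportion = 0.5,
                     observedR = 0.9, reps = 200, seed = 17)
  expect_lt(rs$p, 0.05)
  expect_equal(rs$used, 200)

  # single replicate: p is 0 or 1
  r1 <- resampleTest(same, 20, 0.5, observedR = 0, reps = 1, seed = 19)
  expect_true(r1$p %in% c(0, 1))
})

test_that("hypergeometric enrichment matches the tail-sum oracle", {
  # fully concentrated term: p = 1 / C(100, 10), fold = 10
  ann <- c(
    setNames(rep(list("GO:1"), 10), sprintf("T%02d", 1:10)),
    setNames(rep(list("GO:2"), 90), sprintf("R%02d", 1:90)))
  res <- goEnrichment(sprintf("T%02d", 1:10), names(ann), ann)
  row <- res[res$term == "GO:1", ]
  expect_equal(row$p / (1 / choose(100, 10)), 1, tolerance = 1e-12)
  expect_equal(row$fold, 10)
  # k = 0 gives upper-tail p = 1; equal proportions give fold = 1
  row2 <- res[res$term == "GO:2", ]
  expect_equal(row2$p, 1)
  annEq <- c(setNames(rep(list("GO:9"), 4), paste0("t", 1:4)),
             setNames(rep(list(c("GO:9")), 4), paste0("r", 1:4)))
  resEq <- goEnrichment(paste0("t", 1:4), names(annEq), annEq)
  expect_equal(resEq$fold[resEq$term == "GO:9"], 1)

  # oracle agreement on random configurations, routed through the
  # enrichment table itself
  set.seed(12)
  for (i in seq_len(100)) {
    N <- sample(20:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    prot <- sprintf("P%03d", seq_len(N))
    withTerm <- sample(prot, K)
    annR <- setNames(lapply(prot, function(a)
      if (a %in% withTerm) c("GO:X", "GO:base") else "GO:base"), prot)
    test <- sample(prot, n)
    k <- sum(test %in% withTerm)
    got <- goEnrichment(test, prot, annR)
    expect_equal(got$p[got$term == "GO:X"] / hyperTailOracle(N, K, n, k),
                 1, tolerance = 1e-12)
  }
  # Bonferroni caps at 1 and multiplies by the number of tested terms
  expect_true(all(res$pAdj <= 1))
  expect_equal(res$pAdj[res$term == "GO:1"],
               min(1, res$p[res$term == "GO:1"] * nrow(res)))
})
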