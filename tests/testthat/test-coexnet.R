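toyNetwork <- function(edgePairs, nodes, group = "recurrence") {
  a <- vapply(edgePairs, `[[`, "", 1)
  e <- data.frame(geneA = a, geneB = vapply(edgePairs, `[[`, "", 2),
                  r = rep(1, length(a)), p = rep(0, length(a)),
                  stringsAsFactors = FALSE)
  buildNetwork(e, nodes, groupLabel = group)
}

test_that("pairwise correlations hit their algebraic fixed points", {
  v <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(-1, -2, -3, -4, -5), d = c(5, 1, 4, 2, 3))
  colnames(v) <- paste0("s", 1:5)
  x <- makeExperiment(v, rep("recurrence", 5))
  corr <- correlationMatrix(x, "recurrence")
  expect_equal(corr$r["a", "b"], 1)
  expect_equal(corr$r["a", "c"], -1)
  expect_equal(corr$p["a", "b"], 0)
  # p from the t-transform with n - 2 df
  r <- corr$r["a", "d"]
  tt <- abs(r) * sqrt(3 / (1 - r^2))
  expect_equal(corr$p["a", "d"], 2 * pt(tt, 3, lower.tail = FALSE))
  expect_error(correlationMatrix(makeExperiment(v[, 1:2],
                                                rep("recurrence", 2)),
                                 "recurrence"), "at least 3 samples")
  # constant genes are flagged, not propagated as spurious correlations
  v2 <- rbind(v, e = rep(7, 5))
  corr2 <- correlationMatrix(makeExperiment(v2, rep("recurrence", 5)),
                             "recurrence")
  expect_true(corr2$constant["e"])
  expect_true(all(is.na(corr2$r["e", ])))
})

test_that("independent genes rarely exceed the 0.01 critical correlation", {
  set.seed(55)
  n <- 100
  crit <- sqrt(qt(0.995, n - 2)^2 / (qt(0.995, n - 2)^2 + n - 2))
  hits <- vapply(1:1000, function(i) {
    abs(cor(rnorm(n), rnorm(n))) > crit
  }, TRUE)
  expect_lte(mean(hits), 0.03)  # nominal 0.01; generous population margin
})

test_that("edge selection applies both gates and is null-calibrated", {
  set.seed(66)
  v <- rbind(a = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) + 0.01 * rnorm(10),
             b = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10.2),
             c = c(2, 1, 3, 5, 4, 6, 8, 7, 10, 9) * 0.1)
  colnames(v) <- paste0("s", 1:10)
  x <- makeExperiment(v, rep("recurrence", 10))
  corr <- correlationMatrix(x, "recurrence")
  edges <- significantPairs(corr)
  key <- paste(edges$geneA, edges$geneB)
  expect_true("a b" %in% key)  # r ~ 0.99 at n = 10: retained
  # weak pair at tiny n is excluded
  v2 <- rbind(a = c(1, 2, 1.5, 2.5, 1.2, 2.2),
              b = c(1, 1.1, 2, 0.5, 1.7, 1.3))
  colnames(v2) <- paste0("s", 1:6)
  corr2 <- correlationMatrix(makeExperiment(v2, rep("recurrence", 6)),
                             "recurrence")
  expect_warning(e2 <- significantPairs(corr2), "no significant")
  expect_equal(nrow(e2), 0)
  # null retention at p < 0.05 with no magnitude gate is ~5%
  set.seed(67)
  nullMat <- matrix(rnorm(4000 * 20), nrow = 4000)
  # evaluate 2000 disjoint pairs
  odd <- nullMat[seq(1, 4000, 2), ]; even <- nullMat[seq(2, 4000, 2), ]
  rs <- vapply(1:2000, function(i) cor(odd[i, ], even[i, ]), 1)
  ts <- abs(rs) * sqrt(18 / (1 - rs^2))
  frac <- mean(2 * pt(ts, 18, lower.tail = FALSE) < 0.05)
  expect_lt(abs(frac - 0.05), 2.576 * sqrt(0.05 * 0.95 / 2000))
})

test_that("networks validate, keep isolated nodes, and round-trip", {
  net <- toyNetwork(list(), letters[1:5])
  expect_equal(length(networkNodes(net)), 5)
  expect_equal(unname(connectivity(net)), rep(0L, 5))
  tri <- toyNetwork(list(c("a", "b"), c("b", "c"), c("a", "c")),
                    letters[1:3])
  expect_equal(unname(connectivity(tri)), c(2L, 2L, 2L))
  # conflicting duplicate edge is an error
  e <- data.frame(geneA = c("a", "b"), geneB = c("b", "a"),
                  r = c(0.9, 0.5), p = 0)
  expect_error(buildNetwork(e, c("a", "b")), "conflicting")
  # round trip through the edge-list writer/reader
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(tri, f)
  back <- readEdgeList(f, nodes = networkNodes(tri))
  expect_equal(networkEdges(back), networkEdges(tri))
  expect_equal(sort(networkNodes(back)), sort(networkNodes(tri)))
})

test_that("degree respects the handshake identity on random graphs", {
  set.seed(8)
  for (i in 1:20) {
    nodes <- sprintf("n%02d", 1:30)
    edges <- randomGraphEdges(nodes, 0.1)
    net <- buildNetwork(edges, nodes)
    expect_equal(sum(connectivity(net)), 2L * nrow(networkEdges(net)))
  }
  star <- toyNetwork(lapply(letters[2:7], function(l) c("a", l)),
                     letters[1:7])
  k <- connectivity(star)
  expect_equal(unname(k["a"]), 6L)
  expect_true(all(k[letters[2:7]] == 1L))
})

test_that("k-core matches hand-pruned examples and the per-k oracle", {
  # triangle plus a pendant: the pendant is pruned at k = 2
  g <- toyNetwork(list(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d")),
                  letters[1:4])
  kc <- kcoreDecompose(g)
  expect_equal(kc$core, c(a = 2L, b = 2L, c = 2L, d = 1L))
  expect_equal(sort(networkNodes(kc$maxCore)), c("a", "b", "c"))
  # complete graph on 4 nodes: all core number 3
  k4 <- toyNetwork(combn(letters[1:4], 2, c, simplify = FALSE),
                   letters[1:4])
  expect_true(all(kcoreDecompose(k4)$core == 3L))
  # seeded random graphs vs the independent per-k survival oracle
  set.seed(99)
  for (i in 1:25) {
    nodes <- sprintf("n%02d", seq_len(sample(10:50, 1)))
    edges <- randomGraphEdges(nodes, runif(1, 0.02, 0.3))
    net <- buildNetwork(edges, nodes)
    expect_equal(kcoreDecompose(net)$core,
                 oracleCoreNumbers(nodes, edges$geneA, edges$geneB))
  }
})

test_that("k-core agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(100)
  nodes <- sprintf("n%02d", 1:40)
  edges <- randomGraphEdges(nodes, 0.12)
  net <- buildNetwork(edges, nodes)
  ig <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                      vertices = nodes)
  expect_equal(kcoreDecompose(net)$core,
               igraph::coreness(ig)[networkNodes(net)])
})

test_that("DiffK satisfies its identities, bounds, and tie-breaks", {
  net1 <- toyNetwork(list(c("a", "b"), c("b", "c"), c("a", "c"),
                          c("c", "d")), letters[1:5])
  # identical networks: diffK identically 0
  d0 <- diffK(net1, net1)
  expect_true(all(d0$diffK == 0))
  # a gene maximal in net1 and absent from net2 attains diffK = 1
  net2 <- toyNetwork(list(c("d", "e")), letters[1:5],
                     group = "nonrecurrence")
  d <- diffK(net1, net2)
  expect_equal(d$diffK[d$gene_id == "c"], 1)  # k1 = 3 (max), k2 = 0
  expect_true(all(d$diffK >= -1 & d$diffK <= 1))
  # antisymmetry
  drev <- diffK(net2, net1)
  expect_equal(drev$diffK[match(d$gene_id, drev$gene_id)], -d$diffK)
  # ranked by descending signed diffK, ties by descending k1 then id
  expect_equal(d$gene_id[1], "c")
  expect_true(!is.unsorted(rev(d$diffK)) || all(diff(d$diffK) <= 1e-15))
  # empty network cannot be normalized
  empty <- toyNetwork(list(), letters[1:5], group = "nonrecurrence")
  expect_error(diffK(net1, empty), "maximum degree 0")
  expect_silent(diffK(net1, empty, allowEmpty = TRUE))
})

test_that("diffK stays bounded on random network pairs", {
  set.seed(12)
  for (i in 1:10) {
    nodes <- sprintf("n%02d", 1:25)
    n1 <- buildNetwork(randomGraphEdges(nodes, 0.15), nodes, "recurrence")
    n2 <- buildNetwork(randomGraphEdges(nodes, 0.15), nodes,
                       "nonrecurrence")
    if (max(connectivity(n1)) == 0 || max(connectivity(n2)) == 0) next
    d <- diffK(n1, n2)
    expect_true(all(d$diffK >= -1 & d$diffK <= 1))
    expect_equal(max(d$K1), 1)
    expect_equal(max(d$K2), 1)
  }
})

test_that("planted differential hubs dominate the DiffK ranking", {
  cfg <- simulationConfig(nGenes = 400, nDEUp = 0, nDEDown = 0,
                          deEffect = 0, nRecurrence = 40,
                          nNonRecurrence = 40,
                          moduleSpecs = list(
                            list(size = 20, nHubs = 4, corGroup1 = 0.9,
                                 corGroup2 = 0.0),
                            list(size = 20, nHubs = 2, corGroup1 = 0.8,
                                 corGroup2 = 0.8)),
                          seed = 23L)
  x <- simulateExpression(cfg)
  genes <- rownames(x)
  mkNet <- function(grp) {
    corr <- correlationMatrix(x, grp)
    buildNetwork(significantPairs(corr), genes, groupLabel = grp)
  }
  d <- diffK(mkNet("recurrence"), mkNet("nonrecurrence"))
  hubs <- plantedTruth(x)$modules[[1]]$hubs
  top5 <- head(d$gene_id, ceiling(0.05 * length(genes)))
  expect_gte(mean(hubs %in% top5), 0.9)
})

test_that("permutation p-values are valid and detect planted structure", {
  cfg <- simulationConfig(nGenes = 60, nDEUp = 0, nDEDown = 0,
                          deEffect = 0, nRecurrence = 25,
                          nNonRecurrence = 25,
                          moduleSpecs = list(
                            list(size = 10, nHubs = 2, corGroup1 = 0.9,
                                 corGroup2 = 0.0),
                            list(size = 10, nHubs = 2, corGroup1 = 0.8,
                                 corGroup2 = 0.8)),
                          seed = 29L)
  x <- simulateExpression(cfg)
  expect_warning(permutationDiffK(x, nPerm = 10L, seed = 1), "granularity")
  res <- permutationDiffK(x, nPerm = 100L, seed = 2)
  expect_true(all(res$permP > 0))  # add-one rule: never exactly 0
  expect_true(all(res$permP <= 1))
  hubs <- plantedTruth(x)$modules[[1]]$hubs
  expect_lte(max(res$permP[res$gene_id %in% hubs]), 0.02)
})
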