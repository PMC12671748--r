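test_that("phase randomization preserves amplitude spectrum, mean and norm", {
  set.seed(10)
  for (n in c(64, 101, 250)) {
    x <- abs(as.numeric(stats::filter(rbinom(n, 1, 0.1), 0.9,
                                      method = "recursive"))) + 0.1
    sur <- phaseRandomize(x, seed = n)
    expect_lt(max(abs(Mod(fft(sur)) - Mod(fft(x)))), 1e-10)
    expect_lt(abs(mean(sur) - mean(x)), 1e-10)
    expect_lt(abs(sum(sur^2) - sum(x^2)), 1e-8)
  }
  # constant signal: all power in DC, surrogate unchanged
  expect_equal(phaseRandomize(rep(3, 50), seed = 1), rep(3, 50),
               tolerance = 1e-12)
  expect_error(phaseRandomize(c(1, NA, 2, 3, 4)), "finite")
  expect_error(phaseRandomize(c(1, 2, 3)), "at least 4")
})

test_that("identical traces are linked; the decision is seed-stable", {
  set.seed(20)
  x <- abs(as.numeric(stats::filter(rbinom(2000, 1, 0.08), 0.9,
                                    method = "recursive"))) + 0.05
  ps <- pairSignificance(x, x, nSurrogates = 2000, seed = 5)
  expect_equal(ps$similarity, 1, tolerance = 1e-12)
  expect_lt(ps$threshold, 1)
  expect_true(ps$is_link)
  ps2 <- pairSignificance(x, x, nSurrogates = 2000, seed = 5)
  expect_identical(ps2$threshold, ps$threshold)
})

test_that("duplicated traces yield the complete graph with unit centrality", {
  set.seed(21)
  base <- abs(as.numeric(stats::filter(rbinom(500, 1, 0.1), 0.9,
                                       method = "recursive"))) + 0.05
  tm <- rawTraces(matrix(rep(base, 4), nrow = 4, byrow = TRUE))
  net <- buildNetwork(tm, nSurrogates = 400, seed = 3)
  expect_true(all(adjacencyMatrix(net)[upper.tri(adjacencyMatrix(net))] == 1))
  expect_equal(unname(degreeCentrality(net)), rep(1, 4), tolerance = 1e-12)
})

test_that("degree centrality matches hand counts on path, complete and empty graphs", {
  path <- functionalNetworkFromAdjacency(
    rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)), ids = c("a", "b", "c"))
  expect_identical(unname(degreeCentrality(path)), c(0.5, 1, 0.5))

  complete5 <- functionalNetworkFromAdjacency(
    1 - diag(5), ids = sprintf("n%d", 1:5))
  expect_identical(unname(degreeCentrality(complete5)), rep(1, 5))

  empty <- functionalNetworkFromAdjacency(matrix(0, 4, 4),
                                          ids = sprintf("n%d", 1:4))
  expect_identical(unname(degreeCentrality(empty)), rep(0, 4))
  expect_true(sum(adjacencyMatrix(path)) %% 2 == 0)
})

test_that("edge decisions are invariant under common positive rescaling", {
  s <- simulateSession(simConfig(nNeurons = 8, nFrames = 500, seed = 30))
  n1 <- buildNetwork(s$traces, nSurrogates = 400, seed = 7)
  scaled <- TraceMatrix(activity(s$traces) * 12.3, frameRate = 10,
                        neuronIds = neuronIds(s$traces))
  n2 <- buildNetwork(scaled, nSurrogates = 400, seed = 7)
  expect_identical(adjacencyMatrix(n1), adjacencyMatrix(n2))
  expect_equal(similarityMatrix(n1), similarityMatrix(n2), tolerance = 1e-12)
})

test_that("pooled and full surrogate modes agree on a small session", {
  s <- simulateSession(simConfig(nNeurons = 5, nFrames = 300,
                                 ensembleDriveRateHz = 1, seed = 31))
  pooled <- buildNetwork(s$traces, nSurrogates = 900, mode = "pooled", seed = 2)
  full <- buildNetwork(s$traces, nSurrogates = 900, mode = "full", seed = 2)
  # same raw similarities; thresholds estimate the same null quantile
  expect_equal(similarityMatrix(pooled), similarityMatrix(full),
               tolerance = 1e-12)
  up <- upper.tri(pooled@thresholds)
  expect_lt(max(abs(pooled@thresholds[up] - full@thresholds[up])), 0.15)
})

test_that("subgroup centrality partitions neurons and tolerates empty groups", {
  adj <- 1 - diag(4)
  net <- functionalNetworkFromAdjacency(adj, ids = sprintf("n%d", 1:4))
  calls <- S4Vectors::DataFrame(neuron_id = sprintf("n%d", 1:4),
                                label = c("positive", "negative",
                                          "irrelevant", "irrelevant"))
  sc <- subgroupCentrality(net, calls)
  expect_identical(sc$n, c(4L, 2L, 2L))
  expect_identical(sc$n[1], sc$n[2] + sc$n[3])

  allIrr <- S4Vectors::DataFrame(neuron_id = sprintf("n%d", 1:4),
                                 label = rep("irrelevant", 4))
  sc2 <- subgroupCentrality(net, allIrr)
  expect_identical(sc2$n[sc2$group == "linked"], 0L)
  expect_true(is.na(sc2$mean[sc2$group == "linked"]))
})

test_that("ensemble-drive-sharing neurons out-rank drive-free neurons in centrality", {
  # half the population shares a strong drive, half is independent noise
  cfg <- simConfig(nNeurons = 16, nFrames = 1000, nEnsembles = 2,
                   ensembleDriveRateHz = 1, participationP = 0.95,
                   classMix = c(positive = 0, negative = 0, irrelevant = 1),
                   seed = 33)
  s <- simulateSession(cfg)
  a <- activity(s$traces)
  lone <- simulateSession(simConfig(nNeurons = 8, nFrames = 1000,
                                    ensembleDriveRateHz = 0,
                                    classMix = c(positive = 0, negative = 0,
                                                 irrelevant = 1),
                                    seed = 34))
  keep <- s$truth$ensemble == 1
  m <- rbind(a[keep, ], activity(lone$traces))
  rownames(m) <- NULL
  mixed <- rawTraces(m)
  net <- buildNetwork(mixed, nSurrogates = 2500, seed = 4)
  dc <- degreeCentrality(net)
  driven <- seq_len(sum(keep))
  expect_gt(mean(dc[driven]), mean(dc[-driven]))
})

test_that("GraphML export writes a parseable graph with matching degrees", {
  adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  net <- functionalNetworkFromAdjacency(adj, ids = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
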