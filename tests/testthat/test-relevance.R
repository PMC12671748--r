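test_that("cosine similarity matches hand values and rejects zero norms", {
  expect_equal(cosineSimilarity(c(1, 2), c(1, 2)), 1, tolerance = 1e-12)
  expect_identical(cosineSimilarity(c(1, 0, 1, 0), c(0, 1, 0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.5,
               tolerance = 1e-12)
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosineSimilarity(1:3, 1:4), "equal length")
})

test_that("circular-shift null matches brute-force enumeration of all shifts", {
  b <- toyBehavior(100)
  bvals <- as.numeric(behaviorValues(b))
  set.seed(2)
  trace <- abs(as.numeric(stats::filter(rbinom(100, 1, 0.1), 0.9,
                                        method = "recursive"))) + 0.01
  oracle <- bruteForceShiftCosines(trace, bvals)
  nl <- shuffledNull(trace, b, nPerm = 500, seed = 9)
  # every sampled null value must be one of the enumerated shift cosines
  expect_true(all(vapply(nl$null, function(v) any(abs(v - oracle) < 1e-9),
                         logical(1))))
  # a trace equal to the behavior vector beats every shifted copy
  nlB <- shuffledNull(bvals, b, nPerm = 500, seed = 9)
  expect_lt(max(bruteForceShiftCosines(bvals, bvals)), 1)
  expect_gt(cosineSimilarity(bvals, bvals), nlB$p95)
})

test_that("degenerate inputs raise degenerate-null errors", {
  b <- toyBehavior(100)
  expect_error(shuffledNull(rep(2, 100), b, nPerm = 100), "non-constant")
  expect_error(shuffledNull(runif(100), BehaviorVector(rep(0L, 100)),
                            nPerm = 100), "non-constant")
  expect_error(shuffledNull(runif(100), b, nPerm = 10), "at least 100")
})

test_that("shuffled null is reproducible under a fixed seed", {
  b <- toyBehavior(200)
  set.seed(4)
  tr <- abs(rnorm(200)) + 0.05
  n1 <- shuffledNull(tr, b, nPerm = 300, seed = 77)
  n2 <- shuffledNull(tr, b, nPerm = 300, seed = 77)
  expect_identical(n1$p95, n2$p95)
  expect_identical(n1$null, n2$null)
})

test_that("classification labels follow the strict percentile rule", {
  expect_identical(relevanceLabel(0.8, 0.2, 0.7), "positive")
  expect_identical(relevanceLabel(0.1, 0.2, 0.7), "negative")
  expect_identical(relevanceLabel(0.5, 0.2, 0.7), "irrelevant")
  # exactly at a percentile -> irrelevant (strict inequalities)
  expect_identical(relevanceLabel(0.7, 0.2, 0.7), "irrelevant")
  expect_identical(relevanceLabel(0.2, 0.2, 0.7), "irrelevant")
  expect_identical(relevanceLabel(NA_real_, 0.2, 0.7), "irrelevant")
})

test_that("classifyNeurons labels anchors: b-locked positive, (1-b)-locked negative", {
  cfg <- simConfig(seed = 44)
  bl <- simulateBouts(cfg)
  b <- makeBehaviorVector(bl, 10, 6000)
  bvals <- as.numeric(behaviorValues(b))
  tm <- rawTraces(rbind(pos = bvals, neg = 1 - bvals,
                        flat = rep(1, 6000)))
  calls <- classifyNeurons(tm, b, nPerm = 1000, seed = 3)
  expect_identical(calls$label, c("positive", "negative", "irrelevant"))
  expect_true(is.na(calls$R[3]))
  # the (1 - b) anchor agrees with brute-force enumeration over all shifts
  oracle <- bruteForceShiftCosines(1 - bvals, bvals)
  expect_lt(cosineSimilarity(1 - bvals, bvals),
            quantile(oracle, 0.05, names = FALSE))
})

test_that("classification is invariant under positive rescaling of traces", {
  s <- simulateSession(simConfig(nNeurons = 10, nFrames = 1500, seed = 6))
  c1 <- classifyNeurons(s$traces, s$behavior, nPerm = 300, seed = 5)
  scaled <- TraceMatrix(activity(s$traces) * 37.5, frameRate = 10,
                        neuronIds = neuronIds(s$traces))
  c2 <- classifyNeurons(scaled, s$behavior, nPerm = 300, seed = 5)
  expect_identical(c1$label, c2$label)
  expect_equal(c1$R, c2$R, tolerance = 1e-12)
})

test_that("z-scored traces are refused by the classifier", {
  s <- simulateSession(simConfig(nNeurons = 4, nFrames = 300, seed = 2))
  expect_error(classifyNeurons(zscoreTraces(s$traces), s$behavior),
               "raw non-negative")
})

test_that("relevance ratios normalise against total registered neurons", {
  calls <- S4Vectors::DataFrame(
    neuron_id = sprintf("n%02d", 1:10),
    label = c(rep("positive", 2), "negative", rep("irrelevant", 7)))
  rr <- relevanceRatios(calls, 10)
  expect_identical(rr$percent, c(20, 10, 70))
  expect_identical(sum(rr$ratio), 1)
  rr2 <- relevanceRatios(calls, 20)  # registration denominator larger
  expect_identical(rr2$percent, c(10, 5, 35))
  expect_identical(relevanceRatios(calls[calls$label == "irrelevant", ],
                                   300)$percent[1], 0)
  expect_identical(relevanceRatios(S4Vectors::DataFrame(
    neuron_id = sprintf("n%02d", 1:28),
    label = rep("positive", 28)), 300)$percent[1], 9.3)
  expect_error(relevanceRatios(calls, 0), "positive")
  expect_error(relevanceRatios(calls, 5), "cannot be smaller")
})

test_that("mean in-bout activity summarises z-scored traces correctly", {
  b <- toyBehavior(100)
  on <- behaviorValues(b) == 1L
  set.seed(9)
  m <- matrix(abs(rnorm(300)) + 0.1, nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  z <- zscoreTraces(rawTraces(m))
  mb <- meanBoutActivity(z, b, c("a", "b"))
  expect_equal(unname(mb$perNeuron["a"]), mean(activity(z)["a", on]),
               tolerance = 1e-12)
  expect_identical(length(mb$perNeuron), 2L)
  # all-ones behavior: per-neuron mean of a z-scored trace is 0
  all1 <- BehaviorVector(rep(1L, 100))
  mb1 <- meanBoutActivity(z, all1)
  expect_equal(unname(mb1$perNeuron), rep(0, 3), tolerance = 1e-10)
  expect_error(meanBoutActivity(z, BehaviorVector(rep(0L, 100))), "no in-bout")
  expect_error(meanBoutActivity(z, b, character(0)), "empty")
})

test_that("noise-free positive neurons out-activate irrelevant ones during bouts", {
  s <- simulateSession(simConfig(nNeurons = 30, nFrames = 3000, noiseSd = 0,
                                 ensembleDriveRateHz = 0, seed = 15))
  z <- zscoreTraces(s$traces)
  pos <- s$truth$neuron_id[s$truth$class == "positive"]
  irr <- s$truth$neuron_id[s$truth$class == "irrelevant"]
  expect_gt(meanBoutActivity(z, s$behavior, pos)$mean,
            meanBoutActivity(z, s$behavior, irr)$mean)
})

test_that("session overlap table counts shared responsive neurons", {
  mk <- function(ids, labels) S4Vectors::DataFrame(neuron_id = ids,
                                                   label = labels)
  calls <- list(
    s1 = mk(c("a", "b", "c", "e"), c("positive", "positive", "negative",
                                     "irrelevant")),
    s2 = mk(c("b", "c", "d", "e"), c("negative", "positive", "positive",
                                     "irrelevant")))
  ot <- sessionOverlapTable(calls)
  expect_identical(unname(ot$shared["s1", "s2"]), 2L)
  expect_identical(unname(ot$shared["s1", "s1"]), 3L)
  expect_identical(nrow(ot$long), 8L)

  # disjoint id spaces with no map overlap: all shared counts 0
  calls2 <- list(
    s1 = mk(c("a", "b"), c("positive", "positive")),
    s2 = mk(c("x", "y"), c("positive", "positive")))
  maps <- list(s2 = IdentityMap(character(0), character(0)))
  ot2 <- sessionOverlapTable(calls2, maps)
  expect_identical(unname(ot2$shared["s1", "s2"]), 0L)

  # map targeting unknown ids is a data error
  badmap <- list(s2 = IdentityMap("a", "zzz"))
  expect_error(sessionOverlapTable(calls2, badmap), "absent")
})

test_that("paired sessions with full overlap share their responsive set", {
  p <- simulatePairedSessions(simConfig(nNeurons = 20, nFrames = 2000,
                                        crossSessionOverlapP = 1, seed = 23))
  cA <- classifyNeurons(p$sessionA$traces, p$sessionA$behavior,
                        nPerm = 300, seed = 1)
  respA <- cA$neuron_id[cA$label != "irrelevant"]
  dual <- dualRecordedIds(p$map, respA, sub("^a", "b", respA))
  expect_identical(as.vector(dual$a), respA)
})
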