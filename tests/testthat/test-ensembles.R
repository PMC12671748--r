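zscoredSession <- function(seed, ...) {
  s <- simulateSession(simConfig(seed = seed, ...))
  list(z = zscoreTraces(s$traces), s = s)
}

test_that("WCSS hits zero for identical rows and for singleton clusters", {
  m <- matrix(rep(c(1, 2, 3, 4, 5), each = 4), nrow = 4)
  z <- zscoreTraces(rawTraces(m))
  expect_identical(unname(wcssCurve(z, 1)), 0)

  set.seed(3)
  z2 <- zscoreTraces(rawTraces(matrix(abs(rnorm(50)), nrow = 5)))
  curve <- wcssCurve(z2, 1:5)
  expect_identical(unname(curve["5"]), 0)
  expect_true(all(diff(curve) <= 1e-8))  # non-increasing in k
  expect_error(wcssCurve(z2, 1:9), "nNeurons")
})

test_that("elbow selection maximises the second difference with documented edge cases", {
  expect_identical(selectK(c(`1` = 100, `2` = 10, `3` = 9, `4` = 8)), 2L)
  expect_warning(k <- selectK(c(`1` = 100, `2` = 99, `3` = 98, `4` = 97)),
                 "no elbow")
  expect_identical(k, 1L)
  # tie between k = 2 and k = 3 resolves to the smaller k
  expect_identical(selectK(c(`1` = 10, `2` = 6, `3` = 4, `4` = 3, `5` = 2.5)),
                   2L)
  expect_error(selectK(c(`1` = 3, `2` = 1)), "at least 3")
})

test_that("clustering recovers duplicated-row groups exactly (ARI = 1)", {
  m <- rbind(matrix(rep(c(5, 1, 4, 2, 6, 1), 3), nrow = 3, byrow = TRUE),
             matrix(rep(c(1, 6, 1, 5, 2, 7), 3), nrow = 3, byrow = TRUE))
  z <- zscoreTraces(rawTraces(m))
  model <- clusterNeurons(z, 2, seed = 1)
  truth <- rep(1:2, each = 3)
  expect_identical(mclust::adjustedRandIndex(ensembleLabels(model), truth), 1)

  one <- clusterNeurons(z, 1, seed = 1)
  expect_true(all(ensembleLabels(one) == 1L))
  expect_equal(ensembleMeans(one)[1, ], colMeans(activity(z)),
               tolerance = 1e-12)
})

test_that("ensemble recovery on the default two-ensemble generator is near-perfect", {
  aris <- vapply(1:5, function(sd) {
    zs <- zscoredSession(sd)
    model <- clusterNeurons(zs$z, 2, seed = 1)
    mclust::adjustedRandIndex(ensembleLabels(model), zs$s$truth$ensemble)
  }, numeric(1))
  expect_gte(min(aris), 0.9)
})

test_that("cluster labels are invariant (up to permutation) under row shuffling", {
  zs <- zscoredSession(17, nNeurons = 30, nFrames = 1500)
  model <- clusterNeurons(zs$z, 2, seed = 5)
  perm <- withr::with_seed(1, sample(nNeurons(zs$z)))
  a <- activity(zs$z)[perm, ]
  zp <- TraceMatrix(a, frameRate = 10, normalization = "zscore",
                    neuronIds = rownames(a))
  modelP <- clusterNeurons(zp, 2, seed = 5)
  ids <- neuronIds(zs$z)
  expect_identical(
    mclust::adjustedRandIndex(ensembleLabels(model)[ids],
                              ensembleLabels(modelP)[ids]), 1)
})

test_that("ensemble-behavior correlation hits the +-1 anchors and errors on flat input", {
  b <- toyBehavior(100)
  bv <- as.numeric(behaviorValues(b))
  model <- new("EnsembleModel", k = 2L, wcss = c(`2` = 0),
               labels = c(a = 1L, b = 2L),
               ensembleMeans = rbind(bv, 1 - bv), seed = 1L)
  r <- ensembleBehaviorCorrelation(model, b)
  expect_equal(unname(r), c(1, -1), tolerance = 1e-12)
  flat <- BehaviorVector(rep(1L, 100))
  expect_error(ensembleBehaviorCorrelation(model, flat), "constant")
})

test_that("null ensemble-behavior correlation stays near zero at session length", {
  b <- makeBehaviorVector(simulateBouts(simConfig(seed = 8)), 10, 6000)
  rs <- vapply(1:30, function(sd) {
    m <- withr::with_seed(sd, matrix(rnorm(6000), nrow = 1))
    model <- new("EnsembleModel", k = 1L, wcss = c(`1` = 0),
                 labels = c(a = 1L), ensembleMeans = m, seed = 1L)
    unname(ensembleBehaviorCorrelation(model, b))
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.05), 0.9)
})

test_that("neuron-ensemble correlation is 1 for coherent ensembles and flags singletons", {
  m <- rbind(matrix(rep(c(3, 1, 4, 1, 5, 9), 3), nrow = 3, byrow = TRUE),
             c(2, 7, 1, 8, 2, 8))
  z <- zscoreTraces(rawTraces(m))
  model <- clusterNeurons(z, 2, seed = 1)
  cs <- neuronEnsembleCorrelation(z, model)
  expect_equal(cs$r, rep(1, 4), tolerance = 1e-9)
  expect_identical(sum(cs$singleton), 1L)
  # excluding the neuron from a singleton ensemble leaves r undefined
  csx <- neuronEnsembleCorrelation(z, model, excludeSelf = TRUE)
  expect_true(is.na(csx$r[csx$singleton]))
})

test_that("higher ensemble participation right-shifts neuron-ensemble correlations", {
  rMean <- function(p, sd) {
    s <- simulateSession(simConfig(nNeurons = 20, nFrames = 2000,
                                   participationP = p, seed = sd))
    z <- zscoreTraces(s$traces)
    model <- clusterNeurons(z, 2, seed = 1)
    mean(neuronEnsembleCorrelation(z, model)$r, na.rm = TRUE)
  }
  lo <- vapply(1:5, rMean, numeric(1), p = 0.4)
  hi <- vapply(1:5, rMean, numeric(1), p = 0.95)
  expect_true(all(hi > lo))
})

test_that("KS comparison of correlation CDFs behaves at its anchors", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- compareCorrelationCdfs(x, x)
  expect_equal(same$D, 0, tolerance = 1e-12)
  disjoint <- compareCorrelationCdfs(x, x + 10)
  expect_equal(disjoint$D, 1, tolerance = 1e-12)
  expect_warning(compareCorrelationCdfs(c(1, 2), x), "little power")
})

test_that("KS null rejection rate is calibrated near 5%", {
  ps <- vapply(1:200, function(sd) {
    withr::with_seed(sd, {
      compareCorrelationCdfs(rnorm(200), rnorm(200))$p
    })
  }, numeric(1))
  rate <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("cross-session correlation scatter hits +-1 anchors and needs 3 pairs", {
  r1 <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(crossSessionRScatter(r1, r1)$r, 1, tolerance = 1e-12)
  expect_equal(crossSessionRScatter(r1, -r1)$r, -1, tolerance = 1e-12)
  expect_error(crossSessionRScatter(c(1, 2), c(1, 2)), "at least 3")
})

test_that("independent sessions rarely exceed the n=50 null correlation band", {
  rs <- vapply(1:200, function(sd) {
    withr::with_seed(sd, abs(crossSessionRScatter(rnorm(50), rnorm(50))$r))
  }, numeric(1))
  expect_gte(mean(rs < 0.28), 0.92)
})
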