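# Ensemble detection: k-means on z-scored traces with WCSS-based model
# selection, plus the ensemble-level correlation analyses.

requireZscore <- function(x, what) {
  stopifnot(is(x, "TraceMatrix"))
  if (normalizationState(x) != "zscore")
    stop(what, " expects z-scored traces; run zscoreTraces() first")
}

# Best-of-restarts k-means that tolerates duplicated rows (k-means errors
# when sampled initial centers coincide). Returns NULL only if every
# restart failed.
safeKmeans <- function(a, k, nRestarts) {
  if (k >= nrow(a)) {
    return(list(cluster = seq_len(nrow(a)), tot.withinss = 0,
                centers = a))
  }
  best <- NULL
  fails <- 0L
  for (r in seq_len(nRestarts)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(a, centers = k, iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(km)) { fails <- fails + 1L; next }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) {
    # all restarts collided on duplicated rows: seed centers from the
    # distinct rows instead
    u <- unique(a)
    if (nrow(u) <= k) {
      grp <- match(apply(a, 1L, paste, collapse = "\r"),
                   apply(u, 1L, paste, collapse = "\r"))
      return(list(cluster = grp, tot.withinss = 0, centers = u))
    }
    best <- suppressWarnings(stats::kmeans(a, centers = u[seq_len(k), , drop = FALSE],
                                           iter.max = 100L))
  }
  best
}

#' Within-cluster sum of squares over a range of cluster counts
#'
#' For each candidate `k`, runs best-of-`nRestarts` k-means on the
#' z-scored neuron traces (rows) with Euclidean distance and records the
#' within-cluster sum of squares (WCSS), the curve used to gauge the
#' number of neuronal ensembles. For z-scored rows, Euclidean distance is
#' monotone in one minus the Pearson correlation, so this clusters by
#' activity-pattern correlation.
#'
#' @param x a z-scored `TraceMatrix`.
#' @param kRange integer vector of candidate cluster counts.
#' @param seed integer seed for the k-means restarts.
#' @param nRestarts restarts per `k` (best WCSS kept).
#' @return Named numeric vector, `names = k`, non-increasing in `k`.
#' @export
wcssCurve <- function(x, kRange = 1:6, seed = 1L, nRestarts = 20L) {
  requireZscore(x, "wcssCurve()")
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 1L || max(kRange) > nNeurons(x))
    stop("kRange must lie within [1, nNeurons]")
  a <- activity(x)
  out <- withr::with_seed(seed, {
    vapply(kRange, function(k) safeKmeans(a, k, nRestarts)$tot.withinss,
           numeric(1))
  })
  names(out) <- kRange
  out
}

#' Select the number of ensembles from a WCSS curve
#'
#' Picks the interior `k` maximising the discrete second difference
#' `WCSS(k-1) - 2 WCSS(k) + WCSS(k+1)` (the elbow); ties resolve to the
#' smallest `k`. A curve with no convex elbow (all second differences
#' non-positive, e.g. linear decay) returns 1 with a warning.
#'
#' @param curve named numeric vector as returned by [wcssCurve()], over at
#'   least three consecutive `k` values.
#' @return A single integer `k`.
#' @examples
#' selectK(c(`1` = 100, `2` = 10, `3` = 9, `4` = 8))  # 2
#' @export
selectK <- function(curve) {
  if (length(curve) < 3L) stop("need a WCSS curve over at least 3 k values")
  ks <- as.integer(names(curve))
  if (is.unsorted(ks, strictly = TRUE) || any(diff(ks) != 1L))
    stop("WCSS curve must be indexed by consecutive increasing k")
  v <- unname(curve)
  d2 <- v[-c(length(v), length(v) - 1L)] - 2 * v[-c(1L, length(v))] +
    v[-c(1L, 2L)]
  tol <- 1e-10 * max(1, abs(v[1L]))
  if (max(d2) <= tol) {
    warning("WCSS curve has no elbow (monotone/flat); returning k = 1")
    return(1L)
  }
  ks[-c(1L, length(ks))][which.max(d2)]
}

#' Cluster neurons into ensembles
#'
#' k-means on z-scored traces (Euclidean, best of `nRestarts` restarts by
#' WCSS). The returned model carries per-neuron ensemble labels and the
#' per-ensemble mean z-scored trace.
#'
#' @param x a z-scored `TraceMatrix`.
#' @param k number of ensembles.
#' @param seed integer seed.
#' @param nRestarts restarts (best WCSS kept).
#' @return An `EnsembleModel`.
#' @export
clusterNeurons <- function(x, k, seed = 1L, nRestarts = 20L) {
  requireZscore(x, "clusterNeurons()")
  k <- as.integer(k)
  if (k < 1L || k > nNeurons(x)) stop("k must lie within [1, nNeurons]")
  a <- activity(x)
  km <- withr::with_seed(seed, safeKmeans(a, k, nRestarts))
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(a)
  means <- matrix(NA_real_, nrow = k, ncol = ncol(a))
  for (e in seq_len(k)) {
    members <- which(labels == e)
    means[e, ] <- colMeans(a[members, , drop = FALSE])
  }
  rownames(means) <- sprintf("ensemble%d", seq_len(k))
  new("EnsembleModel", k = k,
      wcss = stats::setNames(km$tot.withinss, as.character(k)),
      labels = labels, ensembleMeans = means, seed = as.integer(seed))
}

#' Correlation between ensemble activity and behavior
#'
#' Pearson correlation of each ensemble's mean z-scored trace with the
#' binary behavior vector (social versus non-social, or
#' object-approaching versus non-approaching, period).
#'
#' @param model an `EnsembleModel`.
#' @param behavior a `BehaviorVector` of matching length.
#' @return Named numeric vector of per-ensemble Pearson r.
#' @export
ensembleBehaviorCorrelation <- function(model, behavior) {
  stopifnot(is(model, "EnsembleModel"), is(behavior, "BehaviorVector"))
  b <- behaviorValues(behavior)
  if (ncol(ensembleMeans(model)) != length(b))
    stop("behavior vector length does not match the ensemble means")
  if (isConstant(b))
    stop("behavior vector is constant; the correlation is undefined")
  apply(ensembleMeans(model), 1L, function(m) stats::cor(m, b))
}

#' Correlation of each neuron with its own ensemble mean
#'
#' Pearson r between a neuron's z-scored trace and the mean trace of the
#' ensemble it belongs to. By default the neuron is included in the mean
#' (the procedure the ensemble analyses quantify); `excludeSelf = TRUE`
#' removes it first. Singleton ensembles are flagged: with the neuron
#' included their r is identically 1.
#'
#' @param x the z-scored `TraceMatrix` the model was fitted on.
#' @param model an `EnsembleModel`.
#' @param excludeSelf drop the neuron from its ensemble mean first.
#' @return A `DataFrame` with `neuron_id`, `ensemble`, `r`, and flags
#'   `singleton`, `constant` (`r` is `NA` for constant neurons, and for
#'   singletons under `excludeSelf`).
#' @export
neuronEnsembleCorrelation <- function(x, model, excludeSelf = FALSE) {
  requireZscore(x, "neuronEnsembleCorrelation()")
  stopifnot(is(model, "EnsembleModel"))
  labels <- ensembleLabels(model)
  a <- activity(x)
  if (!all(rownames(a) %in% names(labels)))
    stop("ensemble labels do not cover all neurons")
  const <- SummarizedExperiment::rowData(x)$constant
  sizes <- table(factor(labels, levels = seq_len(model@k)))
  r <- rep(NA_real_, nrow(a))
  singleton <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    e <- labels[[rownames(a)[i]]]
    size <- as.integer(sizes[[e]])
    singleton[i] <- size == 1L
    if (const[i]) next
    m <- ensembleMeans(model)[e, ]
    if (excludeSelf) {
      if (size == 1L) next
      m <- (m * size - a[i, ]) / (size - 1L)
      if (isConstant(m)) next
    }
    r[i] <- stats::cor(a[i, ], m)
  }
  S4Vectors::DataFrame(neuron_id = rownames(a),
                       ensemble = unname(labels[rownames(a)]),
                       r = r, singleton = singleton, constant = const)
}

#' Compare two samples of correlation coefficients
#'
#' Two-sample Kolmogorov-Smirnov test on cumulative distributions of
#' neuron-ensemble correlation coefficients (asymptotic p).
#'
#' @param sampleA,sampleB numeric vectors (NA dropped).
#' @return A list with `D` and `p`.
#' @export
compareCorrelationCdfs <- function(sampleA, sampleB) {
  sampleA <- sampleA[!is.na(sampleA)]
  sampleB <- sampleB[!is.na(sampleB)]
  if (!length(sampleA) || !length(sampleB))
    stop("both samples must be non-empty")
  if (min(length(sampleA), length(sampleB)) < 3L)
    warning("fewer than 3 values in a sample; the KS test has little power")
  kt <- suppressWarnings(stats::ks.test(sampleA, sampleB, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Cross-session stability of neuron-ensemble correlations
#'
#' Pearson correlation, across dual-recorded neurons, of their
#' neuron-ensemble correlation coefficients in session 1 versus session 2
#' of the same test type.
#'
#' @param rSession1,rSession2 parallel numeric vectors, one value per
#'   dual-recorded neuron.
#' @return A list with `r`, `p` (two-sided) and `n`.
#' @export
crossSessionRScatter <- function(rSession1, rSession2) {
  ok <- !(is.na(rSession1) | is.na(rSession2))
  rSession1 <- rSession1[ok]
  rSession2 <- rSession2[ok]
  if (length(rSession1) != length(rSession2))
    stop("the two sessions' r vectors must be parallel")
  if (length(rSession1) < 3L)
    stop("need at least 3 dual-recorded neurons")
  ct <- stats::cor.test(rSession1, rSession2)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(rSession1))
}
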