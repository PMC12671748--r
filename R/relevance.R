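# Single-neuron behavior-relevance classification: cosine similarity of
# the raw non-negative trace with the binary behavior vector, compared
# against a circular-shift permutation null.

#' Cosine similarity
#'
#' `(a . b) / (||a|| ||b||)`; guaranteed to lie in `[0, 1]` for
#' non-negative inputs, which is why relevance classification uses raw
#' (not z-scored) traces.
#'
#' @param a,b numeric vectors of equal length and positive norm.
#' @return A single number.
#' @examples
#' cosineSimilarity(c(1, 0, 1, 0), c(1, 1, 0, 0))  # 0.5
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

#' Circular-shift null distribution of the cosine statistic
#'
#' Draws `nPerm` uniform random circular-shift offsets in
#' `[1, nFrames - 1]`, computes the cosine similarity of each shifted
#' trace with the behavior vector, and returns the empirical 95th and 5th
#' percentiles (linear interpolation). Circular shifting preserves the
#' trace's autocorrelation (the calcium-kernel structure), making it a
#' conservative surrogate for "randomly shuffled data"; a plain
#' frame-permutation mode is available for comparison.
#'
#' The shifted dot products are evaluated for all offsets at once via the
#' FFT cross-correlation identity, so the cost is `O(n log n)` per trace
#' rather than `O(n nPerm)`.
#'
#' @param trace non-negative, non-constant numeric vector.
#' @param behavior a `BehaviorVector` (non-constant).
#' @param nPerm number of permutations (default 1,000; at least 100).
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @param mode `"circular"` (default) or `"permutation"`.
#' @return A list with `null` (the `nPerm` similarities), `p95`, `p05`.
#' @export
shuffledNull <- function(trace, behavior, nPerm = 1000L, seed = NULL,
                         mode = c("circular", "permutation")) {
  mode <- match.arg(mode)
  stopifnot(is(behavior, "BehaviorVector"))
  b <- as.numeric(behaviorValues(behavior))
  if (length(trace) != length(b))
    stop("trace and behavior vector lengths differ")
  if (nPerm < 100L) stop("need at least 100 permutations")
  if (isConstant(trace) || isConstant(b))
    stop("degenerate null: trace and behavior vector must be non-constant")
  compute <- function() {
    n <- length(trace)
    denom <- sqrt(sum(trace^2)) * sqrt(sum(b^2))
    if (mode == "circular") {
      dots <- circularLagDots(trace, b)
      offsets <- sample(n - 1L, nPerm, replace = TRUE)
      null <- dots[offsets + 1L] / denom
    } else {
      null <- vapply(seq_len(nPerm), function(i)
        sum(trace[sample.int(n)] * b) / denom, numeric(1))
    }
    list(null = null,
         p95 = stats::quantile(null, 0.95, names = FALSE),
         p05 = stats::quantile(null, 0.05, names = FALSE))
  }
  if (is.null(seed)) compute() else withr::with_seed(seed, compute())
}

#' Label a neuron from its cosine statistic and null band
#'
#' Strict inequalities: positive iff `R > p95`, negative iff `R < p05`,
#' otherwise irrelevant — a statistic exactly at a percentile is
#' irrelevant. `NA` statistics (constant neurons) are irrelevant.
#'
#' @param R raw cosine similarity (vectorised).
#' @param p05,p95 null percentiles.
#' @return Character vector of labels.
#' @export
relevanceLabel <- function(R, p05, p95) {
  ifelse(is.na(R), "irrelevant",
         ifelse(R > p95, "positive",
                ifelse(R < p05, "negative", "irrelevant")))
}

#' Classify neurons as positively/negatively behavior-related or irrelevant
#'
#' For each neuron, the raw cosine similarity `R` between its
#' non-negative trace and the binary behavior vector is compared with the
#' 95th/5th percentiles of the circular-shift null ([shuffledNull()]):
#' `R` above the 95th percentile marks a positively related neuron
#' (preferentially active during behavior bouts), below the 5th a
#' negatively related one (active between bouts), otherwise irrelevant.
#' Constant (flat) neurons are labelled irrelevant with `R = NA`.
#'
#' @param x a `TraceMatrix` in `raw_nonneg` state.
#' @param behavior a `BehaviorVector` (non-constant).
#' @param nPerm permutations per neuron (default 1,000).
#' @param seed integer seed.
#' @param mode shuffle mode, see [shuffledNull()].
#' @return A `DataFrame` with `neuron_id`, `R`, `null_p05`, `null_p95`,
#'   `label`, `constant`.
#' @export
classifyNeurons <- function(x, behavior, nPerm = 1000L, seed = 1L,
                            mode = c("circular", "permutation")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "TraceMatrix"), is(behavior, "BehaviorVector"))
  if (normalizationState(x) != "raw_nonneg")
    stop("classifyNeurons() uses raw non-negative traces (cosine in [0, 1]); ",
         "do not z-score first")
  b <- behaviorValues(behavior)
  if (nFrames(x) != length(b))
    stop("trace and behavior vector lengths differ")
  if (isConstant(b))
    stop("behavior vector is constant; classification is undefined")
  a <- activity(x)
  const <- SummarizedExperiment::rowData(x)$constant | rowSums(a) == 0
  n <- nrow(a)
  R <- rep(NA_real_, n)
  p05 <- rep(NA_real_, n)
  p95 <- rep(NA_real_, n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      if (const[i]) next
      nl <- shuffledNull(a[i, ], behavior, nPerm = nPerm, seed = NULL,
                         mode = mode)
      R[i] <- cosineSimilarity(a[i, ], as.numeric(b))
      p05[i] <- nl$p05
      p95[i] <- nl$p95
    }
  })
  S4Vectors::DataFrame(neuron_id = rownames(a), R = R, null_p05 = p05,
                       null_p95 = p95, label = relevanceLabel(R, p05, p95),
                       constant = as.logical(const))
}

#' Per-label counts and ratios of behavior-relevant neurons
#'
#' Counts per label divided by the total number of registered neurons
#' (the denominator after multi-session registration, which may exceed
#' the number classified in this session).
#'
#' @param calls output of [classifyNeurons()].
#' @param totalRegistered denominator; defaults to `nrow(calls)`.
#' @return A data.frame with `label`, `count`, `ratio` and `percent`
#'   (half-up, one decimal).
#' @export
relevanceRatios <- function(calls, totalRegistered = nrow(calls)) {
  if (totalRegistered <= 0) stop("totalRegistered must be positive")
  if (totalRegistered < nrow(calls))
    stop("totalRegistered cannot be smaller than the number of classified neurons")
  labs <- c("positive", "negative", "irrelevant")
  counts <- vapply(labs, function(l) sum(calls$label == l), integer(1))
  data.frame(label = labs, count = counts,
             ratio = counts / totalRegistered,
             percent = vapply(counts, percentOfTotal, numeric(1),
                              total = totalRegistered),
             row.names = NULL)
}

#' Mean in-bout activity of a neuron subset
#'
#' Mean z-scored activity over behavior frames (`b == 1`) per neuron,
#' with the group mean and SEM across neurons — the summary used for
#' positively correlated neurons during behavior.
#'
#' @param x a z-scored `TraceMatrix`.
#' @param behavior a `BehaviorVector` with at least one in-bout frame.
#' @param subset neuron ids to summarise (default: all).
#' @return A list with `perNeuron` (named numeric), `mean`, `sem`.
#' @export
meanBoutActivity <- function(x, behavior, subset = neuronIds(x)) {
  requireZscore(x, "meanBoutActivity()")
  stopifnot(is(behavior, "BehaviorVector"))
  b <- behaviorValues(behavior)
  if (nFrames(x) != length(b))
    stop("trace and behavior vector lengths differ")
  if (!sum(b)) stop("behavior vector has no in-bout frames")
  if (!length(subset)) stop("empty neuron subset")
  missing <- setdiff(subset, neuronIds(x))
  if (length(missing))
    stop("unknown neuron id(s): ", paste(missing, collapse = ", "))
  per <- rowMeans(activity(x)[subset, b == 1L, drop = FALSE])
  list(perNeuron = per, mean = mean(per),
       sem = if (length(per) > 1L) semOf(per) else NA_real_)
}

#' Cross-session overlap of behavior-relevant neurons
#'
#' Builds the long-format table (registered neuron id x session x label)
#' and the pairwise shared-responsive counts underlying cross-session
#' connectogram plots. A neuron is responsive when labelled positive or
#' negative. Sessions either share a registered id space (`maps = NULL`)
#' or are aligned to the first session through identity maps.
#'
#' @param callsBySession named list of [classifyNeurons()] outputs.
#' @param maps optional named list of `IdentityMap`s, one per non-reference
#'   session, mapping reference-session ids to that session's ids.
#' @return A list with `long` (data.frame: `registered_id`, `session`,
#'   `label`, `responsive`) and `shared` (session x session matrix of
#'   shared-responsive counts; the diagonal holds per-session responsive
#'   counts).
#' @export
sessionOverlapTable <- function(callsBySession, maps = NULL) {
  stopifnot(is.list(callsBySession), length(callsBySession) >= 2L,
            !is.null(names(callsBySession)))
  sessions <- names(callsBySession)
  # registered id of every neuron in every session
  regIds <- lapply(sessions, function(s) {
    ids <- callsBySession[[s]]$neuron_id
    if (is.null(maps) || s == sessions[1L]) return(stats::setNames(ids, ids))
    m <- maps[[s]]
    if (is.null(m))
      stop("no identity map supplied for session '", s, "'")
    if (!all(m@to %in% ids))
      stop("identity map for session '", s,
           "' targets neuron ids absent from its calls")
    reg <- ifelse(ids %in% m@to, m@from[match(ids, m@to)],
                  paste0(s, ":", ids))
    stats::setNames(ids, reg)
  })
  names(regIds) <- sessions
  long <- do.call(rbind, lapply(sessions, function(s) {
    calls <- callsBySession[[s]]
    data.frame(registered_id = names(regIds[[s]]),
               session = s,
               label = calls$label[match(unname(regIds[[s]]), calls$neuron_id)],
               stringsAsFactors = FALSE)
  }))
  long$responsive <- long$label %in% c("positive", "negative")
  respSets <- lapply(sessions, function(s)
    long$registered_id[long$session == s & long$responsive])
  names(respSets) <- sessions
  shared <- matrix(0L, length(sessions), length(sessions),
                   dimnames = list(sessions, sessions))
  for (i in seq_along(sessions)) {
    for (j in seq_along(sessions)) {
      shared[i, j] <- length(intersect(respSets[[i]], respSets[[j]]))
    }
  }
  list(long = long, shared = shared)
}
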