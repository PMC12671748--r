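#' Z-score calcium traces
#'
#' Transforms each neuron's trace to mean 0 and population (ddof = 0)
#' standard deviation 1, the normalisation applied to extracted activity
#' before ensemble and correlation analyses. Constant rows cannot be
#' z-scored; they are mapped to all zeros and flagged in
#' `rowData(x)$constant` so that downstream statistics can exclude them
#' instead of propagating NaN.
#'
#' @param x a `TraceMatrix` in `raw_nonneg` state.
#' @return A `TraceMatrix` with `normalization == "zscore"`; any extra
#'   rowData columns (e.g. simulation ground truth) are carried over.
#' @examples
#' tm <- TraceMatrix(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' z <- zscoreTraces(tm)
#' activity(z)["a", ]   # -1.2247 0 1.2247
#' constantNeurons(z)   # "b"
#' @export
zscoreTraces <- function(x) {
  stopifnot(is(x, "TraceMatrix"))
  if (normalizationState(x) == "zscore")
    stop("traces are already z-scored")
  a <- activity(x)
  z <- t(apply(a, 1L, function(r) {
    if (isConstant(r)) rep(0, length(r)) else (r - mean(r)) / popSd(r)
  }))
  rd <- SummarizedExperiment::rowData(x)
  TraceMatrix(z, frameRate = frameRate(x), sessionId = sessionId(x),
              normalization = "zscore", neuronIds = rownames(a),
              rowData = rd[, setdiff(colnames(rd), "constant"), drop = FALSE])
}

#' Build the binary behavior vector from bout intervals
#'
#' Frame `f` (0-based) is marked 1 when its midpoint time
#' `(f + 0.5) / frameRate` falls inside some half-open bout interval
#' `[start, end)`, and 0 otherwise. Midpoint membership makes the
#' discretisation unambiguous at bout edges that do not align with the
#' 10 Hz frame grid.
#'
#' @param bouts a [BoutList()].
#' @param frameRate acquisition rate in Hz.
#' @param nFrames number of frames; must agree with the session duration
#'   within one frame.
#' @return A [BehaviorVector()].
#' @examples
#' b <- makeBehaviorVector(BoutList(cbind(1, 2), 3), frameRate = 10, nFrames = 30)
#' which(behaviorValues(b) == 1)  # frames 11..20 (1-based), i.e. 0-based 10..19
#' @export
makeBehaviorVector <- function(bouts, frameRate, nFrames) {
  stopifnot(is(bouts, "BoutList"))
  nFrames <- as.integer(nFrames)
  if (abs(nFrames - sessionDuration(bouts) * frameRate) > 1)
    stop("nFrames disagrees with sessionDuration * frameRate by more than one frame")
  iv <- boutIntervals(bouts)
  mid <- (seq_len(nFrames) - 0.5) / frameRate
  v <- integer(nFrames)
  for (i in seq_len(nrow(iv))) {
    v[mid >= iv[i, 1L] & mid < iv[i, 2L]] <- 1L
  }
  BehaviorVector(v, frameRate)
}

#' Dual-recorded responsive neurons across two sessions
#'
#' Given the identity map between two sessions of the same test type and
#' the sets of responsive neurons in each, returns the registered pairs
#' responsive in both ("dual-recorded" neurons).
#'
#' @param map an [IdentityMap()] from session A ids to session B ids.
#' @param responsiveA,responsiveB character vectors of responsive ids.
#' @return A `DataFrame` with columns `a` and `b` (possibly zero rows).
#' @examples
#' m <- IdentityMap(c("a", "b"), c("x", "y"))
#' dualRecordedIds(m, c("a", "b"), "x")  # one pair: a-x
#' @export
dualRecordedIds <- function(map, responsiveA, responsiveB) {
  stopifnot(is(map, "IdentityMap"))
  keep <- map@from %in% responsiveA & map@to %in% responsiveB
  S4Vectors::DataFrame(a = map@from[keep], b = map@to[keep])
}

#' Percentage of a total, rounded as printed
#'
#' `100 * count / total` rounded half-up to one decimal, the style used to
#' report neuron-population fractions (e.g. 49 of 300 dual-recorded
#' neurons is 16.3).
#'
#' @param count non-negative integer, `count <= total`.
#' @param total positive integer.
#' @return A single number.
#' @examples
#' percentOfTotal(49, 300)  # 16.3
#' percentOfTotal(16, 242)  # 6.6
#' @export
percentOfTotal <- function(count, total) {
  if (length(total) != 1L || total <= 0) stop("total must be a positive integer")
  if (count < 0 || count > total) stop("need 0 <= count <= total")
  roundHalfUp(100 * count / total, 1L)
}

#' Display a percentage the way the tables print it
#'
#' Integer display when the value is a whole number (9 rather than 9.0),
#' one decimal otherwise.
#'
#' @param x percentage value(s).
#' @return Character vector.
#' @examples
#' formatPercent(c(9, 16.3))  # "9" "16.3"
#' @export
formatPercent <- function(x) {
  vapply(x, function(v) {
    if (abs(v - round(v)) < 1e-9) sprintf("%d", as.integer(round(v)))
    else sprintf("%.1f", v)
  }, character(1))
}
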