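#' TraceMatrix: per-session neuron-by-frame calcium activity
#'
#' An S4 container for extracted calcium traces, one row per neuron and one
#' column per imaging frame, built on [SummarizedExperiment]. The single
#' assay is named `"activity"`. Row metadata carries a logical `constant`
#' flag (rows with zero dynamic range, which downstream statistics must
#' skip) and, for simulated sessions, the ground-truth `class` and
#' `ensemble` columns. The normalization state distinguishes raw
#' non-negative traces (as emitted by signal extraction) from z-scored
#' traces (mean 0, population SD 1 per row).
#'
#' @param activity numeric matrix, neurons x frames; all values finite.
#' @param frameRate acquisition rate in Hz (the recordings here are 10 Hz).
#' @param sessionId free-text session label (e.g. `"RSI-1"`).
#' @param normalization `"raw_nonneg"` (default) or `"zscore"`.
#' @param neuronIds unique neuron identifiers; default taken from rownames
#'   or generated as `n001, n002, ...`.
#' @param rowData optional `DataFrame` of extra per-neuron columns (a
#'   `constant` column is always recomputed from the data).
#'
#' @return A `TraceMatrix` object.
#' @examples
#' tm <- TraceMatrix(matrix(abs(rnorm(50)), 5, 10), frameRate = 10)
#' nFrames(tm)
#' @export
TraceMatrix <- function(activity, frameRate = 10, sessionId = "session",
                        normalization = c("raw_nonneg", "zscore"),
                        neuronIds = rownames(activity), rowData = NULL) {
  normalization <- match.arg(normalization)
  activity <- as.matrix(activity)
  storage.mode(activity) <- "double"
  if (is.null(neuronIds)) {
    neuronIds <- sprintf("n%03d", seq_len(nrow(activity)))
  }
  rownames(activity) <- as.character(neuronIds)
  colnames(activity) <- NULL
  constant <- apply(activity, 1L, isConstant)
  if (is.null(rowData)) {
    rd <- S4Vectors::DataFrame(constant = constant, row.names = rownames(activity))
  } else {
    rd <- S4Vectors::DataFrame(rowData, row.names = rownames(activity))
    rd$constant <- constant
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = activity),
    rowData = rd,
    metadata = list(session_id = sessionId)
  )
  new("TraceMatrix", se, frameRate = as.numeric(frameRate),
      normalization = normalization)
}

setClass("TraceMatrix",
  contains = "SummarizedExperiment",
  slots = c(frameRate = "numeric", normalization = "character")
)

setValidity("TraceMatrix", function(object) {
  a <- SummarizedExperiment::assay(object, "activity")
  msg <- character()
  if (!all(is.finite(a)))
    msg <- c(msg, "activity values must all be finite (no NA/NaN/Inf)")
  if (ncol(a) < 2L)
    msg <- c(msg, "a session needs at least 2 frames")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    msg <- c(msg, "neuron ids must be present and unique")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!object@normalization %in% c("raw_nonneg", "zscore"))
    msg <- c(msg, "normalization must be 'raw_nonneg' or 'zscore'")
  if (object@normalization == "raw_nonneg" && length(a) && min(a) < 0)
    msg <- c(msg, "raw_nonneg activity must be non-negative")
  if (object@normalization == "zscore" && nrow(a)) {
    const <- SummarizedExperiment::rowData(object)$constant
    live <- which(!const)
    for (i in live) {
      r <- a[i, ]
      if (abs(mean(r)) > 1e-6 || abs(popSd(r) - 1) > 1e-6) {
        msg <- c(msg, sprintf(
          "z-scored row '%s' violates mean 0 / SD 1 within 1e-6", rownames(a)[i]))
        break
      }
    }
    if (any(const) && any(a[const, ] != 0))
      msg <- c(msg, "constant rows of a z-scored matrix must be all zero")
  }
  if (length(msg)) msg else TRUE
})

#' BoutList: behavior bout intervals for one session
#'
#' Ordered, pairwise non-overlapping `[start, end)` intervals in seconds
#' (the hand-scored start/end times of social-interaction or
#' object-approach bouts), together with the session duration.
#'
#' @param intervals two-column numeric matrix or data.frame
#'   (`start_s`, `end_s`); zero rows allowed.
#' @param sessionDuration session length in seconds.
#' @return A `BoutList` object.
#' @examples
#' BoutList(cbind(start_s = c(1, 5), end_s = c(2, 7)), sessionDuration = 10)
#' @export
BoutList <- function(intervals, sessionDuration) {
  if (is.null(intervals) || length(intervals) == 0L) {
    intervals <- matrix(numeric(0), ncol = 2L)
  }
  intervals <- as.matrix(intervals)
  storage.mode(intervals) <- "double"
  colnames(intervals) <- c("start_s", "end_s")
  new("BoutList", intervals = intervals,
      sessionDuration = as.numeric(sessionDuration))
}

setClass("BoutList",
  slots = c(intervals = "matrix", sessionDuration = "numeric")
)

setValidity("BoutList", function(object) {
  iv <- object@intervals
  d <- object@sessionDuration
  msg <- character()
  if (length(d) != 1L || !is.finite(d) || d <= 0)
    msg <- c(msg, "sessionDuration must be a single positive number")
  if (ncol(iv) != 2L)
    msg <- c(msg, "intervals must have two columns (start_s, end_s)")
  if (nrow(iv)) {
    if (any(!is.finite(iv)))
      msg <- c(msg, "interval bounds must be finite")
    else {
      if (any(iv[, 1L] < 0) || any(iv[, 2L] > d))
        msg <- c(msg, "intervals must lie within [0, sessionDuration]")
      if (any(iv[, 2L] <= iv[, 1L]))
        msg <- c(msg, "each interval needs start < end")
      if (is.unsorted(iv[, 1L], strictly = FALSE))
        msg <- c(msg, "intervals must be sorted by start time")
      if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
        msg <- c(msg, "intervals must be pairwise non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BehaviorVector: per-frame binary behavior indicator
#'
#' Frame-aligned 0/1 vector marking frames whose midpoint falls inside a
#' behavior bout (social versus non-social period, or object-approaching
#' versus non-approaching period).
#'
#' @param values integer vector of 0s and 1s, one per frame.
#' @param frameRate acquisition rate in Hz.
#' @return A `BehaviorVector` object.
#' @export
BehaviorVector <- function(values, frameRate = 10) {
  new("BehaviorVector", values = as.integer(values),
      frameRate = as.numeric(frameRate))
}

setClass("BehaviorVector",
  slots = c(values = "integer", frameRate = "numeric")
)

setValidity("BehaviorVector", function(object) {
  msg <- character()
  if (!all(object@values %in% c(0L, 1L)))
    msg <- c(msg, "behavior values must be 0 or 1")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' IdentityMap: cross-session neuron identity
#'
#' A partial injective mapping from neuron ids in one session to neuron ids
#' in another, as produced by multi-session registration (registration
#' itself is upstream of this package; the map is consumed, not computed).
#'
#' @param from,to parallel character vectors of neuron ids.
#' @param sessionA,sessionB labels of the mapped sessions.
#' @return An `IdentityMap` object.
#' @examples
#' IdentityMap(from = c("a", "b"), to = c("x", "y"))
#' @export
IdentityMap <- function(from = character(), to = character(),
                        sessionA = "A", sessionB = "B") {
  new("IdentityMap", from = as.character(from), to = as.character(to),
      sessionA = sessionA, sessionB = sessionB)
}

setClass("IdentityMap",
  slots = c(from = "character", to = "character",
            sessionA = "character", sessionB = "character")
)

setValidity("IdentityMap", function(object) {
  msg <- character()
  if (length(object@from) != length(object@to))
    msg <- c(msg, "'from' and 'to' must have the same length")
  if (anyDuplicated(object@from) || anyDuplicated(object@to))
    msg <- c(msg, "identity map must be injective (no duplicated ids)")
  if (length(msg)) msg else TRUE
})

setClass("SimConfig",
  slots = c(
    nNeurons = "integer", nFrames = "integer", frameRate = "numeric",
    meanBoutS = "numeric", meanGapS = "numeric",
    classMix = "numeric",
    rateOnHz = "numeric", rateOffHz = "numeric", rateBaseHz = "numeric",
    nEnsembles = "integer", ensembleDriveRateHz = "numeric",
    participationP = "numeric", kernelTauS = "numeric", noiseSd = "numeric",
    crossSessionOverlapP = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nNeurons < 1L) msg <- c(msg, "nNeurons must be >= 1")
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@meanBoutS <= 0) msg <- c(msg, "meanBoutS must be positive")
  if (object@meanGapS <= 0) msg <- c(msg, "meanGapS must be positive")
  mix <- object@classMix
  if (length(mix) != 3L ||
      !identical(names(mix), c("positive", "negative", "irrelevant")))
    msg <- c(msg, "classMix must be named (positive, negative, irrelevant)")
  else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "classMix fractions must be non-negative and sum to 1")
  for (s in c("rateOnHz", "rateOffHz", "rateBaseHz", "ensembleDriveRateHz",
              "kernelTauS", "noiseSd")) {
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  }
  if (object@kernelTauS <= 0) msg <- c(msg, "kernelTauS must be positive")
  if (object@participationP < 0 || object@participationP > 1)
    msg <- c(msg, "participationP must be in [0, 1]")
  if (object@crossSessionOverlapP < 0 || object@crossSessionOverlapP > 1)
    msg <- c(msg, "crossSessionOverlapP must be in [0, 1]")
  if (object@nEnsembles < 1L || object@nEnsembles > object@nNeurons)
    msg <- c(msg, "nEnsembles must be in [1, nNeurons]")
  if (length(msg)) msg else TRUE
})

setClass("EnsembleModel",
  slots = c(
    k = "integer", wcss = "numeric", labels = "integer",
    ensembleMeans = "matrix", seed = "integer"
  )
)

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (nrow(object@ensembleMeans) != object@k)
    msg <- c(msg, "ensembleMeans must have one row per ensemble")
  if (length(msg)) msg else TRUE
})

setClass("FunctionalNetwork",
  slots = c(
    neuronIds = "character", similarity = "matrix", adjacency = "matrix",
    thresholds = "matrix", thresholdPercentile = "numeric",
    nSurrogates = "integer", degreeCentrality = "numeric"
  )
)

setValidity("FunctionalNetwork", function(object) {
  msg <- character()
  n <- length(object@neuronIds)
  if (!all(dim(object@similarity) == n) || !all(dim(object@adjacency) == n))
    msg <- c(msg, "similarity and adjacency must be n x n")
  if (n && any(diag(object@adjacency) != 0))
    msg <- c(msg, "adjacency diagonal must be zero")
  if (n && !isTRUE(all.equal(object@adjacency, t(object@adjacency))))
    msg <- c(msg, "adjacency must be symmetric")
  if (any(!object@adjacency %in% c(0, 1)))
    msg <- c(msg, "adjacency must be binary")
  if (object@thresholdPercentile <= 50 || object@thresholdPercentile >= 100)
    msg <- c(msg, "thresholdPercentile must be in (50, 100)")
  if (length(object@degreeCentrality) == n && n > 1) {
    dc <- rowSums(object@adjacency) / (n - 1)
    if (max(abs(dc - unname(object@degreeCentrality))) > 1e-12)
      msg <- c(msg, "degreeCentrality must equal adjacency row sums / (n - 1)")
  }
  if (length(msg)) msg else TRUE
})

#' DietSpec: chow and drinking-water nutrient concentrations
#'
#' Baseline chow concentrations (% w/w for amino acids, ppm for minerals),
#' drinking-water supplement concentrations (% w/v, ppm), and the average
#' daily intakes used to convert water-borne supplements into
#' chow-equivalent dietary concentrations.
#'
#' @param waterConc named numeric vector of supplement concentrations in
#'   drinking water.
#' @param chowConc named numeric vector of chow concentrations; defaults to
#'   the LabDiet 5K54 values for Ile, Leu, Val, Ser (% w/w) and Zn (ppm).
#' @param chowIntakeG average chow intake, g/mouse/day (default 3).
#' @param waterIntakeMl average water intake, ml/mouse/day (default 4.8).
#' @return A `DietSpec` object.
#' @examples
#' dietSpec(cocktailPreset("quarter"))
#' @export
dietSpec <- function(waterConc,
                     chowConc = c(Ile = 0.74, Leu = 1.49, Val = 0.87,
                                  Ser = 0.83, Zn = 81),
                     chowIntakeG = 3, waterIntakeMl = 4.8) {
  new("DietSpec", chowConc = chowConc, chowIntakeG = as.numeric(chowIntakeG),
      waterConc = waterConc, waterIntakeMl = as.numeric(waterIntakeMl))
}

setClass("DietSpec",
  slots = c(chowConc = "numeric", chowIntakeG = "numeric",
            waterConc = "numeric", waterIntakeMl = "numeric")
)

setValidity("DietSpec", function(object) {
  msg <- character()
  if (any(object@chowConc < 0) || any(object@waterConc < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (object@chowIntakeG < 0 || object@waterIntakeMl < 0)
    msg <- c(msg, "intakes must be non-negative")
  if (is.null(names(object@chowConc)) || is.null(names(object@waterConc)))
    msg <- c(msg, "concentration vectors must be named by nutrient")
  if (length(msg)) msg else TRUE
})
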