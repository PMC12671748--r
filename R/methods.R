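# Accessor and show methods.

#' @rdname accessors
setMethod("activity", "TraceMatrix", function(x)
  SummarizedExperiment::assay(x, "activity"))

#' @rdname accessors
setMethod("frameRate", "TraceMatrix", function(x) x@frameRate)

#' @rdname accessors
setMethod("frameRate", "BehaviorVector", function(x) x@frameRate)

#' @rdname accessors
setMethod("nNeurons", "TraceMatrix", function(x) nrow(x))

#' @rdname accessors
setMethod("nFrames", "TraceMatrix", function(x) ncol(x))

#' @rdname accessors
setMethod("nFrames", "BehaviorVector", function(x) length(x@values))

#' @rdname accessors
setMethod("neuronIds", "TraceMatrix", function(x) rownames(x))

#' @rdname accessors
setMethod("neuronIds", "FunctionalNetwork", function(x) x@neuronIds)

#' @rdname accessors
setMethod("normalizationState", "TraceMatrix", function(x) x@normalization)

#' @rdname accessors
setMethod("sessionId", "TraceMatrix", function(x)
  S4Vectors::metadata(x)$session_id)

#' @rdname accessors
setMethod("constantNeurons", "TraceMatrix", function(x)
  rownames(x)[SummarizedExperiment::rowData(x)$constant])

#' @rdname accessors
setMethod("behaviorValues", "BehaviorVector", function(x) x@values)

#' @rdname accessors
setMethod("boutIntervals", "BoutList", function(x) x@intervals)

#' @rdname accessors
setMethod("sessionDuration", "BoutList", function(x) x@sessionDuration)

#' @rdname accessors
setMethod("ensembleLabels", "EnsembleModel", function(x) x@labels)

#' @rdname accessors
setMethod("ensembleMeans", "EnsembleModel", function(x) x@ensembleMeans)

#' @rdname accessors
setMethod("wcssValues", "EnsembleModel", function(x) x@wcss)

#' @rdname accessors
setMethod("similarityMatrix", "FunctionalNetwork", function(net) net@similarity)

#' @rdname accessors
setMethod("adjacencyMatrix", "FunctionalNetwork", function(net) net@adjacency)

setMethod("show", "TraceMatrix", function(object) {
  cat(sprintf(
    "TraceMatrix '%s': %d neurons x %d frames @ %g Hz (%s)\n",
    sessionId(object), nNeurons(object), nFrames(object),
    frameRate(object), normalizationState(object)))
  nc <- sum(SummarizedExperiment::rowData(object)$constant)
  if (nc) cat(sprintf("  %d constant neuron(s) flagged\n", nc))
  extra <- setdiff(colnames(SummarizedExperiment::rowData(object)), "constant")
  if (length(extra))
    cat("  rowData:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "BoutList", function(object) {
  iv <- object@intervals
  cat(sprintf("BoutList: %d bout(s) over %g s (bout fraction %.3f)\n",
              nrow(iv), object@sessionDuration,
              if (nrow(iv)) sum(iv[, 2] - iv[, 1]) / object@sessionDuration
              else 0))
})

setMethod("show", "BehaviorVector", function(object) {
  cat(sprintf("BehaviorVector: %d frames @ %g Hz, %d (%.1f%%) in-bout\n",
              length(object@values), object@frameRate, sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "IdentityMap", function(object) {
  cat(sprintf("IdentityMap %s -> %s: %d mapped neuron(s)\n",
              object@sessionA, object@sessionB, length(object@from)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    paste0("SimConfig: %d neurons x %d frames @ %g Hz, %d ensemble(s)\n",
           "  classes (pos/neg/irr): %s; rates on/off/base: %g/%g/%g Hz\n",
           "  drive %g Hz, participation %g, tau %g s, noise SD %g, seed %d\n"),
    object@nNeurons, object@nFrames, object@frameRate, object@nEnsembles,
    paste(object@classMix, collapse = "/"),
    object@rateOnHz, object@rateOffHz, object@rateBaseHz,
    object@ensembleDriveRateHz, object@participationP, object@kernelTauS,
    object@noiseSd, object@seed))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: k = %d over %d neurons (WCSS %.4g)\n",
              object@k, length(object@labels),
              unname(object@wcss[as.character(object@k)])))
  print(table(ensemble = object@labels))
})

setMethod("show", "FunctionalNetwork", function(object) {
  n <- length(object@neuronIds)
  ne <- sum(object@adjacency) / 2
  cat(sprintf(
    paste0("FunctionalNetwork: %d neurons, %d link(s), density %.4f\n",
           "  threshold percentile %.2f over %d surrogate pairs\n"),
    n, ne, if (n > 1) ne / (n * (n - 1) / 2) else 0,
    object@thresholdPercentile, object@nSurrogates))
})

setMethod("show", "DietSpec", function(object) {
  cat("DietSpec:", object@chowIntakeG, "g chow +",
      object@waterIntakeMl, "ml water per day\n")
  print(rbind(chow = object@chowConc,
              water = object@waterConc[names(object@chowConc)]))
})
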