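#' @name accessors
#' @title Accessors for CalciumEnsembles classes
#'
#' @description Slot accessors for the package's S4 classes. `activity()`
#' returns the neuron-by-frame matrix, `frameRate()` the acquisition rate
#' in Hz, `normalizationState()` whether traces are raw non-negative or
#' z-scored, `constantNeurons()` the ids of zero-dynamic-range rows,
#' `behaviorValues()` the 0/1 frame indicator, `boutIntervals()` the bout
#' start/end matrix, `ensembleLabels()`/`ensembleMeans()`/`wcssValues()`
#' the fitted clustering, and `similarityMatrix()`/`adjacencyMatrix()`/
#' `degreeCentrality()` the network components.
#'
#' @param x,net an object of the documented class.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname accessors
#' @export
setGeneric("normalizationState", function(x) standardGeneric("normalizationState"))

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname accessors
#' @export
setGeneric("constantNeurons", function(x) standardGeneric("constantNeurons"))

#' @rdname accessors
#' @export
setGeneric("behaviorValues", function(x) standardGeneric("behaviorValues"))

#' @rdname accessors
#' @export
setGeneric("boutIntervals", function(x) standardGeneric("boutIntervals"))

#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))

#' @rdname accessors
#' @export
setGeneric("ensembleLabels", function(x) standardGeneric("ensembleLabels"))

#' @rdname accessors
#' @export
setGeneric("ensembleMeans", function(x) standardGeneric("ensembleMeans"))

#' @rdname accessors
#' @export
setGeneric("wcssValues", function(x) standardGeneric("wcssValues"))

#' @rdname accessors
#' @export
setGeneric("similarityMatrix", function(net) standardGeneric("similarityMatrix"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(net) standardGeneric("adjacencyMatrix"))

#' Per-neuron degree centrality of a functional network
#'
#' Number of significant-similarity links of each neuron divided by
#' `n - 1`, the normalisation used for graph-theoretic degree centrality.
#'
#' @param net a `FunctionalNetwork`.
#' @return Named numeric vector in `[0, 1]`.
#' @examples
#' adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))  # path a-b-c
#' net <- functionalNetworkFromAdjacency(adj, letters[1:3])
#' degreeCentrality(net)  # 0.5 1.0 0.5
#' @export
setGeneric("degreeCentrality", function(net) standardGeneric("degreeCentrality"))
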