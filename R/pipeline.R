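#' Run the full per-session analysis pipeline
#'
#' Orchestrates, for each supplied session: z-scoring, WCSS-based
#' ensemble-count selection (or a fixed `k`), k-means clustering,
#' ensemble-behavior and neuron-ensemble correlations, single-neuron
#' relevance classification with ratios, mean in-bout activity of the
#' positive neurons, and (optionally) functional-network inference with
#' subgroup centrality. Where identity maps are supplied, dual-recorded
#' neurons are extracted and the cross-session correlation scatter and
#' overlap table computed; without maps the cross-session stages are
#' skipped with a warning. All tables are written as CSV/JSON under
#' `outDir`, along with a manifest recording the package version, seeds
#' and every parameter needed to reproduce the run.
#'
#' @param sessions named list of sessions, each a list with `traces`
#'   (`TraceMatrix`, raw), `bouts` (`BoutList`) and optionally `behavior`
#'   (recomputed from the bouts when absent); alternatively, paths to
#'   session container directories (see [readSessionContainer()]).
#' @param outDir output directory (created if needed).
#' @param k fixed ensemble count; `NULL` (default) selects it from the
#'   WCSS curve over `kRange`.
#' @param kRange candidate cluster counts for [wcssCurve()].
#' @param nPerm relevance permutations (default 1,000).
#' @param network logical: build the functional network (the expensive
#'   stage)?
#' @param nSurrogates,thresholdPercentile,networkMode [buildNetwork()]
#'   parameters.
#' @param identityMaps optional named list of `IdentityMap`s keyed
#'   `"A|B"` for sessions A and B.
#' @param totalRegistered optional denominator for [relevanceRatios()].
#' @param seed master seed; stage seeds derive from it deterministically.
#' @return Invisibly, a named list of per-session results plus
#'   `crossSession` and `manifest`.
#' @export
runPipeline <- function(sessions, outDir, k = NULL, kRange = 1:6,
                        nPerm = 1000L, network = TRUE, nSurrogates = 10000L,
                        thresholdPercentile = 99.17,
                        networkMode = c("pooled", "full"),
                        identityMaps = NULL, totalRegistered = NULL,
                        seed = 1L) {
  networkMode <- match.arg(networkMode)
  if (!is.list(sessions) || is.null(names(sessions)) ||
      any(!nzchar(names(sessions))))
    stop("sessions must be a named list")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, sessionName, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for session '%s': %s",
                   name, sessionName, conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()
  stagesDone <- character()
  for (nm in names(sessions)) {
    ses <- sessions[[nm]]
    if (is.character(ses)) ses <- readSessionContainer(ses)
    if (is.null(ses$behavior))
      ses$behavior <- makeBehaviorVector(ses$bouts, frameRate(ses$traces),
                                         nFrames(ses$traces))
    res <- list()
    z <- stage("zscore", nm, zscoreTraces(ses$traces))
    curve <- stage("wcss", nm,
                   wcssCurve(z, kRange = kRange, seed = seed))
    kUse <- if (is.null(k)) stage("select_k", nm, selectK(curve)) else k
    model <- stage("cluster", nm, clusterNeurons(z, kUse, seed = seed))
    res$wcss <- curve
    res$k <- kUse
    res$model <- model
    res$ensembleBehavior <- stage("ensemble_behavior", nm,
                                  ensembleBehaviorCorrelation(model, ses$behavior))
    res$neuronEnsemble <- stage("neuron_ensemble", nm,
                                neuronEnsembleCorrelation(z, model))
    res$calls <- stage("relevance", nm,
                       classifyNeurons(ses$traces, ses$behavior,
                                       nPerm = nPerm, seed = seed + 1L))
    res$ratios <- stage("ratios", nm,
                        relevanceRatios(res$calls,
                                        totalRegistered %||% nrow(res$calls)))
    pos <- res$calls$neuron_id[res$calls$label == "positive"]
    if (length(pos))
      res$meanBout <- stage("mean_bout", nm,
                            meanBoutActivity(z, ses$behavior, pos))
    if (network) {
      res$network <- stage("network", nm,
                           buildNetwork(ses$traces,
                                        thresholdPercentile = thresholdPercentile,
                                        nSurrogates = nSurrogates,
                                        mode = networkMode, seed = seed + 2L))
      res$centrality <- stage("subgroup_centrality", nm,
                              subgroupCentrality(res$network, res$calls))
    }
    writeSessionOutputs(res, nm, outDir)
    results[[nm]] <- res
    stagesDone <- union(stagesDone, c(
      "zscore", "wcss", "select_k", "cluster", "ensemble_behavior",
      "neuron_ensemble", "relevance", "ratios",
      if (length(pos)) "mean_bout",
      if (network) c("network", "subgroup_centrality")))
  }
  cross <- list()
  if (!is.null(identityMaps) && length(identityMaps)) {
    for (key in names(identityMaps)) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      if (length(ab) != 2L || !all(ab %in% names(results)))
        stop("identityMaps keys must be 'A|B' naming supplied sessions")
      m <- identityMaps[[key]]
      callsA <- results[[ab[1L]]]$calls
      callsB <- results[[ab[2L]]]$calls
      respA <- callsA$neuron_id[callsA$label != "irrelevant"]
      respB <- callsB$neuron_id[callsB$label != "irrelevant"]
      dual <- dualRecordedIds(m, respA, respB)
      entry <- list(dual = dual)
      if (nrow(dual) >= 3L) {
        neA <- results[[ab[1L]]]$neuronEnsemble
        neB <- results[[ab[2L]]]$neuronEnsemble
        entry$scatter <- crossSessionRScatter(
          neA$r[match(dual$a, neA$neuron_id)],
          neB$r[match(dual$b, neB$neuron_id)])
      }
      cross[[key]] <- entry
    }
    maps <- stats::setNames(identityMaps,
                            vapply(strsplit(names(identityMaps), "|",
                                            fixed = TRUE),
                                   `[`, character(1), 2L))
    overlapSessions <- c(names(results)[1L], names(maps))
    if (all(overlapSessions %in% names(results))) {
      cross$overlap <- sessionOverlapTable(
        lapply(results[overlapSessions], `[[`, "calls"), maps = maps)
      utils::write.csv(cross$overlap$long,
                       file.path(outDir, "overlap_long.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(cross$overlap$shared),
                       file.path(outDir, "overlap_shared.csv"))
    }
    stagesDone <- union(stagesDone, "cross_session")
  } else {
    warning("no identity maps supplied; cross-session stages skipped")
  }
  manifest <- list(
    package = "CalciumEnsembles",
    version = as.character(utils::packageVersion("CalciumEnsembles")),
    seed = seed, k = k, kRange = kRange, nPerm = nPerm,
    network = network, nSurrogates = nSurrogates,
    thresholdPercentile = thresholdPercentile, networkMode = networkMode,
    shuffleMode = "circular", elbowRule = "max second difference",
    surrogatePooling = networkMode == "pooled",
    sessions = names(sessions), stages = sort(stagesDone),
    outputs = list.files(outDir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results, list(crossSession = cross, manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeSessionOutputs <- function(res, nm, outDir) {
  pre <- function(f) file.path(outDir, paste0(nm, "_", f))
  utils::write.csv(data.frame(k = as.integer(names(res$wcss)),
                              wcss = unname(res$wcss)),
                   pre("wcss.csv"), row.names = FALSE)
  utils::write.csv(data.frame(neuron_id = names(ensembleLabels(res$model)),
                              ensemble = unname(ensembleLabels(res$model))),
                   pre("ensembles.csv"), row.names = FALSE)
  utils::write.csv(data.frame(ensemble = seq_along(res$ensembleBehavior),
                              r = unname(res$ensembleBehavior)),
                   pre("ensemble_behavior_correlation.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$neuronEnsemble),
                   pre("neuron_ensemble_correlation.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$calls), pre("relevance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$ratios, pre("relevance_summary.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(res$network)) {
    utils::write.csv(as.data.frame(similarityMatrix(res$network)),
                     pre("similarity.csv"), row.names = FALSE)
    adj <- adjacencyMatrix(res$network)
    ids <- neuronIds(res$network)
    edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    utils::write.csv(data.frame(i = ids[edges[, 1L]], j = ids[edges[, 2L]],
                                similarity = similarityMatrix(res$network)[edges],
                                threshold = res$network@thresholds[edges]),
                     pre("edges.csv"), row.names = FALSE)
    utils::write.csv(data.frame(neuron_id = ids,
                                degree_centrality = unname(degreeCentrality(res$network))),
                     pre("centrality.csv"), row.names = FALSE)
    utils::write.csv(res$centrality, pre("subgroup_centrality.csv"),
                     row.names = FALSE)
  }
}
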