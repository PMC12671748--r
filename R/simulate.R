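#' Configuration of the synthetic session generator
#'
#' Defines a seeded miniscope-like session: an alternating bout/gap
#' behavior process, three neuron classes whose event rates are modulated
#' by the behavior state (positive: active during bouts; negative: active
#' between bouts; irrelevant: constant rate), ensemble-shared drive
#' events, an exponential calcium kernel, additive Gaussian noise and
#' rectification at zero. Defaults are the package's reference study
#' conditions: 10 Hz, a 10-minute session (6,000 frames), a 1 s GCaMP-like
#' decay constant, 2 Hz in-state versus 0.2 Hz out-of-state event rates,
#' 0.5 Hz for irrelevant neurons, two ensembles with 0.3 Hz shared drive
#' and participation probability 0.9, and noise SD 0.1.
#'
#' @param nNeurons,nFrames session size.
#' @param frameRate acquisition rate, Hz.
#' @param meanBoutS,meanGapS means of the exponential bout/gap durations
#'   (bouts truncated below at 0.5 s).
#' @param classMix fractions of positive/negative/irrelevant neurons
#'   (must sum to 1).
#' @param rateOnHz,rateOffHz event rates in the preferred versus
#'   non-preferred behavior state for positive/negative neurons.
#' @param rateBaseHz constant event rate of irrelevant neurons.
#' @param nEnsembles number of ensembles (neurons assigned round-robin).
#' @param ensembleDriveRateHz rate of ensemble-shared drive events.
#' @param participationP probability that a drive event fires a member.
#' @param kernelTauS calcium decay constant, seconds.
#' @param noiseSd SD of additive Gaussian noise (applied before
#'   rectification at zero).
#' @param crossSessionOverlapP probability a neuron reappears in the
#'   paired session.
#' @param seed integer seed; every simulation is reproducible from it.
#' @return A `SimConfig` object.
#' @examples
#' cfg <- simConfig(nNeurons = 10, nFrames = 500, seed = 7)
#' s <- simulateSession(cfg)
#' s$traces
#' @export
simConfig <- function(nNeurons = 60L, nFrames = 6000L, frameRate = 10,
                      meanBoutS = 2, meanGapS = 10,
                      classMix = c(positive = 0.10, negative = 0.05,
                                   irrelevant = 0.85),
                      rateOnHz = 2, rateOffHz = 0.2, rateBaseHz = 0.5,
                      nEnsembles = 2L, ensembleDriveRateHz = 0.3,
                      participationP = 0.9, kernelTauS = 1, noiseSd = 0.1,
                      crossSessionOverlapP = 0.5, seed = 1L) {
  new("SimConfig",
      nNeurons = as.integer(nNeurons), nFrames = as.integer(nFrames),
      frameRate = as.numeric(frameRate), meanBoutS = as.numeric(meanBoutS),
      meanGapS = as.numeric(meanGapS), classMix = classMix,
      rateOnHz = as.numeric(rateOnHz), rateOffHz = as.numeric(rateOffHz),
      rateBaseHz = as.numeric(rateBaseHz), nEnsembles = as.integer(nEnsembles),
      ensembleDriveRateHz = as.numeric(ensembleDriveRateHz),
      participationP = as.numeric(participationP),
      kernelTauS = as.numeric(kernelTauS), noiseSd = as.numeric(noiseSd),
      crossSessionOverlapP = as.numeric(crossSessionOverlapP),
      seed = as.integer(seed))
}

#' Hyperconnectivity preset
#'
#' Returns a copy of a configuration with raised ensemble participation
#' (0.97) and shared-drive rate (1.0 Hz), producing the tightly clustered,
#' high-degree-centrality functional networks used to exercise
#' network-discrimination analyses.
#'
#' @param cfg a `SimConfig` to modify (defaults to `simConfig()`).
#' @return A `SimConfig`.
#' @export
hyperconnectivityConfig <- function(cfg = simConfig()) {
  cfg@participationP <- 0.97
  cfg@ensembleDriveRateHz <- 1.0
  validObject(cfg)
  cfg
}

#' Serialise a simulation configuration
#'
#' Round-trips a `SimConfig` through JSON.
#'
#' @param cfg a `SimConfig`.
#' @param path JSON file path.
#' @return `readSimConfig()` returns a `SimConfig`.
#' @export
writeSimConfig <- function(cfg, path) {
  stopifnot(is(cfg, "SimConfig"))
  vals <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(vals) <- slotNames(cfg)
  vals$classMix <- as.list(cfg@classMix)  # keep names through JSON
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals$classMix <- unlist(vals$classMix)
  do.call(simConfig, vals[c("nNeurons", "nFrames", "frameRate", "meanBoutS",
                            "meanGapS", "classMix", "rateOnHz", "rateOffHz",
                            "rateBaseHz", "nEnsembles", "ensembleDriveRateHz",
                            "participationP", "kernelTauS", "noiseSd",
                            "crossSessionOverlapP", "seed")])
}

# Alternating-renewal bout process on the current RNG stream.
simulateBoutsStream <- function(cfg) {
  duration <- cfg@nFrames / cfg@frameRate
  iv <- list()
  t <- 0
  repeat {
    start <- t + stats::rexp(1L, rate = 1 / cfg@meanGapS)
    if (start >= duration) break
    bout <- max(stats::rexp(1L, rate = 1 / cfg@meanBoutS), 0.5)
    end <- min(start + bout, duration)
    iv[[length(iv) + 1L]] <- c(start, end)
    t <- end
    if (t >= duration) break
  }
  if (!length(iv))
    warning("session too short for a single bout; returning an empty BoutList")
  BoutList(do.call(rbind, iv), duration)
}

#' Simulate behavior bouts
#'
#' Alternating-renewal process: gap durations are exponential with mean
#' `meanGapS`, bout durations exponential with mean `meanBoutS` truncated
#' below at 0.5 s, clipped to the session duration. The long-run bout
#' fraction is `E[B] / (E[B] + meanGapS)` with
#' `E[B] = 0.5 + meanBoutS * exp(-0.5 / meanBoutS)`.
#'
#' @param cfg a `SimConfig`.
#' @param seed integer seed (defaults to the config's).
#' @return A `BoutList`.
#' @export
simulateBouts <- function(cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withr::with_seed(seed, simulateBoutsStream(cfg))
}

# Event trains, drive, kernel, noise for a fixed label assignment, on the
# current RNG stream.
genSessionStream <- function(cfg, classes, ensembles, idPrefix = "n") {
  n <- cfg@nNeurons
  nf <- cfg@nFrames
  fr <- cfg@frameRate
  bouts <- simulateBoutsStream(cfg)
  b <- makeBehaviorVector(bouts, fr, nf)
  on <- behaviorValues(b) == 1L

  pOn <- min(cfg@rateOnHz / fr, 1)
  pOff <- min(cfg@rateOffHz / fr, 1)
  pBase <- min(cfg@rateBaseHz / fr, 1)
  prob <- matrix(pBase, nrow = n, ncol = nf)
  prob[classes == "positive", on] <- pOn
  prob[classes == "positive", !on] <- pOff
  prob[classes == "negative", on] <- pOff
  prob[classes == "negative", !on] <- pOn
  events <- matrix(as.numeric(stats::runif(n * nf) < prob), nrow = n)

  pDrive <- min(cfg@ensembleDriveRateHz / fr, 1)
  for (e in seq_len(cfg@nEnsembles)) {
    drive <- stats::runif(nf) < pDrive
    for (i in which(ensembles == e)) {
      events[i, ] <- events[i, ] +
        as.numeric(drive & (stats::runif(nf) < cfg@participationP))
    }
  }

  decay <- exp(-1 / (cfg@kernelTauS * fr))
  traces <- t(apply(events, 1L, function(ev)
    as.numeric(stats::filter(ev, decay, method = "recursive"))))
  noise <- matrix(stats::rnorm(n * nf, sd = cfg@noiseSd), nrow = n)
  traces <- pmax(traces + noise, 0)

  ids <- sprintf("%s%03d", idPrefix, seq_len(n))
  truth <- data.frame(neuron_id = ids, class = classes, ensemble = ensembles,
                      stringsAsFactors = FALSE)
  tm <- TraceMatrix(traces, frameRate = fr, sessionId = paste0("sim-", idPrefix),
                    neuronIds = ids,
                    rowData = S4Vectors::DataFrame(class = classes,
                                                   ensemble = ensembles))
  list(traces = tm, bouts = bouts, behavior = b, truth = truth)
}

classCounts <- function(mix, n) {
  cum <- round(cumsum(mix) * n)
  counts <- diff(c(0, cum))
  names(counts) <- names(mix)
  counts
}

drawClasses <- function(cfg) {
  counts <- classCounts(cfg@classMix, cfg@nNeurons)
  rep(c("positive", "negative", "irrelevant"), times = counts)
}

#' Simulate one session with ground truth
#'
#' Generates behavior bouts, class- and ensemble-structured event trains,
#' convolves them with an exponential calcium kernel, adds Gaussian noise
#' and rectifies at zero (keeping traces valid inputs for the
#' non-negative cosine statistic). The returned `TraceMatrix` carries the
#' ground-truth `class` and `ensemble` labels in its rowData.
#'
#' @param cfg a `SimConfig`.
#' @param seed integer seed (defaults to the config's).
#' @return A list with `traces` (`TraceMatrix`, raw_nonneg), `bouts`
#'   (`BoutList`), `behavior` (`BehaviorVector`) and `truth` (data.frame).
#' @export
simulateSession <- function(cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withr::with_seed(seed, {
    classes <- drawClasses(cfg)
    ensembles <- rep(seq_len(cfg@nEnsembles), length.out = cfg@nNeurons)
    genSessionStream(cfg, classes, ensembles)
  })
}

#' Simulate a pair of sessions with partial neuron overlap
#'
#' The second session retains each first-session neuron with probability
#' `crossSessionOverlapP` (same class and ensemble, traces regenerated);
#' dropped neurons are replaced by fresh ones. The identity map covers
#' exactly the retained neurons, enabling dual-recorded analyses.
#'
#' @param cfg a `SimConfig`.
#' @param seed integer seed (defaults to the config's).
#' @return A list with `sessionA`, `sessionB` (as [simulateSession()]
#'   returns) and `map` (`IdentityMap` from A ids to B ids).
#' @export
simulatePairedSessions <- function(cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withr::with_seed(seed, {
    classesA <- drawClasses(cfg)
    ensembles <- rep(seq_len(cfg@nEnsembles), length.out = cfg@nNeurons)
    sessionA <- genSessionStream(cfg, classesA, ensembles, idPrefix = "a")
    retained <- stats::runif(cfg@nNeurons) < cfg@crossSessionOverlapP
    classesB <- classesA
    if (any(!retained)) {
      classesB[!retained] <- sample(c("positive", "negative", "irrelevant"),
                                    sum(!retained), replace = TRUE,
                                    prob = cfg@classMix)
    }
    sessionB <- genSessionStream(cfg, classesB, ensembles, idPrefix = "b")
    map <- IdentityMap(from = sessionA$truth$neuron_id[retained],
                       to = sessionB$truth$neuron_id[retained],
                       sessionA = sessionId(sessionA$traces),
                       sessionB = sessionId(sessionB$traces))
    list(sessionA = sessionA, sessionB = sessionB, map = map)
  })
}
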