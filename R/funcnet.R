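# Functional-network inference: pairwise cosine similarity of raw traces
# thresholded against phase-randomization surrogates, then degree
# centrality on the resulting graph.

#' Phase-randomization surrogate of a trace
#'
#' Replaces the Fourier phases of all non-DC, non-Nyquist bins by i.i.d.
#' uniform(0, 2*pi) values (Hermitian symmetry enforced) and inverts the
#' transform. The surrogate has exactly the original amplitude spectrum —
#' hence the original mean (DC), norm and autocorrelation — but scrambled
#' temporal alignment, which is what makes it a null for pairwise
#' similarity. A constant signal is returned unchanged (all power in DC).
#'
#' @param trace finite numeric vector, length at least 4.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return Numeric surrogate vector of the same length.
#' @export
phaseRandomize <- function(trace, seed = NULL) {
  if (length(trace) < 4L) stop("need at least 4 samples")
  if (!all(is.finite(trace))) stop("trace must be finite")
  compute <- function() {
    n <- length(trace)
    X <- stats::fft(trace)
    half <- (n - 1L) %/% 2L
    if (half >= 1L) {
      idx <- 2L:(half + 1L)
      theta <- stats::runif(half, 0, 2 * pi)
      X[idx] <- Mod(X[idx]) * exp(1i * theta)
      X[n + 2L - idx] <- Conj(X[idx])
    }
    Re(stats::fft(X, inverse = TRUE)) / n
  }
  if (is.null(seed)) compute() else withr::with_seed(seed, compute())
}

surrogateQuantile <- function(vals, thresholdPercentile) {
  stats::quantile(vals, thresholdPercentile / 100, names = FALSE)
}

#' Surrogate-thresholded similarity of one neuron pair
#'
#' Computes the raw cosine similarity of two traces and an empirical
#' significance threshold from `nSurrogates` surrogate pairs, each made
#' by independently phase-randomizing both traces. The pair is linked
#' (`is_link`) when the raw similarity strictly exceeds the
#' `thresholdPercentile` of the surrogate distribution.
#'
#' @param a,b numeric vectors of equal length and positive norm.
#' @param nSurrogates surrogate pairs (default 10,000).
#' @param thresholdPercentile percentile of the surrogate distribution
#'   (default 99.17).
#' @param seed integer seed.
#' @return A list with `similarity`, `threshold`, `is_link`.
#' @export
pairSignificance <- function(a, b, nSurrogates = 10000L,
                             thresholdPercentile = 99.17, seed = 1L) {
  raw <- cosineSimilarity(a, b)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(nSurrogates), function(i) {
      sa <- phaseRandomize(a)
      sb <- phaseRandomize(b)
      sum(sa * sb) / (sqrt(sum(sa^2)) * sqrt(sum(sb^2)))
    }, numeric(1))
  })
  thr <- surrogateQuantile(vals, thresholdPercentile)
  list(similarity = raw, threshold = thr, is_link = raw > thr)
}

# Internal constructor used by buildNetwork and tests.

#' Build a FunctionalNetwork from a ready adjacency matrix
#'
#' Mostly useful for tests and for importing externally thresholded
#' networks; [buildNetwork()] is the analysis entry point.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @param ids neuron ids.
#' @param similarity optional similarity matrix (defaults to the adjacency).
#' @param thresholds optional per-pair threshold matrix.
#' @param thresholdPercentile,nSurrogates metadata describing how the
#'   adjacency was obtained.
#' @return A `FunctionalNetwork`.
#' @export
functionalNetworkFromAdjacency <- function(adjacency,
                                           ids = rownames(adjacency),
                                           similarity = adjacency,
                                           thresholds = matrix(NA_real_,
                                                               nrow(adjacency),
                                                               ncol(adjacency)),
                                           thresholdPercentile = 99.17,
                                           nSurrogates = 0L) {
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(adjacency)))
  adjacency <- unname(as.matrix(adjacency)) * 1
  n <- length(ids)
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  dc <- if (n > 1) igraph::degree(g) / (n - 1) else rep(0, n)
  new("FunctionalNetwork", neuronIds = as.character(ids),
      similarity = unname(as.matrix(similarity)), adjacency = adjacency,
      thresholds = unname(as.matrix(thresholds)),
      thresholdPercentile = thresholdPercentile,
      nSurrogates = as.integer(nSurrogates),
      degreeCentrality = stats::setNames(as.numeric(dc), ids))
}

#' Infer the functional network of a session
#'
#' Applies surrogate-thresholded cosine similarity to every unordered
#' neuron pair. In the default `"pooled"` mode, `S = round(sqrt(n))`
#' phase-randomized surrogates are generated per neuron and the `S^2`
#' cross pairings form each pair's null distribution (10,000 pair
#' surrogates for the default `nSurrogates = 10000`), which needs
#' `nNeurons * S` Fourier transforms instead of
#' `nPairs * 2 * nSurrogates`; because every surrogate is independently
#' phase-randomized, the pooled pair similarities follow the same null
#' law as freshly drawn pairs (`mode = "full"`, available for
#' cross-checking on small inputs).
#'
#' @param x a `TraceMatrix` (raw non-negative traces; at least 2 neurons,
#'   no zero-norm rows).
#' @param thresholdPercentile surrogate percentile for the link decision
#'   (strict `>`; default 99.17).
#' @param nSurrogates surrogate pairs per neuron pair (default 10,000).
#' @param mode `"pooled"` (default) or `"full"`.
#' @param seed integer seed.
#' @return A `FunctionalNetwork` with the raw similarity matrix, binary
#'   adjacency, per-pair thresholds and degree centrality.
#' @export
buildNetwork <- function(x, thresholdPercentile = 99.17, nSurrogates = 10000L,
                         mode = c("pooled", "full"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(x, "TraceMatrix"))
  a <- activity(x)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 neurons to build a network")
  norms <- sqrt(rowSums(a^2))
  if (any(norms == 0)) stop("zero-norm trace(s); drop silent neurons first")
  if (thresholdPercentile <= 50 || thresholdPercentile >= 100)
    stop("thresholdPercentile must be in (50, 100)")
  sim <- tcrossprod(a / norms)
  diag(sim) <- 1
  thr <- matrix(NA_real_, n, n)
  withr::with_seed(seed, {
    if (mode == "pooled") {
      S <- max(2L, round(sqrt(nSurrogates)))
      surr <- lapply(seq_len(n), function(i) {
        m <- t(vapply(seq_len(S), function(s) phaseRandomize(a[i, ]),
                      numeric(ncol(a))))
        m / sqrt(rowSums(m^2))
      })
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          vals <- tcrossprod(surr[[i]], surr[[j]])
          thr[i, j] <- thr[j, i] <- surrogateQuantile(vals, thresholdPercentile)
        }
      }
      nEff <- S^2
    } else {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          vals <- vapply(seq_len(nSurrogates), function(s) {
            sa <- phaseRandomize(a[i, ])
            sb <- phaseRandomize(a[j, ])
            sum(sa * sb) / (sqrt(sum(sa^2)) * sqrt(sum(sb^2)))
          }, numeric(1))
          thr[i, j] <- thr[j, i] <- surrogateQuantile(vals, thresholdPercentile)
        }
      }
      nEff <- nSurrogates
    }
  })
  adj <- (sim > thr) * 1
  adj[is.na(thr)] <- 0
  diag(adj) <- 0
  net <- functionalNetworkFromAdjacency(
    adj, ids = rownames(a), similarity = sim, thresholds = thr,
    thresholdPercentile = thresholdPercentile, nSurrogates = nEff)
  net
}

#' @rdname degreeCentrality
setMethod("degreeCentrality", "FunctionalNetwork", function(net) {
  n <- length(net@neuronIds)
  if (n < 2L) stop("degree centrality needs at least 2 neurons")
  net@degreeCentrality
})

#' Degree centrality by relevance subgroup
#'
#' Partitions per-neuron degree centrality into all neurons,
#' behavior-linked neurons (positively or negatively correlated) and
#' irrelevant neurons, with group means and SEMs. An empty group is
#' reported with `NA` summaries rather than an error.
#'
#' @param net a `FunctionalNetwork`.
#' @param calls [classifyNeurons()] output covering the network's neurons.
#' @return A data.frame with `group`, `n`, `mean`, `sem`.
#' @export
subgroupCentrality <- function(net, calls) {
  stopifnot(is(net, "FunctionalNetwork"))
  ids <- neuronIds(net)
  if (!all(ids %in% calls$neuron_id))
    stop("relevance calls do not cover all network neurons")
  lab <- calls$label[match(ids, calls$neuron_id)]
  dc <- degreeCentrality(net)
  groups <- list(all = ids,
                 linked = ids[lab %in% c("positive", "negative")],
                 irrelevant = ids[lab == "irrelevant"])
  do.call(rbind, lapply(names(groups), function(g) {
    v <- dc[groups[[g]]]
    data.frame(group = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1L) semOf(v) else NA_real_)
  }))
}

#' Export a functional network as GraphML
#'
#' Writes the thresholded graph (with raw similarity as an edge weight
#' and degree centrality as a node attribute) for external viewers.
#'
#' @param net a `FunctionalNetwork`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$name <- neuronIds(net)
  igraph::V(g)$degree_centrality <- unname(degreeCentrality(net))
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ends))
    igraph::E(g)$similarity <- net@similarity[ends]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
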