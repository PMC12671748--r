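# On-disk formats. Two dialects:
#  * "csv": matrix CSV (rows = neurons, header = frame index f0..f{n-1},
#    first column neuron_id) with a JSON metadata sidecar alongside
#    (same path, .json extension).
#  * "container": a session directory holding the trace CSV + sidecar under
#    traces/, the bout table under bouts/, and identity/ground-truth files,
#    mirroring the /traces, /bouts, /identity groups of a hierarchical
#    container in plain text.
# Numbers are serialised with %.17g so a write/load round trip is
# bit-identical for doubles.

sidecarPath <- function(path) sub("\\.csv$", ".json", path)

fmtNum <- function(x) sprintf("%.17g", x)

writeMatrixCsv <- function(m, path, idCol = "neuron_id") {
  ch <- matrix(fmtNum(m), nrow = nrow(m))
  df <- data.frame(rownames(m), ch, check.names = FALSE)
  colnames(df) <- c(idCol, sprintf("f%d", seq_len(ncol(m)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

readMatrixCsv <- function(path, idCol = "neuron_id") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || colnames(df)[1L] != idCol)
    stop(sprintf("malformed trace CSV '%s': first column must be '%s'",
                 path, idCol))
  ids <- df[[1L]]
  m <- vapply(df[-1L], function(col) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(col %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("malformed trace CSV '%s': non-numeric value '%s' in row %d",
                   path, col[bad[1L]], bad[1L]))
    v
  }, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df))
  rownames(m) <- ids
  if (anyNA(m))
    stop(sprintf("trace CSV '%s' contains NA/NaN values", path))
  m
}

#' Write and load trace matrices
#'
#' `writeTraces()` serialises a `TraceMatrix` as a CSV matrix plus a JSON
#' metadata sidecar (`session_id`, `frame_rate_hz`, `neuron_ids`,
#' `normalization`); `loadTraces()` reads it back. `format = "container"`
#' reads/writes the trace files inside a session container directory (see
#' [writeSessionContainer()]).
#'
#' @param x a `TraceMatrix`.
#' @param path file path of the CSV (format `"csv"`) or the container
#'   directory (format `"container"`).
#' @param format `"csv"` or `"container"`.
#' @return `loadTraces()` returns a `TraceMatrix`; `writeTraces()` returns
#'   `path` invisibly.
#' @examples
#' f <- file.path(tempdir(), "tiny.csv")
#' writeTraces(TraceMatrix(matrix(0, 3, 5)), f)
#' nFrames(loadTraces(f))
#' @export
writeTraces <- function(x, path, format = c("csv", "container")) {
  format <- match.arg(format)
  stopifnot(is(x, "TraceMatrix"))
  if (format == "container") {
    dir.create(file.path(path, "traces"), recursive = TRUE, showWarnings = FALSE)
    path <- file.path(path, "traces", "traces.csv")
  }
  writeMatrixCsv(activity(x), path)
  meta <- list(session_id = sessionId(x), frame_rate_hz = frameRate(x),
               neuron_ids = neuronIds(x), normalization = normalizationState(x))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTraces
#' @export
loadTraces <- function(path, format = c("csv", "container")) {
  format <- match.arg(format)
  if (format == "container") path <- file.path(path, "traces", "traces.csv")
  if (!file.exists(path)) stop(sprintf("no such trace file: '%s'", path))
  mp <- sidecarPath(path)
  if (!file.exists(mp))
    stop(sprintf("missing metadata sidecar '%s' (session_id, frame_rate_hz, ...)", mp))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  need <- c("session_id", "frame_rate_hz", "neuron_ids", "normalization")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("metadata sidecar '%s' lacks field(s): %s", mp,
                 paste(miss, collapse = ", ")))
  m <- readMatrixCsv(path)
  TraceMatrix(m, frameRate = meta$frame_rate_hz, sessionId = meta$session_id,
              normalization = meta$normalization,
              neuronIds = meta$neuron_ids)
}

#' Read and write bout tables
#'
#' Two-column CSV (`start_s`, `end_s`) of behavior bout intervals.
#'
#' @param bouts a `BoutList`.
#' @param path CSV path.
#' @param sessionDuration session length in seconds (stored in the CSV as
#'   a `# session_duration_s=` header comment and recovered on read; an
#'   explicit argument overrides it).
#' @return `readBouts()` returns a `BoutList`.
#' @export
writeBouts <- function(bouts, path) {
  stopifnot(is(bouts, "BoutList"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_duration_s=%s", fmtNum(sessionDuration(bouts))), con)
  iv <- boutIntervals(bouts)
  writeLines("start_s,end_s", con)
  if (nrow(iv))
    writeLines(paste(fmtNum(iv[, 1L]), fmtNum(iv[, 2L]), sep = ","), con)
  invisible(path)
}

#' @rdname writeBouts
#' @export
readBouts <- function(path, sessionDuration = NULL) {
  lines <- readLines(path)
  if (is.null(sessionDuration)) {
    hdr <- grep("^# session_duration_s=", lines, value = TRUE)
    if (!length(hdr))
      stop("bout CSV lacks a session duration; pass sessionDuration=")
    sessionDuration <- as.numeric(sub("^# session_duration_s=", "", hdr[1L]))
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  BoutList(as.matrix(df[, c("start_s", "end_s")]), sessionDuration)
}

#' Write and read a session container
#'
#' A session container is a directory mirroring a hierarchical trace
#' container in plain text: `traces/traces.csv` (+ JSON sidecar),
#' `bouts/bouts.csv`, optional `identity/identity.csv` (cross-session
#' map) and `groundtruth.json` (simulation truth).
#'
#' @param session a list with elements `traces` (`TraceMatrix`), `bouts`
#'   (`BoutList`), and optionally `truth` (data.frame with `neuron_id`,
#'   `class`, `ensemble`) and `map` (`IdentityMap`).
#' @param dir container directory (created if needed).
#' @return `readSessionContainer()` returns such a list (with `behavior`
#'   reconstructed from the bouts); `writeSessionContainer()` returns
#'   `dir` invisibly.
#' @export
writeSessionContainer <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTraces(session$traces, dir, format = "container")
  dir.create(file.path(dir, "bouts"), showWarnings = FALSE)
  writeBouts(session$bouts, file.path(dir, "bouts", "bouts.csv"))
  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, file.path(dir, "groundtruth.json"),
                         dataframe = "columns", digits = NA)
  }
  if (!is.null(session$map)) {
    dir.create(file.path(dir, "identity"), showWarnings = FALSE)
    m <- session$map
    utils::write.csv(
      data.frame(from = m@from, to = m@to, sessionA = m@sessionA,
                 sessionB = m@sessionB),
      file.path(dir, "identity", "identity.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeSessionContainer
#' @export
readSessionContainer <- function(dir) {
  traces <- loadTraces(dir, format = "container")
  bouts <- readBouts(file.path(dir, "bouts", "bouts.csv"))
  out <- list(traces = traces, bouts = bouts,
              behavior = makeBehaviorVector(bouts, frameRate(traces),
                                            nFrames(traces)))
  gt <- file.path(dir, "groundtruth.json")
  if (file.exists(gt)) {
    out$truth <- as.data.frame(jsonlite::read_json(gt, simplifyVector = TRUE))
    rd <- SummarizedExperiment::rowData(out$traces)
    idx <- match(rownames(rd), out$truth$neuron_id)
    rd$class <- out$truth$class[idx]
    rd$ensemble <- out$truth$ensemble[idx]
    SummarizedExperiment::rowData(out$traces) <- rd
  }
  idp <- file.path(dir, "identity", "identity.csv")
  if (file.exists(idp)) {
    df <- utils::read.csv(idp, colClasses = "character")
    out$map <- IdentityMap(df$from, df$to,
                           sessionA = df$sessionA[1L], sessionB = df$sessionB[1L])
  }
  out
}
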