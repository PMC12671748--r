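# Shared fixtures, built in code at test time.

# A deterministic 100-frame toy with generic (non-symmetric) bouts.
toyBehavior <- function(nFrames = 100L, frameRate = 10) {
  bouts <- BoutList(cbind(start_s = c(1.0, 4.2, 7.1),
                          end_s = c(2.3, 5.0, 8.6)),
                    sessionDuration = nFrames / frameRate)
  makeBehaviorVector(bouts, frameRate, nFrames)
}

# Brute-force cosine null over all circular shifts (the independent oracle
# for the FFT-based implementation).
bruteForceShiftCosines <- function(trace, bvals) {
  n <- length(trace)
  vapply(seq_len(n - 1L), function(s) {
    shifted <- c(trace[(n - s + 1L):n], trace[1L:(n - s)])
    sum(shifted * bvals) / (sqrt(sum(shifted^2)) * sqrt(sum(bvals^2)))
  }, numeric(1))
}

# Small raw TraceMatrix from explicit rows.
rawTraces <- function(rows, frameRate = 10, sessionId = "toy") {
  TraceMatrix(rows, frameRate = frameRate, sessionId = sessionId)
}
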