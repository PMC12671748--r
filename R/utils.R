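# Internal numeric helpers shared across modules.

# Round half away from zero (for non-negative x: half-up), the convention used
# for all displayed percentages and concentrations. base::round() rounds half
# to even, which does not reproduce printed values such as 16.3 for 49/300.
# The inner round(, 9) absorbs binary representation error (e.g. 0.15 * 10
# is 1.4999999999999998) before the half is added.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(round(x * p, 9) + 0.5) / p
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

semOf <- function(x) stats::sd(x) / sqrt(length(x))

# Rotate a vector right by `s` positions: element t of the result is
# x[(t - s - 1) mod n + 1]. Offset 0 returns x unchanged.
rotateVec <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0L) return(x)
  c(x[(n - s + 1L):n], x[1L:(n - s)])
}

# Dot products of every circular rotation of x against b in O(n log n):
# result[s + 1] == sum(rotateVec(x, s) * b) for s = 0 .. n-1.
circularLagDots <- function(x, b) {
  n <- length(x)
  Re(stats::fft(Conj(stats::fft(x)) * stats::fft(b), inverse = TRUE)) / n
}

isConstant <- function(x) max(x) - min(x) == 0
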