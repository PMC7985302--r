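# Shared oracles and fixtures, built in code at test time.

# draws from N(0, S) via Cholesky
rmvnOracle <- function(n, S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * nrow(S)), n) %*% chol(S)
}

# Rayleigh moments under the package convention (quadrature variance
# sigma^2): E[A^k] = sigma^k * 2^(k/2) * gamma(1 + k/2)
rayleighMoment <- function(k, sigma) sigma^k * 2^(k / 2) * gamma(1 + k / 2)

# Gaussian MI via differential entropies, an independent route to the same
# quantity as the determinant-ratio closed form
gaussMIEntropyOracle <- function(S, dx) {
  d <- nrow(S)
  h <- function(M) 0.5 * log((2 * pi * exp(1))^nrow(M) * det(M))
  h(S[1:dx, 1:dx, drop = FALSE]) +
    h(S[(dx + 1):d, (dx + 1):d, drop = FALSE]) - h(S)
}

# covariance of two 2-D blocks with matched-component correlation r
cov2Blocks <- function(r) {
  S <- diag(4)
  S[1, 3] <- S[3, 1] <- r
  S[2, 4] <- S[4, 2] <- r
  S
}

# small memoised store for expensive shared computations
.fixtureEnv <- new.env(parent = emptyenv())
fixtureCache <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, force(expr), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

# a small white-noise recording
whiteRecording <- function(nch = 2, n = 400, fs = 20, seed = 1) {
  set.seed(seed)
  multiChannelRecording(matrix(rnorm(nch * n), nch), fs = fs,
                        channelNames = LETTERS[seq_len(nch)])
}
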