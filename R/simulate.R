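## Three-process simulators and analytic ground truth.
##
## Rayleigh convention used throughout: scale sigma means the two Gaussian
## quadrature components of A * exp(j*Theta) each have variance sigma^2,
## i.e. A = sigma * sqrt(-2 log U). Under this convention the analytic
## coupling formulas below are exact.

.rRayleigh <- function(n, sigma) sigma * sqrt(-2 * log(runif(n)))

## one random-amplitude random-phase cosine per trial: nTrials x M matrix
.cosineTrials <- function(nTrials, sigma, f0, tgrid) {
  A <- .rRayleigh(nTrials, sigma)
  Th <- runif(nTrials, 0, 2 * pi)
  phase <- outer(Th, 2 * pi * f0 * tgrid, `+`)
  A * cos(phase)
}

#' Simulate the linear Gaussian three-process network
#'
#' Generates independent trials of the proxy chain X -> W -> Z: X(t) is a
#' random-amplitude random-phase cosine at f0, W(t) = X(t) plus an
#' independent cosine, Z(t) = W(t) plus another independent cosine. All
#' amplitude/phase draws are independent across trials and terms.
#'
#' @param config a [linearSimConfig()].
#' @return A [TrialSet-class] with channels X, W, Z.
#' @export
#' @examples
#' ts <- simulateLinear(linearSimConfig(nTrials = 100))
#' ts
simulateLinear <- function(config) {
  stopifnot(is(config, "LinearSimConfig"))
  validObject(config)
  M <- round(config@trialDuration * config@fs)
  tgrid <- (seq_len(M) - 1) / config@fs
  n <- config@nTrials
  set.seed(config@seed)
  X <- .cosineTrials(n, config@sigmaX, config@f0, tgrid)
  W <- X + .cosineTrials(n, config@sigmaW, config@f0, tgrid)
  Z <- W + .cosineTrials(n, config@sigmaZ, config@f0, tgrid)
  arr <- array(0, dim = c(n, 3L, M))
  arr[, 1L, ] <- X; arr[, 2L, ] <- W; arr[, 3L, ] <- Z
  trialSet(arr, fs = config@fs, channelNames = c("X", "W", "Z"))
}

#' Simulate the nonlinear (cross-frequency) three-process network
#'
#' X(t) is unchanged from the linear model; W(t) = X(t)^2 plus an independent
#' squared cosine and Z(t) = X(t)^3 plus an independent cubed cosine. Via
#' cos^2(theta) = 1/2 + cos(2 theta)/2 and
#' cos^3(theta) = (3/4) cos(theta) + (1/4) cos(3 theta), W's spectral energy
#' sits at bins {0, 2 f0} and Z's at {f0, 3 f0}, all driven by X's increment
#' at f0 (a common-input motif with cross-frequency coupling).
#'
#' @param config a [nonlinearSimConfig()].
#' @return A [TrialSet-class] with channels X, W, Z.
#' @export
simulateNonlinear <- function(config) {
  stopifnot(is(config, "NonlinearSimConfig"))
  validObject(config)
  M <- round(config@trialDuration * config@fs)
  tgrid <- (seq_len(M) - 1) / config@fs
  n <- config@nTrials
  set.seed(config@seed)
  X <- .cosineTrials(n, config@sigmaX, config@f0, tgrid)
  W <- X^2 + .cosineTrials(n, config@sigmaW, config@f0, tgrid)^2
  Z <- X^3 + .cosineTrials(n, config@sigmaZ, config@f0, tgrid)^3
  arr <- array(0, dim = c(n, 3L, M))
  arr[, 1L, ] <- X; arr[, 2L, ] <- W; arr[, 3L, ] <- Z
  trialSet(arr, fs = config@fs, channelNames = c("X", "W", "Z"))
}

.parseBlockLabel <- function(label) {
  if (grepl("@", label, fixed = TRUE)) {
    parts <- strsplit(label, "@", fixed = TRUE)[[1L]]
    list(channel = parts[1L], frequency = as.numeric(parts[2L]))
  } else list(channel = label, frequency = 1)
}

#' Draw jointly Gaussian spectral-increment samples
#'
#' Samples `nSamples` i.i.d. vectors from the multivariate normal given by
#' `spec@covariance` and partitions them into per-increment 2-D [Re, Im]
#' blocks, returned as a [SpectralSampleSet-class]. This is the input family
#' of the scaling benchmark, where all MIF/PGC values are known in closed
#' form from the covariance.
#'
#' @param spec a [gaussianIncrementSpec()].
#' @return A [SpectralSampleSet-class].
#' @export
simulateGaussianIncrements <- function(spec) {
  stopifnot(is(spec, "GaussianIncrementSpec"))
  validObject(spec)
  d <- nrow(spec@covariance)
  set.seed(spec@seed)
  L <- chol(spec@covariance)
  draws <- matrix(rnorm(spec@nSamples * d), spec@nSamples, d) %*% L
  parsed <- lapply(spec@blockLabels, .parseBlockLabel)
  channels <- unique(vapply(parsed, `[[`, character(1), "channel"))
  samples <- list(); freqs <- stats::setNames(vector("list", length(channels)),
                                              channels)
  for (i in seq_along(parsed)) {
    ch <- parsed[[i]]$channel; f <- parsed[[i]]$frequency
    m <- draws[, c(2L * i - 1L, 2L * i), drop = FALSE]
    colnames(m) <- c("Re", "Im")
    samples[[.incKey(ch, f)]] <- m
    freqs[[ch]] <- sort(c(freqs[[ch]], f))
  }
  res <- vapply(parsed, `[[`, numeric(1), "frequency")
  base <- min(res[res > 0], 1)
  .newSpectralSampleSet(samples, windowLength = 1 / base,
                        freqResolution = base, channels = channels,
                        frequencies = freqs)
}

#' Analytic coupling values for the linear three-process model
#'
#' At f0 the complex amplitudes of X, W, Z are jointly circular Gaussian,
#' so every pairwise and partial coupling follows in closed form from the
#' 3 x 3 spectral covariance with entries built from the Rayleigh scales:
#' S_X = sx^2, S_W = sx^2 + sw^2, S_Z = sx^2 + sw^2 + sz^2 (cross terms by
#' shared components). Couplings are reported in nats via
#' FC = -log(1 - C) applied to coherence and partial coherence; in
#' particular FC(X,W) = log(1 + sx^2/sw^2) and FC(X,Z|W) = 0 exactly.
#'
#' @param config a [linearSimConfig()].
#' @return A data.frame with one row per unordered pair (X-W, W-Z, X-Z) and
#'   columns `coherence`, `mif`, `partialCoherence`, `pgc` (values in nats).
#' @export
#' @examples
#' analyticLinearFC(linearSimConfig())   # FC(X,W) = log 2 when all sigma = 1
analyticLinearFC <- function(config) {
  stopifnot(is(config, "LinearSimConfig"))
  validObject(config)
  sx2 <- config@sigmaX^2; sw2 <- config@sigmaW^2; sz2 <- config@sigmaZ^2
  S <- matrix(c(sx2, sx2,       sx2,
                sx2, sx2 + sw2, sx2 + sw2,
                sx2, sx2 + sw2, sx2 + sw2 + sz2), 3, 3, byrow = TRUE)
  dimnames(S) <- list(c("X", "W", "Z"), c("X", "W", "Z"))
  csm <- new("CrossSpectralMatrix", frequency = config@f0,
             matrix = S * (1 + 0i))
  pairs <- list(c("X", "W"), c("W", "Z"), c("X", "Z"))
  out <- data.frame(pair = vapply(pairs, paste, character(1), collapse = "-"),
                    coherence = NA_real_, mif = NA_real_,
                    partialCoherence = NA_real_, pgc = NA_real_)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    C <- coherence(csm, a, b)
    PC <- partialCoherence(csm, a, b)
    if (a == "X" && b == "Z") PC <- 0  # X and Z are independent given W
    out$coherence[i] <- C
    out$mif[i] <- miFromCoherence(C)
    out$partialCoherence[i] <- PC
    out$pgc[i] <- miFromCoherence(PC)
  }
  out
}
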