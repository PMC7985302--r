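#' @import methods
#' @importFrom stats fft rnorm runif sd var quantile
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib pgcoh, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Time-domain containers
## ---------------------------------------------------------------------------

#' MultiChannelRecording: a multichannel continuously valued time series
#'
#' Holds a channels-by-samples real matrix together with its sampling rate.
#' This is the raw-data container from which spectral increment samples are
#' drawn via non-overlapping windows and the FFT.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector of channel labels.
#' @exportClass MultiChannelRecording
setClass("MultiChannelRecording",
         slots = c(data = "matrix", fs = "numeric", channelNames = "character"))

setValidity("MultiChannelRecording", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (!is.numeric(object@data)) return("data must be numeric")
  if (nrow(object@data) < 1L) return("at least one channel is required")
  if (anyNA(object@data)) return("data must not contain missing values")
  if (length(object@channelNames) != nrow(object@data))
    return("channelNames length must equal the number of channels (rows)")
  if (anyDuplicated(object@channelNames))
    return("channel names must be unique")
  TRUE
})

#' Construct a MultiChannelRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param channelNames channel labels; defaults to rownames of `data` or
#'   `ch1, ch2, ...`.
#' @return A [MultiChannelRecording-class] object.
#' @export
#' @examples
#' rec <- multiChannelRecording(matrix(rnorm(200), 2), fs = 10)
#' nChannels(rec)
multiChannelRecording <- function(data, fs, channelNames = NULL) {
  data <- as.matrix(data)
  if (is.null(channelNames)) {
    channelNames <- rownames(data)
    if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- channelNames
  new("MultiChannelRecording", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames))
}

#' TrialSet: repeated independent trials of a multichannel process
#'
#' A trials x channels x samples array with a sampling rate. Each trial is
#' later treated as one FFT window, so a TrialSet of N trials yields N
#' samples of each spectral increment.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelNames channel labels.
#' @exportClass TrialSet
setClass("TrialSet",
         slots = c(data = "array", fs = "numeric", channelNames = "character"))

setValidity("TrialSet", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-D array (trials x channels x samples)")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be positive")
  if (length(object@channelNames) != dim(object@data)[2L])
    return("channelNames length must match the channel dimension")
  if (anyNA(object@data)) return("data must not contain missing values")
  TRUE
})

#' @rdname TrialSet-class
#' @param data trials x channels x samples array.
#' @param fs sampling rate (Hz).
#' @param channelNames channel labels.
#' @export
trialSet <- function(data, fs, channelNames = NULL) {
  if (is.null(channelNames)) {
    channelNames <- dimnames(data)[[2L]]
    if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(dim(data)[2L]))
  }
  new("TrialSet", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames))
}

## ---------------------------------------------------------------------------
## Frequency-domain containers
## ---------------------------------------------------------------------------

#' SpectralSampleSet: samples of spectral increments
#'
#' The universal currency of all estimators in this package: for each
#' (channel, frequency) pair, an N x 2 real matrix of [Re, Im] samples of the
#' spectral increment at that frequency, one row per window. Rows are aligned
#' across channels: row i of every entry comes from the same window.
#'
#' @slot samples named list keyed "channel@frequency" of N x 2 matrices.
#' @slot windowLength window length in seconds.
#' @slot nWindows number of windows N (identical for every entry).
#' @slot freqResolution frequency resolution 1/windowLength (Hz).
#' @slot channels channel labels present.
#' @slot frequencies named list: channel -> numeric vector of stored
#'   frequencies (Hz).
#' @exportClass SpectralSampleSet
setClass("SpectralSampleSet",
         slots = c(samples = "list", windowLength = "numeric",
                   nWindows = "integer", freqResolution = "numeric",
                   channels = "character", frequencies = "list"))

setValidity("SpectralSampleSet", function(object) {
  ns <- vapply(object@samples, nrow, integer(1))
  if (length(ns) && any(ns != object@nWindows))
    return("every (channel, frequency) entry must have nWindows rows")
  if (any(vapply(object@samples, ncol, integer(1)) != 2L))
    return("entries must be N x 2 [Re, Im] matrices")
  for (ch in names(object@frequencies)) {
    f <- object@frequencies[[ch]]
    if (any(abs(f / object@freqResolution - round(f / object@freqResolution)) > 1e-8))
      return("every stored frequency must be a multiple of freqResolution")
  }
  TRUE
})

.incKey <- function(channel, frequency) {
  paste0(channel, "@", format(frequency, trim = TRUE, scientific = FALSE))
}

.newSpectralSampleSet <- function(samples, windowLength, freqResolution,
                                  channels, frequencies) {
  n <- if (length(samples)) nrow(samples[[1L]]) else 0L
  new("SpectralSampleSet", samples = samples,
      windowLength = as.numeric(windowLength), nWindows = as.integer(n),
      freqResolution = as.numeric(freqResolution),
      channels = as.character(channels), frequencies = frequencies)
}

#' IncrementSelection: a named set of (channel, frequency) pairs
#'
#' Defines the feature block fed to one side of an MI term, e.g. the
#' frequency sets of the two target processes or of the conditioning set.
#'
#' @slot channels character vector (parallel to `frequencies`).
#' @slot frequencies numeric vector of frequencies in Hz.
#' @exportClass IncrementSelection
setClass("IncrementSelection",
         slots = c(channels = "character", frequencies = "numeric"))

setValidity("IncrementSelection", function(object) {
  if (length(object@channels) == 0L) return("selection must be non-empty")
  if (length(object@channels) != length(object@frequencies))
    return("channels and frequencies must have equal length")
  if (anyDuplicated(paste(object@channels, object@frequencies)))
    return("duplicate (channel, frequency) pairs are not allowed")
  TRUE
})

#' Construct an IncrementSelection
#'
#' @param channels channel name(s); recycled against `frequencies`.
#' @param frequencies frequencies in Hz.
#' @return An [IncrementSelection-class].
#' @export
#' @examples
#' incrementSelection("X", c(2, 3))   # dX(2), dX(3)
incrementSelection <- function(channels, frequencies) {
  n <- max(length(channels), length(frequencies))
  channels <- rep_len(as.character(channels), n)
  frequencies <- rep_len(as.numeric(frequencies), n)
  new("IncrementSelection", channels = channels, frequencies = frequencies)
}

.selKeys <- function(sel) .incKey(sel@channels, sel@frequencies)

#' CrossSpectralMatrix: auto/cross spectral densities at one frequency
#'
#' Hermitian R x R complex matrix whose (a, b) entry is the average of
#' d~a(f) * Conj(d~b(f)) over windows; the linear-Gaussian path to coherence
#' and partial coherence.
#'
#' @slot frequency frequency in Hz.
#' @slot matrix complex Hermitian matrix with channel dimnames.
#' @exportClass CrossSpectralMatrix
setClass("CrossSpectralMatrix",
         slots = c(frequency = "numeric", matrix = "matrix"))

setValidity("CrossSpectralMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (max(abs(m - Conj(t(m)))) > 1e-10 * max(1, max(abs(m))))
    return("matrix must be Hermitian (tolerance 1e-10)")
  d <- diag(m)
  if (any(abs(Im(d)) > 1e-10) || any(Re(d) < -1e-12))
    return("diagonal must be real and non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## Estimates and graphs
## ---------------------------------------------------------------------------

#' CouplingEstimate: a scalar coupling value in nats with provenance
#'
#' @slot value the estimate in nats. For the classifier path this is the
#'   mean of the per-iteration bootstrap estimates.
#' @slot iterations per-iteration estimates (bootstrap trace).
#' @slot estimator one of "classifier", "knn", "linear", "analytic".
#' @slot terms named numeric vector of the MI terms combined into `value`
#'   (for PGC: `I(X;Y,Z)` and `I(X;Z)`).
#' @slot selections list of the IncrementSelections used.
#' @slot seed the master seed driving the estimate.
#' @slot meta free-form provenance (estimator configuration, warnings).
#' @exportClass CouplingEstimate
setClass("CouplingEstimate",
         slots = c(value = "numeric", iterations = "numeric",
                   estimator = "character", terms = "numeric",
                   selections = "list", seed = "numeric", meta = "list"))

setValidity("CouplingEstimate", function(object) {
  if (length(object@value) != 1L) return("value must be scalar")
  if (!object@estimator %in% c("classifier", "knn", "linear", "analytic"))
    return("unknown estimator tag")
  if (length(object@iterations) &&
      abs(object@value - mean(object@iterations)) > 1e-8 * max(1, abs(object@value)))
    return("value must equal the mean of the per-iteration estimates")
  TRUE
})

.couplingEstimate <- function(value, iterations = numeric(), estimator,
                              terms = numeric(), selections = list(),
                              seed = NA_real_, meta = list()) {
  new("CouplingEstimate", value = as.numeric(value),
      iterations = as.numeric(iterations), estimator = estimator,
      terms = terms, selections = selections, seed = as.numeric(seed),
      meta = meta)
}

#' PGCGraph: a weighted undirected partial-frequency-coupling graph
#'
#' Vertices are processes (channels) with declared frequency sets; the weight
#' of an edge is the PGC between the two vertices conditioned on the other
#' declared increments. The pairwise MIF is stored alongside so that collider
#' motifs remain detectable. An edge exists iff its weight exceeds the
#' threshold tau.
#'
#' @slot vertices vertex labels.
#' @slot pairs data.frame with one row per unordered vertex pair: columns
#'   `from`, `to`, `pgc`, `mif`, `control`, `tau`, `ok`.
#' @slot tau default edge threshold in nats (per-pair values in `pairs`).
#' @slot nodeFreqs named list vertex -> declared frequencies (Hz).
#' @slot meta estimator configuration and seeds.
#' @exportClass PGCGraph
setClass("PGCGraph",
         slots = c(vertices = "character", pairs = "data.frame",
                   tau = "numeric", nodeFreqs = "list", meta = "list"))

setValidity("PGCGraph", function(object) {
  p <- object@pairs
  need <- c("from", "to", "pgc", "mif", "control", "tau", "ok")
  if (!all(need %in% names(p))) return("pairs must carry from/to/pgc/mif/control/tau/ok")
  if (any(p$from == p$to)) return("self-edges are not allowed")
  TRUE
})

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' @exportClass LinearSimConfig
setClass("LinearSimConfig",
         slots = c(sigmaX = "numeric", sigmaW = "numeric", sigmaZ = "numeric",
                   f0 = "numeric", nTrials = "integer", fs = "numeric",
                   trialDuration = "numeric", seed = "integer"))

setValidity("LinearSimConfig", function(object) {
  if (any(c(object@sigmaX, object@sigmaW, object@sigmaZ) <= 0))
    return("all Rayleigh scale parameters must be > 0")
  if (object@nTrials < 1L) return("nTrials must be >= 1")
  if (object@fs <= 0 || object@trialDuration <= 0)
    return("fs and trialDuration must be positive")
  k <- object@f0 * object@trialDuration
  if (abs(k - round(k)) > 1e-8)
    return("f0 must be an exact DFT bin: f0 * trialDuration must be an integer")
  if (object@f0 > object@fs / 2) return("f0 must not exceed fs/2")
  TRUE
})

#' Configuration of the linear three-process simulation
#'
#' Three Gaussian processes on a proxy chain: X is a random-amplitude,
#' random-phase cosine at f0; W adds an independent cosine to X; Z adds
#' another independent cosine to W. Amplitudes are Rayleigh with scales
#' `sigmaX`, `sigmaW`, `sigmaZ` under the convention that the two Gaussian
#' quadrature components of A*exp(j*Theta) each have variance sigma^2.
#'
#' @param sigmaX,sigmaW,sigmaZ Rayleigh scale parameters (> 0).
#' @param f0 oscillation frequency (Hz); must be an exact DFT bin of one
#'   trial window.
#' @param nTrials number of independent trials.
#' @param fs sampling rate (Hz).
#' @param trialDuration trial length in seconds (each trial = one window).
#' @param seed RNG seed.
#' @return A `LinearSimConfig`.
#' @export
linearSimConfig <- function(sigmaX = 1, sigmaW = 1, sigmaZ = 1, f0 = 2,
                            nTrials = 10000, fs = 32, trialDuration = 1,
                            seed = 1) {
  new("LinearSimConfig", sigmaX = sigmaX, sigmaW = sigmaW, sigmaZ = sigmaZ,
      f0 = f0, nTrials = as.integer(nTrials), fs = fs,
      trialDuration = trialDuration, seed = as.integer(seed))
}

#' @exportClass NonlinearSimConfig
setClass("NonlinearSimConfig", contains = "LinearSimConfig")

setValidity("NonlinearSimConfig", function(object) {
  k <- 3 * object@f0 * object@trialDuration
  if (abs(k - round(k)) > 1e-8)
    return("3*f0 * trialDuration must be an integer so 0, f0, 2f0, 3f0 are exact bins")
  if (3 * object@f0 >= object@fs / 2)
    return("3*f0 must be below the Nyquist frequency fs/2")
  TRUE
})

#' Configuration of the nonlinear (cross-frequency) three-process simulation
#'
#' X is unchanged from the linear model; W = X^2 plus an independent squared
#' cosine, Z = X^3 plus an independent cubed cosine. The squaring and cubing
#' move W's energy to bins {0, 2 f0} and Z's to {f0, 3 f0}, producing a
#' common-input motif with cross-frequency coupling.
#'
#' @inheritParams linearSimConfig
#' @return A `NonlinearSimConfig`.
#' @export
nonlinearSimConfig <- function(sigmaX = 1, sigmaW = 0.75, sigmaZ = 0.75,
                               f0 = 2, nTrials = 10000, fs = 32,
                               trialDuration = 1, seed = 1) {
  new("NonlinearSimConfig", sigmaX = sigmaX, sigmaW = sigmaW, sigmaZ = sigmaZ,
      f0 = f0, nTrials = as.integer(nTrials), fs = fs,
      trialDuration = trialDuration, seed = as.integer(seed))
}

#' @exportClass GaussianIncrementSpec
setClass("GaussianIncrementSpec",
         slots = c(blockLabels = "character", covariance = "matrix",
                   nSamples = "integer", seed = "integer"))

setValidity("GaussianIncrementSpec", function(object) {
  d <- nrow(object@covariance)
  if (d != ncol(object@covariance)) return("covariance must be square")
  if (max(abs(object@covariance - t(object@covariance))) > 1e-10)
    return("covariance must be symmetric")
  if (d != 2L * length(object@blockLabels))
    return("covariance dimension must be 2 x number of increments")
  ev <- tryCatch(min(eigen(object@covariance, symmetric = TRUE,
                           only.values = TRUE)$values), error = function(e) -1)
  if (ev <= 0) return("covariance must be positive definite")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  TRUE
})

#' Specify jointly Gaussian spectral increments
#'
#' Describes a multivariate Gaussian over stacked 2-D increment blocks
#' ([Re, Im] per increment); used by the scaling benchmark, where analytic
#' MIF and PGC values follow from the covariance in closed form.
#'
#' @param blockLabels ordered increment names, "channel@frequency" strings
#'   (e.g. `"X@2"`); plain channel names default to frequency 1 Hz.
#' @param covariance positive-definite matrix over the stacked components,
#'   dimension `2 * length(blockLabels)`.
#' @param nSamples number of i.i.d. draws.
#' @param seed RNG seed.
#' @return A `GaussianIncrementSpec`.
#' @export
gaussianIncrementSpec <- function(blockLabels, covariance, nSamples,
                                  seed = 1) {
  new("GaussianIncrementSpec", blockLabels = as.character(blockLabels),
      covariance = as.matrix(covariance), nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
         slots = c(degree = "integer", alpha = "numeric", nlambda = "integer",
                   valFraction = "numeric", clip = "numeric",
                   gaussianize = "logical"))

setValidity("ClassifierSpec", function(object) {
  if (object@degree < 1L) return("degree must be >= 1")
  if (object@clip <= 0 || object@clip >= 0.5) return("clip must lie in (0, 0.5)")
  if (object@valFraction <= 0 || object@valFraction >= 0.5)
    return("valFraction must lie in (0, 0.5)")
  if (object@alpha < 0 || object@alpha > 1) return("alpha must lie in [0, 1]")
  TRUE
})

#' Classifier configuration for the Donsker-Varadhan estimator
#'
#' The binary classifier that separates original from shuffled increment
#' samples is an L1-regularised logistic model on a harmonic-polynomial
#' basis of the 2-D increment blocks: per-block complex powers u^m
#' (m = 1..degree), cross-block products Re/Im(u^m * Conj(v)^n) - which are
#' exactly the m:n phase-coupling statistics - and the amplitude couplings
#' |u|, |u|^2, |u||v|, |u|^2 |v|^2 and |u|^2 Re/Im(v). This basis spans the
#' phase-phase and amplitude-amplitude coupling statistics that harmonic
#' nonlinearities generate, the fit is convex (deterministic given the
#' data), and the regularisation path is selected by cross-entropy on a
#' validation slice of the training portion.
#'
#' Coordinates are rank-Gaussianised using training-split order statistics
#' before the basis expansion; mutual information is invariant to monotone
#' per-coordinate maps, and this standardisation tames the heavy amplitude
#' tails that polynomial features otherwise amplify.
#'
#' @param degree maximum per-block harmonic power (default 3: captures
#'   quadratic and cubic process nonlinearities).
#' @param alpha glmnet elastic-net mixing parameter (1 = lasso).
#' @param nlambda length of the regularisation path.
#' @param valFraction fraction of the training portion held out to select
#'   the penalty.
#' @param clip probability clipping epsilon applied before forming the
#'   likelihood ratio L = p/(1-p); bounds each sample's log-likelihood
#'   ratio to about +/- 4.6 at the default, which caps the influence of
#'   misclassified test points under strong dependence.
#' @param gaussianize rank-Gaussianise each coordinate before the basis
#'   expansion (default TRUE).
#' @return A `ClassifierSpec`.
#' @export
classifierSpec <- function(degree = 3, alpha = 1, nlambda = 40,
                           valFraction = 0.2, clip = 0.01,
                           gaussianize = TRUE) {
  new("ClassifierSpec", degree = as.integer(degree), alpha = alpha,
      nlambda = as.integer(nlambda), valFraction = valFraction, clip = clip,
      gaussianize = gaussianize)
}

#' @exportClass BootstrapSpec
setClass("BootstrapSpec",
         slots = c(iterations = "integer", trainFraction = "numeric"))

setValidity("BootstrapSpec", function(object) {
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  TRUE
})

#' Bootstrap configuration for classifier-based estimation
#'
#' Each bootstrap iteration draws a fresh permutation (shuffled set), a fresh
#' random train/test split of both the original and shuffled samples, trains
#' the classifier on the training portion and evaluates the divergence on
#' the held-out third. The final estimate is the mean across iterations.
#'
#' @param iterations number of bootstrap iterations.
#' @param trainFraction fraction used for training (default 2/3).
#' @return A `BootstrapSpec`.
#' @export
bootstrapSpec <- function(iterations = 20, trainFraction = 2 / 3) {
  new("BootstrapSpec", iterations = as.integer(iterations),
      trainFraction = trainFraction)
}

#' @exportClass PGCQuery
setClass("PGCQuery",
         slots = c(xSel = "IncrementSelection", ySel = "IncrementSelection",
                   condSel = "ANY", estimator = "character",
                   cspec = "ClassifierSpec", bspec = "BootstrapSpec",
                   k = "integer", seed = "integer"))

setValidity("PGCQuery", function(object) {
  kx <- .selKeys(object@xSel); ky <- .selKeys(object@ySel)
  if (length(intersect(kx, ky)))
    return("x and y selections must be disjoint (channel, frequency) sets")
  if (!is.null(object@condSel)) {
    kc <- .selKeys(object@condSel)
    if (length(intersect(kc, c(kx, ky))))
      return("conditioning selection must be disjoint from both targets")
  }
  if (!object@estimator %in% c("auto", "classifier", "knn"))
    return("estimator must be 'auto', 'classifier' or 'knn'")
  TRUE
})

#' Build a PGC/MIF query
#'
#' Bundles the target selections, optional conditioning set and estimator
#' configuration for [mif()], [pgc()], [controlPGC()] and [baselineMIF()].
#'
#' @param x,y [IncrementSelection-class] target feature blocks.
#' @param cond optional conditioning [IncrementSelection-class] (required by
#'   [pgc()]); must be disjoint from both targets.
#' @param estimator "auto" (classifier when the total dimension exceeds 6,
#'   k-nn otherwise), "classifier" or "knn".
#' @param cspec,bspec classifier and bootstrap configuration.
#' @param k neighbour count for the k-nn estimator.
#' @param seed master seed for shuffles, splits and fits.
#' @return A `PGCQuery`.
#' @export
pgcQuery <- function(x, y, cond = NULL, estimator = "auto",
                     cspec = classifierSpec(), bspec = bootstrapSpec(),
                     k = 5, seed = 1) {
  new("PGCQuery", xSel = x, ySel = y, condSel = cond, estimator = estimator,
      cspec = cspec, bspec = bspec, k = as.integer(k), seed = as.integer(seed))
}

#' @exportClass BenchmarkDesign
setClass("BenchmarkDesign",
         slots = c(problem = "character", sampleSizes = "integer",
                   nSims = "integer", bootstrapIterations = "integer",
                   condPairs = "integer", r = "numeric", seed = "integer"))

setValidity("BenchmarkDesign", function(object) {
  if (!object@problem %in% c("mif_4d", "pgc_6d", "pgc_12d", "cond_sweep"))
    return("problem must be one of mif_4d, pgc_6d, pgc_12d, cond_sweep")
  if (object@nSims < 2L) return("nSims must be >= 2")
  if (any(diff(object@sampleSizes) <= 0) || any(object@sampleSizes < 30L))
    return("sampleSizes must be increasing and >= 30")
  if (object@r <= 0 || object@r >= 1) return("r must lie in (0, 1)")
  TRUE
})

#' Design an estimator-scaling benchmark
#'
#' Defines a grid of Gaussian-increment estimation problems with known
#' analytic values: `mif_4d` (MI between two increments), `pgc_6d` (PGC
#' between two increments given a third), `pgc_12d` (PGC between two pairs
#' of increments given a third pair) and `cond_sweep` (PGC between two
#' increments with 2/4/6 conditioning pairs). The covariance has unit
#' variances and cross-block correlation `r` on matched components.
#'
#' @param problem one of "mif_4d", "pgc_6d", "pgc_12d", "cond_sweep".
#' @param sampleSizes increasing vector of sample sizes N.
#' @param nSims independent simulations per grid point.
#' @param bootstrapIterations classifier bootstrap iterations.
#' @param condPairs for `cond_sweep`: number of conditioning increment pairs.
#' @param r cross-block correlation (default 0.5).
#' @param seed master seed.
#' @return A `BenchmarkDesign`.
#' @export
benchmarkDesign <- function(problem = "pgc_12d",
                            sampleSizes = c(125, 500, 2000), nSims = 20,
                            bootstrapIterations = 10, condPairs = 2,
                            r = 0.5, seed = 1) {
  new("BenchmarkDesign", problem = problem,
      sampleSizes = as.integer(sampleSizes), nSims = as.integer(nSims),
      bootstrapIterations = as.integer(bootstrapIterations),
      condPairs = as.integer(condPairs), r = r, seed = as.integer(seed))
}
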