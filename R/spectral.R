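## Windowing and spectral-increment sampling.
##
## DFT convention: the coefficient at bin k is (1/M) * sum_t x_t exp(-2pi i
## k t / M) with M the window sample count, so a unit cosine occupying an
## exact bin yields the sample [1/2, 0]. MI is invariant to any fixed
## invertible per-block scaling, but one convention must be fixed for the
## linear-coherence path; this is it.

#' Split a recording into non-overlapping windows
#'
#' @param rec a [MultiChannelRecording-class].
#' @param windowLength window length in seconds; `windowLength * fs` must be
#'   a positive integer.
#' @return A list of channels x windowSamples matrices, one per window,
#'   contiguous and non-overlapping; a trailing remainder shorter than one
#'   window is discarded.
#' @export
#' @examples
#' rec <- multiChannelRecording(matrix(rnorm(107), 1), fs = 10)
#' length(segmentWindows(rec, 1))  # 10 windows, 7 samples dropped
segmentWindows <- function(rec, windowLength) {
  stopifnot(is(rec, "MultiChannelRecording"))
  M <- windowLength * rec@fs
  if (abs(M - round(M)) > 1e-8 || M <= 0)
    stop("windowLength * fs must be a positive integer", call. = FALSE)
  M <- as.integer(round(M))
  nW <- nSamples(rec) %/% M
  if (nW < 1L)
    stop("recording is shorter than one window (", nSamples(rec),
         " samples < ", M, ")", call. = FALSE)
  lapply(seq_len(nW), function(w)
    rec@data[, ((w - 1L) * M + 1L):(w * M), drop = FALSE])
}

.checkBins <- function(frequencies, windowLength, fs) {
  res <- 1 / windowLength
  for (f in frequencies) {
    k <- f / res
    if (abs(k - round(k)) > 1e-8) {
      lo <- floor(k) * res; hi <- ceiling(k) * res
      stop(sprintf(
        "%g Hz is not an exact DFT bin for %g s windows; nearest valid bins are %g and %g Hz",
        f, windowLength, lo, hi), call. = FALSE)
    }
    if (f > fs / 2 + 1e-8)
      stop(sprintf("%g Hz exceeds the Nyquist frequency %g Hz", f, fs / 2),
           call. = FALSE)
    if (f < 0) stop("frequencies must be non-negative", call. = FALSE)
  }
  invisible(res)
}

## winArray: N x C x M array of aligned windows; computes the DFT
## coefficients at the requested bins as one complex matrix product per
## channel (equivalent to fft(window)[bin + 1] / M for every window)
.incrementsFromWindows <- function(winArray, channels, windowLength, fs,
                                   frequencies, demean) {
  N <- dim(winArray)[1L]; M <- dim(winArray)[3L]
  bins <- as.integer(round(frequencies * windowLength))
  basis <- exp(-2i * pi * outer(0:(M - 1L), bins) / M) / M
  samples <- list()
  freqs <- stats::setNames(rep(list(sort(frequencies)), length(channels)),
                           channels)
  for (c in seq_along(channels)) {
    x <- matrix(winArray[, c, ], N, M)
    if (demean) x <- x - rowMeans(x)
    coef <- x %*% basis
    for (b in seq_along(bins))
      samples[[.incKey(channels[c], frequencies[b])]] <-
        cbind(Re = Re(coef[, b]), Im = Im(coef[, b]))
  }
  .newSpectralSampleSet(samples, windowLength = windowLength,
                        freqResolution = 1 / windowLength,
                        channels = channels, frequencies = freqs)
}

#' @rdname sampleIncrements
setMethod("sampleIncrements", "MultiChannelRecording",
          function(x, windowLength, frequencies, demean = FALSE) {
  .checkBins(frequencies, windowLength, x@fs)
  M <- as.integer(round(windowLength * x@fs))
  nW <- nSamples(x) %/% M
  if (nW < 1L) stop("recording is shorter than one window", call. = FALSE)
  ## channels x samples -> windows x channels x windowSamples
  arr <- aperm(array(x@data[, seq_len(nW * M), drop = FALSE],
                     dim = c(nChannels(x), M, nW)), c(3L, 1L, 2L))
  .incrementsFromWindows(arr, x@channelNames, windowLength, x@fs,
                         frequencies, demean)
})

#' @rdname sampleIncrements
setMethod("sampleIncrements", "TrialSet",
          function(x, windowLength, frequencies, demean = FALSE) {
  dur <- nSamples(x) / x@fs
  if (!missing(windowLength) && !is.null(windowLength) &&
      abs(windowLength - dur) > 1e-8)
    stop("for a TrialSet each trial is one window; windowLength must equal ",
         dur, " s", call. = FALSE)
  .checkBins(frequencies, dur, x@fs)
  .incrementsFromWindows(x@data, x@channelNames, dur, x@fs, frequencies,
                         demean)
})

#' Z-score a recording in independent fixed-length blocks
#'
#' Each channel is standardised (mean 0, sample SD 1) within each
#' consecutive block of `blockLength` seconds, blocks processed
#' independently; mirrors per-block normalisation of long physiological
#' recordings.
#'
#' @param rec a [MultiChannelRecording-class].
#' @param blockLength block length in seconds; the recording must contain at
#'   least one whole block (a trailing remainder is z-scored as a shorter
#'   final block).
#' @return A [MultiChannelRecording-class] of the same shape.
#' @export
zscoreBlocks <- function(rec, blockLength) {
  stopifnot(is(rec, "MultiChannelRecording"))
  M <- blockLength * rec@fs
  if (abs(M - round(M)) > 1e-8 || M <= 0)
    stop("blockLength * fs must be a positive integer", call. = FALSE)
  M <- as.integer(round(M))
  n <- nSamples(rec)
  if (n < M) stop("recording shorter than one block", call. = FALSE)
  out <- rec@data
  starts <- seq(1L, n, by = M)
  for (s in starts) {
    e <- min(s + M - 1L, n)
    block <- out[, s:e, drop = FALSE]
    mu <- rowMeans(block)
    sdv <- apply(block, 1L, sd)
    if (any(sdv == 0))
      stop("constant channel within a block: ",
           paste(rec@channelNames[sdv == 0], collapse = ", "), call. = FALSE)
    out[, s:e] <- (block - mu) / sdv
  }
  multiChannelRecording(out, rec@fs, rec@channelNames)
}

#' Assemble the feature matrix for an increment selection
#'
#' Extracts and column-binds the stored [Re, Im] blocks for each
#' (channel, frequency) pair of `sel`, in order. Rows are windows, aligned
#' across channels (row i of every block comes from the same window).
#'
#' @param sampleset a [SpectralSampleSet-class].
#' @param sel an [IncrementSelection-class].
#' @return An N x (2 * length(sel)) numeric matrix with columns named
#'   `channel@freq.Re` / `.Im`.
#' @export
selectIncrements <- function(sampleset, sel) {
  stopifnot(is(sampleset, "SpectralSampleSet"), is(sel, "IncrementSelection"))
  keys <- .selKeys(sel)
  missing <- setdiff(keys, names(sampleset@samples))
  if (length(missing))
    stop("selection not resolvable in sample set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  blocks <- lapply(keys, function(k) {
    m <- sampleset@samples[[k]]
    colnames(m) <- paste0(k, c(".Re", ".Im"))
    m
  })
  do.call(cbind, blocks)
}
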