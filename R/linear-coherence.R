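## Linear-Gaussian reference path: coherence, partial coherence, and the
## closed-form transform tying them to MIF/PGC for Gaussian processes.

#' Estimate the cross-spectral matrix at one frequency
#'
#' Entry (a, b) is the mean over windows of d~a(f) * Conj(d~b(f)), i.e. the
#' averaged cross-periodogram under this package's 1/M DFT normalisation;
#' Hermitian and positive semidefinite by construction.
#'
#' @param sampleset a [SpectralSampleSet-class].
#' @param channels channels to include (order fixes the matrix order).
#' @param f frequency in Hz; all channels must be sampled at f.
#' @return A [CrossSpectralMatrix-class].
#' @export
estimateCrossSpectralMatrix <- function(sampleset, channels, f) {
  stopifnot(is(sampleset, "SpectralSampleSet"))
  R <- length(channels)
  N <- nWindows(sampleset)
  if (N < R)
    stop("need at least as many windows as channels (N >= R)", call. = FALSE)
  zs <- lapply(channels, function(ch) {
    m <- incrementSamples(sampleset, ch, f)
    complex(real = m[, 1L], imaginary = m[, 2L])
  })
  S <- matrix(0i, R, R, dimnames = list(channels, channels))
  for (a in seq_len(R)) for (b in seq_len(R))
    S[a, b] <- mean(zs[[a]] * Conj(zs[[b]]))
  S <- (S + Conj(t(S))) / 2  # exact Hermitian symmetry
  new("CrossSpectralMatrix", frequency = f, matrix = S)
}

.csmIndex <- function(S, a) {
  if (is.character(a)) {
    i <- match(a, rownames(S@matrix))
    if (is.na(i)) stop("unknown channel: ", a, call. = FALSE)
    i
  } else as.integer(a)
}

#' Coherence between two channels
#'
#' `|S_ab|^2 / (S_a * S_b)`, real-valued in [0, 1]; the frequency-domain
#' analogue of squared correlation and a full dependence measure only for
#' Gaussian processes.
#'
#' @param S a [CrossSpectralMatrix-class].
#' @param a,b channel names or indices.
#' @return Coherence value in [0, 1].
#' @export
coherence <- function(S, a, b) {
  stopifnot(is(S, "CrossSpectralMatrix"))
  i <- .csmIndex(S, a); j <- .csmIndex(S, b)
  sa <- Re(S@matrix[i, i]); sb <- Re(S@matrix[j, j])
  if (sa <= 0 || sb <= 0)
    stop("zero auto-spectrum: coherence undefined", call. = FALSE)
  min(1, Mod(S@matrix[i, j])^2 / (sa * sb))
}

#' Partial coherence between two channels given all others
#'
#' With P = S^-1, returns `|P_ab|^2 / (P_a * P_b)`: the coherence between a
#' and b with the linear influence of every other channel in S removed.
#'
#' @param S a [CrossSpectralMatrix-class]; must be well conditioned.
#' @param a,b channel names or indices.
#' @param maxCondition condition-number guard for the inversion.
#' @return Partial coherence value in [0, 1].
#' @export
partialCoherence <- function(S, a, b, maxCondition = 1e10) {
  stopifnot(is(S, "CrossSpectralMatrix"))
  i <- .csmIndex(S, a); j <- .csmIndex(S, b)
  m <- S@matrix
  sv <- svd(m, nu = 0, nv = 0)$d
  kappa <- sv[1L] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > maxCondition)
    stop(sprintf(
      "cross-spectral matrix is ill-conditioned (condition number %.3g)",
      kappa), call. = FALSE)
  P <- solve(m)
  pa <- Re(P[i, i]); pb <- Re(P[j, j])
  min(1, Mod(P[i, j])^2 / (pa * pb))
}

#' Transform a (partial) coherence into nats
#'
#' For jointly Gaussian processes the MIF between two increments at the same
#' frequency equals -log(1 - C) with C their coherence, and the PGC equals
#' the same transform of the partial coherence. Natural log: values in nats.
#'
#' @param C coherence value in [0, 1).
#' @return `-log(1 - C)` in nats.
#' @export
#' @examples
#' miFromCoherence(0.5)  # log 2
miFromCoherence <- function(C) {
  if (any(C < 0)) stop("coherence must be non-negative", call. = FALSE)
  if (any(C >= 1))
    stop("coherence must be < 1 for a finite information value", call. = FALSE)
  -log(1 - C)
}
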