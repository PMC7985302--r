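## MIF, PGC and the baseline/control protocols, composed from mi_core.

.queryDims <- function(query, withCond = TRUE) {
  d <- 2L * (length(query@xSel@channels) + length(query@ySel@channels))
  if (withCond && !is.null(query@condSel))
    d <- d + 2L * length(query@condSel@channels)
  d
}

.resolveEstimator <- function(query) {
  if (query@estimator != "auto") return(query@estimator)
  ## classifier scales better past ~6 dimensions; k-nn is preferable below
  if (.queryDims(query) > 6L) "classifier" else "knn"
}

#' Mutual information in frequency (MIF)
#'
#' Estimates I(dX(F_i); dY(F_j)) between the selected increment blocks of
#' `query` (the conditioning selection is ignored) using the configured
#' estimator. MIF is the model-free pairwise frequency-coupling measure:
#' zero iff the selected increments are statistically independent.
#'
#' @param query a [pgcQuery()].
#' @param sampleset a [SpectralSampleSet-class].
#' @return A [CouplingEstimate-class].
#' @export
mif <- function(query, sampleset) {
  stopifnot(is(query, "PGCQuery"))
  validObject(query)
  fx <- selectIncrements(sampleset, query@xSel)
  fy <- selectIncrements(sampleset, query@ySel)
  est <- .resolveEstimator(query)
  out <- if (est == "classifier")
    classifierMI(fx, fy, query@cspec, query@bspec, seed = query@seed)
  else
    knnMI(fx, fy, k = query@k)
  out@selections <- list(x = query@xSel, y = query@ySel)
  out@seed <- as.numeric(query@seed)
  out
}

## Classifier PGC: the two MI terms of the difference reuse identical
## per-iteration seeds, so permutation and split noise is paired and
## largely cancels in the difference.
.classifierPGC <- function(fx, fy, fz, cspec, bspec, seed) {
  set.seed(seed)
  iterSeeds <- sample.int(2^30, bspec@iterations)
  e1 <- vapply(iterSeeds, function(s)
    .dvIteration(fx, cbind(fy, fz), s, cspec, bspec@trainFraction), numeric(1))
  e2 <- vapply(iterSeeds, function(s)
    .dvIteration(fx, fz, s, cspec, bspec@trainFraction), numeric(1))
  keep <- is.finite(e1) & is.finite(e2)
  if (!all(keep)) {
    warning(sum(!keep), " bootstrap iteration(s) returned NaN and were excluded")
    e1 <- e1[keep]; e2 <- e2[keep]
  }
  list(diff = e1 - e2, t1 = mean(e1), t2 = mean(e2), iterSeeds = iterSeeds)
}

#' Partial generalized coherence (PGC)
#'
#' The conditional extension of [mif()]: I(dX(F_i); dY(F_j) | dZ(F_k)),
#' computed as the difference of two MI terms,
#' I(X; Y, Z) - I(X; Z). A PGC of zero means the coupling between the two
#' targets is entirely explained by the conditioning increments (indirect
#' coupling); for jointly Gaussian processes PGC equals
#' -log(1 - partial coherence).
#'
#' For the classifier path both terms share per-iteration seeds (identical
#' permutations and train/test splits), so split noise cancels in the
#' difference; the reported bootstrap trace is the per-iteration difference.
#'
#' @param query a [pgcQuery()] with a non-empty conditioning selection.
#' @param sampleset a [SpectralSampleSet-class].
#' @return A [CouplingEstimate-class]; `miTerms()` carries the two MI terms
#'   and `couplingValue()` equals their difference exactly.
#' @export
pgc <- function(query, sampleset) {
  stopifnot(is(query, "PGCQuery"))
  validObject(query)
  if (is.null(query@condSel))
    stop("pgc requires a non-empty conditioning selection; use mif() for the unconditional value",
         call. = FALSE)
  fx <- selectIncrements(sampleset, query@xSel)
  fy <- selectIncrements(sampleset, query@ySel)
  fz <- selectIncrements(sampleset, query@condSel)
  est <- .resolveEstimator(query)
  if (est == "classifier") {
    r <- .classifierPGC(fx, fy, fz, query@cspec, query@bspec, query@seed)
    out <- .couplingEstimate(mean(r$diff), iterations = r$diff,
                             estimator = "classifier",
                             terms = c(ixyz = r$t1, ixz = r$t2),
                             seed = query@seed,
                             meta = list(cspec = query@cspec,
                                         bspec = query@bspec,
                                         iterSeeds = r$iterSeeds))
  } else {
    t1 <- couplingValue(knnMI(fx, cbind(fy, fz), k = query@k))
    t2 <- couplingValue(knnMI(fx, fz, k = query@k))
    out <- .couplingEstimate(t1 - t2, iterations = t1 - t2,
                             estimator = "knn",
                             terms = c(ixyz = t1, ixz = t2),
                             meta = list(k = query@k))
  }
  out@selections <- list(x = query@xSel, y = query@ySel, cond = query@condSel)
  out
}

#' Control PGC: condition on known-irrelevant frequencies
#'
#' Re-runs [pgc()] with the conditioning selection replaced by the same
#' conditioning channel(s) at `controlFreqs`, frequencies known (or
#' declared) to be independent of the target relationship. Because the
#' dimensionality matches the real conditioning, the control carries the
#' same estimation bias and serves as the bias-matched reference against
#' which a genuine PGC drop is judged.
#'
#' @param query a [pgcQuery()] with a conditioning selection (its channels
#'   are reused).
#' @param sampleset a [SpectralSampleSet-class].
#' @param controlFreqs irrelevant frequencies (Hz) for the conditioning
#'   channel(s).
#' @param controlChannels optionally override the conditioning channel(s).
#' @return A [CouplingEstimate-class].
#' @export
controlPGC <- function(query, sampleset, controlFreqs,
                       controlChannels = NULL) {
  stopifnot(is(query, "PGCQuery"))
  if (is.null(controlChannels)) {
    if (is.null(query@condSel))
      stop("no conditioning channel to derive the control from", call. = FALSE)
    controlChannels <- unique(query@condSel@channels)
  }
  sel <- incrementSelection(rep(controlChannels,
                                each = length(controlFreqs)),
                            rep(controlFreqs, times = length(controlChannels)))
  q2 <- pgcQuery(query@xSel, query@ySel, cond = sel,
                 estimator = query@estimator, cspec = query@cspec,
                 bspec = query@bspec, k = query@k, seed = query@seed)
  out <- pgc(q2, sampleset)
  out@meta$control <- TRUE
  out
}

#' Baseline MIF: pair against irrelevant frequencies
#'
#' Computes [mif()] with the second selection moved to `baselineFreqs` on
#' the same channel(s): coupling between a signal at relevant frequencies
#' and a partner at irrelevant ones. Expected near zero; slightly negative
#' values reflect small estimator bias and are reported as-is. The pairwise
#' null reference against which real MIF values are judged.
#'
#' @param query a [pgcQuery()].
#' @param sampleset a [SpectralSampleSet-class].
#' @param baselineFreqs irrelevant frequencies (Hz) for the partner
#'   channel(s).
#' @return A [CouplingEstimate-class].
#' @export
baselineMIF <- function(query, sampleset, baselineFreqs) {
  stopifnot(is(query, "PGCQuery"))
  chans <- unique(query@ySel@channels)
  sel <- incrementSelection(rep(chans, each = length(baselineFreqs)),
                            rep(baselineFreqs, times = length(chans)))
  q2 <- pgcQuery(query@xSel, sel, cond = NULL, estimator = query@estimator,
                 cspec = query@cspec, bspec = query@bspec, k = query@k,
                 seed = query@seed)
  out <- mif(q2, sampleset)
  out@meta$baseline <- TRUE
  out
}

#' Run a batch of queries
#'
#' @param queries list of [pgcQuery()] objects.
#' @param sampleset a [SpectralSampleSet-class].
#' @return A data.frame with one row per query: pair label, kind
#'   ("mif" or "pgc"), estimator, value (nats) and bootstrap SD.
#' @export
runQueries <- function(queries, sampleset) {
  rows <- lapply(queries, function(q) {
    est <- if (is.null(q@condSel)) mif(q, sampleset) else pgc(q, sampleset)
    lab <- function(sel) paste(unique(sel@channels), collapse = "+")
    data.frame(
      pair = paste(lab(q@xSel), lab(q@ySel), sep = "-"),
      x = paste(.selKeys(q@xSel), collapse = ";"),
      y = paste(.selKeys(q@ySel), collapse = ";"),
      cond = if (is.null(q@condSel)) "" else
        paste(.selKeys(q@condSel), collapse = ";"),
      kind = if (is.null(q@condSel)) "mif" else "pgc",
      estimator = estimatorName(est),
      value = couplingValue(est),
      sd = if (length(bootstrapTrace(est)) > 1L) sd(bootstrapTrace(est))
           else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pair = character(), x = character(), y = character(),
                      cond = character(), kind = character(),
                      estimator = character(), value = numeric(),
                      sd = numeric())
  rownames(out) <- NULL
  out
}
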