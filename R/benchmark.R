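## Estimator scaling benchmark on jointly Gaussian spectral increments with
## closed-form target values: classifier vs k-nn across dimensionality and
## sample size.

## Benchmark covariances: unit variances; matched components of coupled
## blocks correlate with r. Target blocks correlate with the conditioning
## block AND each other (a "triple": partial structure survives
## conditioning), so PGC targets are strictly positive. Block layout is
## [x | y | z], each increment contributing [Re, Im].
.benchProblem <- function(problem, r, condPairs = 2L) {
  triple <- function(d, i, j, k3) {
    ## correlate components i<->j, i<->k3, j<->k3 at r
    m <- diag(d)
    m[i, j] <- m[j, i] <- r
    m[i, k3] <- m[k3, i] <- r
    m[j, k3] <- m[k3, j] <- r
    m
  }
  if (problem == "mif_4d") {
    S <- diag(4)
    S[1, 3] <- S[3, 1] <- r
    S[2, 4] <- S[4, 2] <- r
    return(list(cov = S, dx = 2L, dy = 2L, dz = 0L,
                labels = c("X@1", "Y@1")))
  }
  if (problem == "pgc_6d") {
    S <- diag(6)
    for (c in 0:1) {
      i <- 1L + c; j <- 3L + c; k3 <- 5L + c
      S[i, j] <- S[j, i] <- r; S[i, k3] <- S[k3, i] <- r
      S[j, k3] <- S[k3, j] <- r
    }
    return(list(cov = S, dx = 2L, dy = 2L, dz = 2L,
                labels = c("X@1", "Y@1", "Z@1")))
  }
  if (problem == "pgc_12d") {
    S <- diag(12)
    for (c in 0:3) {
      i <- 1L + c; j <- 5L + c; k3 <- 9L + c
      S[i, j] <- S[j, i] <- r; S[i, k3] <- S[k3, i] <- r
      S[j, k3] <- S[k3, j] <- r
    }
    return(list(cov = S, dx = 4L, dy = 4L, dz = 4L,
                labels = c("X@1", "X@2", "Y@1", "Y@2", "Z@1", "Z@2")))
  }
  if (problem == "cond_sweep") {
    dz <- 2L * condPairs
    d <- 4L + dz
    S <- diag(d)
    for (c in 0:1) {                 # x, y and the first conditioning block
      i <- 1L + c; j <- 3L + c; k3 <- 5L + c
      S[i, j] <- S[j, i] <- r; S[i, k3] <- S[k3, i] <- r
      S[j, k3] <- S[k3, j] <- r
    }
    labels <- c("X@1", "Y@1", paste0("Z@", seq_len(condPairs)))
    return(list(cov = S, dx = 2L, dy = 2L, dz = dz, labels = labels))
  }
  stop("unknown problem: ", problem, call. = FALSE)
}

## analytic target: MI or conditional MI (difference of two Gaussian MIs)
.benchTruth <- function(p) {
  if (p$dz == 0L) return(gaussianMIAnalytic(p$cov, p$dx))
  d <- nrow(p$cov)
  ix <- seq_len(p$dx)
  iy <- p$dx + seq_len(p$dy)
  iz <- p$dx + p$dy + seq_len(p$dz)
  full <- gaussianMIAnalytic(p$cov[c(ix, iy, iz), c(ix, iy, iz)], p$dx)
  xz <- gaussianMIAnalytic(p$cov[c(ix, iz), c(ix, iz)], p$dx)
  full - xz
}

.rmvnorm <- function(n, S) matrix(rnorm(n * nrow(S)), n) %*% chol(S)

#' Run the estimator scaling benchmark
#'
#' For each sample size of the design, simulates `nSims` independent sets
#' of jointly Gaussian increments, estimates the design's MIF/PGC problem
#' with both the classifier and the k-nn estimator, and aggregates errors
#' against the closed-form Gaussian value.
#'
#' @param design a [benchmarkDesign()].
#' @param k neighbour count for the k-nn arm.
#' @param cspec classifier configuration.
#' @return A data.frame: problem, N, estimator, trueValue, meanError,
#'   errorVariance, meanAbsError, nSims.
#' @export
runBenchmark <- function(design, k = 5, cspec = classifierSpec()) {
  stopifnot(is(design, "BenchmarkDesign"))
  validObject(design)
  p <- .benchProblem(design@problem, design@r, design@condPairs)
  truth <- .benchTruth(p)
  set.seed(design@seed)
  simSeeds <- matrix(sample.int(2^30,
                                length(design@sampleSizes) * design@nSims),
                     nrow = design@nSims)
  bspec <- bootstrapSpec(iterations = design@bootstrapIterations)
  rows <- list()
  for (ni in seq_along(design@sampleSizes)) {
    N <- design@sampleSizes[ni]
    errC <- numeric(design@nSims); errK <- numeric(design@nSims)
    for (s in seq_len(design@nSims)) {
      seed <- simSeeds[s, ni]
      set.seed(seed)
      draws <- .rmvnorm(N, p$cov)
      fx <- draws[, seq_len(p$dx), drop = FALSE]
      fy <- draws[, p$dx + seq_len(p$dy), drop = FALSE]
      if (p$dz > 0L) {
        fz <- draws[, p$dx + p$dy + seq_len(p$dz), drop = FALSE]
        rC <- .classifierPGC(fx, fy, fz, cspec, bspec, seed = seed + 1L)
        estC <- mean(rC$diff)
        estK <- couplingValue(knnMI(fx, cbind(fy, fz), k = k)) -
          couplingValue(knnMI(fx, fz, k = k))
      } else {
        estC <- couplingValue(classifierMI(fx, fy, cspec, bspec,
                                           seed = seed + 1L))
        estK <- couplingValue(knnMI(fx, fy, k = k))
      }
      errC[s] <- estC - truth; errK[s] <- estK - truth
    }
    rows[[length(rows) + 1L]] <- data.frame(
      problem = design@problem, N = N, estimator = c("classifier", "knn"),
      trueValue = truth,
      meanError = c(mean(errC), mean(errK)),
      errorVariance = c(var(errC), var(errK)),
      meanAbsError = c(mean(abs(errC)), mean(abs(errK))),
      nSims = design@nSims)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative-average bootstrap variability curve
#'
#' Runs one simulation of the given benchmark problem at sample size N and
#' estimates it with the classifier over `maxIterations` bootstrap
#' iterations, returning the cumulative average of the per-iteration
#' estimates together with its [convergenceStat()]. Illustrates how
#' bootstrap averaging stabilises classifier-based PGC estimates.
#'
#' @param problem benchmark problem name (see [benchmarkDesign()]).
#' @param N sample size.
#' @param maxIterations number of bootstrap iterations (>= 21).
#' @param seed RNG seed.
#' @param r cross-block correlation.
#' @param cspec classifier configuration.
#' @return A list: `trace` (per-iteration estimates), `cumulative`
#'   (cumulative mean, same length), `convergence` (the statistic),
#'   `trueValue`.
#' @export
bootstrapVariabilityCurve <- function(problem = "pgc_6d", N = 2000,
                                      maxIterations = 50, seed = 1, r = 0.5,
                                      cspec = classifierSpec()) {
  if (maxIterations < 21L)
    stop("maxIterations must be >= 21 for the convergence statistic",
         call. = FALSE)
  p <- .benchProblem(problem, r)
  truth <- .benchTruth(p)
  set.seed(seed)
  draws <- .rmvnorm(N, p$cov)
  fx <- draws[, seq_len(p$dx), drop = FALSE]
  fy <- draws[, p$dx + seq_len(p$dy), drop = FALSE]
  bspec <- bootstrapSpec(iterations = maxIterations)
  if (p$dz > 0L) {
    fz <- draws[, p$dx + p$dy + seq_len(p$dz), drop = FALSE]
    trace <- .classifierPGC(fx, fy, fz, cspec, bspec, seed = seed + 1L)$diff
  } else {
    trace <- bootstrapTrace(classifierMI(fx, fy, cspec, bspec,
                                         seed = seed + 1L))
  }
  cum <- cumsum(trace) / seq_along(trace)
  list(trace = trace, cumulative = cum,
       convergence = convergenceStat(trace), trueValue = truth)
}
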