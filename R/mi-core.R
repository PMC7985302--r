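## The estimation engine: shuffling to the independence distribution,
## classifier-based Donsker-Varadhan estimation with bootstrap averaging,
## the k-nn (KSG) baseline, the Gaussian closed form, and the bootstrap
## convergence diagnostic.

#' Shuffle one block against another to sample the independence distribution
#'
#' Permutes the rows of `blockYZ` as one unit (columns within the block stay
#' paired) while leaving `blockX` ordered, so the output rows are draws from
#' q = p_X * p_YZ, the reference distribution of the Donsker-Varadhan
#' estimator.
#'
#' @param blockX N x d_x matrix, left untouched.
#' @param blockYZ N x d_yz matrix, rows permuted jointly.
#' @param seed optional seed for the permutation (uses the current RNG state
#'   when NULL).
#' @return N x (d_x + d_yz) matrix of shuffled samples.
#' @export
shuffleIndependence <- function(blockX, blockYZ, seed = NULL) {
  blockX <- as.matrix(blockX); blockYZ <- as.matrix(blockYZ)
  N <- nrow(blockX)
  if (nrow(blockYZ) != N) stop("blocks must have equal N", call. = FALSE)
  if (N < 2L) stop("need at least 2 samples to shuffle", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(N)
  cbind(blockX, blockYZ[perm, , drop = FALSE])
}

#' Donsker-Varadhan divergence estimate from a likelihood function
#'
#' Given test samples from the joint distribution p and from the
#' independence distribution q, plus a (learned) likelihood-ratio function
#' L(s) = P(label = 1 | s) / (1 - P(label = 1 | s)), returns
#' `mean(log L(orig)) - log(mean(L(shuf)))` - the plug-in form of the
#' Donsker-Varadhan bound, exact when L is the true density ratio p/q.
#' Finite-sample estimates may be negative and are reported as-is.
#'
#' @param testOrig matrix of test samples from p.
#' @param testShuf matrix of test samples from q.
#' @param likelihood function mapping a sample matrix to positive
#'   likelihood-ratio values (one per row).
#' @return The divergence estimate in nats.
#' @export
#' @examples
#' dvEstimate(matrix(rnorm(10)), matrix(rnorm(10)), function(m) rep(1, nrow(m)))
dvEstimate <- function(testOrig, testShuf, likelihood) {
  testOrig <- as.matrix(testOrig); testShuf <- as.matrix(testShuf)
  if (nrow(testOrig) == 0L || nrow(testShuf) == 0L)
    stop("test sets must be non-empty", call. = FALSE)
  lp <- likelihood(testOrig); lq <- likelihood(testShuf)
  if (any(lp <= 0) || any(lq <= 0))
    stop("likelihood must return positive values", call. = FALSE)
  mean(log(lp)) - log(mean(lq))
}

## ---------------------------------------------------------------------------
## Harmonic-polynomial feature basis
## ---------------------------------------------------------------------------

## Treats consecutive column pairs of X as complex increment blocks
## u = col1 + i col2 (a trailing odd column is a real-only block) and builds:
## per block u^m (Re, Im; m = 1..degree), |u| and |u|^2; per block pair the
## cross products Re/Im(u^m Conj(v)^n) for m, n = 1..degree plus the
## amplitude couplings |u||v|, |u|^2 |v|^2, |u|^2 Re/Im(v) and
## Re/Im(u) |v|^2. Phase-phase coupling between harmonics m f and n f
## appears exactly in the (m, n) product, which is why this basis is a
## natural function class for spectral increments.
.harmonicFeatures <- function(X, degree = 3L) {
  d <- ncol(X)
  nb <- d %/% 2L
  u <- vector("list", nb + (d %% 2L))
  for (b in seq_len(nb))
    u[[b]] <- complex(real = X[, 2L * b - 1L], imaginary = X[, 2L * b])
  if (d %% 2L) u[[nb + 1L]] <- complex(real = X[, d], imaginary = 0 * X[, d])
  B <- length(u)
  pw <- lapply(u, function(z) lapply(seq_len(degree), function(m) z^m))
  cols <- vector("list", 0L)
  for (b in seq_len(B)) {
    for (m in seq_len(degree)) {
      z <- pw[[b]][[m]]
      cols[[length(cols) + 1L]] <- Re(z)
      cols[[length(cols) + 1L]] <- Im(z)
    }
    cols[[length(cols) + 1L]] <- Mod(u[[b]])
    cols[[length(cols) + 1L]] <- Mod(u[[b]])^2
  }
  if (B >= 2L) for (a in seq_len(B - 1L)) for (b in (a + 1L):B) {
    for (m in seq_len(degree)) for (n in seq_len(degree)) {
      z <- pw[[a]][[m]] * Conj(pw[[b]][[n]])
      cols[[length(cols) + 1L]] <- Re(z)
      cols[[length(cols) + 1L]] <- Im(z)
    }
    ma <- Mod(u[[a]]); mb <- Mod(u[[b]])
    cols[[length(cols) + 1L]] <- ma * mb
    cols[[length(cols) + 1L]] <- ma^2 * mb^2
    cols[[length(cols) + 1L]] <- ma^2 * Re(u[[b]])
    cols[[length(cols) + 1L]] <- ma^2 * Im(u[[b]])
    cols[[length(cols) + 1L]] <- Re(u[[a]]) * mb^2
    cols[[length(cols) + 1L]] <- Im(u[[a]]) * mb^2
  }
  out <- do.call(cbind, cols)
  ## drop numerically constant columns (e.g. Im of a DC bin)
  keep <- apply(out, 2L, function(v) diff(range(v)) > 0)
  out[, keep, drop = FALSE]
}

## Monotone per-coordinate rank-Gaussian map fitted on training rows and
## applied to train and test alike. MI is invariant to such maps; the
## transform removes heavy amplitude tails before polynomial expansion.
.rankGaussianize <- function(train, tests) {
  for (j in seq_len(ncol(train))) {
    xs <- sort(train[, j])
    n <- length(xs)
    g <- function(v)
      stats::qnorm(pmin(pmax(findInterval(v, xs) / (n + 1), 1 / (n + 1)),
                        n / (n + 1)))
    tests <- lapply(tests, function(m) { m[, j] <- g(m[, j]); m })
    train[, j] <- g(train[, j])
  }
  c(list(train), tests)
}

## One bootstrap iteration of the classifier DV estimate. Returns one
## divergence value. Everything random (permutation, splits, validation
## slice) is driven by `seed`, making the estimate bit-reproducible; the
## glmnet fit itself is deterministic.
.dvIteration <- function(x, y, seed, cspec, trainFraction) {
  set.seed(seed)
  N <- nrow(x)
  perm <- sample.int(N)
  orig <- cbind(x, y)
  shuf <- cbind(x, y[perm, , drop = FALSE])
  nTr <- floor(trainFraction * N)
  trO <- sample.int(N, nTr)
  trS <- sample.int(N, nTr)
  trX <- rbind(orig[trO, , drop = FALSE], shuf[trS, , drop = FALSE])
  trL <- c(rep(1, nTr), rep(0, nTr))
  teO <- orig[-trO, , drop = FALSE]
  teS <- shuf[-trS, , drop = FALSE]
  ## zero out numerically degenerate columns (e.g. FFT round-off in bins a
  ## band-limited signal does not occupy); rank or z standardisation would
  ## otherwise inflate pure round-off into apparent structure
  sdTr <- apply(trX, 2L, sd)
  degen <- sdTr < 1e-9 * max(sdTr, 0) | !is.finite(sdTr)
  if (any(degen)) {
    trX[, degen] <- 0; teO[, degen] <- 0; teS[, degen] <- 0
  }
  ## standardise with training statistics only
  if (cspec@gaussianize) {
    gz <- .rankGaussianize(trX, list(teO, teS))
    trX <- gz[[1L]]; teO <- gz[[2L]]; teS <- gz[[3L]]
  }
  mu <- colMeans(trX)
  sdv <- apply(trX, 2L, sd); sdv[sdv == 0] <- 1
  std <- function(m) sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  Ftr <- .harmonicFeatures(std(trX), cspec@degree)
  FteO <- .harmonicFeatures(std(teO), cspec@degree)
  FteS <- .harmonicFeatures(std(teS), cspec@degree)
  n <- nrow(Ftr)
  vi <- sample.int(n, max(10L, floor(n * cspec@valFraction)))
  fit <- suppressWarnings(
    glmnet::glmnet(Ftr[-vi, , drop = FALSE], trL[-vi],
                   family = "binomial", alpha = cspec@alpha,
                   nlambda = cspec@nlambda, thresh = 1e-5))
  pv <- stats::predict(fit, Ftr[vi, , drop = FALSE], type = "response")
  vl <- trL[vi]
  xent <- apply(pv, 2L, function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(vl * log(p) + (1 - vl) * log(1 - p))
  })
  s <- which.min(xent)
  eps <- cspec@clip
  clipL <- function(m) {
    p <- stats::predict(fit, m, type = "response")[, s]
    p <- pmin(pmax(p, eps), 1 - eps)
    p / (1 - p)
  }
  dvEstimate(FteO, FteS, clipL)
}

#' Classifier-based mutual information between two feature blocks
#'
#' Estimates I(X; Y) by training a binary classifier to separate original
#' samples (label 1) from shuffled samples (label 0, Y rows permuted) and
#' plugging the learned likelihood ratio into the Donsker-Varadhan bound.
#' Each bootstrap iteration uses a fresh permutation and a fresh random
#' train/test split; the estimate is the mean across iterations. Negative
#' finite-sample estimates are reported as-is (small-sample bias, not
#' clamped).
#'
#' @param x N x d_x feature matrix (columns in [Re, Im] block pairs).
#' @param y N x d_y feature matrix, shuffled as one unit.
#' @param cspec a [classifierSpec()].
#' @param bspec a [bootstrapSpec()].
#' @param seed master seed; spawns one child seed per iteration.
#' @return A [CouplingEstimate-class] with the bootstrap trace.
#' @export
classifierMI <- function(x, y, cspec = classifierSpec(),
                         bspec = bootstrapSpec(), seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  N <- nrow(x)
  if (nrow(y) != N) stop("x and y must have equal N", call. = FALSE)
  if (N < 30L)
    stop("need at least 30 samples for the 2/3-1/3 split", call. = FALSE)
  set.seed(seed)
  iterSeeds <- sample.int(2^30, bspec@iterations)
  ests <- vapply(iterSeeds, function(s)
    .dvIteration(x, y, s, cspec, bspec@trainFraction), numeric(1))
  bad <- !is.finite(ests)
  if (any(bad)) {
    warning(sum(bad), " bootstrap iteration(s) returned NaN and were excluded")
    ests <- ests[!bad]
  }
  .couplingEstimate(mean(ests), iterations = ests, estimator = "classifier",
                    seed = seed,
                    meta = list(cspec = cspec, bspec = bspec,
                                iterSeeds = iterSeeds))
}

#' k-nearest-neighbour (KSG) mutual information
#'
#' Kraskov-type estimator with max-norm neighbourhoods; deterministic given
#' the inputs. Duplicate joint points (which would give zero k-th neighbour
#' distances) are broken by a tiny deterministic jitter, with a warning.
#'
#' @param x,y feature matrices with equal N.
#' @param k neighbour count (default 5).
#' @return A [CouplingEstimate-class] (estimator "knn").
#' @export
knnMI <- function(x, y, k = 5) {
  x <- as.matrix(x); y <- as.matrix(y)
  N <- nrow(x)
  if (nrow(y) != N) stop("x and y must have equal N", call. = FALSE)
  if (N <= k || k < 1L) stop("need N > k >= 1", call. = FALSE)
  joint <- cbind(x, y)
  if (anyDuplicated(joint)) {
    warning("duplicate joint points; applying tiny deterministic jitter")
    scl <- pmax(apply(joint, 2L, sd), .Machine$double.eps)
    idx <- seq_len(N)
    jit <- outer(sin(idx * 0.7391) * 1e-9, scl)
    joint <- joint + jit
    x <- joint[, seq_len(ncol(x)), drop = FALSE]
    y <- joint[, -seq_len(ncol(x)), drop = FALSE]
  }
  val <- .ksgMICpp(x, y, as.integer(k))
  sat <- digamma(N) - digamma(k) - 0.5
  if (val > sat)
    warning("k-nn MI estimate near its saturation bound (", round(sat, 2),
            " nats): inputs are (close to) functionally dependent")
  .couplingEstimate(val, iterations = val, estimator = "knn",
                    meta = list(k = k))
}

#' Closed-form mutual information between jointly Gaussian blocks
#'
#' `0.5 * log(det(S_X) * det(S_Y) / det(S))` for a joint covariance S whose
#' first `dX` coordinates form block X; the analytic oracle for the
#' Gaussian-increment benchmark.
#'
#' @param cov joint covariance matrix (positive definite).
#' @param dX dimension of the first block.
#' @return Mutual information in nats.
#' @export
#' @examples
#' S <- diag(4); S[1, 3] <- S[3, 1] <- 0.5
#' gaussianMIAnalytic(S, 2)   # -0.5 * log(0.75)
gaussianMIAnalytic <- function(cov, dX) {
  cov <- as.matrix(cov)
  d <- nrow(cov)
  if (dX < 1L || dX >= d) stop("dX must split the covariance", call. = FALSE)
  ev <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("covariance must be positive definite", call. = FALSE)
  ix <- seq_len(dX); iy <- (dX + 1L):d
  0.5 * log(det(cov[ix, ix, drop = FALSE]) * det(cov[iy, iy, drop = FALSE]) /
              det(cov))
}

#' Bootstrap convergence statistic
#'
#' Builds the cumulative mean of the per-iteration estimates and returns the
#' average of the 20 squared differences between the final 21 points of that
#' cumulative average: the empirical convergence diagnostic used to verify
#' that a bootstrap-averaged coupling estimate has stabilised.
#'
#' @param perIteration numeric vector of at least 21 per-iteration
#'   estimates (e.g. [bootstrapTrace()] of a classifier estimate).
#' @return Non-negative convergence statistic.
#' @export
convergenceStat <- function(perIteration) {
  if (length(perIteration) < 21L)
    stop("need at least 21 iterations for the convergence statistic",
         call. = FALSE)
  cm <- cumsum(perIteration) / seq_along(perIteration)
  last <- tail(cm, 21L)
  mean(diff(last)^2)
}
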