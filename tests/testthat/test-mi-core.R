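test_that("shuffling samples the independence distribution", {
  ## N = 2: the only non-identity permutation swaps both rows of the yz
  ## block while x stays put
  x <- matrix(1:2, 2); yz <- matrix(c(10, 20, 100, 200), 2)
  seen <- replicate(40, {
    s <- shuffleIndependence(x, yz, seed = sample.int(1e6, 1))
    paste(s, collapse = ",")
  })
  expect_true(all(seen %in% c("1,2,10,20,100,200", "1,2,20,10,200,100")))

  ## within-block column pairing is preserved exactly
  set.seed(5)
  y2 <- cbind(a = rnorm(500), b = rnorm(500))
  y2[, 2] <- y2[, 1] * 2 + 1
  s <- shuffleIndependence(matrix(rnorm(500)), y2, seed = 9)
  expect_equal(unname(s[, 2] * 2 + 1), unname(s[, 3]))

  ## cross-block alignment is destroyed: corr(x, y) ~ 0 for y == x
  xx <- matrix(rnorm(1000))
  s2 <- shuffleIndependence(xx, xx, seed = 11)
  expect_lt(abs(cor(s2[, 1], s2[, 2])), 0.1)

  expect_error(shuffleIndependence(matrix(1), matrix(1)), "at least 2")
})

test_that("the Donsker-Varadhan plug-in estimate has its algebraic properties", {
  o <- matrix(rnorm(50)); s <- matrix(rnorm(50))
  ## constant likelihood (p = 0.5 everywhere): exactly zero
  expect_identical(dvEstimate(o, s, function(m) rep(1, nrow(m))), 0)

  ## invariant to constant rescaling of L (log c cancels)
  L <- function(m) exp(m[, 1])
  expect_equal(dvEstimate(o, s, L),
               dvEstimate(o, s, function(m) 7.3 * L(m)))

  ## true density ratio for N(1,1) vs N(0,1): estimate -> KL = 0.5
  set.seed(13)
  op <- matrix(rnorm(20000, 1)); sq <- matrix(rnorm(20000, 0))
  ratio <- function(m) exp(m[, 1] - 0.5)   # p1/p0 for unit-variance shift
  expect_equal(dvEstimate(op, sq, ratio), 0.5, tolerance = 0.05)

  expect_error(dvEstimate(o[0, , drop = FALSE], s, L), "non-empty")
  expect_error(dvEstimate(o, s, function(m) rep(-1, nrow(m))), "positive")
})

test_that("classifier MI is calibrated on Gaussian blocks and reproducible", {
  ## independent blocks: estimate pinned near zero
  set.seed(17)
  xi <- matrix(rnorm(10000), ncol = 2); yi <- matrix(rnorm(10000), ncol = 2)
  e0 <- classifierMI(xi, yi, bspec = bootstrapSpec(20), seed = 3)
  expect_lte(abs(couplingValue(e0)), 0.05)

  ## correlated blocks with analytic MI log 2
  Z <- rmvnOracle(10000, cov2Blocks(sqrt(0.5)), seed = 18)
  e1 <- classifierMI(Z[, 1:2], Z[, 3:4], bspec = bootstrapSpec(10),
                     seed = 3)
  expect_equal(couplingValue(e1), log(2), tolerance = 0.1)
  expect_equal(couplingValue(e1), mean(bootstrapTrace(e1)))

  ## bit-reproducible under a fixed seed
  e2 <- classifierMI(Z[, 1:2], Z[, 3:4], bspec = bootstrapSpec(10),
                     seed = 3)
  expect_identical(couplingValue(e1), couplingValue(e2))
})

test_that("bootstrap averaging reduces estimate variability", {
  Z <- rmvnOracle(2000, cov2Blocks(0.5), seed = 19)
  one <- vapply(1:8, function(s)
    couplingValue(classifierMI(Z[, 1:2], Z[, 3:4],
                               bspec = bootstrapSpec(1), seed = s)),
    numeric(1))
  many <- vapply(1:8, function(s)
    couplingValue(classifierMI(Z[, 1:2], Z[, 3:4],
                               bspec = bootstrapSpec(10), seed = s)),
    numeric(1))
  expect_lt(sd(many), sd(one))
})

test_that("the KSG estimator matches closed forms and guards degeneracies", {
  ## independent uniform blocks
  set.seed(23)
  u1 <- matrix(runif(4000), ncol = 2); u2 <- matrix(runif(4000), ncol = 2)
  expect_lte(abs(couplingValue(knnMI(u1, u2))), 0.05)

  ## scalar Gaussian pair: MI = -0.5 log(1 - r^2)
  r <- 0.6
  S <- matrix(c(1, r, r, 1), 2)
  Z <- rmvnOracle(5000, S, seed = 24)
  expect_equal(couplingValue(knnMI(Z[, 1, drop = FALSE],
                                   Z[, 2, drop = FALSE], k = 5)),
               -0.5 * log(1 - r^2), tolerance = 0.05)

  ## identical copies: guarded large value with warning
  x <- matrix(rnorm(500))
  expect_warning(big <- knnMI(x, x), "functionally dependent")
  expect_true(is.finite(couplingValue(big)) && couplingValue(big) > 2)

  ## duplicate joint points are jittered deterministically
  set.seed(25)
  xd <- matrix(rep(rnorm(100), 2), ncol = 1)
  yd <- matrix(rep(rnorm(100), 2), ncol = 1)
  expect_warning(j1 <- knnMI(xd, yd), "jitter")
  expect_warning(j2 <- knnMI(xd, yd), "jitter")
  expect_identical(couplingValue(j1), couplingValue(j2))
  expect_true(is.finite(couplingValue(j1)))

  expect_error(knnMI(x[1:4, , drop = FALSE], x[1:4, , drop = FALSE], k = 5),
               "N > k")
})

test_that("the Gaussian closed form is exact and transform-invariant", {
  expect_equal(gaussianMIAnalytic(diag(6), 2), 0)
  S <- diag(4); S[1, 3] <- S[3, 1] <- 0.5
  expect_equal(gaussianMIAnalytic(S, 2), -0.5 * log(0.75))
  ## agrees with the entropy-difference route
  expect_equal(gaussianMIAnalytic(S, 2), gaussMIEntropyOracle(S, 2))

  ## invariance under separate invertible linear maps of each block
  A <- matrix(c(2, 1, 0, 1), 2); B <- matrix(c(1, -1, 3, 0.5), 2)
  Tm <- as.matrix(Matrix::bdiag(A, B))
  S2 <- Tm %*% S %*% t(Tm)
  expect_equal(gaussianMIAnalytic(S2, 2), gaussianMIAnalytic(S, 2))

  expect_error(gaussianMIAnalytic(matrix(1, 4, 4), 2), "positive definite")
})

test_that("the convergence statistic is exact on constructed traces", {
  expect_lt(convergenceStat(rep(0.4, 30)), 1e-30)  # exact up to float accumulation

  ## build per-iteration values whose cumulative mean ends in a ramp of
  ## step 1e-3: each of the 20 squared differences is 1e-6
  cm <- c(rep(0.2, 9), 0.2 + 1e-3 * (1:21))
  n <- length(cm)
  per <- cm * seq_len(n) - c(0, cm[-n] * seq_len(n - 1))
  expect_equal(convergenceStat(per), 1e-6, tolerance = 1e-12)

  expect_error(convergenceStat(rnorm(20)), "21")
})

test_that("both estimators converge toward the Gaussian oracle as N grows", {
  S <- cov2Blocks(0.5)
  truth <- gaussianMIAnalytic(S, 2)
  medAbs <- function(est) median(abs(est - truth))
  errK <- errC <- numeric(3)
  for (i in seq_along(Ns <- c(500, 2000, 8000))) {
    ek <- ec <- numeric(5)
    for (s in 1:5) {
      Z <- rmvnOracle(Ns[i], S, seed = 100 * i + s)
      ek[s] <- couplingValue(knnMI(Z[, 1:2], Z[, 3:4]))
      ec[s] <- couplingValue(classifierMI(Z[, 1:2], Z[, 3:4],
                                          bspec = bootstrapSpec(5),
                                          seed = 100 * i + s))
    }
    errK[i] <- medAbs(ek); errC[i] <- medAbs(ec)
  }
  expect_true(all(diff(errK) < 0))
  expect_lt(errC[3], errC[1])
})
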