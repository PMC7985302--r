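test_that("simulators are bit-reproducible and respect their invariants", {
  ts1 <- simulateLinear(linearSimConfig(nTrials = 50, seed = 7))
  ts2 <- simulateLinear(linearSimConfig(nTrials = 50, seed = 7))
  ts3 <- simulateLinear(linearSimConfig(nTrials = 50, seed = 8))
  expect_identical(recordingData(ts1), recordingData(ts2))
  expect_false(identical(recordingData(ts1), recordingData(ts3)))

  expect_error(linearSimConfig(sigmaX = 0), "scale")
  expect_error(linearSimConfig(f0 = 2.3), "integer")
  expect_error(nonlinearSimConfig(f0 = 7, fs = 32), "Nyquist")
})

test_that("vanishing noise scales give the degenerate limits", {
  tsL <- simulateLinear(linearSimConfig(sigmaW = 1e-9, nTrials = 20,
                                        seed = 1))
  d <- recordingData(tsL)
  expect_lt(max(abs(d[, 2, ] - d[, 1, ])), 1e-6)  # W -> X as sigmaW -> 0

  tsN <- simulateNonlinear(nonlinearSimConfig(sigmaW = 1e-9, nTrials = 20,
                                              seed = 1))
  dn <- recordingData(tsN)
  expect_lt(max(abs(dn[, 2, ] - dn[, 1, ]^2)), 1e-12)  # W -> X^2
})

test_that("linear-simulation spectral amplitudes follow the Rayleigh convention", {
  ts <- fixtureCache("linHuge",
                     simulateLinear(linearSimConfig(nTrials = 10000,
                                                    seed = 42)))
  sss <- fixtureCache("linHugeSss", sampleIncrements(ts, frequencies = 2))
  xs <- incrementSamples(sss, "X", 2)
  ## under the 1/M DFT convention each component of the f0 increment has
  ## variance sigma^2 / 4
  expect_equal(var(xs[, 1]), 0.25, tolerance = 0.05)
  expect_equal(var(xs[, 2]), 0.25, tolerance = 0.05)

  ## per-component amplitudes are Gaussian (normality at alpha = 0.01)
  expect_gt(stats::shapiro.test(xs[seq_len(5000), 1])$p.value, 0.01)
  expect_gt(stats::shapiro.test(xs[seq_len(5000), 2])$p.value, 0.01)

  ## empirical coherence X-W at f0 matches sigma_x^2/(sigma_x^2+sigma_w^2)
  csm <- estimateCrossSpectralMatrix(sss, c("X", "W"), 2)
  expect_equal(coherence(csm, "X", "W"), 0.5, tolerance = 0.03)
})

test_that("nonlinear simulation concentrates energy at the harmonic bins", {
  ts <- fixtureCache("nlMid",
                     simulateNonlinear(nonlinearSimConfig(nTrials = 20000,
                                                          seed = 9)))
  sss <- sampleIncrements(ts, frequencies = 0:16)
  maxAbs <- function(ch, f) max(abs(incrementSamples(sss, ch, f)))
  for (f in setdiff(0:16, c(0, 4)))
    expect_lt(maxAbs("W", f), 1e-10)
  for (f in setdiff(0:16, c(2, 6)))
    expect_lt(maxAbs("Z", f), 1e-10)
  expect_gt(maxAbs("W", 0), 0.1)
  expect_gt(maxAbs("W", 4), 0.1)
  expect_gt(maxAbs("Z", 2), 0.1)
  expect_gt(maxAbs("Z", 6), 0.1)

  ## Z at 3 f0: cos^3 keeps amplitude A^3/4 at the third harmonic, halved
  ## by the two-sided spectrum, so each component has variance
  ## (1/64) * (E[Ax^6] + E[Az^6]) / 2
  zs <- incrementSamples(sss, "Z", 6)
  expectVar <- (rayleighMoment(6, 1) + rayleighMoment(6, 0.75)) / 128
  expect_equal(var(zs[, 1]), expectVar, tolerance = 0.1)
  expect_equal(var(zs[, 2]), expectVar, tolerance = 0.1)
})

test_that("analytic linear couplings satisfy the coherence identity and printed values", {
  fc <- analyticLinearFC(linearSimConfig())
  expect_equal(fc$mif, -log(1 - fc$coherence))
  expect_equal(fc$pgc, -log(1 - fc$partialCoherence))
  expect_equal(fc$mif[fc$pair == "X-W"], log(2))
  expect_equal(fc$mif[fc$pair == "W-Z"], log(3))
  expect_equal(fc$mif[fc$pair == "X-Z"], log(3 / 2))
  expect_equal(fc$pgc[fc$pair == "X-Z"], 0)
  expect_equal(fc$pgc[fc$pair == "X-W"], log(4 / 3))
  expect_equal(fc$pgc[fc$pair == "W-Z"], log(2))

  ## general scales: FC(X,W) = log(1 + sx^2/sw^2)
  fc2 <- analyticLinearFC(linearSimConfig(sigmaX = 2, sigmaW = 0.5))
  expect_equal(fc2$mif[fc2$pair == "X-W"], log(1 + 4 / 0.25))
})

test_that("gaussian increment draws match their specification", {
  S <- cov2Blocks(0.6)
  spec <- gaussianIncrementSpec(c("X@1", "Y@1"), S, nSamples = 20000,
                                seed = 5)
  sss <- simulateGaussianIncrements(spec)
  expect_equal(nWindows(sss), 20000L)
  xs <- incrementSamples(sss, "X", 1)
  ys <- incrementSamples(sss, "Y", 1)
  expect_equal(cor(xs[, 1], ys[, 1]), 0.6, tolerance = 0.03)
  expect_equal(cor(xs[, 1], ys[, 2]), 0, tolerance = 0.03)
  ## analytic MI for this structure: -log(1 - r^2)
  expect_equal(gaussianMIAnalytic(S, 2), -log(1 - 0.36))

  ## identity covariance: independent blocks, zero analytic MI
  spec0 <- gaussianIncrementSpec(c("X@1", "Y@1"), diag(4), nSamples = 5000,
                                 seed = 6)
  s0 <- simulateGaussianIncrements(spec0)
  expect_equal(gaussianMIAnalytic(diag(4), 2), 0)
  expect_lt(abs(cor(incrementSamples(s0, "X", 1)[, 1],
                    incrementSamples(s0, "Y", 1)[, 1])), 0.05)

  expect_error(gaussianIncrementSpec(c("X@1", "Y@1"),
                                     matrix(1, 4, 4), 100),
               "positive definite")

  ## the twelve-dimensional benchmark layout resolves as six increments
  p12 <- pgcoh:::.benchProblem("pgc_12d", 0.5)
  expect_equal(nrow(p12$cov), 12)
  s12 <- simulateGaussianIncrements(
    gaussianIncrementSpec(p12$labels, p12$cov, nSamples = 100, seed = 1))
  expect_length(s12@samples, 6)
})

test_that("downstream estimates are invariant to trial order", {
  ts <- simulateLinear(linearSimConfig(nTrials = 400, seed = 3))
  arr <- recordingData(ts)
  set.seed(99)
  perm <- sample(dim(arr)[1])
  tsP <- trialSet(arr[perm, , , drop = FALSE], fs = samplingRate(ts),
                  channelNames = channelNames(ts))
  s1 <- sampleIncrements(ts, frequencies = 2)
  s2 <- sampleIncrements(tsP, frequencies = 2)
  c1 <- estimateCrossSpectralMatrix(s1, c("X", "W"), 2)
  c2 <- estimateCrossSpectralMatrix(s2, c("X", "W"), 2)
  expect_equal(coherence(c1, "X", "W"), coherence(c2, "X", "W"))
  k1 <- couplingValue(knnMI(incrementSamples(s1, "X", 2),
                            incrementSamples(s1, "W", 2)))
  k2 <- couplingValue(knnMI(incrementSamples(s2, "X", 2),
                            incrementSamples(s2, "W", 2)))
  expect_equal(k1, k2)
})
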