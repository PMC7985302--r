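# MIF/PGC composition on the linear three-process simulation; the k-nn
# estimator is used for most unit checks (fast, deterministic), the
# classifier path where the bootstrap machinery itself is under test.

linSss <- function() fixtureCache("linPgc", {
  ts <- simulateLinear(linearSimConfig(nTrials = 3000, seed = 77))
  ## add broadband sensor noise (so every bin has content) and append an
  ## independent white channel "N" for null checks
  arr <- recordingData(ts)
  set.seed(78)
  arr <- arr + 0.1 * rnorm(length(arr))
  arr2 <- array(0, dim = dim(arr) + c(0, 1, 0))
  arr2[, 1:3, ] <- arr
  arr2[, 4, ] <- rnorm(dim(arr)[1] * dim(arr)[3])
  sampleIncrements(trialSet(arr2, samplingRate(ts),
                            c(channelNames(ts), "N")),
                   frequencies = c(1, 2))
})

qk <- function(a, b, cond = NULL, f = 2, fc = 2)
  pgcQuery(incrementSelection(a, f), incrementSelection(b, f),
           cond = if (!is.null(cond)) incrementSelection(cond, fc),
           estimator = "knn", seed = 5)

test_that("MIF recovers the analytic coupling and vanishes for null pairs", {
  sss <- linSss()
  expect_equal(couplingValue(mif(qk("X", "W"), sss)), log(2),
               tolerance = 0.1)
  expect_lt(abs(couplingValue(mif(qk("X", "N"), sss))), 0.06)
})

test_that("MIF is symmetric in its arguments for the deterministic estimator", {
  sss <- linSss()
  expect_equal(couplingValue(mif(qk("X", "W"), sss)),
               couplingValue(mif(qk("W", "X"), sss)))
})

test_that("PGC equals the difference of its stored MI terms exactly", {
  sss <- linSss()
  for (est in c("knn", "classifier")) {
    q <- pgcQuery(incrementSelection("X", 2), incrementSelection("Z", 2),
                  cond = incrementSelection("W", 2), estimator = est,
                  bspec = bootstrapSpec(5), seed = 9)
    p <- pgc(q, sss)
    tm <- miTerms(p)
    expect_equal(couplingValue(p), unname(tm["ixyz"] - tm["ixz"]),
                 tolerance = 1e-10)
  }
})

test_that("conditioning eliminates the indirect X-Z link but not direct links", {
  sss <- linSss()
  expect_lt(abs(couplingValue(pgc(qk("X", "Z", cond = "W"), sss))), 0.1)
  expect_gt(couplingValue(pgc(qk("W", "Z", cond = "X"), sss)), 0.4)
})

test_that("conditioning on an independent channel reduces to plain MIF", {
  sss <- linSss()
  m <- couplingValue(mif(qk("X", "W"), sss))
  p <- couplingValue(pgc(qk("X", "W", cond = "N"), sss))
  expect_equal(p, m, tolerance = 0.06)
})

test_that("conditioning on a duplicate of the partner drives PGC to zero", {
  ## I(X; Y, Y') - I(X; Y') = 0 when Y' carries exactly Y's increments;
  ## also exercises window alignment across duplicated channels
  ts <- simulateLinear(linearSimConfig(nTrials = 2000, seed = 55))
  arr <- recordingData(ts)
  arr2 <- array(0, dim = dim(arr) + c(0, 1, 0))
  arr2[, 1:3, ] <- arr
  arr2[, 4, ] <- arr[, 2, ] + 1e-8 * rnorm(length(arr[, 2, ]))
  sss <- sampleIncrements(trialSet(arr2, samplingRate(ts),
                                   c("X", "W", "Z", "Wdup")),
                          frequencies = 2)
  q <- pgcQuery(incrementSelection("X", 2), incrementSelection("W", 2),
                cond = incrementSelection("Wdup", 2), estimator = "knn")
  expect_lt(abs(couplingValue(pgc(q, sss))), 0.12)
})

test_that("selection disjointness is enforced as an error", {
  expect_error(pgcQuery(incrementSelection("X", 2),
                        incrementSelection("X", 2)), "disjoint")
  expect_error(pgcQuery(incrementSelection("X", 2),
                        incrementSelection("Y", 2),
                        cond = incrementSelection("Y", 2)), "disjoint")
  ## same channels at different frequencies are allowed
  expect_s4_class(pgcQuery(incrementSelection("X", 2),
                           incrementSelection("X", 3)), "PGCQuery")
  q <- pgcQuery(incrementSelection("X", 2), incrementSelection("Y", 2))
  expect_error(pgc(q, linSss()), "conditioning")
})

test_that("control PGC and baseline MIF rewire the expected selections", {
  sss <- linSss()
  q <- qk("X", "W", cond = "Z")
  ctrl <- controlPGC(q, sss, controlFreqs = 1)
  expect_equal(ctrl@selections$cond@frequencies, 1)
  expect_equal(ctrl@selections$cond@channels, "Z")
  ## the 1 Hz bin of Z is pure independent noise here, so control ~ MIF
  expect_equal(couplingValue(ctrl), couplingValue(mif(q, sss)),
               tolerance = 0.08)

  base <- baselineMIF(q, sss, baselineFreqs = 1)
  expect_equal(base@selections$y@frequencies, 1)
  expect_lt(abs(couplingValue(base)), 0.06)
})

test_that("batch queries produce a tabular report", {
  sss <- linSss()
  df <- runQueries(list(qk("X", "W"), qk("X", "Z", cond = "W")), sss)
  expect_equal(nrow(df), 2)
  expect_equal(df$kind, c("mif", "pgc"))
  expect_equal(df$estimator, c("knn", "knn"))
  expect_true(all(is.finite(df$value)))

  empty <- runQueries(list(), sss)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("pair", "kind", "value") %in% names(empty)))
})
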