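test_that("windowing counts and errors are exact", {
  rec <- whiteRecording(nch = 1, n = 30 * 60 * 20, fs = 20)
  expect_length(segmentWindows(rec, 1), 1800)  # 30 min of 1 s windows

  rec2 <- whiteRecording(nch = 1, n = 107, fs = 10)
  w <- segmentWindows(rec2, 1)
  expect_length(w, 10)                          # 7 trailing samples dropped
  expect_identical(w[[1]], recordingData(rec2)[, 1:10, drop = FALSE])

  rec3 <- whiteRecording(nch = 1, n = 10, fs = 10)
  expect_identical(segmentWindows(rec3, 1)[[1]], recordingData(rec3))
  expect_error(segmentWindows(rec3, 2), "shorter than one window")
  expect_error(segmentWindows(rec3, 0.35), "positive integer")
})

test_that("a pure on-bin cosine yields the sample [a/2, 0]", {
  fs <- 32; a <- 1.8; f <- 3
  tgrid <- (0:(fs - 1)) / fs
  rec <- multiChannelRecording(matrix(a * cos(2 * pi * f * tgrid), 1), fs,
                               "c")
  sss <- sampleIncrements(rec, windowLength = 1, frequencies = f)
  expect_equal(incrementSamples(sss, "c", f)[1, ],
               c(Re = a / 2, Im = 0), tolerance = 1e-12)

  ## off-bin frequencies error, naming the nearest valid bins
  expect_error(sampleIncrements(rec, 1, 2.5), "2 and 3 Hz")
  expect_error(sampleIncrements(rec, 1, 17), "Nyquist")
  expect_silent(sampleIncrements(rec, 1, c(2, 3)))
})

test_that("Parseval holds for the 1/M DFT convention", {
  fs <- 16
  rec <- whiteRecording(nch = 1, n = fs, fs = fs, seed = 12)
  sss <- sampleIncrements(rec, 1, 0:(fs / 2))
  mags <- vapply(0:(fs / 2), function(f)
    sum(incrementSamples(sss, "A", f)[1, ]^2), numeric(1))
  ## two-sided spectrum: interior bins count twice
  weights <- c(1, rep(2, fs / 2 - 1), 1)
  expect_equal(sum(weights * mags), mean(recordingData(rec)^2),
               tolerance = 1e-10)
})

test_that("block z-scoring standardises each block independently", {
  fs <- 2
  x <- matrix(2 * (1:8) + 5, 1)             # affine channel
  rec <- multiChannelRecording(x, fs, "c")
  z <- zscoreBlocks(rec, blockLength = 4)   # one block
  expect_equal(mean(recordingData(z)), 0)
  expect_equal(sd(recordingData(z)[1, ]), 1)

  ## two 2-sample blocks with different means: each centred independently
  rec2 <- multiChannelRecording(matrix(c(1, 2, 11, 12), 1), 1, "c")
  z2 <- zscoreBlocks(rec2, blockLength = 2)
  expect_equal(as.numeric(recordingData(z2)),
               rep(c(-0.5, 0.5), 2) / sd(c(1, 2)))

  ## near-standard white noise stays close to itself
  rec3 <- whiteRecording(nch = 1, n = 200, fs = 10, seed = 4)
  z3 <- zscoreBlocks(rec3, 20)
  expect_gt(cor(recordingData(z3)[1, ], recordingData(rec3)[1, ]), 0.999)

  recC <- multiChannelRecording(rbind(rnorm(8), rep(3, 8)), 2,
                                c("a", "b"))
  expect_error(zscoreBlocks(recC, 4), "constant channel")
})

test_that("selectIncrements returns ordered aligned feature blocks", {
  rec <- whiteRecording(nch = 2, n = 400, fs = 20, seed = 3)
  sss <- sampleIncrements(rec, 1, c(2, 3))
  one <- selectIncrements(sss, incrementSelection("A", 2))
  expect_equal(unname(one), unname(incrementSamples(sss, "A", 2)))

  two <- selectIncrements(sss, incrementSelection(c("A", "B"), c(2, 3)))
  expect_equal(dim(two), c(nWindows(sss), 4L))
  expect_equal(colnames(two),
               c("A@2.Re", "A@2.Im", "B@3.Re", "B@3.Im"))
  expect_equal(unname(two[, 3:4]), unname(incrementSamples(sss, "B", 3)))

  expect_error(selectIncrements(sss, incrementSelection("A", 5)),
               "not resolvable")
  expect_error(incrementSelection(c("A", "A"), c(2, 2)), "duplicate")
})

test_that("window alignment carries dependence; broken alignment destroys it", {
  set.seed(21)
  base <- rnorm(6000)
  rec <- multiChannelRecording(rbind(base, base), fs = 20,
                               channelNames = c("orig", "copy"))
  sss <- sampleIncrements(rec, 1, 2)
  a <- incrementSamples(sss, "orig", 2)
  b <- incrementSamples(sss, "copy", 2)
  expect_warning(hi <- couplingValue(knnMI(a, b)), "functionally dependent")
  set.seed(22)
  lo <- couplingValue(knnMI(a, b[sample(nrow(b)), ]))
  expect_gt(hi, 2)
  expect_lt(abs(lo), 0.1)

  ## bit-exact reproducibility from identical recordings
  sss2 <- sampleIncrements(rec, 1, 2)
  expect_identical(sss@samples, sss2@samples)
})
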