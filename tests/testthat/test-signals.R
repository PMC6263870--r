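# Segmentation, signal derivation and the feature schema / extractor.

test_that("window counts follow the sliding-window arithmetic", {
  rec <- simulateRecording(c(standing = 2.56), seed = 1)
  ws <- segmentWindows(rec)
  expect_equal(dim(ws@values)[1], 128L)
  expect_equal(nWindows(ws), 1L)

  # N = 256, T = 128, hop = 64 -> 3 windows
  rec <- simulateRecording(c(standing = 5.12), seed = 1)
  expect_equal(nWindows(segmentWindows(rec)), 3L)

  # shorter than one window -> empty, not an error
  rec <- simulateRecording(c(standing = 2), seed = 1)
  expect_equal(nWindows(segmentWindows(rec)), 0L)

  expect_error(segmentWindows(rec, overlap = 1), "overlap")
  expect_error(segmentWindows(rec, overlap = -0.1), "overlap")
})

test_that("window labels are majority votes with canonical-order ties", {
  mk <- function(labels) {
    RawRecording(matrix(0, length(labels), 6),
      samplingRate = 50,
      labels = labels
    )
  }
  ws <- segmentWindows(mk(c(rep("walking", 100), rep("sitting", 28))),
    windowSeconds = 2.56, overlap = 0
  )
  expect_equal(windowLabels(ws), "walking")
  # exact tie: sitting precedes standing in the canonical order
  ws <- segmentWindows(mk(c(rep("standing", 64), rep("sitting", 64))),
    windowSeconds = 2.56, overlap = 0
  )
  expect_equal(windowLabels(ws), "sitting")
})

test_that("gravity/body decomposition conserves the filtered signal", {
  set.seed(42)
  for (i in 1:5) {
    w <- matrix(rnorm(128 * 6), 128, 6)
    ds <- deriveSignals(w, rate = 50)
    expect_lt(max(abs(ds$tBodyAcc + ds$tGravityAcc - ds$filteredAcc)), 1e-9)
    expect_equal(ds$tBodyGyroMag, sqrt(rowSums(ds$tBodyGyro^2)))
    expect_equal(nrow(ds$fBodyAcc), 64L)
  }
})

test_that("a constant window decomposes into gravity = the constant and body = 0", {
  w <- cbind(
    matrix(rep(c(0.6, -0.8, 0), each = 128), 128, 3),
    matrix(0, 128, 3)
  )
  ds <- deriveSignals(w, rate = 50)
  expect_lt(max(abs(sweep(ds$tGravityAcc, 2L, c(0.6, -0.8, 0)))), 1e-8)
  expect_lt(max(abs(ds$tBodyAcc)), 1e-8)
  # per-sample Euclidean norm: (0.6, -0.8, 0) has magnitude 1
  expect_equal(ds$tGravityAccMag, rep(1, 128), tolerance = 1e-6)
})

test_that("spectra match a direct discrete-Fourier evaluation and locate injected tones", {
  t <- (0:127) / 50
  w <- matrix(0, 128, 6)
  w[, 4] <- sin(2 * pi * 5 * t) # 5 Hz tone on gyro_x
  ds <- deriveSignals(w, rate = 50)
  m <- ds$fBodyGyro[, 1]
  peakHz <- ds$freqHz[which.max(m)]
  expect_lt(abs(peakHz - 5), 50 / 128 * 1.5) # within one bin

  # oracle: direct DFT of the derived time signal at a few bins
  for (k in c(1, 5, 13, 40)) {
    expect_equal(m[k], oDFTMagnitude(ds$tBodyGyro[, 1], k), tolerance = 1e-8)
  }
})

test_that("the pinned schema has the published tallies and unique names", {
  schema <- buildFeatureSchema()
  counts <- schemaCounts(schema)
  expect_equal(unname(counts["total"]), 561)
  expect_equal(unname(counts["time"]), 272)
  expect_equal(unname(counts["frequency"]), 289)
  expect_equal(unname(counts["acc"]), 348)
  expect_equal(unname(counts["gyro"]), 211)
  expect_equal(unname(counts["cross"]), 2)
  expect_false(anyDuplicated(schema$name) > 0)
  # sensor x domain cross-tabulation of the acc/gyro split
  expect_equal(sum(schema$sensor == "acc" & schema$domain == "time"), 164)
  expect_equal(sum(schema$sensor == "acc" & schema$domain == "frequency"), 184)
  expect_equal(sum(schema$sensor == "gyro" & schema$domain == "time"), 106)
  expect_equal(sum(schema$sensor == "gyro" & schema$domain == "frequency"), 105)
})

test_that("extraction is deterministic and covariant with schema reordering", {
  rec <- simulateRecording(c(walking = 2.56), seed = 9)
  w <- windowValues(segmentWindows(rec), 1)
  schema <- buildFeatureSchema()
  v1 <- extractFeatures(w, schema)
  v2 <- extractFeatures(w, schema)
  expect_identical(v1, v2)
  perm <- sample(nrow(schema))
  expect_identical(extractFeatures(w, schema[perm, ]), v1[perm])
  sub <- schema[schema$signal == "tBodyGyro", ]
  expect_identical(extractFeatures(w, sub), v1[sub$name])
})

test_that("degenerate windows give the expected constants", {
  w <- matrix(rep(c(1, 2, 3, 0, 0, 0), each = 128), 128, 6)
  v <- extractFeatures(w)
  # gyro is exactly zero: every tBodyGyro statistic of spread vanishes
  expect_equal(unname(v["tBodyGyro-mean()-X"]), 0)
  expect_equal(unname(v["tBodyGyro-std()-X"]), 0)
  expect_equal(unname(v["tBodyGyro-mad()-Y"]), 0)
  expect_equal(unname(v["tBodyGyro-iqr()-Z"]), 0)
  expect_equal(unname(v["tBodyGyro-energy()-X"]), 0)
  expect_equal(unname(v["tBodyGyro-sma()"]), 0)
  # constant acceleration: gravity mean equals the constant, body is zero
  expect_equal(unname(v["tGravityAcc-mean()-Y"]), 2, tolerance = 1e-8)
  expect_equal(unname(v["tBodyAcc-energy()-Z"]), 0, tolerance = 1e-12)
  # zero-variance correlation convention
  expect_equal(unname(v["tBodyGyro-correlation()-X,Y"]), 0)
})

test_that("identical axes correlate perfectly", {
  t <- (0:127) / 50
  w <- matrix(0, 128, 6)
  w[, 4] <- sin(2 * pi * 3 * t)
  w[, 5] <- w[, 4]
  v <- extractFeatures(w)
  expect_equal(unname(v["tBodyGyro-correlation()-X,Y"]), 1, tolerance = 1e-12)
})

test_that("autoregression coefficients agree with the reference Burg estimator", {
  set.seed(7)
  for (i in 1:10) {
    x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), 128)) + rnorm(128, sd = 0.1)
    ref <- stats::ar.burg(x, aic = FALSE, order.max = 4, demean = TRUE)$ar
    expect_equal(harrier:::.arCoeffs(x), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("feature ranges respect their definitions on random windows", {
  set.seed(11)
  schema <- buildFeatureSchema()
  for (i in 1:5) {
    w <- matrix(rnorm(128 * 6), 128, 6)
    v <- extractFeatures(w, schema)
    expect_true(all(v[schema$fun == "energy"] >= 0))
    expect_true(all(v[schema$fun == "entropy"] >= 0))
    expect_true(all(v[schema$fun == "bandsEnergy"] >= 0))
    expect_true(all(v[schema$fun == "mad"] >= 0))
    expect_true(all(v[schema$fun == "iqr"] >= 0))
    corr <- v[schema$fun == "correlation"]
    expect_true(all(corr >= -1 - 1e-12 & corr <= 1 + 1e-12))
  }
})

test_that("min/max rescaling maps bounds to [-1, 1] and round trips", {
  tr <- matrix(c(0, 5, 10, 2, 2, 2), ncol = 2) # second feature constant
  res <- normalizeFeatures(tr)
  expect_equal(res$tables[[1]][, 1], c(-1, 0, 1))
  expect_equal(res$tables[[1]][, 2], c(0, 0, 0)) # constant feature -> 0

  set.seed(13)
  x <- matrix(rnorm(60), 12, 5)
  res <- normalizeFeatures(x)
  back <- invertNormalization(res$tables[[1]], res$bounds)
  expect_equal(back, x, tolerance = 1e-12)

  extra <- matrix(rnorm(20), 4, 5)
  res2 <- normalizeFeatures(x, extra)
  expect_equal(applyNormalization(extra, res2$bounds), res2$tables[[2]])
})
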