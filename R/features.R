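# Per-window feature extraction over the pinned schema, and the
# [-1, 1] min/max rescaling convention.

# --- scalar feature functions ----------------------------------------------

# fast median of an already-sorted vector
.medianSorted <- function(sx) {
  n <- length(sx)
  if (n %% 2L) sx[(n + 1L) %/% 2L] else (sx[n %/% 2L] + sx[n %/% 2L + 1L]) / 2
}

.fastMedian <- function(x) .medianSorted(sort.int(x, method = "quick"))

# type-7 quantile of an already-sorted vector
.quantileSorted <- function(sx, p) {
  h <- (length(sx) - 1) * p + 1
  lo <- floor(h)
  v <- sx[lo]
  if (h > lo) v + (h - lo) * (sx[lo + 1L] - v) else v
}

.safeMad <- function(x) .fastMedian(abs(x - .fastMedian(x)))

.signalEnergy <- function(x) mean(x^2)

.signalIqr <- function(x) {
  sx <- sort.int(x, method = "quick")
  .quantileSorted(sx, 0.75) - .quantileSorted(sx, 0.25)
}

# Shannon entropy (bits) of a 10-bin equal-width histogram of the window.
.signalEntropy <- function(x, nBins = 10L) {
  r <- range(x)
  if (r[1] == r[2]) {
    return(0)
  }
  b <- pmin(floor((x - r[1]) / (r[2] - r[1]) * nBins) + 1L, nBins)
  p <- tabulate(b, nBins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

# Burg-estimated AR coefficients of fixed order (demeaned, forward +
# backward prediction-error minimisation); zero for (near-)constant or
# too-short input. Agrees with stats::ar.burg to machine precision but is
# fast enough for the per-window inner loop.
.arCoeffs <- function(x, order = 4L) {
  x <- x - mean(x)
  n <- length(x)
  if (n <= order + 1L || sum(x^2) < 1e-24) {
    return(rep(0, order))
  }
  f <- x[2:n]
  b <- x[1:(n - 1L)]
  a <- numeric(0)
  for (m in seq_len(order)) {
    den <- sum(f * f) + sum(b * b)
    k <- if (den == 0) 0 else 2 * sum(f * b) / den
    a <- if (length(a)) c(a - k * rev(a), k) else k
    fn <- f - k * b
    bn <- b - k * f
    f <- fn[-1L]
    b <- bn[-length(bn)]
  }
  a
}

# Pearson correlation with zero-variance inputs defined as 0.
.safeCor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(0)
  }
  cor(x, y)
}

# Angle (radians) between two vectors; 0 when either has zero norm.
.vectorAngle <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(0)
  }
  acos(min(1, max(-1, sum(a * b) / (na * nb))))
}

.spectralSkewness <- function(m) {
  s2 <- mean((m - mean(m))^2)
  if (s2 == 0) {
    return(0)
  }
  mean((m - mean(m))^3) / s2^1.5
}

.spectralKurtosis <- function(m) {
  s2 <- mean((m - mean(m))^2)
  if (s2 == 0) {
    return(0)
  }
  mean((m - mean(m))^4) / s2^2 - 3
}

# unnamed, fixed positions: mean, std, mad, max, min, energy, iqr, entropy
.scalarTime <- function(x) {
  sx <- sort.int(x, method = "quick")
  n <- length(sx)
  med <- .medianSorted(sx)
  c(
    mean(x), sd(x), .fastMedian(abs(x - med)),
    sx[n], sx[1],
    mean(x^2),
    .quantileSorted(sx, 0.75) - .quantileSorted(sx, 0.25),
    .signalEntropy(x)
  )
}

# 8 scalars per axis in schema order: mean,std,mad,max,min (x3), sma,
# energy,iqr,entropy (x3).
.triScalarBlock <- function(mat) {
  s <- vapply(seq_len(ncol(mat)), function(j) .scalarTime(mat[, j]), numeric(8))
  c(
    s[1, ], s[2, ], s[3, ], s[4, ], s[5, ],
    mean(rowSums(abs(mat))), # sma
    s[6, ], s[7, ], s[8, ]
  )
}

.triTimeBlock <- function(mat) {
  c(
    .triScalarBlock(mat),
    as.numeric(vapply(seq_len(ncol(mat)), function(j) .arCoeffs(mat[, j]), numeric(4))),
    .safeCor(mat[, 1], mat[, 2]),
    .safeCor(mat[, 1], mat[, 3]),
    .safeCor(mat[, 2], mat[, 3])
  )
}

.magTimeBlock <- function(x) {
  s <- .scalarTime(x)
  c(
    s[1:5], # mean, std, mad, max, min
    mean(abs(x)), # sma
    s[6:8], # energy, iqr, entropy
    .arCoeffs(x)
  )
}

.freqAxisExtras <- function(m, freqHz) {
  maxInds <- freqHz[which.max(m)]
  meanFreq <- if (sum(m) == 0) 0 else sum(freqHz * m) / sum(m)
  c(maxInds, meanFreq)
}

.triFreqBlock <- function(mat, freqHz) {
  nb <- nrow(mat)
  extras <- vapply(seq_len(ncol(mat)), function(j) {
    .freqAxisExtras(mat[, j], freqHz)
  }, numeric(2))
  skewkurt <- as.numeric(vapply(seq_len(ncol(mat)), function(j) {
    c(.spectralSkewness(mat[, j]), .spectralKurtosis(mat[, j]))
  }, numeric(2)))
  bands <- .bandRanges(nb)
  bandsE <- as.numeric(vapply(seq_len(ncol(mat)), function(j) {
    m <- mat[, j]
    vapply(bands, function(r) sum(m[r[1]:r[2]]^2), numeric(1))
  }, numeric(length(bands))))
  c(
    .triScalarBlock(mat),
    extras[1, ], extras[2, ],
    skewkurt,
    bandsE
  )
}

.magFreqBlock <- function(m, freqHz) {
  s <- .scalarTime(m)
  ex <- .freqAxisExtras(m, freqHz)
  c(
    s[1:5], # mean, std, mad, max, min
    mean(abs(m)), # sma
    s[6:8], # energy, iqr, entropy
    ex[1], ex[2],
    .spectralSkewness(m), .spectralKurtosis(m)
  )
}

# Full pinned feature vector (561 values in schema order) from derived
# signals.
.allFeatures <- function(ds) {
  out <- c(
    unlist(lapply(
      ds[.timeTriSignals()], .triTimeBlock
    ), use.names = FALSE),
    unlist(lapply(
      ds[.timeMagSignals()], .magTimeBlock
    ), use.names = FALSE)
  )
  gMean <- colMeans(ds$tGravityAcc)
  angles <- c(
    .vectorAngle(colMeans(ds$tBodyAcc), gMean),
    .vectorAngle(colMeans(ds$tBodyAccJerk), gMean),
    .vectorAngle(colMeans(ds$tBodyGyro), gMean),
    .vectorAngle(colMeans(ds$tBodyGyroJerk), gMean),
    .vectorAngle(c(1, 0, 0), gMean),
    .vectorAngle(c(0, 1, 0), gMean),
    .vectorAngle(c(0, 0, 1), gMean)
  )
  out <- c(out, angles)
  out <- c(out, unlist(lapply(
    ds[.freqTriSignals()], .triFreqBlock,
    freqHz = ds$freqHz
  ), use.names = FALSE))
  out <- c(out, unlist(lapply(
    ds[.freqMagSignals()], .magFreqBlock,
    freqHz = ds$freqHz
  ), use.names = FALSE))
  out
}

#' Extract the schema features from one window
#'
#' Derives the signal families of a window and evaluates the requested
#' schema descriptors. The result is aligned with the schema order, so
#' extraction is covariant with any reordering or subsetting of the
#' schema rows.
#'
#' @param values \code{T x 6} numeric window (acc in g, gyro in rad/s).
#' @param schema Schema rows to evaluate; defaults to the full pinned
#'   schema of \code{\link{buildFeatureSchema}}.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector, one value per schema row.
#' @export
extractFeatures <- function(values, schema = buildFeatureSchema(), rate = 50) {
  full <- buildFeatureSchema()
  v <- .allFeatures(deriveSignals(values, rate))
  names(v) <- full$name
  v[schema$name]
}

#' Extract a feature table from a window set
#'
#' Applies \code{\link{extractFeatures}} to every window.
#'
#' @param windows A \code{\link{WindowSet}}.
#' @param schema Schema rows to evaluate (default: full pinned schema).
#' @param rate Sampling rate; defaults to the window set's rate.
#' @return A \code{\link{FeatureTable}} carrying the window labels.
#' @export
#' @examples
#' rec <- simulateRecording(c(standing = 10, walking = 10), seed = 1)
#' ws <- segmentWindows(rec)
#' tab <- extractFeatureTable(ws)
#' tab
extractFeatureTable <- function(windows, schema = buildFeatureSchema(),
                                rate = NULL) {
  stopifnot(is(windows, "WindowSet"))
  if (is.null(rate)) rate <- windows@samplingRate
  n <- nWindows(windows)
  vals <- matrix(0, n, nrow(schema))
  for (i in seq_len(n)) {
    vals[i, ] <- extractFeatures(windowValues(windows, i), schema, rate)
  }
  colnames(vals) <- schema$name
  FeatureTable(
    vals,
    labels = if (length(windows@labels)) windows@labels else NULL,
    subject = if (length(windows@subject)) windows@subject else NULL
  )
}

# ---------------------------------------------------------------------------
# [-1, 1] rescaling
# ---------------------------------------------------------------------------

#' Min/max feature rescaling to [-1, 1]
#'
#' Fits a per-feature affine map on the training table that sends the
#' training minimum and maximum to -1 and +1, and applies the same map
#' unchanged to any further tables. Constant features map to 0.
#' \code{applyNormalization} and \code{invertNormalization} apply and
#' undo a fitted map.
#'
#' @param train Training \code{FeatureTable} or matrix (non-empty).
#' @param ... Further tables to rescale with the training bounds.
#' @return \code{normalizeFeatures} returns a list with \code{tables} (a
#'   list of rescaled tables: the training table first, then the extras)
#'   and \code{bounds} (a data frame of per-feature \code{min} and
#'   \code{max}).
#' @export
#' @examples
#' tr <- matrix(c(0, 5, 10), ncol = 1)
#' normalizeFeatures(tr)$tables[[1]]
normalizeFeatures <- function(train, ...) {
  trainM <- asFeatureMatrix(train)$values
  stopIfNot(nrow(trainM) > 0, "training table is empty")
  bounds <- data.frame(
    min = apply(trainM, 2L, min),
    max = apply(trainM, 2L, max)
  )
  rownames(bounds) <- colnames(trainM)
  tables <- lapply(c(list(train), list(...)), applyNormalization, bounds = bounds)
  list(tables = tables, bounds = bounds)
}

.rescaleMatrix <- function(m, bounds, invert = FALSE) {
  stopIfNot(
    ncol(m) == nrow(bounds),
    "table has ", ncol(m), " features but bounds cover ", nrow(bounds)
  )
  span <- bounds$max - bounds$min
  out <- m
  for (j in seq_len(ncol(m))) {
    if (span[j] == 0) {
      out[, j] <- if (invert) bounds$min[j] else 0
    } else if (invert) {
      out[, j] <- (m[, j] + 1) / 2 * span[j] + bounds$min[j]
    } else {
      out[, j] <- (m[, j] - bounds$min[j]) / span[j] * 2 - 1
    }
  }
  out
}

#' @rdname normalizeFeatures
#' @param x Table to rescale (or un-rescale).
#' @param bounds Bounds data frame from a previous fit.
#' @export
applyNormalization <- function(x, bounds) {
  if (is(x, "FeatureTable")) {
    FeatureTable(.rescaleMatrix(featureValues(x), bounds),
      labels = activityLabels(x)
    )
  } else {
    .rescaleMatrix(as.matrix(x), bounds)
  }
}

#' @rdname normalizeFeatures
#' @export
invertNormalization <- function(x, bounds) {
  if (is(x, "FeatureTable")) {
    FeatureTable(.rescaleMatrix(featureValues(x), bounds, invert = TRUE),
      labels = activityLabels(x)
    )
  } else {
    .rescaleMatrix(as.matrix(x), bounds, invert = TRUE)
  }
}
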