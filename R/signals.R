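# Sliding-window segmentation and derivation of the time/frequency signal
# families from a raw six-channel window.

#' Sliding-window segmentation
#'
#' Cuts a recording into fixed-length windows of
#' \code{round(rate * windowSeconds)} samples with hop
#' \code{T * (1 - overlap)}. A recording shorter than one window yields an
#' empty set. Each window is labelled by the majority of its per-sample
#' labels; ties are broken in favour of the earlier activity in
#' \code{\link{activityOrder}} (unknown activities follow, alphabetically).
#'
#' @param recording A \code{\link{RawRecording}}.
#' @param windowSeconds Window length in seconds (default 2.56, i.e. 128
#'   samples at 50 Hz).
#' @param overlap Fractional overlap between adjacent windows, in
#'   \code{[0, 1)} (default 0.5).
#' @return A \code{\link{WindowSet}}.
#' @export
#' @examples
#' rec <- simulateRecording(c(standing = 6), seed = 1)
#' segmentWindows(rec)
segmentWindows <- function(recording, windowSeconds = 2.56, overlap = 0.5) {
  stopifnot(is(recording, "RawRecording"))
  stopIfNot(
    overlap >= 0 && overlap < 1,
    "'overlap' must lie in [0, 1), got ", overlap
  )
  rate <- recording@samplingRate
  T <- round(rate * windowSeconds)
  stopIfNot(T >= 2, "window length must be at least 2 samples")
  N <- nrow(recording@samples)
  hop <- round(T * (1 - overlap))
  stopIfNot(hop >= 1, "overlap too large: hop below one sample")
  if (N < T) {
    return(WindowSet(array(0, dim = c(T, 6, 0)), samplingRate = rate))
  }
  nWin <- floor((N - T) / hop) + 1L
  values <- array(0, dim = c(T, 6L, nWin))
  labels <- character()
  hasLabels <- length(recording@labels) > 0L
  if (hasLabels) labels <- character(nWin)
  for (w in seq_len(nWin)) {
    i0 <- (w - 1L) * hop + 1L
    values[, , w] <- recording@samples[i0:(i0 + T - 1L), ]
    if (hasLabels) {
      labels[w] <- majorityLabel(recording@labels[i0:(i0 + T - 1L)])
    }
  }
  WindowSet(values, samplingRate = rate, labels = labels)
}

# Majority vote with deterministic tie-breaking: the earlier activity in
# the canonical order wins; activities outside it follow alphabetically.
majorityLabel <- function(labels) {
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) {
    return(winners)
  }
  pref <- c(activityOrder(), sort(setdiff(winners, activityOrder())))
  winners[order(match(winners, pref))][1]
}

# ---------------------------------------------------------------------------
# Signal derivation
# ---------------------------------------------------------------------------

# One forward pass of the IIR filter (b, a) with zero initial conditions.
.iirPass <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)[nb:length(xp)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

# Zero-phase (forward-backward) application of (b, a); numerically
# identical to signal::filtfilt with the same zero padding.
.zeroPhase <- function(b, a, x) {
  npad <- 2L * max(length(a), length(b))
  y <- .iirPass(b, a, c(x, rep(0, npad)))
  y <- rev(.iirPass(b, a, rev(y)))
  y[seq_along(x)]
}

# Zero-phase Butterworth low-pass (order 3) of each column. The filter
# design is cached per (order, normalised cutoff).
.lowpass <- function(x, cutoffHz, rate, order = 3) {
  w <- cutoffHz / (rate / 2)
  if (w >= 1) {
    return(x)
  }
  key <- paste0("butter_", order, "_", signif(w, 12))
  bf <- get0(key, envir = .harrierCache)
  if (is.null(bf)) {
    bf <- signal::butter(order, w, type = "low")
    assign(key, bf, envir = .harrierCache)
  }
  # filter the demeaned signal and restore the mean: the DC component
  # passes a low-pass unchanged in steady state, and demeaning removes the
  # zero-padding transient that would otherwise dominate a short window
  # at a 0.3 Hz corner
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j])
    x[, j] <- mu + .zeroPhase(bf$b, bf$a, x[, j] - mu)
  }
  x
}

# 3-sample running median denoiser per column.
.median3 <- function(x) {
  for (j in seq_len(ncol(x))) {
    x[, j] <- as.numeric(stats::runmed(x[, j], 3L))
  }
  x
}

# First difference scaled by the rate, padded (last value repeated) to
# keep the window length.
.jerk <- function(x, rate) {
  d <- diff(x) * rate
  rbind(d, d[nrow(d), , drop = FALSE])
}

.rowNorms <- function(x) sqrt(rowSums(x^2))

# Magnitudes of the non-DC bins of the real FFT (bins 1..floor(T/2)).
.spectrum <- function(x) {
  T <- length(x)
  nb <- floor(T / 2)
  Mod(fft(x))[2:(nb + 1L)]
}

.spectrumCols <- function(x) apply(x, 2L, .spectrum)

#' Derive the time- and frequency-domain signal families
#'
#' From one six-channel window, computes the standard inertial signal
#' families: the filtered total acceleration is separated into gravity
#' (zero-phase Butterworth low-pass, order 3, 0.3 Hz corner, after a
#' 3-sample median filter and a 20 Hz low-pass denoiser) and body
#' acceleration (their difference, so body + gravity reproduces the
#' filtered signal exactly). Filters run on the demeaned signal with the
#' mean restored afterwards, so a constant window decomposes exactly into
#' gravity = the constant and body = 0. Jerk signals are first differences scaled by
#' the rate; magnitudes are per-sample Euclidean norms; and spectra are
#' the magnitudes of the non-DC bins of the real FFT of the body signals
#' and magnitudes (no windowing taper).
#'
#' @param values \code{T x 6} numeric matrix (acc_x..gyro_z) or a
#'   \code{WindowSet} index pair.
#' @param rate Sampling rate in Hz.
#' @return Named list of signals: tri-axial matrices (\code{tBodyAcc},
#'   \code{tGravityAcc}, \code{tBodyAccJerk}, \code{tBodyGyro},
#'   \code{tBodyGyroJerk}), magnitude vectors (\code{tBodyAccMag} ...),
#'   and spectra (\code{fBodyAcc} ... \code{fBodyGyroJerkMag}), plus
#'   \code{freqHz}, the bin frequencies of the spectra.
#' @export
deriveSignals <- function(values, rate) {
  values <- as.matrix(values)
  stopIfNot(ncol(values) == 6L, "a window must have 6 channels")
  stopIfNot(!anyNA(values), "window contains missing values")
  acc <- .lowpass(.median3(values[, 1:3, drop = FALSE]), 20, rate)
  gyro <- .lowpass(.median3(values[, 4:6, drop = FALSE]), 20, rate)
  gravity <- .lowpass(acc, 0.3, rate)
  body <- acc - gravity
  bodyJerk <- .jerk(body, rate)
  gyroJerk <- .jerk(gyro, rate)
  s <- list(
    tBodyAcc = body,
    tGravityAcc = gravity,
    tBodyAccJerk = bodyJerk,
    tBodyGyro = gyro,
    tBodyGyroJerk = gyroJerk,
    filteredAcc = acc,
    tBodyAccMag = .rowNorms(body),
    tGravityAccMag = .rowNorms(gravity),
    tBodyAccJerkMag = .rowNorms(bodyJerk),
    tBodyGyroMag = .rowNorms(gyro),
    tBodyGyroJerkMag = .rowNorms(gyroJerk)
  )
  s$fBodyAcc <- .spectrumCols(body)
  s$fBodyAccJerk <- .spectrumCols(bodyJerk)
  s$fBodyGyro <- .spectrumCols(gyro)
  s$fBodyAccMag <- .spectrum(s$tBodyAccMag)
  s$fBodyAccJerkMag <- .spectrum(s$tBodyAccJerkMag)
  s$fBodyGyroMag <- .spectrum(s$tBodyGyroMag)
  s$fBodyGyroJerkMag <- .spectrum(s$tBodyGyroJerkMag)
  T <- nrow(values)
  s$freqHz <- seq_len(floor(T / 2)) * rate / T
  s
}
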