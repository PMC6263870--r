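# Synthetic inertial streams and planted-structure feature tables, so the
# whole pipeline is testable without any external recording.

#' Default dynamic-gait parameters
#'
#' Per-activity oscillation frequency (Hz), amplitude (g) and signed
#' vertical bias (g) of the dynamic activities. Walking has the highest
#' cadence and no bias; going upstairs and downstairs share the same gait
#' but differ by the sign of the vertical bias, which makes them the
#' confusable pair within the dynamic group.
#'
#' @return Data frame with columns \code{activity}, \code{freq},
#'   \code{amp}, \code{bias}.
#' @export
defaultGaitParams <- function() {
  data.frame(
    activity = c("walking", "upstairs", "downstairs"),
    freq = c(2.0, 1.4, 1.4),
    amp = c(0.6, 0.5, 0.5),
    bias = c(0, 0.15, -0.15),
    stringsAsFactors = FALSE
  )
}

#' Default static-posture gravity orientations
#'
#' Unit gravity direction (in the device frame, g) of each static
#' posture: standing is upright (+z), sitting is the same posture tilted
#' by 25 degrees (hence confusable with standing), lying is horizontal
#' (+x).
#'
#' @return Named list of unit 3-vectors.
#' @export
defaultOrientations <- function() {
  tilt <- 25 * pi / 180
  list(
    standing = c(0, 0, 1),
    sitting = c(sin(tilt), 0, cos(tilt)),
    lying = c(1, 0, 0)
  )
}

#' Simulate a labelled inertial recording
#'
#' Generates a tri-axial accelerometer + gyroscope stream following an
#' ordered activity plan. Static postures are a constant gravity vector
#' plus Gaussian noise (gyroscope pure noise); dynamic activities are
#' gravity plus a sinusoidal gait oscillation with activity-specific
#' frequency, amplitude and signed vertical bias, plus noise, with a
#' matching oscillation on the gyroscope. With \code{noiseSd = 0} a
#' static segment is exactly the gravity vector and the gyroscope exactly
#' zero.
#'
#' @param plan Activity plan: a data frame with columns \code{activity}
#'   and \code{seconds}, or a named numeric vector of durations.
#' @param samplingRate Sampling rate in Hz (default 50).
#' @param noiseSd Gaussian noise standard deviation, g (accelerometer)
#'   and rad/s (gyroscope). Default 0.05.
#' @param gaitParams Dynamic-activity parameters, see
#'   \code{\link{defaultGaitParams}}.
#' @param orientations Static gravity orientations, see
#'   \code{\link{defaultOrientations}}; each must be a unit vector.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   streams.
#' @return A \code{\link{RawRecording}} with per-sample labels.
#' @export
#' @examples
#' rec <- simulateRecording(c(standing = 2.56), seed = 1)
#' rec
simulateRecording <- function(plan, samplingRate = 50, noiseSd = 0.05,
                              gaitParams = defaultGaitParams(),
                              orientations = defaultOrientations(),
                              seed = NULL) {
  stopIfNot(samplingRate > 0, "'samplingRate' must be positive")
  if (!is.data.frame(plan)) {
    plan <- data.frame(
      activity = names(plan), seconds = as.numeric(plan),
      stringsAsFactors = FALSE
    )
  }
  stopIfNot(
    all(c("activity", "seconds") %in% names(plan)),
    "'plan' needs columns 'activity' and 'seconds'"
  )
  stopIfNot(all(plan$seconds > 0), "durations must be positive")
  known <- c(gaitParams$activity, names(orientations))
  bad <- setdiff(plan$activity, known)
  if (length(bad)) {
    stop("unknown activity: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (v in orientations) {
    stopIfNot(
      abs(sqrt(sum(v^2)) - 1) < 1e-8,
      "orientation vectors must have unit norm"
    )
  }
  withSeed(seed, {
    segs <- lapply(seq_len(nrow(plan)), function(i) {
      act <- plan$activity[i]
      n <- round(plan$seconds[i] * samplingRate)
      t <- seq_len(n) / samplingRate
      acc <- matrix(0, n, 3)
      gyro <- matrix(0, n, 3)
      if (act %in% names(orientations)) {
        g <- orientations[[act]]
        acc <- matrix(g, n, 3, byrow = TRUE)
      } else {
        gp <- gaitParams[gaitParams$activity == act, ]
        w <- 2 * pi * gp$freq
        acc[, 1] <- 0.4 * gp$amp * sin(w * t + pi / 2)
        acc[, 2] <- 0.2 * gp$amp * sin(w * t + pi / 4)
        acc[, 3] <- 1 + gp$bias + gp$amp * sin(w * t)
        gyro[, 1] <- 0.5 * gp$amp * sin(w * t + pi / 3)
        gyro[, 2] <- 0.3 * gp$amp * sin(w * t + 2 * pi / 3)
        gyro[, 3] <- 0.1 * gp$amp * sin(w * t)
      }
      if (noiseSd > 0) {
        acc <- acc + matrix(rnorm(3 * n, sd = noiseSd), n, 3)
        gyro <- gyro + matrix(rnorm(3 * n, sd = noiseSd), n, 3)
      }
      list(values = cbind(acc, gyro), labels = rep(act, n))
    })
    RawRecording(
      do.call(rbind, lapply(segs, `[[`, "values")),
      samplingRate = samplingRate,
      labels = unlist(lapply(segs, `[[`, "labels"), use.names = FALSE)
    )
  })
}

#' Planted-structure feature table
#'
#' Generates a labelled feature table in which class membership is
#' decided by exactly one informative feature per class against a
#' threshold (class \code{k} samples lie strictly on one side of feature
#' \eqn{F_k}'s threshold, all other samples strictly on the other side),
#' while the remaining features are label-independent Gaussian noise.
#' Class-dependent selection should therefore recover exactly
#' \eqn{\{F_1\}, \{F_2\}, \ldots} as the per-class subsets.
#'
#' @param nPerClass Samples per class (labels are balanced).
#' @param nClasses Number of classes \code{C >= 2}.
#' @param informative Optional data frame with one row per class and
#'   columns \code{feature} (index), \code{threshold} and
#'   \code{direction} (\code{"below"} or \code{"above"}: the side of the
#'   threshold on which class members lie). Defaults to feature \code{k}
#'   for class \code{k}, threshold 0, alternating directions.
#' @param nNoiseFeatures Number of irrelevant standard-normal features.
#' @param margin Mean distance of samples from the threshold (default 1).
#' @param seed Optional integer seed.
#' @return A \code{\link{FeatureTable}} with labels \code{A1..AC}.
#' @export
#' @examples
#' tab <- makePlantedTable(nPerClass = 50, nClasses = 3, seed = 7)
#' tab
makePlantedTable <- function(nPerClass = 100, nClasses = 3,
                             informative = NULL, nNoiseFeatures = 5,
                             margin = 1, seed = NULL) {
  stopIfNot(nClasses >= 2L, "at least 2 classes required")
  stopIfNot(nPerClass >= 1L, "'nPerClass' must be positive")
  if (is.null(informative)) {
    informative <- data.frame(
      feature = seq_len(nClasses),
      threshold = 0,
      direction = rep(c("below", "above"), length.out = nClasses),
      stringsAsFactors = FALSE
    )
  }
  stopIfNot(
    nrow(informative) == nClasses,
    "'informative' needs one row per class"
  )
  stopIfNot(
    !anyDuplicated(informative$feature),
    "informative features must be pairwise distinct"
  )
  totalFeatures <- nClasses + nNoiseFeatures
  stopIfNot(
    all(informative$feature <= totalFeatures),
    "informative feature index exceeds the total number of features (",
    totalFeatures, ")"
  )
  n <- nPerClass * nClasses
  labels <- rep(paste0("A", seq_len(nClasses)), each = nPerClass)
  withSeed(seed, {
    x <- matrix(rnorm(n * totalFeatures), n, totalFeatures)
    for (k in seq_len(nClasses)) {
      j <- informative$feature[k]
      thr <- informative$threshold[k]
      side <- informative$direction[k]
      member <- labels == paste0("A", k)
      offset <- abs(rnorm(n, mean = margin, sd = 0.3)) + 1e-6
      s <- if (side == "below") -1 else 1
      x[, j] <- ifelse(member, thr + s * offset, thr - s * offset)
    }
    colnames(x) <- paste0("F", seq_len(totalFeatures))
    FeatureTable(x, labels = labels)
  })
}
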