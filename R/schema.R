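# The pinned 561-descriptor feature schema: 272 time-domain and 289
# frequency-domain descriptors over the derived signal families, with the
# sensor split 348 accelerometer-only / 211 gyroscope-only / 2
# cross-sensor.

.timeTriSignals <- function() {
  c("tBodyAcc", "tGravityAcc", "tBodyAccJerk", "tBodyGyro", "tBodyGyroJerk")
}
.timeMagSignals <- function() {
  c(
    "tBodyAccMag", "tGravityAccMag", "tBodyAccJerkMag", "tBodyGyroMag",
    "tBodyGyroJerkMag"
  )
}
.freqTriSignals <- function() c("fBodyAcc", "fBodyAccJerk", "fBodyGyro")
.freqMagSignals <- function() {
  c("fBodyAccMag", "fBodyAccJerkMag", "fBodyGyroMag", "fBodyGyroJerkMag")
}

.sensorOf <- function(signal) {
  ifelse(grepl("Gyro", signal), "gyro", "acc")
}

# Frequency-band index ranges over nb non-DC bins: eight equal bands, then
# four, then two (14 per axis).
.bandRanges <- function(nb = 64L) {
  out <- list()
  for (parts in c(8L, 4L, 2L)) {
    edges <- round(seq(0L, nb, length.out = parts + 1L))
    for (i in seq_len(parts)) {
      out[[length(out) + 1L]] <- c(edges[i] + 1L, edges[i + 1L])
    }
  }
  out
}

.scalarTimeFuns <- function() {
  c("mean", "std", "mad", "max", "min")
}

# One block = a set of schema rows sharing a signal.
.schemaRows <- function(signal, fun, arg, domain, sensor) {
  data.frame(
    name = if (is.na(arg[1]) && length(arg) == 1L) {
      paste0(signal, "-", fun, "()")
    } else {
      paste0(signal, "-", fun, "()-", arg)
    },
    signal = signal, fun = fun, arg = arg,
    domain = domain, sensor = sensor, stringsAsFactors = FALSE
  )
}

#' Build the pinned 561-feature schema
#'
#' Returns the ordered schema of the 561 per-window descriptors:
#' \itemize{
#'   \item 5 tri-axial time signals x 40 descriptors (per-axis mean, std,
#'     mad, max, min, energy, iqr, entropy; sma; 4 Burg autoregression
#'     coefficients per axis; 3 inter-axis correlations) = 200;
#'   \item 5 time magnitudes x 13 (the 9 scalar functions + 4 AR
#'     coefficients) = 65;
#'   \item 7 angle descriptors (5 accelerometer-only, 2 cross-sensor);
#'   \item 3 tri-axial spectra x 79 (per-axis scalars; sma; per-axis
#'     maxInds, meanFreq, skewness, kurtosis; 42 bands energies) = 237;
#'   \item 4 spectral magnitudes x 13 = 52.
#' }
#' Total 561 = 272 time + 289 frequency descriptors; by source sensor,
#' 348 accelerometer-only, 211 gyroscope-only and 2 cross-sensor (the
#' angles of the gyroscope mean vectors against gravity).
#'
#' @return A data frame of class \code{FeatureSchema} with columns
#'   \code{name}, \code{signal}, \code{fun}, \code{arg}, \code{domain}
#'   and \code{sensor}; the ordering is deterministic.
#' @export
#' @examples
#' schema <- buildFeatureSchema()
#' nrow(schema) # 561
#' table(schema$domain)
#' table(schema$sensor)
buildFeatureSchema <- function() {
  cached <- get0(".featureSchemaCache", envir = .harrierCache)
  if (!is.null(cached)) {
    return(cached)
  }
  axes <- c("X", "Y", "Z")
  blocks <- list()
  add <- function(df) blocks[[length(blocks) + 1L]] <<- df

  # tri-axial time signals: 40 each
  for (sig in .timeTriSignals()) {
    sen <- .sensorOf(sig)
    for (fn in .scalarTimeFuns()) {
      add(.schemaRows(sig, fn, axes, "time", sen))
    }
    add(.schemaRows(sig, "sma", NA_character_, "time", sen))
    for (fn in c("energy", "iqr", "entropy")) {
      add(.schemaRows(sig, fn, axes, "time", sen))
    }
    add(.schemaRows(
      sig, "arCoeff",
      paste0(rep(axes, each = 4L), ",", rep(1:4, 3L)), "time", sen
    ))
    add(.schemaRows(sig, "correlation", c("X,Y", "X,Z", "Y,Z"), "time", sen))
  }

  # time magnitudes: 13 each
  for (sig in .timeMagSignals()) {
    sen <- .sensorOf(sig)
    for (fn in c(.scalarTimeFuns(), "sma", "energy", "iqr", "entropy")) {
      add(.schemaRows(sig, fn, NA_character_, "time", sen))
    }
    add(.schemaRows(sig, "arCoeff", as.character(1:4), "time", sen))
  }

  # angle features (time domain)
  angleArgs <- c(
    "tBodyAccMean,gravityMean", "tBodyAccJerkMean,gravityMean",
    "tBodyGyroMean,gravityMean", "tBodyGyroJerkMean,gravityMean",
    "X,gravityMean", "Y,gravityMean", "Z,gravityMean"
  )
  angleSensor <- c("acc", "acc", "both", "both", "acc", "acc", "acc")
  add(data.frame(
    name = paste0("angle(", angleArgs, ")"),
    signal = "angle", fun = "angle", arg = angleArgs,
    domain = "time", sensor = angleSensor, stringsAsFactors = FALSE
  ))

  # tri-axial spectra: 79 each
  bandNames <- vapply(
    .bandRanges(), function(r) paste0(r[1], ",", r[2]),
    character(1)
  )
  for (sig in .freqTriSignals()) {
    sen <- .sensorOf(sig)
    for (fn in .scalarTimeFuns()) {
      add(.schemaRows(sig, fn, axes, "frequency", sen))
    }
    add(.schemaRows(sig, "sma", NA_character_, "frequency", sen))
    for (fn in c("energy", "iqr", "entropy", "maxInds", "meanFreq")) {
      add(.schemaRows(sig, fn, axes, "frequency", sen))
    }
    for (ax in axes) {
      add(.schemaRows(sig, "skewness", ax, "frequency", sen))
      add(.schemaRows(sig, "kurtosis", ax, "frequency", sen))
    }
    add(.schemaRows(
      sig, "bandsEnergy",
      paste0(rep(bandNames, 3L), "-", rep(axes, each = length(bandNames))),
      "frequency", sen
    ))
  }

  # spectral magnitudes: 13 each
  for (sig in .freqMagSignals()) {
    sen <- .sensorOf(sig)
    for (fn in c(
      .scalarTimeFuns(), "sma", "energy", "iqr", "entropy",
      "maxInds", "meanFreq", "skewness", "kurtosis"
    )) {
      add(.schemaRows(sig, fn, NA_character_, "frequency", sen))
    }
  }

  schema <- do.call(rbind, blocks)
  rownames(schema) <- NULL
  class(schema) <- c("FeatureSchema", "data.frame")
  assign(".featureSchemaCache", schema, envir = .harrierCache)
  schema
}

.harrierCache <- new.env(parent = emptyenv())

#' Schema summary counts
#'
#' Tallies of the pinned schema by domain and source sensor.
#'
#' @param schema A schema from \code{\link{buildFeatureSchema}}.
#' @return Named integer vector with \code{total}, \code{time},
#'   \code{frequency}, \code{acc}, \code{gyro}, \code{cross}.
#' @export
schemaCounts <- function(schema = buildFeatureSchema()) {
  c(
    total = nrow(schema),
    time = sum(schema$domain == "time"),
    frequency = sum(schema$domain == "frequency"),
    acc = sum(schema$sensor == "acc"),
    gyro = sum(schema$sensor == "gyro"),
    cross = sum(schema$sensor == "both")
  )
}
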