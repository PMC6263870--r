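#' @import methods
#' @importFrom stats cor fft median quantile sd var setNames rnorm runif predict
NULL

#' Canonical six-activity label order
#'
#' The canonical ordering of the six basic activities used throughout the
#' package: the three dynamic activities (walking, walking upstairs, walking
#' downstairs) followed by the three static postures (sitting, standing,
#' lying). Majority-vote ties during window labelling are broken in favour
#' of the earlier activity in this order.
#'
#' @return Character vector of length six.
#' @export
#' @examples
#' activityOrder()
activityOrder <- function() {
  c("walking", "upstairs", "downstairs", "sitting", "standing", "lying")
}

# ---------------------------------------------------------------------------
# RawRecording
# ---------------------------------------------------------------------------

#' @rdname RawRecording
#' @export
setClass("RawRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    labels = "character"
  )
)

setValidity("RawRecording", function(object) {
  msg <- NULL
  if (!is.numeric(object@samples)) {
    msg <- c(msg, "'samples' must be a numeric matrix")
  }
  if (ncol(object@samples) != 6L) {
    msg <- c(msg, "'samples' must have 6 columns (acc_x..gyro_z)")
  }
  if (!identical(colnames(object@samples), recordingChannels())) {
    msg <- c(msg, "column names must be acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z")
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
    msg <- c(msg, "'samplingRate' must be a single positive number")
  }
  if (length(object@labels) && length(object@labels) != nrow(object@samples)) {
    msg <- c(msg, "'labels' must be empty or one per sample")
  }
  if (anyNA(object@samples)) msg <- c(msg, "'samples' must not contain NA")
  if (is.null(msg)) TRUE else msg
})

#' Raw inertial recording
#'
#' A fixed-rate stream of tri-axial accelerometer (g) and gyroscope (rad/s)
#' readings with optional per-sample activity labels.
#'
#' @param samples Numeric matrix with columns
#'   \code{acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z}.
#' @param samplingRate Sampling rate in Hz.
#' @param labels Optional character vector of per-sample activity labels.
#' @return A \code{RawRecording} object.
#' @export
RawRecording <- function(samples, samplingRate, labels = character()) {
  samples <- as.matrix(samples)
  colnames(samples) <- recordingChannels()
  new("RawRecording",
    samples = samples, samplingRate = as.numeric(samplingRate),
    labels = as.character(labels)
  )
}

recordingChannels <- function() {
  c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
}

setMethod("show", "RawRecording", function(object) {
  n <- nrow(object@samples)
  cat(
    "RawRecording:", n, "samples at", object@samplingRate, "Hz (",
    format(n / object@samplingRate, digits = 4), "s )\n"
  )
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat(
      "labels:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n"
    )
  } else {
    cat("labels: none\n")
  }
})

# ---------------------------------------------------------------------------
# WindowSet
# ---------------------------------------------------------------------------

#' @rdname WindowSet
#' @export
setClass("WindowSet",
  representation(
    values = "array",
    labels = "character",
    samplingRate = "numeric",
    subject = "character"
  )
)

setValidity("WindowSet", function(object) {
  msg <- NULL
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "'values' must be a T x 6 x n array")
  else {
    if (d[2] != 6L) msg <- c(msg, "windows must have 6 channels")
    if (length(object@labels) && length(object@labels) != d[3]) {
      msg <- c(msg, "'labels' must be empty or one per window")
    }
    if (length(object@subject) && length(object@subject) != d[3]) {
      msg <- c(msg, "'subject' must be empty or one per window")
    }
  }
  if (anyNA(object@values)) msg <- c(msg, "windows must not contain NA")
  if (is.null(msg)) TRUE else msg
})

#' Set of fixed-length sensor windows
#'
#' Fixed-length segments of a six-channel inertial stream, stored as a
#' \code{T x 6 x n} array together with one activity label per window.
#'
#' @param values \code{T x 6 x n} numeric array (samples x channels x
#'   windows).
#' @param labels Optional character vector, one label per window.
#' @param samplingRate Sampling rate in Hz.
#' @param subject Optional character vector of subject identifiers.
#' @return A \code{WindowSet} object.
#' @export
WindowSet <- function(values, samplingRate, labels = character(),
                      subject = character()) {
  new("WindowSet",
    values = values, samplingRate = as.numeric(samplingRate),
    labels = as.character(labels), subject = as.character(subject)
  )
}

#' @describeIn WindowSet number of windows in the set
#' @param x,object A \code{WindowSet}.
#' @export
nWindows <- function(x) {
  stopifnot(is(x, "WindowSet"))
  dim(x@values)[3]
}

#' @describeIn WindowSet extract one window as a \code{T x 6} matrix
#' @param i Window index.
#' @export
windowValues <- function(x, i) {
  stopifnot(is(x, "WindowSet"))
  v <- x@values[, , i, drop = FALSE]
  dim(v) <- dim(x@values)[1:2]
  colnames(v) <- recordingChannels()
  v
}

#' @describeIn WindowSet per-window activity labels
#' @export
windowLabels <- function(x) {
  stopifnot(is(x, "WindowSet"))
  x@labels
}

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@values)
  cat(
    "WindowSet:", d[3], "windows of", d[1], "samples at",
    object@samplingRate, "Hz\n"
  )
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat("labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# FeatureTable (SummarizedExperiment-backed)
# ---------------------------------------------------------------------------

#' @rdname FeatureTable
#' @export
#' @import SummarizedExperiment
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- NULL
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'features' is required")
  } else {
    a <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(a)) msg <- c(msg, "feature values must be numeric")
    if (anyNA(a)) msg <- c(msg, "feature values must not contain NA")
    if (anyDuplicated(rownames(a))) msg <- c(msg, "feature names must be unique")
  }
  if (is.null(msg)) TRUE else msg
})

#' Feature table (windows x features with labels)
#'
#' A matrix of per-window features with one activity (or meta-class) label
#' per window, backed by a \linkS4class{SummarizedExperiment} whose assay
#' stores features in rows and windows in columns; labels and optional
#' subject identifiers live in \code{colData}.
#'
#' @param values Numeric matrix, windows in rows and features in columns.
#' @param labels Optional per-window labels (character or factor).
#' @param featureNames Optional feature names (defaults to column names of
#'   \code{values}, or \code{F1..Fn}).
#' @param subject Optional per-window subject identifiers.
#' @return A \code{FeatureTable} object.
#' @seealso \code{\link{featureValues}}, \code{\link{activityLabels}}
#' @export
#' @examples
#' ft <- FeatureTable(matrix(rnorm(20), 5, 4), labels = c("a", "a", "b", "b", "a"))
#' dim(featureValues(ft))
#' activityLabels(ft)
FeatureTable <- function(values, labels = NULL, featureNames = NULL,
                         subject = NULL) {
  values <- as.matrix(values)
  if (is.null(featureNames)) {
    featureNames <- colnames(values)
    if (is.null(featureNames)) {
      featureNames <- paste0("F", seq_len(ncol(values)))
    }
  }
  if (length(featureNames) != ncol(values)) {
    stop("'featureNames' must have one entry per feature column")
  }
  assay <- t(values)
  rownames(assay) <- featureNames
  colnames(assay) <- NULL
  cd <- S4Vectors::DataFrame(row.names = seq_len(ncol(assay)))
  if (!is.null(labels)) {
    if (length(labels) != ncol(assay)) {
      stop(
        "'labels' length (", length(labels),
        ") must equal the number of windows (", ncol(assay), ")"
      )
    }
    cd$label <- as.character(labels)
  }
  if (!is.null(subject)) cd$subject <- as.character(subject)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay), colData = cd
  )
  new("FeatureTable", se)
}

#' @describeIn FeatureTable the windows x features value matrix
#' @param x A \code{FeatureTable}.
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  t(SummarizedExperiment::assay(x, "features"))
}

#' @describeIn FeatureTable per-window activity labels (or \code{NULL})
#' @export
activityLabels <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% colnames(cd)) as.character(cd$label) else NULL
}

setMethod("show", "FeatureTable", function(object) {
  cat(
    "FeatureTable:", ncol(object), "windows x", nrow(object),
    "features\n"
  )
  lab <- activityLabels(object)
  if (!is.null(lab)) {
    tab <- table(lab)
    cat("labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else {
    cat("labels: none\n")
  }
})

# ---------------------------------------------------------------------------
# FeatureSubset
# ---------------------------------------------------------------------------

#' @rdname FeatureSubset
#' @export
setClass("FeatureSubset",
  representation(
    indices = "integer",
    featureNames = "character",
    scores = "numeric"
  )
)

setValidity("FeatureSubset", function(object) {
  msg <- NULL
  if (anyDuplicated(object@indices)) msg <- c(msg, "indices must be unique")
  if (length(object@scores) != length(object@indices)) {
    msg <- c(msg, "one score per index required")
  }
  if (length(object@scores) &&
    (any(object@scores < -1e-12) || any(object@scores > 1 + 1e-12))) {
    msg <- c(msg, "scores must lie in [0, 1]")
  }
  if (length(object@scores) > 1L && any(diff(object@scores) > 1e-12)) {
    msg <- c(msg, "scores must be in descending order")
  }
  if (is.null(msg)) TRUE else msg
})

#' Ordered selected-feature subset
#'
#' An ordered set of feature indices with their relevance scores
#' (symmetrical uncertainty with the class), sorted by descending
#' relevance.
#'
#' @param indices Integer feature indices.
#' @param scores Relevance scores in \code{[0, 1]}, descending.
#' @param featureNames Optional feature names.
#' @return A \code{FeatureSubset}.
#' @export
FeatureSubset <- function(indices, scores, featureNames = character()) {
  new("FeatureSubset",
    indices = as.integer(indices), scores = as.numeric(scores),
    featureNames = as.character(featureNames)
  )
}

#' @describeIn FeatureSubset the selected feature indices, most relevant
#'   first
#' @param x A \code{FeatureSubset}.
#' @export
subsetIndices <- function(x) {
  stopifnot(is(x, "FeatureSubset"))
  x@indices
}

#' @describeIn FeatureSubset the per-feature relevance scores
#' @export
subsetScores <- function(x) {
  stopifnot(is(x, "FeatureSubset"))
  x@scores
}

setMethod("show", "FeatureSubset", function(object) {
  cat("FeatureSubset:", length(object@indices), "features\n")
  if (length(object@indices)) {
    nm <- if (length(object@featureNames)) {
      object@featureNames
    } else {
      paste0("F", object@indices)
    }
    k <- min(5L, length(nm))
    cat(
      " top:", paste(sprintf(
        "%s (SU=%.3f)", nm[seq_len(k)],
        object@scores[seq_len(k)]
      ), collapse = ", "),
      if (length(nm) > k) "..." else "", "\n"
    )
  }
})

# ---------------------------------------------------------------------------
# DiscretizationModel
# ---------------------------------------------------------------------------

#' @rdname mdlDiscretize
#' @export
setClass("DiscretizationModel",
  representation(cutPoints = "list", featureNames = "character")
)

setValidity("DiscretizationModel", function(object) {
  ok <- vapply(object@cutPoints, function(cp) {
    length(cp) < 2L || all(diff(cp) > 0)
  }, logical(1))
  if (all(ok)) TRUE else "cut points must be strictly increasing"
})

setMethod("show", "DiscretizationModel", function(object) {
  nc <- lengths(object@cutPoints)
  cat(
    "DiscretizationModel:", length(nc), "features;",
    sum(nc == 0L), "single-bin;", "median cuts", median(nc), "\n"
  )
})

# ---------------------------------------------------------------------------
# GaussianNB
# ---------------------------------------------------------------------------

#' @rdname nbFit
#' @export
setClass("GaussianNB",
  representation(
    classes = "character",
    priors = "numeric",
    means = "matrix",
    variances = "matrix",
    varianceFloor = "numeric",
    featureNames = "character"
  )
)

setValidity("GaussianNB", function(object) {
  msg <- NULL
  C <- length(object@classes)
  if (length(object@priors) != C) msg <- c(msg, "one prior per class required")
  if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
  if (nrow(object@means) != C || nrow(object@variances) != C) {
    msg <- c(msg, "means/variances must have one row per class")
  }
  if (any(object@variances < 0)) msg <- c(msg, "variances must be non-negative")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GaussianNB", function(object) {
  cat(
    "GaussianNB:", length(object@classes), "classes x",
    ncol(object@means), "features\n"
  )
  cat(
    " classes:", paste(object@classes, collapse = ", "), "\n",
    "priors:", paste(format(object@priors, digits = 3), collapse = ", "), "\n"
  )
})

# ---------------------------------------------------------------------------
# CDEnsemble
# ---------------------------------------------------------------------------

#' @rdname cdFit
#' @export
setClass("CDEnsemble",
  representation(
    classes = "character",
    subsets = "list",
    classifiers = "list"
  )
)

setValidity("CDEnsemble", function(object) {
  msg <- NULL
  C <- length(object@classes)
  if (length(object@subsets) != C) msg <- c(msg, "one subset per class required")
  if (length(object@classifiers) != C) {
    msg <- c(msg, "one classifier per class required")
  }
  if (!all(vapply(object@subsets, is, logical(1), "FeatureSubset"))) {
    msg <- c(msg, "subsets must be FeatureSubset objects")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CDEnsemble", function(object) {
  cat("CDEnsemble:", length(object@classes), "one-vs-rest classifiers\n")
  for (i in seq_along(object@classes)) {
    cat(
      " ", object@classes[i], ":",
      length(object@subsets[[i]]@indices), "features\n"
    )
  }
})

# ---------------------------------------------------------------------------
# LabelTree
# ---------------------------------------------------------------------------

#' @rdname LabelTree
#' @export
setClass("LabelTree",
  representation(
    nodeIds = "character",
    parentIds = "character", # NA for the root, parallel to nodeIds
    isLeaf = "logical"
  )
)

setValidity("LabelTree", function(object) {
  msg <- NULL
  n <- length(object@nodeIds)
  if (length(object@parentIds) != n || length(object@isLeaf) != n) {
    msg <- c(msg, "parentIds and isLeaf must parallel nodeIds")
  }
  if (anyDuplicated(object@nodeIds)) {
    msg <- c(msg, "node identifiers (meta-class and activity names) must be unique")
  }
  roots <- which(is.na(object@parentIds))
  if (length(roots) != 1L) msg <- c(msg, "exactly one root required")
  known <- object@parentIds[!is.na(object@parentIds)]
  if (!all(known %in% object@nodeIds)) {
    msg <- c(msg, "every parent must be a known node")
  }
  if (is.null(msg)) {
    nchild <- table(factor(object@parentIds, levels = object@nodeIds))
    internal <- !object@isLeaf
    if (any(nchild[internal] < 2L)) {
      msg <- c(msg, "every internal node must have at least 2 children")
    }
    if (any(nchild[object@isLeaf] > 0L)) {
      msg <- c(msg, "leaves cannot have children")
    }
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LabelTree", function(object) {
  cat(
    "LabelTree:", sum(!object@isLeaf), "internal nodes,",
    sum(object@isLeaf), "activities\n"
  )
  printNode <- function(id, depth) {
    cat(strrep("  ", depth), "- ", id,
      if (!object@isLeaf[match(id, object@nodeIds)]) "/" else "", "\n",
      sep = ""
    )
    for (ch in treeChildren(object, id)) printNode(ch, depth + 1L)
  }
  printNode(treeRoot(object), 0L)
})

# ---------------------------------------------------------------------------
# HierarchicalModel
# ---------------------------------------------------------------------------

#' @rdname trainHierarchical
#' @export
setClass("HierarchicalModel",
  representation(
    tree = "LabelTree",
    nodeModels = "list", # named by internal node id
    fsMode = "character",
    featureNames = "character"
  )
)

setValidity("HierarchicalModel", function(object) {
  msg <- NULL
  internal <- object@tree@nodeIds[!object@tree@isLeaf]
  if (!setequal(names(object@nodeModels), internal)) {
    msg <- c(msg, "exactly one model per internal node required")
  }
  if (!object@fsMode %in% c("none", "ci", "cd")) {
    msg <- c(msg, "fsMode must be one of 'none', 'ci', 'cd'")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "HierarchicalModel", function(object) {
  cat(
    "HierarchicalModel (fs mode:", object@fsMode, "):",
    length(object@nodeModels), "node classifiers\n"
  )
  for (nd in names(object@nodeModels)) {
    m <- object@nodeModels[[nd]]
    if (is(m$model, "CDEnsemble")) {
      sizes <- vapply(m$model@subsets, function(s) length(s@indices), integer(1))
      cat(
        " ", nd, ": class-dependent, subset sizes",
        paste(sizes, collapse = "/"), "\n"
      )
    } else {
      cat(" ", nd, ":", length(m$subset@indices), "features\n")
    }
  }
})

# ---------------------------------------------------------------------------
# ConfusionMatrix
# ---------------------------------------------------------------------------

#' @rdname confusionMatrix
#' @export
setClass("ConfusionMatrix", contains = "matrix")

setValidity("ConfusionMatrix", function(object) {
  msg <- NULL
  m <- object@.Data
  if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
  if (any(m < 0) || any(m != round(m))) {
    msg <- c(msg, "cells must be non-negative integers")
  }
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    msg <- c(msg, "rows and columns must carry the same class order")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = predicted, columns = true):\n")
  print(object@.Data)
  cat(sprintf("accuracy: %.4f\n", accuracy(object)))
})
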