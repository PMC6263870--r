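# Readers and writers for the dataset's plain-text formats: CSV
# recordings, whitespace feature matrices with one-integer-per-line label
# files, per-channel inertial-signal window files, tree configuration
# files, and the directory-based model bundle.

#' Default activity label dictionary
#'
#' Maps the integer codes of the six-activity dataset layout to activity
#' names: 1 = walking ... 6 = lying.
#'
#' @return Named integer vector (names = activities).
#' @export
defaultLabelMap <- function() {
  setNames(1:6, activityOrder())
}

#' Read / write a raw recording as CSV
#'
#' The CSV layout is \code{time, acc_x..gyro_z, label}; \code{label} is
#' omitted for unlabelled recordings.
#'
#' @param path File path.
#' @param recording A \code{\link{RawRecording}}.
#' @param samplingRate Sampling rate used when reading (the \code{time}
#'   column is not trusted to infer it exactly); default 50.
#' @return \code{readRecording} returns a \code{RawRecording};
#'   \code{writeRecording} returns \code{path} invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "RawRecording"))
  n <- nrow(recording@samples)
  df <- data.frame(
    time = (seq_len(n) - 1L) / recording@samplingRate,
    recording@samples,
    check.names = FALSE
  )
  if (length(recording@labels)) df$label <- recording@labels
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, samplingRate = 50) {
  stopIfNot(file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- recordingChannels()
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("recording CSV lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  RawRecording(as.matrix(df[, need]),
    samplingRate = samplingRate,
    labels = if ("label" %in% names(df)) df$label else character()
  )
}

# Parse a whitespace-delimited numeric matrix with located errors.
.readNumericMatrix <- function(path) {
  stopIfNot(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) > 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop(
      "row ", bad, " of ", path, " has ", ncols[bad],
      " values; expected ", ncols[1],
      call. = FALSE
    )
  }
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1]
    r <- (flat - 1L) %/% ncols[1] + 1L
    cidx <- (flat - 1L) %% ncols[1] + 1L
    stop(
      "non-numeric value '", rows[[r]][cidx], "' at row ", r,
      ", column ", cidx, " of ", path,
      call. = FALSE
    )
  }
  matrix(vals, nrow = length(rows), ncol = ncols[1], byrow = TRUE)
}

#' Read / write a feature table in the whitespace-matrix layout
#'
#' The layout of the public smartphone dataset: a whitespace-delimited
#' numeric matrix (one window per row), a parallel one-integer-per-line
#' label file, and an optional one-name-per-line feature manifest.
#' Integer labels are translated through a configurable label dictionary.
#'
#' @param xPath Path of the feature matrix.
#' @param yPath Optional path of the label file.
#' @param namesPath Optional path of the feature-name manifest.
#' @param labelMap Named integer vector mapping activity names to codes;
#'   see \code{\link{defaultLabelMap}}.
#' @param table A \code{\link{FeatureTable}} (for writing).
#' @return \code{readFeatureTable} returns a \code{FeatureTable};
#'   \code{writeFeatureTable} returns \code{xPath} invisibly.
#' @export
readFeatureTable <- function(xPath, yPath = NULL, namesPath = NULL,
                             labelMap = defaultLabelMap()) {
  x <- .readNumericMatrix(xPath)
  labels <- NULL
  if (!is.null(yPath)) {
    y <- .readNumericMatrix(yPath)
    stopIfNot(ncol(y) == 1L, "label file must have one value per line")
    if (nrow(y) != nrow(x)) {
      stop(
        "row-count mismatch: ", nrow(x), " feature rows but ",
        nrow(y), " labels",
        call. = FALSE
      )
    }
    codes <- as.integer(y[, 1])
    unknown <- setdiff(codes, labelMap)
    if (length(unknown)) {
      stop(
        "label code(s) outside the label dictionary: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    labels <- names(labelMap)[match(codes, labelMap)]
  }
  featureNames <- NULL
  if (!is.null(namesPath)) {
    stopIfNot(file.exists(namesPath), "file not found: ", namesPath)
    featureNames <- readLines(namesPath)
    featureNames <- featureNames[nzchar(featureNames)]
    if (length(featureNames) != ncol(x)) {
      stop(
        "manifest has ", length(featureNames), " names but the matrix has ",
        ncol(x), " columns",
        call. = FALSE
      )
    }
  }
  FeatureTable(x, labels = labels, featureNames = featureNames)
}

#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(table, xPath, yPath = NULL, namesPath = NULL,
                              labelMap = defaultLabelMap()) {
  stopifnot(is(table, "FeatureTable"))
  m <- featureValues(table)
  lines <- apply(m, 1L, function(r) {
    paste(sprintf("%.15g", r), collapse = " ")
  })
  writeLines(lines, xPath)
  labels <- activityLabels(table)
  if (!is.null(yPath)) {
    stopIfNot(!is.null(labels), "the table has no labels to write")
    unknown <- setdiff(unique(labels), names(labelMap))
    if (length(unknown)) {
      stop(
        "label(s) outside the label dictionary: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    writeLines(as.character(labelMap[labels]), yPath)
  }
  if (!is.null(namesPath)) writeLines(colnames(m), namesPath)
  invisible(xPath)
}

#' Read pre-segmented inertial-signal window files
#'
#' Reads the six per-channel window files of the public dataset layout
#' (each row one window, each file one channel) and assembles them into a
#' \code{\link{WindowSet}}. All six files must have identical shapes.
#'
#' @param directory Directory containing the channel files.
#' @param prefix Filename prefix; channel \code{acc_x} is read from
#'   \code{<prefix>acc_x.txt} and so on.
#' @param rate Sampling rate in Hz.
#' @param labelsPath Optional one-integer-per-line label file.
#' @param labelMap Label dictionary for \code{labelsPath}.
#' @return A \code{WindowSet} of \code{T x 6} windows.
#' @export
readInertialSignals <- function(directory, prefix = "", rate = 50,
                                labelsPath = NULL,
                                labelMap = defaultLabelMap()) {
  mats <- lapply(recordingChannels(), function(ch) {
    .readNumericMatrix(file.path(directory, paste0(prefix, ch, ".txt")))
  })
  shapes <- vapply(mats, dim, integer(2))
  if (length(unique(shapes[1, ])) > 1L || length(unique(shapes[2, ])) > 1L) {
    stop(
      "channel files disagree in shape: ",
      paste(apply(shapes, 2L, paste, collapse = "x"), collapse = ", "),
      call. = FALSE
    )
  }
  nWin <- nrow(mats[[1]])
  T <- ncol(mats[[1]])
  values <- array(0, dim = c(T, 6L, nWin))
  for (ch in seq_len(6L)) {
    values[, ch, ] <- t(mats[[ch]])
  }
  labels <- character()
  if (!is.null(labelsPath)) {
    y <- .readNumericMatrix(labelsPath)
    stopIfNot(
      nrow(y) == nWin,
      "label file rows (", nrow(y), ") must match windows (", nWin, ")"
    )
    labels <- names(labelMap)[match(as.integer(y[, 1]), labelMap)]
  }
  WindowSet(values, samplingRate = rate, labels = labels)
}

# ---------------------------------------------------------------------------
# Tree configuration
# ---------------------------------------------------------------------------

#' Read a label-tree configuration
#'
#' Parses a YAML or JSON file describing the activity hierarchy as a
#' nested mapping of group names to child groups or activity-label
#' lists.
#'
#' @param path Path of a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{\link{LabelTree}}.
#' @export
readLabelTree <- function(path) {
  stopIfNot(file.exists(path), "file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  cfg <- rapply(cfg, as.character, how = "replace")
  LabelTree(cfg)
}

# ---------------------------------------------------------------------------
# Model bundle
# ---------------------------------------------------------------------------

.serializeClassifier <- function(cls) {
  if (is(cls, "GaussianNB")) {
    # matrices stored flat (column-major) with an explicit feature count,
    # so JSON round trips cannot change their shape
    list(
      type = "GaussianNB", classes = as.list(cls@classes),
      priors = as.list(cls@priors), nFeatures = ncol(cls@means),
      means = as.numeric(cls@means), variances = as.numeric(cls@variances),
      varianceFloor = cls@varianceFloor, featureNames = as.list(cls@featureNames)
    )
  } else {
    stop("only GaussianNB node classifiers can be serialized", call. = FALSE)
  }
}

.deserializeClassifier <- function(x) {
  stopIfNot(identical(x$type, "GaussianNB"), "unknown classifier type")
  C <- length(x$classes)
  p <- as.integer(x$nFeatures)
  new("GaussianNB",
    classes = as.character(unlist(x$classes)),
    priors = as.numeric(unlist(x$priors)),
    means = matrix(as.numeric(unlist(x$means)), C, p),
    variances = matrix(as.numeric(unlist(x$variances)), C, p),
    varianceFloor = as.numeric(x$varianceFloor),
    featureNames = as.character(unlist(x$featureNames))
  )
}

.serializeSubset <- function(s) {
  list(indices = s@indices, scores = s@scores, featureNames = s@featureNames)
}

.deserializeSubset <- function(x) {
  FeatureSubset(
    as.integer(unlist(x$indices)), as.numeric(unlist(x$scores)),
    as.character(unlist(x$featureNames))
  )
}

#' Save / load a hierarchical model bundle
#'
#' Serializes a trained \code{HierarchicalModel} as a directory of JSON
#' files: a tree manifest (\code{tree.json}), model metadata
#' (\code{meta.json}) and one file per internal node under \code{nodes/}
#' holding the node's classifier parameters (means, variances, priors,
#' class order) and feature subset(s).
#'
#' @param model A \code{HierarchicalModel}.
#' @param directory Bundle directory (created if absent).
#' @return \code{saveHierarchicalModel} returns \code{directory}
#'   invisibly; \code{loadHierarchicalModel} returns the restored
#'   \code{HierarchicalModel}.
#' @export
saveHierarchicalModel <- function(model, directory) {
  stopifnot(is(model, "HierarchicalModel"))
  dir.create(file.path(directory, "nodes"),
    recursive = TRUE,
    showWarnings = FALSE
  )
  tree <- model@tree
  jsonlite::write_json(
    list(
      nodeIds = tree@nodeIds, parentIds = tree@parentIds,
      isLeaf = tree@isLeaf
    ),
    file.path(directory, "tree.json"),
    auto_unbox = FALSE, digits = NA, na = "null"
  )
  internal <- names(model@nodeModels)
  jsonlite::write_json(
    list(
      fsMode = model@fsMode, featureNames = model@featureNames,
      nodes = internal, nodeFiles = sprintf("node_%03d.json", seq_along(internal))
    ),
    file.path(directory, "meta.json"),
    auto_unbox = FALSE, digits = NA
  )
  for (i in seq_along(internal)) {
    entry <- model@nodeModels[[internal[i]]]
    payload <- if (is(entry$model, "CDEnsemble")) {
      list(
        kind = "cd", classes = entry$model@classes,
        subsets = lapply(entry$model@subsets, .serializeSubset),
        classifiers = lapply(entry$model@classifiers, .serializeClassifier)
      )
    } else {
      list(
        kind = "single",
        subset = .serializeSubset(entry$subset),
        classifier = .serializeClassifier(entry$model)
      )
    }
    jsonlite::write_json(payload,
      file.path(directory, "nodes", sprintf("node_%03d.json", i)),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(directory)
}

#' @rdname saveHierarchicalModel
#' @export
loadHierarchicalModel <- function(directory) {
  treeSpec <- jsonlite::fromJSON(file.path(directory, "tree.json"))
  tree <- new("LabelTree",
    nodeIds = as.character(treeSpec$nodeIds),
    parentIds = as.character(treeSpec$parentIds),
    isLeaf = as.logical(treeSpec$isLeaf)
  )
  meta <- jsonlite::fromJSON(file.path(directory, "meta.json"))
  nodeModels <- list()
  for (i in seq_along(meta$nodes)) {
    payload <- jsonlite::fromJSON(
      file.path(directory, "nodes", meta$nodeFiles[i]),
      simplifyVector = TRUE, simplifyMatrix = FALSE,
      simplifyDataFrame = FALSE
    )
    nodeModels[[meta$nodes[i]]] <- if (identical(payload$kind, "cd")) {
      list(model = new("CDEnsemble",
        classes = as.character(payload$classes),
        subsets = lapply(payload$subsets, .deserializeSubset),
        classifiers = lapply(payload$classifiers, .deserializeClassifier)
      ))
    } else {
      list(
        model = .deserializeClassifier(payload$classifier),
        subset = .deserializeSubset(payload$subset)
      )
    }
  }
  new("HierarchicalModel",
    tree = tree, nodeModels = nodeModels,
    fsMode = meta$fsMode, featureNames = as.character(meta$featureNames)
  )
}
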