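# The activity label tree and the hierarchical (local classifier per
# parent node) training and top-down prediction procedures.

#' Activity label tree
#'
#' A rooted tree whose internal nodes are named activity groups
#' (meta-classes) and whose leaves are the activity labels. Built from a
#' nested named list: a named element is an internal node whose value is
#' either a character vector of leaf activities or a further nested list.
#' Every internal node must have at least two children, leaf labels must
#' be unique, and meta-class names must not collide with activity labels.
#'
#' @param groups Nested named list (or character vector of plain leaves)
#'   describing the children of the root.
#' @param rootId Identifier for the root node.
#' @return A \code{LabelTree} object.
#' @seealso \code{\link{defaultActivityTree}}, \code{\link{readLabelTree}}
#' @export
#' @examples
#' tree <- LabelTree(list(
#'   static = c("standing", "sitting", "lying"),
#'   dynamic = c("walking", "upstairs", "downstairs")
#' ))
#' tree
#' treeChildren(tree, "static")
LabelTree <- function(groups, rootId = "root") {
  ids <- rootId
  parents <- NA_character_
  leaf <- FALSE
  addChildren <- function(parentId, spec) {
    if (is.character(spec)) {
      for (lab in spec) {
        ids <<- c(ids, lab)
        parents <<- c(parents, parentId)
        leaf <<- c(leaf, TRUE)
      }
    } else if (is.list(spec)) {
      nms <- names(spec)
      for (i in seq_along(spec)) {
        child <- spec[[i]]
        if (is.null(nms) || nms[i] == "") {
          # unnamed character entries are leaves of `parentId`
          stopIfNot(
            is.character(child),
            "unnamed tree entries must be activity labels"
          )
          addChildren(parentId, child)
        } else {
          ids <<- c(ids, nms[i])
          parents <<- c(parents, parentId)
          leaf <<- c(leaf, FALSE)
          addChildren(nms[i], child)
        }
      }
    } else {
      stop("tree configuration must be a nested named list of character vectors")
    }
  }
  addChildren(rootId, groups)
  new("LabelTree", nodeIds = ids, parentIds = parents, isLeaf = leaf)
}

#' Default six-activity tree
#'
#' The two-level hierarchy used throughout: the root splits into a
#' \code{static} group (standing, sitting, lying) and a \code{dynamic}
#' group (walking, upstairs, downstairs).
#'
#' @return A \code{LabelTree}.
#' @export
defaultActivityTree <- function() {
  LabelTree(list(
    static = c("standing", "sitting", "lying"),
    dynamic = c("walking", "upstairs", "downstairs")
  ))
}

#' @describeIn LabelTree identifier of the root node
#' @param tree A \code{LabelTree}.
#' @export
treeRoot <- function(tree) {
  tree@nodeIds[is.na(tree@parentIds)]
}

#' @describeIn LabelTree children of a node, in insertion order
#' @param id A node identifier.
#' @export
treeChildren <- function(tree, id) {
  tree@nodeIds[!is.na(tree@parentIds) & tree@parentIds == id]
}

#' @describeIn LabelTree parent of a node (\code{NA} for the root)
#' @export
treeParent <- function(tree, id) {
  tree@parentIds[match(id, tree@nodeIds)]
}

#' @describeIn LabelTree ancestors of a node, nearest first
#' @export
treeAncestors <- function(tree, id) {
  out <- character()
  p <- treeParent(tree, id)
  while (!is.na(p)) {
    out <- c(out, p)
    p <- treeParent(tree, p)
  }
  out
}

#' @describeIn LabelTree all descendants of a node (internal and leaf)
#' @export
treeDescendants <- function(tree, id) {
  ch <- treeChildren(tree, id)
  if (!length(ch)) {
    return(character())
  }
  c(ch, unlist(lapply(ch, treeDescendants, tree = tree), use.names = FALSE))
}

#' @describeIn LabelTree siblings of a node
#' @export
treeSiblings <- function(tree, id) {
  p <- treeParent(tree, id)
  if (is.na(p)) {
    return(character())
  }
  setdiff(treeChildren(tree, p), id)
}

#' @describeIn LabelTree activity labels (leaves) under a node
#' @export
treeLeafLabels <- function(tree, id) {
  i <- match(id, tree@nodeIds)
  stopIfNot(!is.na(i), "unknown node '", id, "'")
  if (tree@isLeaf[i]) {
    return(id)
  }
  d <- treeDescendants(tree, id)
  d[tree@isLeaf[match(d, tree@nodeIds)]]
}

#' @describeIn LabelTree identifiers of the internal (non-leaf) nodes
#' @export
treeInternalNodes <- function(tree) {
  tree@nodeIds[!tree@isLeaf]
}

#' @describeIn LabelTree all activity labels (leaves) of the tree
#' @export
treeLeaves <- function(tree) {
  tree@nodeIds[tree@isLeaf]
}

# depth of a node below the root (root = 0)
treeDepth <- function(tree, id) {
  length(treeAncestors(tree, id))
}

# ---------------------------------------------------------------------------
# Node training sets
# ---------------------------------------------------------------------------

#' Training set of an internal node
#'
#' Builds the local training set for an internal node: every sample whose
#' activity label lies under child \code{c} is relabelled with the child's
#' meta-class name (for leaf children, the activity itself), and samples
#' outside the node's descendants are excluded.
#'
#' @param tree A \code{LabelTree}.
#' @param node An internal node identifier.
#' @param x Numeric matrix (rows = samples) or \code{FeatureTable}.
#' @param labels Activity labels (taken from the table when omitted).
#' @return List with \code{values} (the retained rows), \code{labels}
#'   (meta-class labels) and \code{classOrder} (the node's children).
#' @export
nodeTrainingSet <- function(tree, node, x, labels = NULL) {
  i <- match(node, tree@nodeIds)
  stopIfNot(!is.na(i), "unknown node '", node, "'")
  stopIfNot(!tree@isLeaf[i], "node '", node, "' is a leaf")
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required")
  children <- treeChildren(tree, node)
  meta <- rep(NA_character_, length(labels))
  for (ch in children) {
    meta[labels %in% treeLeafLabels(tree, ch)] <- ch
  }
  keep <- !is.na(meta)
  list(
    values = x[keep, , drop = FALSE],
    labels = meta[keep],
    classOrder = children
  )
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

#' Train a hierarchical activity recognizer
#'
#' Trains one local model per internal node of the label tree. For each
#' internal node the local training set is assembled with
#' \code{\link{nodeTrainingSet}} and then, depending on \code{fsMode}:
#' \describe{
#'   \item{\code{"none"}}{the full feature set is used and a single
#'     multi-class classifier is fitted;}
#'   \item{\code{"ci"}}{class-independent selection
#'     (\code{\link{fcbfSelect}}) picks one subset for the node, and a
#'     single classifier is fitted on it;}
#'   \item{\code{"cd"}}{class-dependent selection
#'     (\code{\link{classDependentSelect}}) on the node's meta-labels
#'     yields one subset per child, and a \code{\link{cdFit}} one-vs-rest
#'     ensemble is fitted.}
#' }
#'
#' @param x Numeric matrix (rows = samples) or \code{FeatureTable}.
#' @param labels Activity labels (taken from the table when omitted);
#'   must be a subset of the tree's leaves.
#' @param tree A \code{LabelTree}; defaults to the six-activity tree.
#' @param fsMode Feature-selection mode: \code{"none"}, \code{"ci"} or
#'   \code{"cd"}.
#' @param classifierFactory Function \code{(x, labels, classOrder)}
#'   returning a probabilistic classifier; defaults to \code{\link{nbFit}}.
#' @param delta FCBF relevance threshold.
#' @param verbose Log per-node selected-feature counts via
#'   \code{message()}.
#' @return A \code{HierarchicalModel}.
#' @seealso \code{\link{predictTopdown}}
#' @export
#' @examples
#' tab <- makePlantedTable(nPerClass = 30, nClasses = 2, seed = 1)
#' tree <- LabelTree(list(g1 = "A1", g2 = "A2")) # degenerate flat tree
#' \dontrun{
#' model <- trainHierarchical(tab, tree = tree, fsMode = "ci")
#' }
trainHierarchical <- function(x, labels = NULL, tree = defaultActivityTree(),
                              fsMode = c("none", "ci", "cd"),
                              classifierFactory = nbFit, delta = 0,
                              verbose = FALSE) {
  fsMode <- match.arg(fsMode)
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required for training")
  unknown <- setdiff(unique(labels), treeLeaves(tree))
  if (length(unknown)) {
    stop(
      "labels not present among the tree leaves: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("F", seq_len(ncol(x)))
  nodeModels <- list()
  for (nd in treeInternalNodes(tree)) {
    tr <- nodeTrainingSet(tree, nd, x, labels)
    present <- unique(tr$labels)
    missing <- setdiff(tr$classOrder, present)
    if (length(missing)) {
      stop(
        "node '", nd, "': no training samples for child '",
        missing[1], "'",
        call. = FALSE
      )
    }
    if (fsMode == "cd") {
      subs <- classDependentSelect(tr$values, tr$labels,
        delta = delta,
        classOrder = tr$classOrder
      )
      ens <- cdFit(tr$values, tr$labels,
        subsets = subs,
        classifierFactory = classifierFactory
      )
      if (verbose) {
        sizes <- vapply(ens@subsets, function(s) length(s@indices), integer(1))
        message(
          "node ", nd, " (cd): subset sizes ",
          paste(paste0(tr$classOrder, "=", sizes), collapse = ", ")
        )
      }
      nodeModels[[nd]] <- list(model = ens)
    } else {
      sub <- if (fsMode == "ci") {
        fcbfSelect(tr$values, tr$labels, delta = delta)
      } else {
        FeatureSubset(seq_len(ncol(x)), rep(1, ncol(x)), nm)
      }
      useIdx <- if (length(sub@indices)) sub@indices else seq_len(ncol(x))
      cls <- classifierFactory(
        tr$values[, useIdx, drop = FALSE], tr$labels,
        classOrder = tr$classOrder
      )
      if (verbose) {
        message("node ", nd, " (", fsMode, "): ", length(useIdx), " features")
      }
      nodeModels[[nd]] <- list(
        model = cls,
        subset = FeatureSubset(useIdx,
          if (length(sub@indices)) sub@scores else rep(1, ncol(x)),
          nm[useIdx]
        )
      )
    }
  }
  new("HierarchicalModel",
    tree = tree, nodeModels = nodeModels,
    fsMode = fsMode, featureNames = nm
  )
}

# ---------------------------------------------------------------------------
# Prediction
# ---------------------------------------------------------------------------

# Predict the child meta-class at one node, batched over rows.
.predictNode <- function(model, nd, newdata) {
  entry <- model@nodeModels[[nd]]
  if (is(entry$model, "CDEnsemble")) {
    cdPredict(entry$model, newdata)
  } else {
    predict(entry$model, newdata[, entry$subset@indices, drop = FALSE])
  }
}

#' Top-down hierarchical prediction
#'
#' Predicts activity labels by descending the label tree from the root:
#' at each internal node the local classifier (projecting the query onto
#' that node's feature subset or subsets) chooses one child, and the
#' descent recurses until a leaf is reached. Exactly one classifier is
#' evaluated per level along the predicted path, so the returned leaf is
#' always reachable through the predicted internal nodes.
#'
#' @param model A \code{HierarchicalModel}.
#' @param newdata Numeric matrix over the full training feature space
#'   (rows = samples), or a single numeric vector.
#' @param path Return the full predicted node path instead of only the
#'   leaf label.
#' @return Character vector of predicted activity labels; with
#'   \code{path = TRUE}, a list of root-to-leaf node paths.
#' @export
predictTopdown <- function(model, newdata, path = FALSE) {
  stopifnot(is(model, "HierarchicalModel"))
  if (is(newdata, "FeatureTable")) newdata <- featureValues(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  out <- rep(NA_character_, n)
  paths <- if (path) vector("list", n) else NULL
  recurse <- function(nd, rows) {
    if (!length(rows)) {
      return(invisible())
    }
    pred <- .predictNode(model, nd, newdata[rows, , drop = FALSE])
    for (ch in unique(pred)) {
      sel <- rows[pred == ch]
      if (path) {
        for (r in sel) paths[[r]] <<- c(paths[[r]], ch)
      }
      if (model@tree@isLeaf[match(ch, model@tree@nodeIds)]) {
        out[sel] <<- ch
      } else {
        recurse(ch, sel)
      }
    }
  }
  recurse(treeRoot(model@tree), seq_len(n))
  if (path) {
    lapply(paths, function(p) c(treeRoot(model@tree), p))
  } else {
    out
  }
}

#' @describeIn trainHierarchical predict activity labels for new samples
#'   (wrapper around \code{\link{predictTopdown}})
#' @param object A \code{HierarchicalModel}.
#' @param newdata Matrix of query samples.
#' @param ... Unused.
#' @export
setMethod("predict", "HierarchicalModel", function(object, newdata, ...) {
  predictTopdown(object, newdata)
})
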