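# Probabilistic base classifier (Gaussian naive Bayes) and the
# class-dependent one-vs-rest ensemble fused by maximal positive-class
# probability.

#' @rdname predictProba
#' @export
setGeneric("predictProba", function(object, newdata, ...) {
  standardGeneric("predictProba")
})

#' Gaussian naive Bayes
#'
#' Fits a Gaussian naive Bayes classifier: class priors are the empirical
#' class frequencies and each feature gets an independent normal
#' class-conditional model. Per-feature, per-class variances are floored
#' at \code{1e-9} times the largest per-feature variance of the whole
#' training table, which keeps the model finite on (near-)constant
#' features.
#'
#' @param x Numeric matrix (rows = samples) or \code{FeatureTable}.
#' @param labels Class labels, one per row (taken from the table when
#'   omitted). Every class must have at least 2 samples.
#' @param classOrder Optional fixed class order.
#' @return A \code{GaussianNB} object.
#' @seealso \code{\link{predictProba}}
#' @export
#' @examples
#' x <- matrix(c(rnorm(20, 0), rnorm(20, 3)), ncol = 1)
#' y <- rep(c("a", "b"), each = 20)
#' fit <- nbFit(x, y)
#' predictProba(fit, matrix(1.5))
nbFit <- function(x, labels = NULL, classOrder = NULL) {
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required to fit a classifier")
  stopIfNot(nrow(x) == length(labels), "one label per row required")
  if (is.null(classOrder)) classOrder <- classOrderOf(labels)
  f <- factor(labels, levels = classOrder)
  counts <- table(f)
  if (any(counts < 2L)) {
    bad <- names(counts)[counts < 2L][1]
    stop("class '", bad, "' has fewer than 2 samples", call. = FALSE)
  }
  C <- length(classOrder)
  p <- ncol(x)
  means <- matrix(0, C, p)
  vars <- matrix(0, C, p)
  for (i in seq_len(C)) {
    rows <- x[f == classOrder[i], , drop = FALSE]
    means[i, ] <- colMeans(rows)
    vars[i, ] <- apply(rows, 2L, var)
  }
  featVar <- apply(x, 2L, var)
  floorv <- max(1e-9 * max(featVar), .Machine$double.xmin)
  vars <- pmax(vars, floorv)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("F", seq_len(p))
  new("GaussianNB",
    classes = classOrder,
    priors = as.numeric(counts) / length(labels),
    means = means, variances = vars,
    varianceFloor = floorv, featureNames = nm
  )
}

#' Class-membership probabilities
#'
#' Posterior class probabilities for new samples. Probabilities are
#' computed in log space and normalised with the log-sum-exp trick, so
#' each row is non-negative and sums to one.
#'
#' @param object A fitted classifier (e.g. \code{GaussianNB}).
#' @param newdata Numeric matrix (rows = samples) or a single numeric
#'   vector, with features in the training order.
#' @param ... Unused.
#' @return Numeric matrix, one row per sample and one column per class
#'   (in the classifier's class order).
#' @export
setMethod("predictProba", "GaussianNB", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  stopIfNot(
    ncol(newdata) == ncol(object@means),
    "query has ", ncol(newdata), " features but the model expects ",
    ncol(object@means)
  )
  C <- length(object@classes)
  n <- nrow(newdata)
  logp <- matrix(0, n, C)
  for (i in seq_len(C)) {
    mu <- object@means[i, ]
    s2 <- object@variances[i, ]
    ll <- sweep(newdata, 2L, mu)^2
    ll <- sweep(ll, 2L, -2 * s2, FUN = "/")
    logp[, i] <- log(object@priors[i]) + rowSums(ll) -
      0.5 * sum(log(2 * pi * s2))
  }
  mx <- apply(logp, 1L, max)
  w <- exp(logp - mx)
  proba <- w / rowSums(w)
  colnames(proba) <- object@classes
  proba
})

#' @describeIn nbFit predicted class labels (row-wise argmax of the
#'   posterior; ties go to the earlier class in the class order)
#' @param object A fitted \code{GaussianNB}.
#' @param newdata Matrix of query samples.
#' @export
setMethod("predict", "GaussianNB", function(object, newdata, ...) {
  proba <- predictProba(object, newdata)
  object@classes[apply(proba, 1L, which.max)]
})

# ---------------------------------------------------------------------------
# Class-dependent ensemble
# ---------------------------------------------------------------------------

#' Class-dependent one-vs-rest ensemble
#'
#' Trains one binary classifier per class: the labels are binarized
#' (\code{+1} for the class, \code{-1} for the rest), the table is
#' projected onto that class's feature subset, and a probabilistic binary
#' classifier is fitted. Prediction fuses the ensemble by the maximal
#' positive-class probability: the predicted label is
#' \deqn{L(x) = \arg\max_k \; p_k(x^{(k)}),}
#' where \eqn{x^{(k)}} is the query projected onto subset \eqn{S_k} and
#' \eqn{p_k} the probability of the positive outcome under classifier
#' \eqn{k}. Ties go to the earlier class in the fixed class order.
#'
#' An empty subset for a class falls back to that class's single most
#' relevant feature (highest one-vs-rest symmetrical uncertainty, ties by
#' lower index), with a message.
#'
#' @param x Numeric matrix (rows = samples) or \code{FeatureTable}.
#' @param labels Class labels (taken from the table when omitted).
#' @param subsets Named list of \code{\link{FeatureSubset}}, one per class
#'   (as returned by \code{\link{classDependentSelect}}).
#' @param classifierFactory Function \code{(x, labels, classOrder)} that
#'   returns a classifier understood by \code{\link{predictProba}};
#'   defaults to \code{\link{nbFit}}.
#' @return \code{cdFit} returns a \code{CDEnsemble}.
#' @export
cdFit <- function(x, labels = NULL, subsets, classifierFactory = nbFit) {
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required to fit an ensemble")
  classOrder <- names(subsets)
  stopIfNot(
    !is.null(classOrder) && setequal(classOrder, classOrderOf(labels)),
    "'subsets' must be a named list with one subset per class"
  )
  classifiers <- vector("list", length(classOrder))
  subsets <- subsets[classOrder]
  for (i in seq_along(classOrder)) {
    k <- classOrder[i]
    sub <- subsets[[i]]
    if (!length(sub@indices)) {
      # fall back to the single most relevant feature for this class
      yk <- binarizeLabels(labels, k)
      xd <- mdlDiscretizeApply(mdlDiscretizeFit(x, yk), x)
      su <- vapply(seq_len(ncol(xd)), function(j) {
        symmetricalUncertainty(xd[, j], yk)
      }, numeric(1))
      best <- order(-su, seq_len(ncol(x)))[1]
      nm <- colnames(x)
      if (is.null(nm)) nm <- paste0("F", seq_len(ncol(x)))
      sub <- FeatureSubset(best, su[best], nm[best])
      subsets[[i]] <- sub
      message(
        "empty subset for class '", k,
        "': falling back to top-relevance feature ", nm[best]
      )
    }
    yk <- factor(ifelse(labels == k, "+1", "-1"), levels = c("+1", "-1"))
    classifiers[[i]] <- classifierFactory(
      x[, sub@indices, drop = FALSE], yk,
      classOrder = c("+1", "-1")
    )
  }
  new("CDEnsemble",
    classes = classOrder, subsets = subsets,
    classifiers = classifiers
  )
}

#' @describeIn cdFit per-class positive-class probabilities for new
#'   samples (one column per class, in class order)
#' @param ensemble A \code{CDEnsemble}.
#' @param newdata Numeric matrix (or vector for a single sample) over the
#'   full feature space; each subset's indices must be covered.
#' @export
cdPositiveProba <- function(ensemble, newdata) {
  stopifnot(is(ensemble, "CDEnsemble"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  proba <- vapply(seq_along(ensemble@classes), function(i) {
    idx <- ensemble@subsets[[i]]@indices
    stopIfNot(
      max(idx) <= ncol(newdata),
      "query does not cover feature index ", max(idx),
      " required by class '", ensemble@classes[i], "'"
    )
    p <- predictProba(
      ensemble@classifiers[[i]],
      newdata[, idx, drop = FALSE]
    )
    p[, "+1"]
  }, numeric(nrow(newdata)))
  if (!is.matrix(proba)) proba <- matrix(proba, nrow = nrow(newdata))
  colnames(proba) <- ensemble@classes
  proba
}

#' @describeIn cdFit fused prediction: the class with the maximal
#'   positive-class probability (ties to the earlier class in class order)
#' @export
cdPredict <- function(ensemble, newdata) {
  proba <- cdPositiveProba(ensemble, newdata)
  ensemble@classes[apply(proba, 1L, which.max)]
}
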