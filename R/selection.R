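# Feature selection: symmetrical-uncertainty relevance, MDL supervised
# discretization, the fast correlation-based filter (FCBF), and the
# class-dependent one-vs-rest scheme.

#' Shannon entropy of a discrete sample
#'
#' Plug-in Shannon entropy, in bits, of the empirical distribution of a
#' discrete sample.
#'
#' @param x Vector of discrete values (any atomic type; values are compared
#'   for equality).
#' @return Entropy in bits (non-negative).
#' @export
#' @examples
#' discreteEntropy(c(0, 1, 0, 1)) # 1 bit
#' discreteEntropy(rep("a", 10)) # 0
discreteEntropy <- function(x) {
  stopIfNot(length(x) > 0L, "entropy of an empty sample is undefined")
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log2(p))
}

# Joint entropy of two parallel discrete vectors, in bits.
jointEntropy <- function(x, y) {
  discreteEntropy(paste(x, y, sep = "\r"))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' Normalised mutual information
#' \deqn{SU(X, Y) = 2 \, I(X; Y) / (H(X) + H(Y)),}
#' a symmetric relevance measure in \code{[0, 1]}: 0 for empirically
#' independent variables and 1 for a bijective relation. When both
#' variables are constant (\eqn{H(X) + H(Y) = 0}) the value is defined
#' as 0.
#'
#' @param x,y Parallel vectors of discrete values.
#' @return Symmetrical uncertainty in \code{[0, 1]}.
#' @export
#' @examples
#' symmetricalUncertainty(c(1, 2, 1, 2), c("a", "b", "a", "b")) # 1
#' symmetricalUncertainty(c(1, 1, 1, 1), c("a", "b", "a", "b")) # 0
symmetricalUncertainty <- function(x, y) {
  stopIfNot(
    length(x) == length(y),
    "'x' and 'y' must have the same length (got ", length(x), " and ", length(y), ")"
  )
  hx <- discreteEntropy(x)
  hy <- discreteEntropy(y)
  if (hx + hy == 0) {
    return(0)
  }
  mi <- hx + hy - jointEntropy(x, y)
  min(1, max(0, 2 * mi / (hx + hy)))
}

# ---------------------------------------------------------------------------
# MDL (entropy-based) supervised discretization, Fayyad-Irani style
# ---------------------------------------------------------------------------

# Entropy (bits) from a vector of class counts.
.entropyFromCounts <- function(counts) {
  n <- sum(counts)
  if (n == 0) {
    return(0)
  }
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Row-wise entropy (bits) of a candidates x classes count matrix.
.entropyRows <- function(counts, n) {
  p <- counts / n
  p[p == 0] <- 1 # log2(1) = 0, so empty cells contribute nothing
  -rowSums(p * log2(p))
}

# Recursively find accepted cut points for one numeric feature against the
# labels, using entropy minimisation with the minimum-description-length
# acceptance criterion. Returns a sorted numeric vector (possibly empty).
.mdlCutsRec <- function(v, ycode, K) {
  n <- length(v)
  if (n < 2L) {
    return(numeric())
  }
  # cumulative class counts along the sorted order
  cum <- vapply(seq_len(K), function(k) cumsum(ycode == k), numeric(n))
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  entS <- .entropyFromCounts(total)
  if (entS == 0) {
    return(numeric())
  }
  # candidate split positions: between distinct adjacent values
  cand <- which(diff(v) > 0)
  if (!length(cand)) {
    return(numeric())
  }
  left <- cum[cand, , drop = FALSE]
  right <- sweep(left, 2L, total, FUN = function(a, b) b - a) # total - left
  nl <- cand
  nr <- n - cand
  entL <- .entropyRows(left, nl)
  entR <- .entropyRows(right, nr)
  wEnt <- (nl * entL + nr * entR) / n
  gain <- entS - wEnt
  best <- which.max(gain)
  i <- cand[best]
  k0 <- sum(total > 0)
  k1 <- sum(left[best, ] > 0)
  k2 <- sum(right[best, ] > 0)
  delta <- log2(3^k0 - 2) - (k0 * entS - k1 * entL[best] - k2 * entR[best])
  threshold <- log2(n - 1) / n + delta / n
  if (gain[best] <= threshold) {
    return(numeric())
  }
  cut <- (v[i] + v[i + 1L]) / 2
  c(
    .mdlCutsRec(v[seq_len(i)], ycode[seq_len(i)], K),
    cut,
    .mdlCutsRec(v[(i + 1L):n], ycode[(i + 1L):n], K)
  )
}

#' Supervised MDL discretization
#'
#' Learns per-feature cut points by recursive entropy minimisation, each
#' candidate cut accepted only if it passes the minimum-description-length
#' criterion. A feature for which no cut is accepted becomes a single bin
#' (and therefore has zero symmetrical uncertainty with the class).
#' \code{mdlDiscretizeApply} maps new values to bin indices with the stored
#' cut points.
#'
#' @param x Numeric matrix (rows = samples) or \code{FeatureTable}.
#' @param labels Discrete class labels, one per row.
#' @param model A fitted \code{DiscretizationModel}.
#' @return \code{mdlDiscretizeFit} returns a \code{DiscretizationModel};
#'   \code{mdlDiscretizeApply} returns an integer matrix of bin indices
#'   (starting at 1).
#' @references Fayyad, U. M. and Irani, K. B. (1993) Multi-interval
#'   discretization of continuous-valued attributes for classification
#'   learning.
#' @export
#' @examples
#' x <- matrix(c(sort(rnorm(20)), rnorm(20)), ncol = 2)
#' y <- rep(c("a", "b"), each = 10)
#' m <- mdlDiscretizeFit(x, y)
#' head(mdlDiscretizeApply(m, x))
mdlDiscretizeFit <- function(x, labels = NULL) {
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required to fit a discretization")
  stopIfNot(nrow(x) == length(labels), "one label per row required")
  ycode <- match(labels, unique(labels))
  K <- max(ycode)
  cuts <- lapply(seq_len(ncol(x)), function(j) {
    s <- sort.int(x[, j], method = "quick", index.return = TRUE)
    sort(.mdlCutsRec(s$x, ycode[s$ix], K))
  })
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("F", seq_len(ncol(x)))
  new("DiscretizationModel", cutPoints = cuts, featureNames = nm)
}

#' @rdname mdlDiscretize
#' @export
mdlDiscretizeApply <- function(model, x) {
  stopifnot(is(model, "DiscretizationModel"))
  x <- asFeatureMatrix(x)$values
  stopIfNot(
    ncol(x) == length(model@cutPoints),
    "table has ", ncol(x), " features but the model was fitted on ",
    length(model@cutPoints)
  )
  out <- vapply(seq_len(ncol(x)), function(j) {
    findInterval(x[, j], model@cutPoints[[j]]) + 1L
  }, integer(nrow(x)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(x))
  colnames(out) <- model@featureNames
  out
}

# ---------------------------------------------------------------------------
# FCBF
# ---------------------------------------------------------------------------

#' Fast correlation-based filter (FCBF)
#'
#' Class-independent filter selection. Features are discretized (supervised
#' MDL by default), ranked by symmetrical uncertainty (SU) with the class,
#' and every feature with \code{SU > delta} is kept; then, walking the
#' ranking from the top, any lower-ranked feature \eqn{F_j} is removed when
#' a retained higher-ranked feature \eqn{F_i} satisfies
#' \eqn{SU(F_i, F_j) \ge SU(F_j, class)} (the "predominant correlation"
#' rule). Ties in the ranking are broken by the lower feature index, so the
#' result is deterministic.
#'
#' @param x Numeric matrix (rows = samples) or \code{FeatureTable}.
#' @param labels Class labels, one per row (taken from the table when
#'   omitted).
#' @param delta Relevance threshold; only features with SU strictly above
#'   \code{delta} enter the ranking. Default 0.
#' @param discretize Either \code{"mdl"} (supervised MDL cut points),
#'   \code{"width"} (unsupervised 10-bin equal-width fallback, for
#'   diagnostics), or \code{"none"} (values are already discrete).
#' @return A \code{\link{FeatureSubset}} of the predominant features,
#'   ordered by descending relevance. May be empty.
#' @references Yu, L. and Liu, H. (2003) Feature selection for
#'   high-dimensional data: a fast correlation-based filter solution.
#' @export
#' @examples
#' y <- rep(c("a", "b"), each = 30)
#' x <- cbind(
#'   ifelse(y == "a", 0, 1) + rnorm(60, sd = 0.05), # relevant
#'   rnorm(60) # noise
#' )
#' subsetIndices(fcbfSelect(x, y))
fcbfSelect <- function(x, labels = NULL, delta = 0,
                       discretize = c("mdl", "width", "none")) {
  discretize <- match.arg(discretize)
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required for feature selection")
  stopIfNot(nrow(x) >= 2L, "at least 2 samples required")
  xd <- switch(discretize,
    mdl = mdlDiscretizeApply(mdlDiscretizeFit(x, labels), x),
    width = equalWidthDiscretize(x, nBins = 10L),
    none = x
  )
  p <- ncol(xd)
  n <- nrow(xd)
  # integer-coded columns with cached entropies make the O(p^2) pairwise
  # SU evaluations of the pruning step cheap
  codes <- vector("list", p)
  nBinsOf <- integer(p)
  hFeat <- numeric(p)
  for (j in seq_len(p)) {
    cj <- match(xd[, j], unique(xd[, j]))
    codes[[j]] <- cj
    nBinsOf[j] <- max(cj)
    hFeat[j] <- .entropyFromCounts(tabulate(cj, nBinsOf[j]))
  }
  ycode <- match(labels, unique(labels))
  nY <- max(ycode)
  hY <- .entropyFromCounts(tabulate(ycode, nY))
  suWith <- function(j, other, nOther, hOther) {
    if (hFeat[j] + hOther == 0) {
      return(0)
    }
    joint <- .entropyFromCounts(
      tabulate((codes[[j]] - 1L) * nOther + other, nBinsOf[j] * nOther)
    )
    min(1, max(0, 2 * (hFeat[j] + hOther - joint) / (hFeat[j] + hOther)))
  }
  su <- vapply(seq_len(p), function(j) suWith(j, ycode, nY, hY), numeric(1))
  ranked <- order(-su, seq_len(p))
  ranked <- ranked[su[ranked] > delta]
  # predominant-feature pruning
  keep <- ranked
  i <- 1L
  while (i <= length(keep)) {
    fp <- keep[i]
    if (i < length(keep)) {
      rest <- keep[(i + 1L):length(keep)]
      redundant <- vapply(rest, function(fq) {
        suWith(fp, codes[[fq]], nBinsOf[fq], hFeat[fq]) >= su[fq]
      }, logical(1))
      keep <- c(keep[seq_len(i)], rest[!redundant])
    }
    i <- i + 1L
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("F", seq_len(p))
  FeatureSubset(keep, su[keep], nm[keep])
}

# Unsupervised equal-width binning (diagnostic fallback).
equalWidthDiscretize <- function(x, nBins = 10L) {
  out <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    r <- range(v)
    if (r[1] == r[2]) {
      return(rep(1L, length(v)))
    }
    b <- pmin(pmax(floor((v - r[1]) / (r[2] - r[1]) * nBins) + 1L, 1L), nBins)
    as.integer(b)
  }, integer(nrow(x)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(x))
  out
}

# ---------------------------------------------------------------------------
# Class-dependent selection
# ---------------------------------------------------------------------------

#' One-vs-rest label binarization
#'
#' Recodes labels for the \code{k}-th one-vs-rest problem: \code{+1} where
#' the label equals class \code{k}, \code{-1} elsewhere.
#'
#' @param labels Vector of class labels.
#' @param k The positive class; must occur in \code{labels}.
#' @return Integer vector of \code{+1} / \code{-1}.
#' @export
#' @examples
#' binarizeLabels(c(1, 2, 3, 1), 1)
binarizeLabels <- function(labels, k) {
  labels <- as.character(labels)
  stopIfNot(
    as.character(k) %in% labels,
    "class '", k, "' does not occur in the labels"
  )
  ifelse(labels == as.character(k), 1L, -1L)
}

#' Class-dependent one-vs-rest feature selection
#'
#' Selects one feature subset per class: for each class \code{k} the labels
#' are binarized (\code{k} vs rest) and the class-independent filter
#' (\code{\link{fcbfSelect}}) is run on the binary problem. The returned
#' subsets may differ between classes and may overlap. Binary problems
#' (\code{C = 2}) are handled the same way and yield two subsets, one per
#' class.
#'
#' @inheritParams fcbfSelect
#' @param classOrder Optional fixed class order; defaults to factor levels
#'   or sorted unique labels.
#' @return Named list of \code{\link{FeatureSubset}} objects, one per
#'   class, in class order.
#' @seealso \code{\link{cdFit}} for training the matching one-vs-rest
#'   ensemble.
#' @export
classDependentSelect <- function(x, labels = NULL, delta = 0,
                                 discretize = c("mdl", "width", "none"),
                                 classOrder = NULL) {
  discretize <- match.arg(discretize)
  fm <- asFeatureMatrix(x, labels)
  x <- fm$values
  labels <- fm$labels
  stopIfNot(!is.null(labels), "labels are required for feature selection")
  if (is.null(classOrder)) classOrder <- classOrderOf(labels)
  stopIfNot(length(classOrder) >= 2L, "at least 2 classes required")
  counts <- table(factor(labels, levels = classOrder))
  if (any(counts < 2L)) {
    bad <- names(counts)[counts < 2L][1]
    stop("class '", bad, "' has fewer than 2 samples", call. = FALSE)
  }
  out <- lapply(classOrder, function(k) {
    fcbfSelect(x, binarizeLabels(labels, k), delta = delta, discretize = discretize)
  })
  names(out) <- classOrder
  out
}
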