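# Independent oracle implementations used to cross-check the package:
# coded from the definitions, sharing no code with the implementation.

# plug-in entropy in bits, via table()
oEntropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log2(p))
}

# symmetrical uncertainty from the definition, via joint table()
oSU <- function(x, y) {
  hx <- oEntropy(x)
  hy <- oEntropy(y)
  if (hx + hy == 0) {
    return(0)
  }
  hxy <- oEntropy(paste(x, y, sep = "|"))
  2 * (hx + hy - hxy) / (hx + hy)
}

# Exhaustive predominant-feature filter, literal transcription of the
# definition: rank features by SU with the class (descending, ties by
# lower index), drop those at or below delta, then repeatedly mark as
# redundant every feature F_j for which some retained higher-ranked F_i
# has SU(F_i, F_j) >= SU(F_j, class). Operates on discrete values.
oracleFCBF <- function(xd, y, delta = 0) {
  p <- ncol(xd)
  su <- vapply(seq_len(p), function(j) oSU(xd[, j], y), numeric(1))
  ord <- order(-su, seq_len(p))
  ord <- ord[su[ord] > delta]
  status <- rep("kept", length(ord)) # provisional
  for (ii in seq_along(ord)) {
    if (status[ii] != "kept") next
    for (jj in seq_along(ord)) {
      if (jj <= ii || status[jj] != "kept") next
      fi <- ord[ii]
      fj <- ord[jj]
      if (oSU(xd[, fi], xd[, fj]) >= su[fj]) status[jj] <- "removed"
    }
  }
  ord[status == "kept"]
}

# direct discrete Fourier magnitude at bin k (1-based non-DC index)
oDFTMagnitude <- function(x, k) {
  n <- length(x)
  t <- seq_len(n) - 1
  Mod(sum(x * exp(-2i * pi * k * t / n)))
}

# Gaussian naive Bayes posterior from explicit parameters (Bayes rule on
# normal densities)
oNBPosterior <- function(x, means, vars, priors) {
  lik <- vapply(seq_along(priors), function(i) {
    prod(dnorm(x, means[i, ], sqrt(vars[i, ])))
  }, numeric(1))
  post <- priors * lik
  post / sum(post)
}

# random discrete table generator for the filter-equivalence checks
randomDiscreteTable <- function(p, n, nLevels = 3L) {
  xd <- matrix(sample.int(nLevels, n * p, replace = TRUE), n, p)
  y <- sample.int(nLevels, n, replace = TRUE)
  # occasionally plant a (possibly redundant) informative pair
  if (runif(1) < 0.6) {
    j <- sample.int(p, 1)
    xd[, j] <- y
    if (p > 1 && runif(1) < 0.5) {
      xd[, sample(setdiff(seq_len(p), j), 1)] <- xd[, j]
    }
  }
  list(x = xd, y = y)
}

# well-separated Gaussian-blob table over the six activities
sixActivityBlobs <- function(nPerClass = 20, nFeatures = 8, sep = 4, sd = 1) {
  acts <- activityOrder()
  centers <- matrix(rnorm(length(acts) * nFeatures, sd = sep),
    length(acts), nFeatures
  )
  x <- do.call(rbind, lapply(seq_along(acts), function(i) {
    matrix(rnorm(nPerClass * nFeatures, sd = sd),
      nPerClass, nFeatures,
      byrow = TRUE
    ) + matrix(centers[i, ], nPerClass, nFeatures, byrow = TRUE)
  }))
  list(x = x, y = rep(acts, each = nPerClass))
}
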