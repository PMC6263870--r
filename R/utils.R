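# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL leaves the current RNG untouched).
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce a FeatureTable-or-matrix argument to a plain windows x features
# matrix, returning labels alongside when available.
asFeatureMatrix <- function(x, labels = NULL) {
  if (is(x, "FeatureTable")) {
    list(values = featureValues(x), labels = if (is.null(labels)) activityLabels(x) else as.character(labels))
  } else {
    list(values = as.matrix(x), labels = if (is.null(labels)) NULL else as.character(labels))
  }
}

# Deterministic class order: factor levels if a factor, otherwise order of
# first appearance is NOT used -- sorted unique values, so that the same
# label set always yields the same order.
classOrderOf <- function(labels) {
  if (is.factor(labels)) levels(droplevels(labels)) else sort(unique(as.character(labels)))
}

stopIfNot <- function(ok, ...) {
  if (!ok) stop(..., call. = FALSE)
}
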