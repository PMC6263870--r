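# Gaussian naive Bayes and the class-dependent one-vs-rest ensemble.

test_that("posteriors match a hand evaluation of Bayes' rule", {
  set.seed(1)
  x <- matrix(c(rnorm(30, 0, 1), rnorm(20, 3, 1.5)), ncol = 1)
  y <- rep(c("a", "b"), c(30, 20))
  fit <- nbFit(x, y)
  for (q in c(-1, 0.8, 1.5, 2.4, 5)) {
    want <- oNBPosterior(q, fit@means, fit@variances, fit@priors)
    got <- predictProba(fit, matrix(q))
    expect_equal(as.numeric(got), want, tolerance = 1e-9)
  }
  # empirical moments and priors feed the model
  expect_equal(fit@priors, c(0.6, 0.4))
  expect_equal(fit@means[1, 1], mean(x[1:30, 1]))
  expect_equal(fit@variances[2, 1], var(x[31:50, 1]))
})

test_that("degenerate and symmetric configurations behave as expected", {
  # single training class: probability 1 always
  fit <- nbFit(matrix(rnorm(6), ncol = 2), rep("only", 3))
  p <- predictProba(fit, matrix(rnorm(10), ncol = 2))
  expect_equal(as.numeric(p), rep(1, 5))

  # two symmetric classes, equidistant query, equal priors -> (0.5, 0.5)
  x <- matrix(c(-2, -1, -1.5, 1, 2, 1.5), ncol = 1)
  y <- rep(c("lo", "hi"), c(3, 3))
  fit <- nbFit(x, y)
  p <- predictProba(fit, matrix(0))
  expect_equal(as.numeric(p), c(0.5, 0.5), tolerance = 1e-9)

  expect_error(nbFit(matrix(rnorm(6), ncol = 2), c("a", "a", "b")), "'b'")
})

test_that("posterior rows sum to one on random queries", {
  set.seed(2)
  x <- matrix(rnorm(300), ncol = 3)
  y <- sample(letters[1:4], 100, replace = TRUE)
  fit <- nbFit(x, y)
  p <- predictProba(fit, matrix(rnorm(60), ncol = 3))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0))
})

test_that("a zero-information feature recovers the class priors", {
  set.seed(3)
  n <- 2000
  y <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.7, 0.3))
  x <- matrix(rnorm(n), ncol = 1) # identical distribution in both classes
  fit <- nbFit(x, y)
  p <- predictProba(fit, matrix(rnorm(500), ncol = 1))
  expect_equal(colMeans(p), c(a = 0.7, b = 0.3), tolerance = 0.05)
})

test_that("posteriors agree with an independent naive Bayes implementation", {
  set.seed(4)
  x <- matrix(rnorm(240), ncol = 3)
  y <- rep(c("a", "b", "c", "d"), each = 20)
  colnames(x) <- paste0("V", 1:3)
  fit <- nbFit(x, y)
  ref <- e1071::naiveBayes(x, factor(y))
  q <- matrix(rnorm(30), ncol = 3, dimnames = list(NULL, colnames(x)))
  pRef <- predict(ref, q, type = "raw")
  pGot <- predictProba(fit, q)
  expect_equal(unname(pGot), unname(pRef[, fit@classes]), tolerance = 1e-6)
})

test_that("the ensemble trains one binary classifier per class on its subset", {
  tab <- makePlantedTable(nPerClass = 60, nClasses = 3, seed = 5)
  subs <- classDependentSelect(tab)
  ens <- cdFit(tab, subsets = subs)
  expect_length(ens@classifiers, 3L)
  expect_equal(ens@classes, c("A1", "A2", "A3"))
  for (i in 1:3) {
    expect_equal(ncol(ens@classifiers[[i]]@means), 1L) # one planted feature
    expect_equal(ens@classifiers[[i]]@classes, c("+1", "-1"))
  }

  # degenerate configuration: every subset is the full feature set
  x <- featureValues(tab)
  full <- lapply(
    setNames(nm = c("A1", "A2", "A3")),
    function(k) FeatureSubset(1:ncol(x), rep(1, ncol(x)), colnames(x))
  )
  ensFull <- cdFit(tab, subsets = full)
  expect_true(all(vapply(
    ensFull@classifiers,
    function(f) ncol(f@means), integer(1)
  ) == ncol(x)))
})

test_that("an empty subset falls back to the top-relevance feature, with a message", {
  tab <- makePlantedTable(nPerClass = 50, nClasses = 2, seed = 6)
  subs <- list(
    A1 = FeatureSubset(integer(0), numeric(0)),
    A2 = FeatureSubset(2L, 1)
  )
  expect_message(ens <- cdFit(tab, subsets = subs), "falling back")
  expect_length(subsetIndices(ens@subsets[[1]]), 1L)
  expect_equal(subsetIndices(ens@subsets[[1]]), 1L) # A1's planted feature
})

test_that("fused predictions recompute as the argmax of stored per-class posteriors", {
  tab <- makePlantedTable(nPerClass = 80, nClasses = 3, seed = 7)
  x <- featureValues(tab)
  y <- activityLabels(tab)
  train <- c(1:60, 81:140, 161:220)
  ens <- cdFit(x[train, ], y[train], subsets = classDependentSelect(x[train, ], y[train]))
  held <- x[-train, ]
  pred <- cdPredict(ens, held)
  # independent route: per-class positive posteriors from the stored
  # Gaussian parameters, fused by hand
  for (i in seq_len(nrow(held))) {
    pk <- vapply(1:3, function(k) {
      cls <- ens@classifiers[[k]]
      q <- held[i, subsetIndices(ens@subsets[[k]]), drop = FALSE]
      oNBPosterior(as.numeric(q), cls@means, cls@variances, cls@priors)[1]
    }, numeric(1))
    expect_equal(pred[i], ens@classes[which.max(pk)])
  }
  expect_gt(mean(pred == y[-train]), 0.95)
})

test_that("fusion ties go to the earlier class and survive monotone rescaling", {
  # two identical binary classifiers -> identical probabilities -> tie
  x <- matrix(c(-1, -2, 1, 2), ncol = 1)
  yk <- factor(c("+1", "+1", "-1", "-1"), levels = c("+1", "-1"))
  cls <- nbFit(x, yk, classOrder = c("+1", "-1"))
  ens <- new("CDEnsemble",
    classes = c("first", "second"),
    subsets = list(FeatureSubset(1L, 1), FeatureSubset(1L, 1)),
    classifiers = list(cls, cls)
  )
  expect_equal(cdPredict(ens, matrix(-1.5)), "first")

  # argmax is invariant to any common strictly increasing transform
  tab <- makePlantedTable(nPerClass = 40, nClasses = 3, seed = 8)
  ens <- cdFit(tab, subsets = classDependentSelect(tab))
  q <- featureValues(tab)[seq(1, 120, by = 7), ]
  p <- cdPositiveProba(ens, q)
  direct <- ens@classes[apply(p, 1L, which.max)]
  rescaled <- ens@classes[apply(sqrt(p / (2 - p)), 1L, which.max)]
  expect_equal(cdPredict(ens, q), direct)
  expect_equal(direct, rescaled)
})
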