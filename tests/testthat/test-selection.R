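# Entropy, symmetrical uncertainty, MDL discretization, FCBF and the
# class-dependent one-vs-rest scheme.

test_that("entropy matches the closed form", {
  expect_equal(discreteEntropy(c(0, 1, 0, 1)), 1)
  expect_equal(discreteEntropy(rep("a", 7)), 0)
  # frequencies (1/4, 3/4)
  expect_equal(discreteEntropy(c(1, 2, 2, 2)),
    -(0.25 * log2(0.25) + 0.75 * log2(0.75)),
    tolerance = 1e-12
  )
  expect_equal(discreteEntropy(c(1, 2, 2, 2)), 0.8112781, tolerance = 1e-6)
  expect_error(discreteEntropy(integer(0)), "empty")
})

test_that("symmetrical uncertainty obeys its contract and a hand evaluation", {
  x <- c(1, 2, 1, 2, 1)
  expect_equal(symmetricalUncertainty(x, x), 1)
  expect_equal(symmetricalUncertainty(rep(1, 5), x), 0)
  expect_equal(symmetricalUncertainty(rep(1, 5), rep(2, 5)), 0) # 0/0 convention
  expect_error(symmetricalUncertainty(1:3, 1:4), "length")

  # joint counts {(0,0):2, (0,1):1, (1,0):1, (1,1):2}:
  # H(X) = H(Y) = 1, H(X,Y) = (2/3) log2 3 + (1/3) log2 6
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1)
  hxy <- (2 / 3) * log2(3) + (1 / 3) * log2(6)
  expect_equal(symmetricalUncertainty(x, y), 2 * (2 - hxy) / 2, tolerance = 1e-12)
  expect_equal(symmetricalUncertainty(x, y), 0.0817042, tolerance = 1e-6)

  # symmetry and bounds on random discrete inputs
  set.seed(21)
  for (i in 1:20) {
    a <- sample.int(4, 30, replace = TRUE)
    b <- sample.int(3, 30, replace = TRUE)
    s <- symmetricalUncertainty(a, b)
    expect_identical(s, symmetricalUncertainty(b, a))
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("MDL discretization accepts a perfect split and rejects pure noise", {
  set.seed(31)
  y <- rep(c("a", "b"), each = 100)
  x <- cbind(ifelse(y == "a", 0, 1) + runif(200, -0.3, 0.3))
  m <- mdlDiscretizeFit(x, y)
  expect_length(m@cutPoints[[1]], 1L)
  expect_gt(m@cutPoints[[1]], 0.3)
  expect_lt(m@cutPoints[[1]], 0.7)

  rejected <- 0L
  for (s in seq_len(20)) {
    set.seed(400 + s)
    x <- matrix(rnorm(200), ncol = 1)
    y <- sample(rep(c("a", "b"), each = 100))
    m <- mdlDiscretizeFit(x, y)
    if (length(m@cutPoints[[1]]) == 0L) rejected <- rejected + 1L
  }
  expect_gte(rejected, 18L) # >= 90% of 20 seeds
})

test_that("discretizing an already two-valued feature is the identity up to bin labels", {
  y <- rep(c("a", "b"), each = 20)
  x <- cbind(ifelse(y == "a", 10, 20))
  m <- mdlDiscretizeFit(x, y)
  d <- mdlDiscretizeApply(m, x)[, 1]
  expect_equal(length(unique(d)), 2L)
  expect_true(all(tapply(d, x[, 1], function(v) length(unique(v))) == 1L))
  # a single-bin feature has zero SU with the class
  m0 <- mdlDiscretizeFit(matrix(rnorm(40), ncol = 1), y)
  if (length(m0@cutPoints[[1]]) == 0L) {
    d0 <- mdlDiscretizeApply(m0, matrix(rnorm(40), ncol = 1))[, 1]
    expect_equal(symmetricalUncertainty(d0, y), 0)
  }
})

test_that("FCBF keeps the predominant feature and drops copies and noise", {
  set.seed(41)
  y <- rep(c("a", "b"), each = 50)
  f1 <- ifelse(y == "a", 0, 1) + runif(100, -0.2, 0.2)
  x <- cbind(F1 = f1, F2 = f1, F3 = rnorm(100))
  sub <- fcbfSelect(x, y)
  expect_equal(subsetIndices(sub), 1L)
  expect_equal(sub@featureNames, "F1")
  expect_gte(min(subsetScores(sub)), 0)

  expect_length(subsetIndices(fcbfSelect(x, y, delta = 1)), 0L)

  # single informative feature among noise is ranked first
  x <- cbind(rnorm(100), rnorm(100), f1, rnorm(100))
  sub <- fcbfSelect(x, y)
  expect_equal(subsetIndices(sub)[1], 3L)
})

test_that("FCBF equals the exhaustive predominant-feature oracle on random tables", {
  set.seed(51)
  for (i in 1:40) {
    p <- sample(2:8, 1)
    n <- sample(20:60, 1)
    tb <- randomDiscreteTable(p, n)
    got <- subsetIndices(fcbfSelect(tb$x, tb$y, discretize = "none"))
    want <- oracleFCBF(tb$x, tb$y)
    expect_identical(got, as.integer(want))
  }
})

test_that("label binarization partitions the samples", {
  expect_equal(binarizeLabels(c(1, 2, 3, 1), 1), c(1L, -1L, -1L, 1L))
  expect_equal(binarizeLabels(rep("k", 4), "k"), rep(1L, 4))
  expect_error(binarizeLabels(c(1, 2), 5), "does not occur")
  y <- sample(letters[1:4], 40, replace = TRUE)
  pos <- vapply(
    sort(unique(y)),
    function(k) sum(binarizeLabels(y, k) == 1L), integer(1)
  )
  expect_equal(sum(pos), length(y))
})

test_that("class-dependent selection recovers the planted per-class features", {
  tab <- makePlantedTable(nPerClass = 100, nClasses = 3, seed = 61)
  subs <- classDependentSelect(tab)
  expect_named(subs, c("A1", "A2", "A3"))
  expect_equal(subsetIndices(subs$A1), 1L)
  expect_equal(subsetIndices(subs$A2), 2L)
  expect_equal(subsetIndices(subs$A3), 3L)
})

test_that("for two classes the one-vs-rest problems are label flips of each other", {
  tab <- makePlantedTable(nPerClass = 60, nClasses = 2, seed = 62)
  subs <- classDependentSelect(tab)
  expect_length(subs, 2L)
  # flipped labels carry the same information: identical subsets
  expect_equal(subsetIndices(subs[[1]]), subsetIndices(subs[[2]]))
  expect_equal(subsetScores(subs[[1]]), subsetScores(subs[[2]]))

  x <- featureValues(tab)
  y <- activityLabels(tab)
  expect_error(
    classDependentSelect(rbind(x, x[1, ]), c(y, "A9")),
    "fewer than 2 samples"
  )
})

test_that("appending label-independent noise never changes the informative set", {
  for (s in 1:5) {
    tab <- makePlantedTable(nPerClass = 100, nClasses = 3, seed = 70 + s)
    x <- featureValues(tab)
    y <- activityLabels(tab)
    base <- lapply(classDependentSelect(x, y), subsetIndices)
    set.seed(70 + s)
    xWide <- cbind(x, matrix(rnorm(nrow(x) * 4), ncol = 4))
    colnames(xWide) <- paste0("F", seq_len(ncol(xWide)))
    wide <- lapply(classDependentSelect(xWide, y), subsetIndices)
    for (k in names(base)) {
      expect_true(all(base[[k]] %in% wide[[k]]))
      expect_setequal(setdiff(wide[[k]], base[[k]]), integer(0))
    }
  }
})
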