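# Label tree, per-node training sets, hierarchical training and top-down
# prediction.

test_that("the label tree enforces its structural invariants", {
  tree <- defaultActivityTree()
  expect_equal(treeRoot(tree), "root")
  expect_setequal(treeLeaves(tree), activityOrder())
  expect_equal(treeChildren(tree, "static"), c("standing", "sitting", "lying"))
  expect_equal(treeParent(tree, "upstairs"), "dynamic")
  expect_equal(treeAncestors(tree, "upstairs"), c("dynamic", "root"))
  expect_setequal(treeSiblings(tree, "sitting"), c("standing", "lying"))
  expect_setequal(
    treeDescendants(tree, "dynamic"),
    c("walking", "upstairs", "downstairs")
  )
  expect_equal(treeInternalNodes(tree), c("root", "static", "dynamic"))

  # duplicate leaf labels
  expect_error(LabelTree(list(a = c("x", "y"), b = c("y", "z"))), "unique")
  # an internal node with a single child
  expect_error(LabelTree(list(a = "x", b = c("y", "z"))), "at least 2")
  # meta-class name colliding with an activity label
  expect_error(LabelTree(list(g = c("g", "x"), h = c("y", "z"))), "unique")
})

test_that("tree configurations round trip through YAML and JSON", {
  cfg <- list(
    static = c("standing", "sitting", "lying"),
    dynamic = c("walking", "upstairs", "downstairs")
  )
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  expect_equal(treeChildren(readLabelTree(yml), "root"), c("static", "dynamic"))
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn)
  t2 <- readLabelTree(jsn)
  expect_setequal(treeLeaves(t2), activityOrder())
})

test_that("node training sets relabel to the children's meta-classes", {
  tree <- defaultActivityTree()
  blobs <- withr::with_seed(31, sixActivityBlobs(nPerClass = 10))
  tr <- nodeTrainingSet(tree, "root", blobs$x, blobs$y)
  expect_equal(nrow(tr$values), 60L)
  expect_setequal(unique(tr$labels), c("static", "dynamic"))
  expect_equal(length(unique(tr$labels)), length(treeChildren(tree, "root")))

  tr <- nodeTrainingSet(tree, "static", blobs$x, blobs$y)
  expect_equal(nrow(tr$values), 30L)
  expect_setequal(unique(tr$labels), c("standing", "sitting", "lying"))

  expect_error(nodeTrainingSet(tree, "walking", blobs$x, blobs$y), "leaf")
})

test_that("training builds one model per internal node in every mode", {
  blobs <- withr::with_seed(32, sixActivityBlobs(nPerClass = 15))
  for (mode in c("none", "ci", "cd")) {
    model <- trainHierarchical(blobs$x, blobs$y, fsMode = mode)
    expect_length(model@nodeModels, 3L)
    expect_setequal(names(model@nodeModels), c("root", "static", "dynamic"))
  }
  modelNone <- trainHierarchical(blobs$x, blobs$y, fsMode = "none")
  for (nd in names(modelNone@nodeModels)) {
    expect_equal(
      subsetIndices(modelNone@nodeModels[[nd]]$subset),
      seq_len(ncol(blobs$x))
    )
  }

  # a node whose training set lacks one child's samples
  keep <- blobs$y != "lying"
  expect_error(
    trainHierarchical(blobs$x[keep, ], blobs$y[keep]),
    "no training samples for child 'lying'"
  )
  expect_error(
    trainHierarchical(blobs$x, c(blobs$y[-1], "jumping")),
    "not present among the tree leaves"
  )
})

test_that("top-down prediction descends one classifier per level and stays consistent", {
  blobs <- withr::with_seed(33, sixActivityBlobs(nPerClass = 15))
  model <- trainHierarchical(blobs$x, blobs$y, fsMode = "none")
  paths <- predictTopdown(model, blobs$x, path = TRUE)
  tree <- model@tree
  for (p in paths[seq(1, 90, by = 9)]) {
    expect_equal(p[1], "root")
    expect_length(p, 3L) # depth-2 tree: two classifier decisions
    for (i in 2:length(p)) {
      expect_true(p[i] %in% treeChildren(tree, p[i - 1]))
    }
  }
  leaves <- vapply(paths, function(p) p[length(p)], character(1))
  expect_equal(leaves, predictTopdown(model, blobs$x))
})

test_that("a flat tree reproduces the flat classifier exactly", {
  blobs <- withr::with_seed(34, sixActivityBlobs(nPerClass = 12, sep = 1.2))
  flatTree <- LabelTree(activityOrder())
  expect_length(treeInternalNodes(flatTree), 1L)
  model <- trainHierarchical(blobs$x, blobs$y,
    tree = flatTree,
    fsMode = "none"
  )
  flat <- nbFit(blobs$x, blobs$y)
  q <- withr::with_seed(99, {
    blobs$x + matrix(rnorm(length(blobs$x), sd = 0.5), nrow(blobs$x))
  })
  expect_identical(predictTopdown(model, q), unname(predict(flat, q)))
})

test_that("deeper trees train and predict with one classifier per internal node", {
  blobs <- withr::with_seed(35, sixActivityBlobs(nPerClass = 15))
  deep <- LabelTree(list(
    moving = list(
      stairs = c("upstairs", "downstairs"),
      "walking"
    ),
    still = list(
      seated = c("sitting", "lying"),
      "standing"
    )
  ))
  expect_length(treeInternalNodes(deep), 5L)
  model <- trainHierarchical(blobs$x, blobs$y, tree = deep, fsMode = "ci")
  expect_length(model@nodeModels, 5L)
  pred <- predictTopdown(model, blobs$x)
  expect_gt(mean(pred == blobs$y), 0.9)
  # leaves at different depths: path lengths differ accordingly
  paths <- predictTopdown(model, blobs$x, path = TRUE)
  lens <- lengths(paths)
  expect_setequal(sort(unique(lens)), c(3L, 4L))
})

test_that("model bundles round trip through the on-disk format", {
  blobs <- withr::with_seed(36, sixActivityBlobs(nPerClass = 12))
  for (mode in c("ci", "cd")) {
    model <- trainHierarchical(blobs$x, blobs$y, fsMode = mode)
    dir <- file.path(tempfile(), paste0("bundle_", mode))
    saveHierarchicalModel(model, dir)
    back <- loadHierarchicalModel(dir)
    expect_equal(back@fsMode, mode)
    expect_identical(
      predictTopdown(back, blobs$x),
      predictTopdown(model, blobs$x)
    )
  }
})
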