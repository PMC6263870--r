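# Worked-example confusion matrices for a six-activity recognizer
# evaluated on a smartphone accelerometer+gyroscope benchmark: a flat
# model without feature selection, a flat model with class-dependent
# selection, and the hierarchical model with class-dependent selection.
# Orientation: rows = predicted labels, columns = true labels.

.exampleActivities <- c(
  "walking", "upstairs", "downstairs", "sitting", "standing", "lying"
)

exampleMatrixFlatNoFS <- function() {
  m <- matrix(c(
    416, 9, 80, 0, 4, 0,
    38, 451, 83, 7, 15, 3,
    42, 11, 257, 0, 0, 0,
    0, 0, 0, 368, 54, 212,
    0, 0, 0, 111, 455, 0,
    0, 0, 0, 5, 8, 322
  ), nrow = 6, byrow = TRUE, dimnames = list(.exampleActivities, .exampleActivities))
  asConfusionMatrix(m)
}

exampleMatrixFlatCD <- function() {
  m <- matrix(c(
    455, 58, 34, 0, 4, 0,
    26, 388, 22, 9, 8, 0,
    15, 25, 364, 0, 0, 0,
    0, 0, 0, 215, 15, 0,
    0, 0, 0, 262, 505, 0,
    0, 0, 0, 5, 0, 537
  ), nrow = 6, byrow = TRUE, dimnames = list(.exampleActivities, .exampleActivities))
  asConfusionMatrix(m)
}

exampleMatrixHierCD <- function() {
  m <- matrix(c(
    470, 27, 18, 0, 1, 0,
    8, 440, 35, 4, 17, 1,
    18, 4, 367, 0, 0, 0,
    0, 0, 0, 395, 58, 0,
    0, 0, 0, 92, 455, 0,
    0, 0, 0, 0, 0, 536
  ), nrow = 6, byrow = TRUE, dimnames = list(.exampleActivities, .exampleActivities))
  asConfusionMatrix(m)
}

dynamicActivities <- function() c("walking", "upstairs", "downstairs")
staticActivities <- function() c("sitting", "standing", "lying")
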