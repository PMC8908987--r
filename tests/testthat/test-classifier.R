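test_that("layer widths follow the two-thirds reduction rule", {
  expect_equal(buildStackedSAE(200)$layerDims, c(134L, 90L, 60L))
  expect_equal(buildStackedSAE(2500)$layerDims, c(1667L, 1112L, 742L))
  expect_equal(buildStackedSAE(3)$layerDims, c(2L, 2L, 2L))
  expect_error(buildStackedSAE(2), "inputDim")
})

test_that("a separable toy problem is learned perfectly", {
  set.seed(1)
  X <- cbind(c(rnorm(20, 0), rnorm(20, 5)), c(rnorm(20, 0), rnorm(20, 5)))
  y <- rep(c("benign", "malignant"), each = 20)
  tr <- trainDescriptorClassifier(X, y, buildStackedSAE(3, layerDims = c(2, 2, 2)))
  expect_equal(mean((tr$prob >= 0.5) == (y == "malignant")), 1)
  expect_true(all(tr$prob >= 0 & tr$prob <= 1))
})

test_that("zero-variance features yield the class prior", {
  X <- matrix(1, 30, 4)
  y <- rep(c("benign", "malignant"), c(20, 10))
  tr <- trainDescriptorClassifier(X, y, buildStackedSAE(4, epochs = 300))
  expect_equal(mean(tr$prob), 1 / 3, tolerance = 0.05)
  expect_lt(sd(tr$prob), 0.01) # uninformative input: identical outputs
})

test_that("training rejects degenerate label sets and is deterministic", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(trainDescriptorClassifier(X, rep("benign", 10)),
               "both classes")
  y <- rep(c("benign", "malignant"), 5)
  t1 <- trainDescriptorClassifier(X, y, buildStackedSAE(4, seed = 9, epochs = 30))
  t2 <- trainDescriptorClassifier(X, y, buildStackedSAE(4, seed = 9, epochs = 30))
  expect_identical(t1$prob, t2$prob)
})

test_that("fusion accepts stage-1 probabilities and stays in [0,1]", {
  set.seed(2)
  n <- 40
  y <- rep(c("benign", "malignant"), each = n / 2)
  P <- matrix(runif(n * 6, 0, 0.2), n, 6)
  P[y == "malignant", ] <- P[y == "malignant", ] + 0.8
  fu <- fuseProbabilities(P, y, seed = 3, epochs = 100)
  expect_true(all(fu$prob >= 0 & fu$prob <= 1))
  expect_equal(mean((fu$prob >= 0.5) == (y == "malignant")), 1)
  expect_error(fuseProbabilities(P * 2, y), "probabilities")
})

test_that("fusion tracks one informative column among noise", {
  set.seed(4)
  n <- 80
  y <- rep(c("benign", "malignant"), each = n / 2)
  P <- matrix(runif(n * 6), n, 6)
  P[, 3] <- ifelse(y == "malignant", 0.95, 0.05)
  sp <- splitTrainTest(y, seed = 5)
  fu <- fuseProbabilities(P[sp$train, ], y[sp$train], seed = 5)
  pr <- predictProb(fu$model, P[sp$test, ])
  accFused <- mean((pr >= 0.5) == (y[sp$test] == "malignant"))
  accInfo <- mean((P[sp$test, 3] >= 0.5) == (y[sp$test] == "malignant"))
  expect_gte(accFused, accInfo - 0.02)
})

test_that("evaluation metrics recompute from the confusion counts", {
  lab <- c(rep("malignant", 10), rep("benign", 10))
  pr <- c(rep(0.9, 9), 0.1, rep(0.1, 8), 0.9, 0.9)
  ev <- evaluateClassifier(pr, lab)
  expect_equal(unname(ev@confusion), c(9, 2, 8, 1)) # TP FP TN FN
  expect_equal(ev@sensitivity, 90)
  expect_equal(ev@specificity, 80)
  expect_equal(ev@accuracy, 85)
  expect_equal(ev@precision, 100 * 9 / 11, tolerance = 1e-9)
  # metrics consistent with stored counts
  cf <- ev@confusion
  expect_equal(ev@accuracy, 100 * (cf["TP"] + cf["TN"]) / sum(cf),
               ignore_attr = TRUE)
  perfect <- evaluateClassifier(c(rep(0.9, 10), rep(0.1, 10)), lab)
  expect_equal(c(perfect@accuracy, perfect@sensitivity, perfect@specificity,
                 perfect@precision), rep(100, 4))
  expect_equal(perfect@auc, 1)
  inverted <- evaluateClassifier(c(rep(0.1, 10), rep(0.9, 10)), lab)
  expect_equal(inverted@auc, 0)
  expect_error(evaluateClassifier(pr, rep("benign", 20)), "both classes")
})

test_that("stratified split preserves proportions and is seeded", {
  y <- rep(c("benign", "malignant"), each = 100)
  sp <- splitTrainTest(y, 0.70, seed = 11)
  expect_length(sp$train, 140)
  expect_length(sp$test, 60)
  expect_equal(sum(y[sp$train] == "benign"), 70)
  expect_equal(sum(y[sp$test] == "malignant"), 30)
  sp2 <- splitTrainTest(y, 0.70, seed = 11)
  expect_identical(sp, sp2)
  # uneven class sizes: proportions within one sample
  y2 <- rep(c("benign", "malignant"), c(55, 45))
  sp3 <- splitTrainTest(y2, 0.70, seed = 12)
  expect_equal(sum(y2[sp3$train] == "benign"), round(0.7 * 55))
  expect_equal(sum(y2[sp3$train] == "malignant"), round(0.7 * 45))
})
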