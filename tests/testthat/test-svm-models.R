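test_that("training recovers a separable classification and planted regression", {
  ds <- synthTrainingSet(4, 90)
  fit <- trainModels(ds)
  X <- ds@features
  attr(X, "schema_version") <- ds@schemaVersion
  # regression: planted noiseless signal recovered on training data
  expect_gt(pearsonCC(predictRasa(fit, X), ds@rasa), 0.95)
  # classification: high training agreement on the planted labels
  acc <- mean(predictBurial(fit, X) == ds@labels)
  expect_gt(acc, 0.95)
})

test_that("a linearly separable two-cluster set is fit perfectly", {
  set.seed(5)
  X <- rbind(matrix(stats::rnorm(60, 0), ncol = 3),
             matrix(stats::rnorm(60, 6), ncol = 3))
  lab <- rep(c("B", "E"), each = 20)
  ds <- datasetSplit(X, rasa = rep(c(0.01, 0.5), each = 20), labels = lab,
                     chain = rep(c("C1", "C2"), 20),
                     schema_version = "synthetic-fv-1")
  fit <- trainModels(ds)
  Xs <- ds@features
  attr(Xs, "schema_version") <- "synthetic-fv-1"
  expect_equal(predictBurial(fit, Xs), lab)
  expect_equal(predictBurial(fit, Xs[0, , drop = FALSE]), character(0))
})

test_that("single-class training refuses and schema mismatches refuse", {
  ds <- synthTrainingSet(3, 36)
  one <- datasetSplit(ds@features, ds@rasa, labels = rep("E", length(ds@rasa)),
                      chain = ds@chain, schema_version = ds@schemaVersion)
  expect_error(trainModels(one), "single-class")
  fit <- trainModels(ds)
  X <- ds@features
  attr(X, "schema_version") <- "some-other-schema"
  expect_error(predictRasa(fit, X), "schema mismatch")
  expect_error(predictBurial(fit, X), "schema mismatch")
})

test_that("predicted rASA is clamped into [0, 1]", {
  # stub regressor producing out-of-range raw outputs exercises the rule
  stub <- structure(list(), class = "tmexpo_stub_reg")
  registerS3method("predict", "tmexpo_stub_reg",
                   function(object, newdata, ...) c(-0.1, 1.2, 0.37),
                   envir = asNamespace("stats"))
  bundle <- new("TMexpoModel", classifier = NULL, regressor = stub,
                hyperparams = tmHyperparams(), schemaVersion = "s",
                meta = list())
  X <- matrix(0, 3, 2)
  attr(X, "schema_version") <- "s"
  expect_equal(predictRasa(bundle, X), c(0, 1, 0.37))
  # and real predictions never escape the interval
  ds <- synthTrainingSet(3, 36, noise_sd = 0.05)
  fit <- trainModels(ds)
  Xs <- ds@features
  attr(Xs, "schema_version") <- ds@schemaVersion
  p <- predictRasa(fit, Xs)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("ASA denormalisation multiplies by the reference value", {
  ref <- loadReferenceTable()
  expect_equal(asaFromRasa(0, "TRP", ref), 0)
  expect_equal(asaFromRasa(1, "GLY", ref), ref[["GLY"]])
  expect_equal(asaFromRasa(0.5, "LEU", ref), ref[["LEU"]] / 2)
  expect_error(asaFromRasa(0.5, "UNK", ref), "no reference")
})

test_that("chain-wise LOOCV has one fold per chain without leakage", {
  ds <- synthTrainingSet(5, 36)
  cv <- chainwiseLOOCV(ds)
  expect_setequal(unique(cv$predictions$chain), unique(ds@chain))
  expect_equal(nrow(cv$predictions), length(ds@rasa))
  # every chain predicted exactly once, with all its residues
  expect_equal(as.numeric(table(cv$predictions$chain)),
               as.numeric(table(ds@chain)))
  # no-leakage sanity: held-out performance close to training performance
  fit <- trainModels(ds)
  X <- ds@features
  attr(X, "schema_version") <- ds@schemaVersion
  train_pcc <- pearsonCC(predictRasa(fit, X), ds@rasa)
  expect_lt(abs(train_pcc - cv$report@pcc), 0.1)
  expect_error(chainwiseLOOCV(synthTrainingSet(2, 36)), NA)
  one_chain <- datasetSplit(ds@features, ds@rasa, labels = ds@labels,
                            chain = rep("C1", length(ds@rasa)),
                            schema_version = ds@schemaVersion)
  expect_error(chainwiseLOOCV(one_chain), "at least 2 chains")
})

test_that("training is deterministic for fixed data and seed", {
  ds <- synthTrainingSet(3, 36, noise_sd = 0.02)
  X <- ds@features
  attr(X, "schema_version") <- ds@schemaVersion
  p1 <- predictRasa(trainModels(ds, seed = 9), X)
  p2 <- predictRasa(trainModels(ds, seed = 9), X)
  expect_identical(p1, p2)
})
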