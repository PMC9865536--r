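make_feature_task <- function(n = 120, seed = 70) {
  # depth-separable synthetic task: features driven by a latent depth
  set.seed(seed)
  d <- runif(n)
  psi <- pmin(pmax(round(100 * (1 - d)), 0), 100)
  feats <- cbind(matrix(rnorm(n * 3, 10), n, 3),
                 0.2 + 0.6 * d + matrix(rnorm(n * 5, 0, 0.05), n, 5),
                 30 - 20 * d + rnorm(n, 0, 2),
                 30 - 20 * d + rnorm(n, 0, 2),
                 matrix(1.5 - d + rnorm(n * 4, 0, 0.1), n, 4))
  colnames(feats) <- feature_names()
  list(features = feats, psi = psi)
}

test_that("baseline specs enforce the documented structures", {
  task <- make_feature_task()
  ann <- baseline_fit(baseline_spec("ann", ann_epochs = 10L), task$features,
                      task$psi)
  expect_equal(ann_layer_sizes(ann), c(14, 64, 16, 1))

  rf <- baseline_fit(baseline_spec("rf"), task$features, task$psi)
  expect_equal(rf$fit$ntree, 300)

  expect_error(baseline_fit("svr", task$features[, 1:10], task$psi),
               "14 feature")
  expect_error(predict(rf, task$features[, 1:10]), "14 feature")
})

test_that("fitted baselines track a depth-separable feature task", {
  task <- make_feature_task()
  std <- standardize(task$features)
  for (kind in c("svr", "rf", "ann")) {
    spec <- baseline_spec(kind, seed = 3, ann_epochs = 60L)
    fit <- baseline_fit(spec, std$train, task$psi)
    p <- predict(fit, std$train)
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 100))
    expect_gt(suppressWarnings(cor(p, task$psi, method = "spearman")), 0.5)
  }
})

test_that("constant labels produce near-constant predictions", {
  task <- make_feature_task(80)
  std <- standardize(task$features)
  y <- rep(42, 80)
  rf <- baseline_fit(baseline_spec("rf", seed = 1), std$train, y)
  expect_equal(unname(predict(rf, std$train)), rep(42, 80))
  svr <- baseline_fit(baseline_spec("svr"), std$train, y)
  expect_lt(max(abs(predict(svr, std$train) - 42)), 2)
  ann <- baseline_fit(baseline_spec("ann", seed = 1, ann_epochs = 150L),
                      std$train, y)
  pa <- predict(ann, std$train)
  expect_lt(abs(mean(pa) - 42), 2)
  expect_lt(sd(pa), 5)
})

test_that("random forest fits are deterministic given the seed", {
  task <- make_feature_task(60)
  f1 <- baseline_fit(baseline_spec("rf", seed = 11), task$features, task$psi)
  f2 <- baseline_fit(baseline_spec("rf", seed = 11), task$features, task$psi)
  expect_equal(predict(f1, task$features), predict(f2, task$features))
})
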