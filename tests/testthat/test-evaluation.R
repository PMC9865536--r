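test_that("standardization uses train statistics and guards degeneracy", {
  set.seed(80)
  tr <- matrix(rnorm(50 * 10, 5, 2), 50)
  te <- matrix(rnorm(20 * 10, 5, 2), 20)
  tr[, 3] <- 7                               # constant column
  s <- standardize(tr, te)
  expect_equal(colMeans(s$train), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(s$train[, -3], 2, sd), rep(1, 9), tolerance = 1e-12)
  expect_true(all(s$train[, 3] == 0))
  expect_true(all(s$test[, 3] == 0))
  # test columns standardized with *train* statistics
  expect_equal(s$test[, 1], (te[, 1] - mean(tr[, 1])) / sd(tr[, 1]))
  expect_error(standardize(matrix(0, 0, 5)), "empty")
  expect_error(standardize(tr, te[, 1:4]), "mismatch")
})

test_that("PSI state bins follow the clinical table with half-open edges", {
  expect_equal(as.character(psi_to_state(c(81, 100))), c("AW", "AW"))
  expect_equal(as.character(psi_to_state(80)), "LA")
  expect_equal(as.character(psi_to_state(51)), "LA")
  expect_equal(as.character(psi_to_state(50)), "NA")
  expect_equal(as.character(psi_to_state(26)), "NA")
  expect_equal(as.character(psi_to_state(25)), "DA")
  expect_equal(as.character(psi_to_state(0)), "DA")
  expect_equal(as.character(psi_to_state(80.5)), "AW")
  expect_error(psi_to_state(101), "\\[0, 100\\]")
  expect_error(psi_to_state(-1), "\\[0, 100\\]")
})

test_that("perfect and anti-perfect predictions hit the metric extremes", {
  truth <- c(90, 85, 70, 60, 40, 30, 20, 10)
  m <- compute_metrics(truth, truth)
  expect_equal(m$mse, 0)
  expect_equal(m$macro_acc, 1)
  expect_equal(m$macro_se, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$spearman, 1)
  rev <- compute_metrics(rev(truth), truth)
  expect_equal(rev$spearman, -1)
  expect_error(compute_metrics(1:3, 1:4), "mismatch")
})

test_that("a hand-tallied toy set reproduces the confusion arithmetic", {
  truth <- c(90, 95, 70, 60, 40, 35, 20, 10, 85, 55)
  pred  <- c(88, 92, 72, 45, 42, 38, 22, 12, 82, 58)  # two misclassified
  m <- compute_metrics(pred, truth)
  # state NA: truth {40,35}, predictions into NA {45->NA? no:(25,50]}:
  # pred 45 belongs to NA although its truth (60) is LA -> FP for NA
  expect_equal(m$per_state$TP[m$per_state$state == "NA"], 2)
  expect_equal(m$per_state$FP[m$per_state$state == "NA"], 1)
  expect_equal(m$per_state$FN[m$per_state$state == "LA"], 1)
  expect_equal(m$multiclass_acc, 0.9)
  expect_equal(m$mse, mean((pred - truth)^2))
})

test_that("the metric suite equals brute-force tallies on random vectors", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    truth <- runif(n, 0, 100)
    pred <- runif(n, 0, 100)
    m <- compute_metrics(pred, truth)
    bf <- metrics_bruteforce(as.character(psi_to_state(pred)),
                             as.character(psi_to_state(truth)))
    for (st in c("AW", "LA", "NA", "DA")) {
      row <- m$per_state[m$per_state$state == st, ]
      expect_equal(unname(c(row$acc, row$se, row$pr, row$f1)),
                   unname(bf[[st]]), tolerance = 1e-12)
    }
    expect_equal(m$macro_f1,
                 mean(vapply(bf, `[[`, numeric(1), "f1")),
                 tolerance = 1e-12)
    expect_equal(m$spearman, cor(pred, truth, method = "spearman"))
  }
})

test_that("zero-support cells are defined as zero", {
  truth <- c(90, 95, 88)                       # only AW present
  pred <- c(92, 91, 89)
  m <- compute_metrics(pred, truth)
  expect_equal(m$per_state$se[m$per_state$state == "DA"], 0)
  expect_equal(m$per_state$f1[m$per_state$state == "DA"], 0)
  expect_warning(compute_metrics(pred, truth, warn = TRUE), "zero denominator")
})

test_that("random folds partition the indices with balanced sizes", {
  f <- kfold_random(22, 5, seed = 1)
  expect_setequal(sort(vapply(f, length, integer(1))), c(4, 4, 4, 5, 5))
  expect_setequal(unlist(f), 1:22)
  expect_equal(sum(duplicated(unlist(f))), 0)
  expect_identical(kfold_random(22, 5, seed = 1), f)
  expect_false(identical(kfold_random(22, 5, seed = 2), f))
  expect_error(kfold_random(3, 5), "folds")
})

test_that("subject folds never split a subject", {
  subjects <- rep(sprintf("S%02d", 1:18), times = sample(5:12, 18,
                                                         replace = TRUE))
  f <- kfold_by_subject(subjects, k = 5)
  sizes <- vapply(f, function(idx) length(unique(subjects[idx])),
                  integer(1))
  expect_setequal(sort(sizes), c(3, 3, 4, 4, 4))
  expect_equal(sum(vapply(f, length, integer(1))), length(subjects))
  for (fold in f)
    expect_length(intersect(unique(subjects[fold]),
                            unique(subjects[-fold])), 0)
  expect_error(kfold_by_subject(subjects,
                                groups = list(c("S01", "S02"),
                                              c("S02", "S03"))),
               "more than one group")
  expect_error(kfold_by_subject(rep("S01", 10), k = 1),
               "empty training set")
})

test_that("a small experiment runs end to end with shared folds", {
  ds <- generate_dataset(sim_spec(n_subjects = 3,
                                  duration_per_subject = 60, seed = 14))
  samples <- prepare_samples(ds)
  cfg <- drsn_config(stages = c(4L, 16L), max_epochs = 3L, seed = 1L)
  ev <- run_experiment(samples, models = c("rf", "drsn"), k = 3,
                       drsn_cfg = cfg, seed = 2)
  expect_setequal(unique(ev$summary$model), c("rf", "drsn"))
  expect_setequal(unique(ev$summary$metric),
                  c("mse", "acc", "se", "f1", "spearman"))
  expect_true(all(is.finite(ev$summary$mean)))
  mse <- eval_metric(ev, "mse")
  expect_true(all(mse > 0))
  # identical seed reproduces the report
  ev2 <- run_experiment(samples, models = c("rf", "drsn"), k = 3,
                        drsn_cfg = cfg, seed = 2)
  expect_equal(ev$summary, ev2$summary)
})
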