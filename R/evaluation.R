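## Evaluation protocol: train-set column standardization, PSI -> state
## binning, the regression/classification metric suite with macro
## averaging, Spearman rank correlation, and the cross-validation drivers.

#' Column-wise standardization with train-set statistics
#'
#' Flattened samples (2848 columns for 4 x 712 windows, or 14 feature
#' columns) are standardized by subtracting the per-column mean and dividing
#' by the per-column standard deviation, both computed on the training set
#' only and applied to both sets.  Columns with (near-)zero spread map to 0.
#'
#' @param train `N x P` training matrix.
#' @param test optional `M x P` test matrix.
#' @return list with `train`, `test` (or `NULL`), and `stats`
#'   (`mean`, `sd` per column).
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  stop_if(nrow(train) == 0L, "empty training set")
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- Inf   # degenerate columns -> 0
  apply_std <- function(m) {
    m <- as.matrix(m)
    stop_if(ncol(m) != length(mu), "column count mismatch: ", ncol(m),
            " vs ", length(mu))
    sweep(m, 2, mu) / rep(sdv, each = nrow(m))
  }
  list(train = apply_std(train),
       test = if (!is.null(test)) apply_std(test),
       stats = list(mean = mu, sd = ifelse(is.infinite(sdv), 0, sdv)))
}

.state_levels <- c("AW", "LA", "NA", "DA")

#' Map PSI values to anesthetized states
#'
#' Awake (AW) for PSI in (80, 100\], light anesthesia (LA) for (50, 80\],
#' normal anesthesia (NA) for (25, 50\] and deep anesthesia (DA) for
#' \[0, 25\].  Half-open bins reproduce the integer table (AW 81-100, LA
#' 51-80, NA 26-50, DA 0-25) and give continuous predictions a unique bin.
#'
#' @param psi numeric vector in \[0, 100\].
#' @return factor with levels `AW`, `LA`, `NA`, `DA`.
#' @export
psi_to_state <- function(psi) {
  stop_if(any(!is.finite(psi)) || any(psi < 0 | psi > 100),
          "PSI values must lie in [0, 100]")
  lab <- ifelse(psi > 80, "AW",
                ifelse(psi > 50, "LA", ifelse(psi > 25, "NA", "DA")))
  factor(lab, levels = .state_levels)
}

#' Regression and classification metric suite
#'
#' MSE on the PSI scale; per-state one-vs-rest accuracy, sensitivity,
#' precision and F1 from the state confusion counts; their unweighted
#' (macro) means over the four states; plain multiclass accuracy; and the
#' Spearman rank correlation of predictions with ground truth (average
#' ranks for ties).  Cells with zero denominator (e.g. precision with no
#' positive predictions) are defined as 0.
#'
#' @param predictions predicted PSI values in \[0, 100\].
#' @param ground_truth true PSI values in \[0, 100\].
#' @param warn warn when a zero-denominator cell is zeroed.
#' @return object of class `"eval_metrics"`: list with `mse`, `per_state`
#'   (data frame of TP/TN/FP/FN/acc/se/pr/f1), `macro_acc`, `macro_se`,
#'   `macro_pr`, `macro_f1`, `multiclass_acc`, `spearman`, `n`.
#' @export
compute_metrics <- function(predictions, ground_truth, warn = FALSE) {
  stop_if(length(predictions) != length(ground_truth),
          "length mismatch: ", length(predictions), " predictions vs ",
          length(ground_truth), " truths")
  stop_if(length(predictions) == 0L, "empty input")
  mse <- mean((predictions - ground_truth)^2)
  ps <- psi_to_state(predictions)
  ts <- psi_to_state(ground_truth)
  n <- length(ps)
  per_state <- do.call(rbind, lapply(.state_levels, function(st) {
    tp <- sum(ps == st & ts == st)
    fp <- sum(ps == st & ts != st)
    fn <- sum(ps != st & ts == st)
    tn <- n - tp - fp - fn
    safe <- function(num, den, what) {
      if (den == 0) {
        if (warn) warning("zero denominator for ", what, " of state ", st,
                          "; defined as 0")
        0
      } else num / den
    }
    se <- safe(tp, tp + fn, "sensitivity")
    pr <- safe(tp, tp + fp, "precision")
    data.frame(state = st, TP = tp, TN = tn, FP = fp, FN = fn,
               acc = (tp + tn) / n, se = se, pr = pr,
               f1 = safe(2 * se * pr, se + pr, "F1"))
  }))
  structure(list(mse = mse, per_state = per_state,
                 macro_acc = mean(per_state$acc),
                 macro_se = mean(per_state$se),
                 macro_pr = mean(per_state$pr),
                 macro_f1 = mean(per_state$f1),
                 multiclass_acc = mean(ps == ts),
                 spearman = suppressWarnings(
                   cor(predictions, ground_truth, method = "spearman")),
                 n = n),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("n = %d   MSE = %.2f   Spearman rho = %.4f\n", x$n, x$mse,
              x$spearman))
  cat(sprintf("macro: ACC %.4f  SE %.4f  PR %.4f  F1 %.4f   (multiclass ACC %.4f)\n",
              x$macro_acc, x$macro_se, x$macro_pr, x$macro_f1,
              x$multiclass_acc))
  invisible(x)
}

#' Random k-fold split
#'
#' Shuffles the indices and deals them into `k` disjoint, exhaustive folds
#' whose sizes differ by at most one.
#'
#' @param n number of samples (or a `"doa_samples"` object).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of `k` integer vectors (test indices per fold).
#' @export
kfold_random <- function(n, k = 5L, seed = 1L) {
  if (inherits(n, "doa_samples")) n <- nrow(n$x)
  stop_if(k > n, "cannot make ", k, " folds from ", n, " samples")
  ord <- with_seed(seed, sample(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  unname(split(ord, rep(seq_len(k), times = sizes)))
}

#' Subject-grouped k-fold split
#'
#' Each fold's test set contains all samples of its group's subjects and
#' none from any other group, so evaluation is strictly cross-subject.
#'
#' @param subjects character vector, one subject id per sample (or a
#'   `"doa_samples"` object).
#' @param groups list of character vectors partitioning the subject ids;
#'   `NULL` deals subjects round-robin into `k` groups of near-equal size
#'   (e.g. 18 subjects into 4/4/4/3/3).
#' @param k number of groups when `groups` is `NULL`.
#' @return list of integer vectors (test indices per fold).
#' @export
kfold_by_subject <- function(subjects, groups = NULL, k = 5L) {
  if (inherits(subjects, "doa_samples")) subjects <- subjects$subject
  ids <- unique(subjects)
  if (is.null(groups)) {
    stop_if(k > length(ids), "cannot make ", k, " groups from ",
            length(ids), " subjects")
    groups <- split(ids, rep(seq_len(k), length.out = length(ids)))
  }
  all_ids <- unlist(groups)
  stop_if(anyDuplicated(all_ids) > 0, "subject(s) in more than one group: ",
          paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  stop_if(!all(ids %in% all_ids), "subject(s) missing from groups: ",
          paste(setdiff(ids, all_ids), collapse = ", "))
  folds <- lapply(groups, function(g) which(subjects %in% g))
  for (i in seq_along(folds))
    stop_if(length(folds[[i]]) == length(subjects),
            "fold ", i, " would leave an empty training set")
  unname(folds)
}

#' Cross-validated model comparison
#'
#' For every fold: standardize EEG windows and feature vectors on the
#' training part only, fit the requested models, and evaluate on the held
#' out part.  The deep model consumes the standardized raw windows; the
#' baselines consume the standardized 14-feature vectors.  With
#' `ablate = TRUE` the deep model is additionally run with its soft
#' thresholding removed on identical folds and seeds.
#'
#' @param samples a `"doa_samples"` set from [prepare_samples()].
#' @param models character subset of `c("svr", "rf", "ann", "drsn")`.
#' @param cv `"random"` or `"subject"`.
#' @param k folds.
#' @param drsn_cfg a [drsn_config()] for the deep model.
#' @param ablate also fit the ablated deep model.
#' @param features optional precomputed `N x 14` feature table (computed
#'   with [features_table()] when any baseline is requested and missing).
#' @param seed seed for fold shuffling and model fits.
#' @param verbose print progress.
#' @return object of class `"doa_eval"`: list with `folds` (per-fold
#'   `"eval_metrics"` per model), `summary` (data frame of mean +- SD per
#'   model and metric), and `predictions` (per-model truth/prediction table
#'   pooled over folds).
#' @export
run_experiment <- function(samples, models = c("svr", "rf", "ann", "drsn"),
                           cv = c("random", "subject"), k = 5L,
                           drsn_cfg = NULL, ablate = FALSE,
                           features = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(samples, "doa_samples"))
  cv <- match.arg(cv)
  models <- match.arg(models, several.ok = TRUE)
  if (ablate && !"drsn" %in% models) models <- c(models, "drsn")
  run_models <- c(models, if (ablate) "drsn_ablated")
  if (is.null(drsn_cfg))
    drsn_cfg <- drsn_config(max_epochs = 60L, val_fraction = 0.12,
                            patience = 10L, seed = seed)
  need_feat <- any(models %in% c("svr", "rf", "ann"))
  if (need_feat && is.null(features)) {
    if (verbose) message("extracting 14-feature table ...")
    features <- features_table(samples)
  }
  folds <- if (cv == "random") kfold_random(nrow(samples$x), k, seed)
           else kfold_by_subject(samples$subject, k = k)
  fold_metrics <- list()
  preds <- list()
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(samples$x)), test_idx)
    sx <- standardize(samples$x[train_idx, , drop = FALSE],
                      samples$x[test_idx, , drop = FALSE])
    sf <- if (need_feat)
      standardize(features[train_idx, , drop = FALSE],
                  features[test_idx, , drop = FALSE])
    y_tr <- samples$psi[train_idx]
    y_te <- samples$psi[test_idx]
    for (m in run_models) {
      if (verbose) message(sprintf("fold %d/%d: %s", f, length(folds), m))
      p <- switch(m,
        drsn = {
          cfg <- drsn_cfg; cfg$seed <- child_seed(seed, 10L * f)
          fit <- drsn_fit(sx$train, y_tr, cfg)
          predict(fit, sx$test)
        },
        drsn_ablated = {
          cfg <- drsn_cfg; cfg$seed <- child_seed(seed, 10L * f)
          fit <- drsn_fit(sx$train, y_tr, cfg, ablate_soft_threshold = TRUE)
          predict(fit, sx$test)
        },
        {
          spec <- baseline_spec(m, seed = child_seed(seed, 10L * f))
          fit <- baseline_fit(spec, sf$train, y_tr)
          predict(fit, sf$test)
        })
      fold_metrics[[m]][[f]] <- compute_metrics(p, y_te)
      preds[[m]] <- rbind(preds[[m]],
                          data.frame(fold = f, truth = y_te, pred = p))
    }
  }
  metric_names <- c(mse = "mse", acc = "macro_acc", se = "macro_se",
                    f1 = "macro_f1", spearman = "spearman")
  summary_df <- do.call(rbind, lapply(run_models, function(m) {
    vals <- sapply(names(metric_names), function(mn)
      vapply(fold_metrics[[m]], `[[`, numeric(1), metric_names[[mn]]))
    data.frame(model = m, metric = names(metric_names),
               mean = colMeans(vals), sd = apply(vals, 2, sd),
               row.names = NULL)
  }))
  structure(list(folds = fold_metrics, summary = summary_df,
                 predictions = preds, cv = cv, k = length(folds),
                 models = run_models),
            class = "doa_eval")
}

#' @export
print.doa_eval <- function(x, ...) {
  cat(sprintf("%s %d-fold cross-validation (%s)\n",
              if (x$cv == "random") "Random" else "Subject-grouped", x$k,
              paste(x$models, collapse = ", ")))
  s <- x$summary
  for (mn in unique(s$metric)) {
    row <- s[s$metric == mn, ]
    cat(sprintf("  %-9s %s\n", mn, paste(
      sprintf("%s %.4g+-%.2g", row$model, row$mean, row$sd),
      collapse = "   ")))
  }
  invisible(x)
}

#' Pull one metric's mean per model from an experiment
#' @param ev a `"doa_eval"`.
#' @param metric one of `"mse"`, `"acc"`, `"se"`, `"f1"`, `"spearman"`.
#' @return named numeric vector (one value per model).
#' @export
eval_metric <- function(ev, metric = "mse") {
  s <- ev$summary[ev$summary$metric == metric, ]
  stats::setNames(s$mean, s$model)
}
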