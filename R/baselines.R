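## Conventional feature-based baselines: support vector regression with an
## RBF kernel, random forest with 300 trees, and a 14-64-16-1 multilayer
## perceptron.  All consume the standardized 14-feature vectors.

#' Specification of a conventional baseline regressor
#'
#' @param kind `"svr"`, `"rf"` or `"ann"`.
#' @param n_trees random forest size.
#' @param ann_hidden hidden layer widths of the ANN (input is the 14
#'   features, output one PSI value, hence 14-64-16-1 by default).
#' @param ann_epochs ANN training epochs.
#' @param seed seed for the stochastic fits (rf, ann).
#' @param ... extra arguments forwarded to the underlying fitter
#'   (e.g. `cost`, `epsilon`, `gamma` for the SVR).
#' @return object of class `"baseline_spec"`.
#' @export
baseline_spec <- function(kind = c("svr", "rf", "ann"), n_trees = 300L,
                          ann_hidden = c(64L, 16L), ann_epochs = 120L,
                          seed = 1L, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 ann_hidden = as.integer(ann_hidden),
                 ann_epochs = as.integer(ann_epochs),
                 seed = as.integer(seed), extra = list(...)),
            class = "baseline_spec")
}

#' Fit a conventional baseline on feature vectors
#'
#' @param spec a [baseline_spec()] (or a kind string).
#' @param features `N x 14` matrix of standardized features.
#' @param psi PSI labels in \[0, 100\].
#' @return object of class `"doa_baseline"` exposing [predict()].
#' @export
baseline_fit <- function(spec, features, psi) {
  if (is.character(spec)) spec <- baseline_spec(spec)
  stopifnot(inherits(spec, "baseline_spec"))
  features <- as.matrix(features)
  stop_if(ncol(features) != 14L, "expected 14 feature columns, got ",
          ncol(features))
  stop_if(any(psi < 0 | psi > 100), "PSI labels must lie in [0, 100]")
  fit <- switch(spec$kind,
    svr = tryCatch(
      do.call(e1071::svm,
              c(list(x = features, y = psi, type = "eps-regression",
                     kernel = "radial", scale = FALSE), spec$extra)),
      error = function(e) {
        ## a response with no spread leaves no support vectors; fall back
        ## to the trivial constant predictor
        if (grepl("empty", conditionMessage(e), ignore.case = TRUE))
          structure(list(value = mean(psi)), class = "constant_predictor")
        else stop(e)
      }),
    rf = with_seed(spec$seed,
                   randomForest::randomForest(x = features, y = psi,
                                              ntree = spec$n_trees)),
    ann = mlp_fit(features, psi, hidden = spec$ann_hidden,
                  epochs = spec$ann_epochs, seed = spec$seed))
  structure(list(spec = spec, fit = fit, n_features = ncol(features)),
            class = "doa_baseline")
}

#' Predict PSI from a fitted baseline
#'
#' Predictions are clipped to \[0, 100\] for parity with the bounded output
#' of the deep model when binning into anesthetized states.
#'
#' @param object a `"doa_baseline"`.
#' @param newdata `N x 14` standardized feature matrix.
#' @param ... unused.
#' @return numeric PSI predictions in \[0, 100\].
#' @export
predict.doa_baseline <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stop_if(ncol(newdata) != object$n_features, "expected ",
          object$n_features, " feature columns, got ", ncol(newdata))
  p <- switch(object$spec$kind,
    svr = if (inherits(object$fit, "constant_predictor"))
      rep(object$fit$value, nrow(newdata))
    else as.numeric(predict(object$fit, newdata)),
    rf = as.numeric(predict(object$fit, newdata)),
    ann = mlp_predict(object$fit, newdata))
  pmin(pmax(p, 0), 100)
}

#' @export
print.doa_baseline <- function(x, ...) {
  desc <- switch(x$spec$kind,
    svr = "support vector regression (RBF kernel)",
    rf = sprintf("random forest (%d trees)", x$spec$n_trees),
    ann = sprintf("multilayer perceptron (%s)",
                  paste(c(14, x$spec$ann_hidden, 1), collapse = "-")))
  cat("Baseline PSI regressor:", desc, "\n")
  invisible(x)
}

#' Layer widths of a fitted ANN baseline
#' @param model a `"doa_baseline"` of kind `"ann"`.
#' @return integer vector of layer sizes (input, hidden..., output).
#' @export
ann_layer_sizes <- function(model) {
  stopifnot(inherits(model, "doa_baseline"), model$spec$kind == "ann")
  model$fit$sizes
}
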