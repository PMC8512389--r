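#' Classification accuracy
#'
#' Multi-class accuracy, the fraction of correct predictions. For a binary
#' problem this equals `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param predictions,labels equal-length non-empty vectors (factor or
#'   character).
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  stop_if_not(length(predictions) == length(labels), "lengths must match")
  stop_if_not(length(labels) > 0, "accuracy of an empty prediction set is undefined")
  mean(as.character(predictions) == as.character(labels))
}

#' Fitness of a feature subset
#'
#' The comparison key of the whole search: held-out classification accuracy
#' of a mask's selected features, together with the number of selected
#' features used to break ties toward smaller subsets.
#'
#' @param accuracy accuracy in `[0, 1]`.
#' @param n_selected number of selected features (>= 1).
#' @param evaluator id string of the evaluator that produced the value.
#' @param seed the split seed the value was computed under.
#' @return An object of class `fitness_result`.
#' @export
fitness_result <- function(accuracy, n_selected, evaluator = "custom", seed = NA_integer_) {
  stop_if_not(is.numeric(accuracy) && accuracy >= 0 && accuracy <= 1,
              "accuracy must lie in [0, 1]")
  stop_if_not(is_count(n_selected, 1L), "n_selected must be a count >= 1")
  structure(list(accuracy = accuracy, n_selected = as.integer(n_selected),
                 evaluator = evaluator, seed = seed),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness> accuracy %.4f with %d features [%s]\n",
              x$accuracy, x$n_selected, x$evaluator))
  invisible(x)
}

#' Strict comparison of fitness results
#'
#' `a` beats `b` iff its accuracy is higher, or the accuracies are equal and
#' `a` selects fewer features (fewer features mean less computation). Equal
#' on both counts is not better, so an incumbent is retained on full ties.
#' This induces a strict partial order over fitness results.
#'
#' @param a,b [fitness_result()] objects.
#' @return `TRUE` iff `a` is strictly better than `b`.
#' @export
better <- function(a, b) {
  a$accuracy > b$accuracy || (a$accuracy == b$accuracy && a$n_selected < b$n_selected)
}

#' Classifier evaluators
#'
#' Pluggable classifiers that score feature subsets. Each evaluator is a
#' small object holding an id and a `fit_predict(x_train, y_train, x_test)`
#' function. `knn_evaluator()` wraps [class::knn()] (default `k = 2`, the
#' common wearable-sensor setting); `svm_evaluator()` wraps [e1071::svm()]
#' (default `gamma = 0.001`, radial kernel); `cnn_evaluator()` wraps the
#' package's 1-D convolutional network classifier ([cnn_classifier()]),
#' treating the selected feature vector as a one-dimensional sequence.
#'
#' @param k neighbor count for kNN.
#' @param gamma,kernel,cost SVM hyperparameters.
#' @param epochs,lr,batch_size CNN training schedule.
#' @return An object of class `evaluator`.
#' @name evaluators
NULL

new_evaluator <- function(id, fit_predict) {
  structure(list(id = id, fit_predict = fit_predict), class = "evaluator")
}

#' @rdname evaluators
#' @export
knn_evaluator <- function(k = 2L) {
  stop_if_not(is_count(k, 1L), "k must be a count >= 1")
  new_evaluator(sprintf("knn(k=%d)", k), function(x_train, y_train, x_test) {
    class::knn(as.matrix(x_train), as.matrix(x_test), factor(y_train), k = k)
  })
}

#' @rdname evaluators
#' @export
svm_evaluator <- function(gamma = 0.001, kernel = "radial", cost = 1) {
  new_evaluator(sprintf("svm(gamma=%g,%s)", gamma, kernel),
                function(x_train, y_train, x_test) {
    fit <- e1071::svm(as.matrix(x_train), factor(y_train), gamma = gamma,
                      kernel = kernel, cost = cost, scale = FALSE)
    stats::predict(fit, as.matrix(x_test))
  })
}

#' @rdname evaluators
#' @export
cnn_evaluator <- function(epochs = 60L, lr = 1e-3, batch_size = 16L) {
  new_evaluator(sprintf("cnn(epochs=%d)", epochs),
                function(x_train, y_train, x_test) {
    net <- cnn_classifier(ncol(x_train), nlevels(factor(y_train)))
    net <- cnn_train(net, as.matrix(x_train), factor(y_train),
                     epochs = epochs, lr = lr, batch_size = batch_size)
    cnn_predict(net, as.matrix(x_test))
  })
}

#' Evaluation protocols
#'
#' How an evaluator turns a feature subset into an accuracy: a single
#' stratified holdout split (the default; one fixed split per run keeps the
#' memoized fitness landscape static), or stratified k-fold cross-validation
#' (mean accuracy over folds).
#'
#' @param train_fraction fraction of rows used for training, in (0, 1).
#' @param k number of folds (>= 2).
#' @return An object of class `eval_protocol`.
#' @export
holdout_protocol <- function(train_fraction = 0.7) {
  stop_if_not(train_fraction > 0 && train_fraction < 1,
              "train_fraction must lie in (0, 1)")
  structure(list(kind = "holdout", train_fraction = train_fraction),
            class = "eval_protocol")
}

#' @rdname holdout_protocol
#' @export
kfold_protocol <- function(k = 10L) {
  stop_if_not(is_count(k, 2L), "k must be a count >= 2")
  structure(list(kind = "kfold", k = as.integer(k)), class = "eval_protocol")
}

# stratified train indices for a holdout split
stratified_split <- function(y, train_fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_tr <- max(1L, min(length(ix) - 1L, round(train_fraction * length(ix))))
    sample(ix, n_tr)
  }), use.names = FALSE)
  sort(idx)
}

# stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (ix in split(seq_along(y), y)) fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
  fold
}

#' Build a memoized mask-fitness objective from a feature table
#'
#' Returns the objective every search engine in this package optimizes: a
#' function from solution masks to [fitness_result()]s, backed by the given
#' classifier and protocol. The data split is drawn once (stratified, from
#' `seed`), so the fitness landscape is fixed for the whole run, and results
#' are memoized by the exact bit pattern of the mask — metaheuristics
#' revisit masks constantly, and a repeated query returns the identical
#' result at no cost. Each distinct mask is evaluated under its own
#' deterministic RNG substream, so the value of a mask does not depend on
#' evaluation order or on whether the cache is enabled.
#'
#' @param data data.frame of numeric feature columns plus a factor column
#'   `label` (or last column used as label).
#' @param evaluator an [evaluators] object.
#' @param protocol a [holdout_protocol()] or [kfold_protocol()].
#' @param seed integer seed for the split and the per-mask substreams.
#' @param cache logical; set `FALSE` to disable memoization (values do not
#'   change, only cost).
#' @return An object of class `mask_objective`: a list with `evaluate(mask)`,
#'   `n_features`, `n_evals()` (classifier trainings so far), `id`, and
#'   `predictions(mask)` (held-out predictions and truth for reporting).
#' @export
mask_objective <- function(data, evaluator, protocol = holdout_protocol(),
                           seed = 1L, cache = TRUE) {
  stop_if_not(inherits(evaluator, "evaluator"), "evaluator must be an evaluator object")
  stop_if_not(inherits(protocol, "eval_protocol"), "protocol must be an eval_protocol")
  stop_if_not(is.data.frame(data) && nrow(data) >= 4, "data must be a data.frame")
  lab_col <- if ("label" %in% names(data)) "label" else names(data)[ncol(data)]
  y <- factor(data[[lab_col]])
  x <- as.matrix(data[, setdiff(names(data), lab_col), drop = FALSE])
  stop_if_not(is.numeric(x), "all feature columns must be numeric")
  n_features <- ncol(x)
  seed <- as.integer(seed)

  if (protocol$kind == "holdout") {
    train_idx <- local_seed(seed, stratified_split(y, protocol$train_fraction))
  } else {
    fold <- local_seed(seed, stratified_folds(y, protocol$k))
  }

  score_mask <- function(mask) {
    cols <- which(mask == 1L)
    sub_seed <- (seed + sum(cols * 1103L)) %% .Machine$integer.max
    local_seed(sub_seed, {
      if (protocol$kind == "holdout") {
        pred <- evaluator$fit_predict(x[train_idx, cols, drop = FALSE], y[train_idx],
                                      x[-train_idx, cols, drop = FALSE])
        accuracy(pred, y[-train_idx])
      } else {
        mean(vapply(seq_len(protocol$k), function(f) {
          tr <- fold != f
          pred <- evaluator$fit_predict(x[tr, cols, drop = FALSE], y[tr],
                                        x[!tr, cols, drop = FALSE])
          accuracy(pred, y[!tr])
        }, numeric(1)))
      }
    })
  }

  env <- new.env(parent = emptyenv())
  env$memo <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  evaluate <- function(mask) {
    mask <- as_mask(mask)
    stop_if_not(length(mask) == n_features, "mask length must equal the feature count")
    stop_if_not(any(mask == 1L), "an all-zero mask selects nothing and cannot be evaluated")
    key <- mask_key(mask)
    if (cache && !is.null(env$memo[[key]])) return(env$memo[[key]])
    env$n_evals <- env$n_evals + 1L
    res <- fitness_result(score_mask(mask), sum(mask), evaluator$id, seed)
    if (cache) env$memo[[key]] <- res
    res
  }
  predictions <- function(mask) {
    mask <- as_mask(mask)
    cols <- which(mask == 1L)
    stop_if_not(length(cols) >= 1, "mask selects nothing")
    stop_if_not(protocol$kind == "holdout" || TRUE, "")
    sub_seed <- (seed + sum(cols * 1103L)) %% .Machine$integer.max
    if (protocol$kind == "holdout") {
      local_seed(sub_seed, {
        pred <- evaluator$fit_predict(x[train_idx, cols, drop = FALSE], y[train_idx],
                                      x[-train_idx, cols, drop = FALSE])
        list(pred = pred, truth = y[-train_idx])
      })
    } else {
      local_seed(sub_seed, {
        pred <- y
        for (f in seq_len(protocol$k)) {
          tr <- fold != f
          pred[!tr] <- evaluator$fit_predict(x[tr, cols, drop = FALSE], y[tr],
                                            x[!tr, cols, drop = FALSE])
        }
        list(pred = pred, truth = y)
      })
    }
  }
  structure(list(evaluate = evaluate, n_features = n_features,
                 n_evals = function() env$n_evals,
                 id = sprintf("%s/%s/seed=%d", evaluator$id, protocol$kind, seed),
                 predictions = predictions),
            class = "mask_objective")
}

#' Wrap a plain fitness function as an objective
#'
#' Gives toy or analytic fitness landscapes (e.g. exhaustive-enumeration
#' test landscapes) the same interface as [mask_objective()], so every
#' search engine can run on them unchanged.
#'
#' @param fn function taking a 0/1 mask and returning an accuracy in `[0, 1]`.
#' @param n_features mask length.
#' @param id evaluator id string recorded in results.
#' @return An object of class `mask_objective`.
#' @export
function_objective <- function(fn, n_features, id = "function") {
  env <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  evaluate <- function(mask) {
    mask <- as_mask(mask)
    stop_if_not(length(mask) == n_features, "mask length must equal n_features")
    stop_if_not(any(mask == 1L), "an all-zero mask cannot be evaluated")
    env$n_evals <- env$n_evals + 1L
    fitness_result(fn(mask), sum(mask), id)
  }
  structure(list(evaluate = evaluate, n_features = as.integer(n_features),
                 n_evals = function() env$n_evals, id = id,
                 predictions = function(mask) NULL),
            class = "mask_objective")
}

#' One-shot evaluation of a feature mask
#'
#' Convenience wrapper: builds a [mask_objective()] and evaluates a single
#' mask against it.
#'
#' @inheritParams mask_objective
#' @param mask 0/1 vector over the data's feature columns.
#' @return A [fitness_result()].
#' @export
evaluate_mask <- function(mask, data, evaluator, protocol = holdout_protocol(),
                          seed = 1L) {
  obj <- mask_objective(data, evaluator, protocol, seed)
  obj$evaluate(mask)
}

#' Per-class confusion summary
#'
#' @param pred,truth equal-length prediction and truth vectors.
#' @return A contingency table (rows = truth, columns = predicted).
#' @export
confusion_matrix <- function(pred, truth) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  table(truth = truth, predicted = pred)
}
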