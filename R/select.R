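#' Select a feature subset with a wrapper metaheuristic
#'
#' The package's front door. Fits a feature selector to a labeled feature
#' table by searching the space of binary feature masks with one of the
#' implemented algorithms, scoring candidate masks by held-out accuracy of
#' the chosen classifier (ties broken toward fewer features):
#'
#' * `"baroque"` — the hybrid: bee-swarm outer search with the multi-agent
#'   deep-Q local search (the default),
#' * `"bso"` — bee-swarm search with hill-climbing local search,
#' * `"qbso"` — bee-swarm search with tabular Q-learning local search,
#' * `"dqn"` — the deep-Q local search alone, no swarm,
#' * `"ga"`, `"bpso"`, `"aco"` — genetic-algorithm, binary particle-swarm
#'   and ant-colony comparators.
#'
#' @param x data.frame or matrix of numeric features (one row per window),
#'   or a data.frame containing a `label` column if `y` is missing.
#' @param y class labels (factor); taken from `x$label` when `NULL`.
#' @param method search algorithm, see above.
#' @param evaluator an [evaluators] object scoring candidate subsets.
#' @param protocol a [holdout_protocol()] or [kfold_protocol()].
#' @param seed integer seed; the fit is deterministic given it.
#' @param control a config object matching the method ([bso_config()],
#'   [ga_config()], [bpso_config()] or [aco_config()]); defaults are the
#'   published settings. Its `seed` is overridden by `seed`.
#' @return An object of class `feat_select` (also `fs_run`) with components
#'   `best_mask`, `best_fitness`, `history`, `selected` (column indices),
#'   `feature_names`, `confusion` (held-out confusion matrix of the best
#'   mask) and the training data for [predict.feat_select()].
#' @examples
#' \donttest{
#' tab <- sim_feature_table(planted_spec(120, 3, 5, 0, 15, effect_size = 2, seed = 1))
#' fit <- select_features(tab$data, method = "baroque", seed = 1,
#'                        control = bso_config(max_iter = 5))
#' print(fit)
#' }
#' @export
select_features <- function(x, y = NULL,
                            method = c("baroque", "bso", "qbso", "dqn",
                                       "ga", "bpso", "aco"),
                            evaluator = knn_evaluator(),
                            protocol = holdout_protocol(),
                            seed = 1L, control = NULL) {
  method <- match.arg(method)
  if (is.null(y)) {
    stop_if_not(is.data.frame(x) && "label" %in% names(x),
                "y is missing and x has no 'label' column")
    data <- x
  } else {
    data <- as.data.frame(x)
    data$label <- factor(y)
  }
  obj <- mask_objective(data, evaluator, protocol, seed = seed)
  run <- run_engine(method, obj, seed, control)
  feature_names <- setdiff(names(data), "label")
  run$selected <- which(run$best_mask == 1L)
  run$feature_names <- feature_names
  pr <- obj$predictions(run$best_mask)
  run$confusion <- if (!is.null(pr)) confusion_matrix(pr$pred, pr$truth)
  run$data <- data
  run$evaluator <- evaluator
  run$seed <- seed
  class(run) <- c("feat_select", class(run))
  run
}

run_engine <- function(method, obj, seed, control) {
  if (method %in% c("baroque", "bso", "qbso", "dqn")) {
    cfg <- if (is.null(control)) bso_config() else control
    stop_if_not(inherits(cfg, "bso_config"), "control must be a bso_config for %s", method)
    cfg$seed <- as.integer(seed)
    cfg$local_search <- switch(method, baroque = "deep-q", qbso = "tabular-q",
                               bso = "hill", dqn = "deep-q")
    if (cfg$local_search == "tabular-q") cfg$qlearn$mode <- "tabular"
    if (cfg$local_search == "deep-q") cfg$qlearn$mode <- "deep"
    if (method == "dqn") run_dqn(obj, cfg) else run_bso(obj, cfg)
  } else if (method == "ga") {
    cfg <- if (is.null(control)) ga_config() else control
    stop_if_not(inherits(cfg, "ga_config"), "control must be a ga_config")
    cfg$seed <- as.integer(seed)
    run_ga(obj, cfg)
  } else if (method == "bpso") {
    cfg <- if (is.null(control)) bpso_config() else control
    stop_if_not(inherits(cfg, "bpso_config"), "control must be a bpso_config")
    cfg$seed <- as.integer(seed)
    run_bpso(obj, cfg)
  } else {
    cfg <- if (is.null(control)) aco_config() else control
    stop_if_not(inherits(cfg, "aco_config"), "control must be an aco_config")
    cfg$seed <- as.integer(seed)
    run_aco(obj, cfg)
  }
}

#' @export
print.fs_run <- function(x, ...) {
  cat(sprintf("<%s run> best fitness %.4f with %d/%d features (%d evaluations)\n",
              x$method, x$best_fitness$accuracy, x$best_fitness$n_selected,
              length(x$best_mask), x$n_evals))
  invisible(x)
}

#' @export
print.feat_select <- function(x, ...) {
  cat(sprintf("Feature selection by '%s' (%s)\n", x$method, x$objective_id))
  cat(sprintf("  %d of %d features selected, held-out accuracy %.4f\n",
              length(x$selected), length(x$best_mask), x$best_fitness$accuracy))
  cat(sprintf("  %d classifier evaluations over %d recorded iterations\n",
              x$n_evals, nrow(x$history)))
  invisible(x)
}

#' @export
summary.feat_select <- function(object, ...) {
  cat(sprintf("Feature selection by '%s'\n\n", object$method))
  cat(sprintf("Best held-out accuracy: %.4f using %d of %d features\n",
              object$best_fitness$accuracy, length(object$selected),
              length(object$best_mask)))
  cat("Selected features (0-based indices):\n  ")
  cat(paste(object$selected - 1L, collapse = ","), "\n")
  if (!is.null(object$feature_names))
    cat("Selected feature names:\n  ",
        paste(object$feature_names[object$selected], collapse = ", "), "\n")
  if (!is.null(object$confusion)) {
    cat("\nHeld-out confusion matrix of the selected subset:\n")
    print(object$confusion)
  }
  invisible(object)
}

#' Convergence plot of a search run
#'
#' Best-so-far held-out accuracy against cumulative classifier evaluations.
#'
#' @param x an `fs_run` or `feat_select` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fs_run <- function(x, ...) {
  h <- x$history
  graphics::plot(h$n_evaluations, h$best_fitness, type = "s",
                 xlab = "classifier evaluations", ylab = "best accuracy",
                 main = sprintf("%s convergence", x$method), ...)
  invisible(x)
}

#' Predict activity labels from a fitted feature selector
#'
#' Trains the fit's evaluator on the full training data restricted to the
#' selected columns and predicts the new rows.
#'
#' @param object a [select_features()] fit.
#' @param newdata data.frame or matrix with the training feature columns.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.feat_select <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  cols <- object$feature_names[object$selected]
  stop_if_not(all(cols %in% names(newdata)),
              "newdata lacks selected feature columns")
  x_tr <- as.matrix(object$data[, cols, drop = FALSE])
  y_tr <- factor(object$data$label)
  local_seed(object$seed, {
    object$evaluator$fit_predict(x_tr, y_tr, as.matrix(newdata[, cols, drop = FALSE]))
  })
}

#' Selected feature indices of a fit
#'
#' @param object a `feat_select` or `fs_run` object.
#' @param zero_based report 0-based indices (the convention used in run
#'   reports and printed subset tables) instead of R's 1-based ones.
#' @return Integer vector of selected feature indices, sorted ascending.
#' @export
selected_features <- function(object, zero_based = FALSE) {
  ix <- which(object$best_mask == 1L)
  if (zero_based) ix - 1L else ix
}

#' Run several search algorithms on one dataset
#'
#' Budget-matched side-by-side comparison: every algorithm gets its own
#' objective (same data, evaluator, protocol and split seed, so an identical
#' fitness landscape) and stops after `eval_budget` classifier evaluations.
#'
#' @inheritParams select_features
#' @param methods character vector of methods (see [select_features()]).
#' @param eval_budget classifier evaluations allowed per method.
#' @param seed integer seed shared by all methods.
#' @return A list with `table` (data.frame: method, accuracy, n_selected,
#'   n_evaluations) and `runs` (named list of `fs_run` objects).
#' @export
compare_methods <- function(x, y = NULL,
                            methods = c("baroque", "bso", "dqn"),
                            evaluator = knn_evaluator(),
                            protocol = holdout_protocol(),
                            eval_budget = 500L, seed = 1L) {
  if (is.null(y)) { data <- x } else { data <- as.data.frame(x); data$label <- factor(y) }
  runs <- list()
  for (m in methods) {
    obj <- mask_objective(data, evaluator, protocol, seed = seed)
    # every method gets the same evaluation allowance; the iteration caps
    # are generous enough that the allowance is the binding constraint for
    # the population methods, while the learning methods also stop once
    # their step schedule is exhausted
    cfg <- if (m %in% c("baroque", "bso", "qbso", "dqn")) {
      bso_config(max_iter = 60L, eval_budget = eval_budget, seed = seed)
    } else if (m == "ga") {
      ga_config(generations = 1000L, eval_budget = eval_budget, seed = seed)
    } else if (m == "bpso") {
      bpso_config(iterations = 1000L, eval_budget = eval_budget, seed = seed)
    } else {
      aco_config(iterations = 1000L, eval_budget = eval_budget, seed = seed)
    }
    runs[[m]] <- run_engine(m, obj, seed, cfg)
  }
  table <- do.call(rbind, lapply(runs, function(r) {
    data.frame(method = r$method, accuracy = r$best_fitness$accuracy,
               n_selected = r$best_fitness$n_selected, n_evaluations = r$n_evals)
  }))
  rownames(table) <- NULL
  list(table = table, runs = runs)
}
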