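# Cross-validated performance-index evaluation: AUROC / R^2 metrics, the
# index rescaling, the LOO-jackknife / fivefold-bootstrap protocol with a
# random-forest learner, and the correlation-based index for neural
# distance datasets.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with average-rank tie handling: the
#' probability that a random positive outranks a random negative, ties
#' counted one half.
#'
#' @param labels binary vector (0/1 or logical); both classes present.
#' @param scores numeric prediction scores, higher meaning more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; may be negative when predictions are worse than
#' the mean.
#'
#' @param y observed numeric values, not constant, length `>= 2`.
#' @param pred predicted values.
#' @return real `<= 1`.
#' @export
r_squared <- function(y, pred) {
  if (length(y) != length(pred)) stop("y/pred length mismatch")
  if (length(y) < 2) stop("need >= 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y")
  1 - sum((y - pred)^2) / ss_tot
}

#' Rescale a raw metric to the performance index
#'
#' Linear maps anchored so that 0 is random and 100 is perfect
#' performance: classification `(AUROC - 0.5) / 0.5 * 100`, regression
#' `R^2 * 100`. (A scale factor of 100 on the centered AUROC would put
#' perfect classification at 50, contradicting the 0/100 anchors; the
#' anchors win.)
#'
#' @param metric raw metric value; AUROC must lie in `[0, 1]`.
#' @param task `"classification"` or `"regression"`.
#' @return performance index (`<= 100`).
#' @export
to_performance_index <- function(metric, task = c("classification",
                                                  "regression")) {
  task <- match.arg(task)
  if (task == "classification") {
    if (metric < 0 || metric > 1) {
      stop("AUROC out of [0, 1]: ", metric)
    }
    (metric - 0.5) * 200
  } else {
    metric * 100
  }
}

#' Evaluation dataset
#'
#' @param keys molecule keys.
#' @param targets numeric matrix (molecule x target); classification
#'   targets must be binary with both classes present.
#' @param task `"classification"` or `"regression"`.
#' @param name dataset name.
#' @return object of class `eval_dataset`.
#' @export
eval_dataset <- function(keys, targets, task = c("classification",
                                                 "regression"),
                         name = "dataset") {
  task <- match.arg(task)
  targets <- as.matrix(targets)
  if (is.null(colnames(targets))) {
    colnames(targets) <- paste0("target_", seq_len(ncol(targets)))
  }
  if (nrow(targets) != length(keys)) stop("keys/targets size mismatch")
  if (task == "classification") {
    for (j in seq_len(ncol(targets))) {
      v <- targets[, j]
      if (!all(v %in% c(0, 1))) {
        stop("classification target ", colnames(targets)[j],
             " is not binary")
      }
      if (length(unique(v)) < 2) {
        stop("classification target ", colnames(targets)[j],
             " has a single class")
      }
    }
  }
  structure(list(keys = keys, targets = targets, task = task, name = name),
            class = "eval_dataset")
}

#' Evaluation protocol
#'
#' Leave-one-out with jackknife-resampled training sets for datasets of
#' size `N <= 200`, fivefold cross-validation with bootstrap-resampled
#' training sets otherwise (`split = "auto"`).
#'
#' @param split `"auto"`, `"loo"` or `"fivefold"`.
#' @param seeds integer vector of model/resampling seeds (one full
#'   evaluation per seed).
#' @param resample `"auto"` (jackknife under LOO, bootstrap under
#'   fivefold), `"jackknife"`, `"bootstrap"` or `"none"`.
#' @param model_grid list of hyperparameter settings scanned; the best
#'   setting by mean index is reported.
#' @return object of class `eval_protocol`.
#' @export
eval_protocol <- function(split = c("auto", "loo", "fivefold"),
                          seeds = 1:5,
                          resample = c("auto", "jackknife", "bootstrap",
                                       "none"),
                          model_grid = default_model_grid()) {
  structure(list(split = match.arg(split), seeds = seeds,
                 resample = match.arg(resample), model_grid = model_grid),
            class = "eval_protocol")
}

#' Default random-forest hyperparameter grid
#'
#' A small grid over the forest hyperparameters worth scanning (tree
#' count, features per split, minimum node size); extend or replace it via
#' [eval_protocol()].
#'
#' @return list of named hyperparameter lists.
#' @export
default_model_grid <- function() {
  list(list(num_trees = 200, mtry = NULL, min_node_size = NULL))
}

#' Random-forest model factory
#'
#' Wraps [ranger::ranger()] behind the fit/predict interface
#' [evaluate_dataset()] expects. Classification fits a probability forest
#' and scores with the positive-class probability; a degenerate
#' single-class training set yields that class's constant score.
#'
#' @param params named hyperparameter list (`num_trees`, `mtry`,
#'   `min_node_size`, `class_weights`).
#' @return list with functions `fit(x, y, task, seed)` and
#'   `predict(fit, x)`.
#' @export
ranger_model <- function(params = list()) {
  num_trees <- params$num_trees %||% 200
  list(
    fit = function(x, y, task, seed) {
      df <- as.data.frame(x)
      if (task == "classification" && length(unique(y)) < 2) {
        return(list(constant = unique(y)[1]))
      }
      if (task == "classification") {
        df$.y <- factor(y, levels = c(0, 1))
        fit <- ranger::ranger(
          dependent.variable.name = ".y", data = df,
          num.trees = num_trees, mtry = params$mtry,
          min.node.size = params$min_node_size,
          class.weights = params$class_weights,
          probability = TRUE, seed = seed, num.threads = 1)
      } else {
        df$.y <- y
        fit <- ranger::ranger(
          dependent.variable.name = ".y", data = df,
          num.trees = num_trees, mtry = params$mtry,
          min.node.size = params$min_node_size,
          seed = seed, num.threads = 1)
      }
      list(model = fit, task = task)
    },
    predict = function(fit, x) {
      if (!is.null(fit$constant)) return(rep(fit$constant, nrow(x)))
      pr <- stats::predict(fit$model, data = as.data.frame(x),
                           num.threads = 1)$predictions
      if (fit$task == "classification") pr[, "1"] else pr
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pooled held-out predictions for one seed under one hyperparameter set.
# Under LOO classification the jackknife deletion is stratified: a random
# training point of the class OPPOSITE the held-out sample is removed, so
# the training class counts are identical whichever class is held out
# (pooled LOO predictions are otherwise biased against the held-out
# class by the prior shift).
.cv_predictions <- function(x, targets, task, split, resample, seed,
                            model) {
  n <- nrow(x)
  preds <- matrix(NA_real_, n, ncol(targets))
  .with_seed(seed, {
    if (split == "loo") {
      for (i in seq_len(n)) {
        base_train <- setdiff(seq_len(n), i)
        for (j in seq_len(ncol(targets))) {
          train <- base_train
          if (resample == "jackknife" && length(train) > 2) {
            pool <- if (task == "classification") {
              which(targets[train, j] != targets[i, j])
            } else {
              seq_along(train)
            }
            if (!length(pool)) pool <- seq_along(train)
            train <- train[-pool[sample.int(length(pool), 1)]]
          } else if (resample == "bootstrap") {
            train <- train[sample.int(length(train), length(train),
                                      replace = TRUE)]
          }
          fit <- model$fit(x[train, , drop = FALSE], targets[train, j],
                           task, seed)
          preds[i, j] <- model$predict(fit, x[i, , drop = FALSE])
        }
      }
    } else {
      folds <- sample(rep(seq_len(5), length.out = n))
      for (f in seq_len(5)) {
        test <- which(folds == f)
        train <- which(folds != f)
        if (resample == "bootstrap") {
          train <- train[sample.int(length(train), length(train),
                                    replace = TRUE)]
        } else if (resample == "jackknife" && length(train) > 2) {
          train <- train[-sample.int(length(train), 1)]
        }
        for (j in seq_len(ncol(targets))) {
          fit <- model$fit(x[train, , drop = FALSE], targets[train, j],
                           task, seed)
          preds[test, j] <- model$predict(fit, x[test, , drop = FALSE])
        }
      }
    }
  })
  preds
}

#' Cross-validated performance index of a representation on a dataset
#'
#' Implements the evaluation protocol: leave-one-out (with per-seed
#' jackknife resampling of the training points) for `N <= 200`, fivefold
#' cross-validation (with per-seed bootstrap resampling) otherwise. For
#' each seed, held-out predictions are pooled, the raw metric (AUROC or
#' R^2) is computed per target, rescaled to the performance index and
#' averaged over targets; the reported index is the across-seed mean and
#' `sd_across_seeds` its SD. Every entry of the protocol's hyperparameter
#' grid is evaluated with the same seeds and the best entry is reported.
#'
#' @param ds an [eval_dataset()].
#' @param table a `representation_table` featurizing every dataset key.
#' @param proto an [eval_protocol()].
#' @param model_factory function taking one hyperparameter list and
#'   returning a fit/predict pair; default [ranger_model()].
#' @return object of class `performance_result`: `dataset`,
#'   `representation`, `index`, `sd_across_seeds`, `per_seed`,
#'   `raw_metric` (per target, best grid entry, averaged over seeds),
#'   `best_params`, `split`.
#' @export
evaluate_dataset <- function(ds, table, proto = eval_protocol(),
                             model_factory = ranger_model) {
  stopifnot(inherits(ds, "eval_dataset"),
            inherits(table, "representation_table"))
  absent <- setdiff(ds$keys, rownames(table$vectors))
  if (length(absent)) {
    stop("key(s) not featurized: ", paste(absent, collapse = ", "))
  }
  x <- table$vectors[ds$keys, , drop = FALSE]
  n <- length(ds$keys)
  split <- proto$split
  if (split == "auto") split <- if (n <= 200) "loo" else "fivefold"
  if (split == "fivefold" && n < 5) stop("fivefold needs N >= 5")
  resample <- proto$resample
  if (resample == "auto") {
    resample <- if (split == "loo") "jackknife" else "bootstrap"
  }

  best <- NULL
  for (params in proto$model_grid) {
    model <- model_factory(params)
    per_seed <- numeric(length(proto$seeds))
    raw <- matrix(NA_real_, length(proto$seeds), ncol(ds$targets))
    for (s in seq_along(proto$seeds)) {
      preds <- .cv_predictions(x, ds$targets, ds$task, split, resample,
                               proto$seeds[s], model)
      metr <- vapply(seq_len(ncol(ds$targets)), function(j) {
        if (ds$task == "classification") {
          auroc(ds$targets[, j], preds[, j])
        } else {
          r_squared(ds$targets[, j], preds[, j])
        }
      }, numeric(1))
      raw[s, ] <- metr
      per_seed[s] <- mean(vapply(metr, to_performance_index,
                                 numeric(1), task = ds$task))
    }
    cand <- list(index = mean(per_seed),
                 sd_across_seeds = stats::sd(per_seed),
                 per_seed = stats::setNames(per_seed, proto$seeds),
                 raw_metric = stats::setNames(colMeans(raw),
                                              colnames(ds$targets)),
                 best_params = params)
    if (is.null(best) || cand$index > best$index) best <- cand
  }
  structure(c(list(dataset = ds$name, representation = table$name,
                   split = split), best),
            class = "performance_result")
}

#' @export
print.performance_result <- function(x, ...) {
  cat(sprintf(
    "<performance_result> %s / %s (%s): index %.1f +/- %.1f (%d seeds)\n",
    x$dataset, x$representation, x$split, x$index, x$sd_across_seeds,
    length(x$per_seed)))
  invisible(x)
}

#' Per-seed performance-index difference between two representations
#'
#' @param a,b `performance_result`s for the same dataset evaluated under
#'   identical seed lists.
#' @return list with `mean`, `sd` and the per-seed `deltas` (`a - b`).
#' @export
representation_delta <- function(a, b) {
  if (!identical(a$dataset, b$dataset)) {
    stop("results come from different datasets")
  }
  if (!identical(names(a$per_seed), names(b$per_seed))) {
    stop("seed lists are not aligned")
  }
  d <- a$per_seed - b$per_seed
  list(mean = mean(d), sd = stats::sd(d), deltas = d)
}

#' Correlation-based performance index for neural distance data
#'
#' Per experimental condition: center the activity matrix per neuron and
#' compute odorant-pair correlation distances; center the representation
#' per feature dimension and compute the molecular correlation distances
#' of the same odorant pairs; correlate the two distance vectors (Pearson).
#' The index is the across-condition mean correlation rescaled by 100
#' (0 = uncorrelated, 100 = perfect).
#'
#' @param activity odorant x neuron numeric matrix (row/col names set).
#' @param tables list of `representation_table`s covering all odorants.
#' @param conditions named list of neuron-name vectors partitioning the
#'   columns; default one condition with every neuron.
#' @return named numeric vector: one index per representation, with
#'   attribute `per_condition` (representation x condition correlations).
#' @export
neural_distance_index <- function(activity, tables,
                                  conditions = list(all = colnames(activity))) {
  if (inherits(tables, "representation_table")) tables <- list(tables)
  activity <- as.matrix(activity)
  if (nrow(activity) < 3) stop("need >= 3 odorants")
  odorants <- rownames(activity)
  lower <- lower.tri(matrix(0, nrow(activity), nrow(activity)))
  neural_d <- lapply(conditions, function(neurons) {
    if (length(neurons) < 2) stop("condition needs >= 2 neurons")
    a <- center_rows(activity[, neurons, drop = FALSE])
    if (any(apply(a, 1, stats::sd) == 0)) {
      stop("constant odorant row(s) in activity")
    }
    (1 - stats::cor(t(a)))[lower]
  })
  per_cond <- vapply(tables, function(tab) {
    dm <- distance_matrix(tab, odorants)
    rep_d <- dm$values[lower]
    vapply(neural_d, function(nd) pearson_r(nd, rep_d), numeric(1))
  }, numeric(length(conditions)))
  per_cond <- matrix(per_cond, nrow = length(conditions),
                     dimnames = list(names(conditions),
                                     vapply(tables, `[[`, character(1),
                                            "name")))
  idx <- colMeans(per_cond) * 100
  attr(idx, "per_condition") <- per_cond
  idx
}
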