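#' Severity class from the MDS-UPDRS Part III score
#'
#' Healthy controls are their own class; PD subjects are binned by the
#' published cut-off scores: mild for scores up to 32, moderate for 33--58,
#' severe for 59 and above.
#'
#' @param group Character vector, `"PD"`/`"HC"`.
#' @param updrs3_score Non-negative integer scores.
#' @return Factor with levels `HC`, `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' label_updrs(c("HC", "PD", "PD", "PD"), c(10, 32, 33, 59))
label_updrs <- function(group, updrs3_score) {
  if (any(updrs3_score < 0, na.rm = TRUE)) abort("MDS-UPDRS scores must be >= 0")
  if (anyNA(updrs3_score)) abort("MDS-UPDRS score missing")
  out <- ifelse(group == "HC", "HC",
                ifelse(updrs3_score <= 32, "mild",
                       ifelse(updrs3_score <= 58, "moderate", "severe")))
  factor(out, levels = c("HC", "mild", "moderate", "severe"))
}

#' Hoehn & Yahr class
#'
#' Healthy controls are assigned stage 0 (the H&Y examination is not
#' administered to them); PD subjects keep their stage 1--5, giving six
#' classes in total.
#'
#' @param group Character vector, `"PD"`/`"HC"`.
#' @param hy_stage Integer stages.
#' @return Factor with levels `0`--`5`.
#' @export
label_hy <- function(group, hy_stage) {
  if (any(group == "PD" & (is.na(hy_stage) | hy_stage < 1 | hy_stage > 5))) {
    abort("PD subjects must carry an H&Y stage in 1..5")
  }
  out <- ifelse(group == "HC", 0L, as.integer(hy_stage))
  factor(out, levels = 0:5)
}

#' Class labels for a feature table under a labelling scheme
#'
#' @param table A `pd_features` tibble (or any tibble with the label
#'   columns).
#' @param scheme `"pdhc"`, `"hy"` or `"updrs"`.
#' @return Factor of class labels.
#' @export
scheme_labels <- function(table, scheme = c("pdhc", "hy", "updrs")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         pdhc = factor(table$group, levels = c("HC", "PD")),
         hy = label_hy(table$group, table$hy_stage),
         updrs = label_updrs(table$group, table$updrs3_score))
}

#' Classification metrics with class-count weighting
#'
#' Accuracy is the fraction of correct predictions, \eqn{N_c / N_t}.
#' Precision, recall and F1 are computed per class and averaged with
#' weights equal to the number of test subjects per class,
#' \eqn{W = \sum_i w_i X_i / \sum_i w_i}, which is appropriate for the
#' highly imbalanced severity classes. Undefined per-class ratios (no
#' predictions for a class) are substituted with 0.
#'
#' @param truth,predicted Equal-length class vectors (factors or
#'   coercible).
#' @return One-row tibble with `accuracy`, `precision`, `recall`, `f1`;
#'   attribute `per_class` holds the per-class breakdown.
#' @export
#' @examples
#' evaluate_metrics(c("a", "a", "b"), c("a", "b", "b"))
evaluate_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  if (length(truth) == 0L) abort("empty prediction set")
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  cm <- table(truth, predicted)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- rowSums(cm)   # test subjects per class
  wsum <- function(x) sum(w * x) / sum(w)
  out <- tibble(accuracy = sum(tp) / length(truth),
                precision = wsum(prec), recall = wsum(rec), f1 = wsum(f1))
  attr(out, "per_class") <- tibble(class = lev, n = as.numeric(unname(w)),
                                   precision = unname(prec),
                                   recall = unname(rec), f1 = unname(f1))
  out
}

# Stratified holdout split; falls back to a simple random split when any
# class has a single member. Returns test-set indices.
holdout_split <- function(y, test_fraction) {
  n <- length(y)
  counts <- table(y)
  counts <- counts[counts > 0]
  if (any(counts == 1L)) {
    return(sample.int(n, max(1L, round(test_fraction * n))))
  }
  test <- integer(0)
  for (cl in names(counts)) {
    idx <- which(y == cl)
    k <- round(test_fraction * length(idx))
    if (k > 0L) test <- c(test, sample(idx, k))
  }
  if (!length(test)) test <- sample.int(n, 1L)
  sort(test)
}

# K-fold CV accuracy of one parameter setting on the training portion.
# Folds that cannot be fitted (e.g. a singleton class) are skipped.
cv_accuracy <- function(method, X, y, params, folds, seed) {
  accs <- c()
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(as.character(y[tr]))) < 2L || !any(!tr)) next
    acc <- tryCatch({
      fit <- fit_pd_model(method, X[tr, , drop = FALSE], y[tr], params, seed)
      prob <- predict_pd_model(fit, X[!tr, , drop = FALSE])
      pred <- predicted_classes(prob, levels(y))
      mean(pred == y[!tr])
    }, error = function(e) NA_real_)
    if (!is.na(acc)) accs <- c(accs, acc)
  }
  if (!length(accs)) return(NA_real_)
  mean(accs)
}

grid_search <- function(method, X, y, grid, n_folds = 5L, seed = 1) {
  if (nrow(grid) == 1L) return(as.list(grid[1L, ]))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), length(y)))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    cv_accuracy(method, X, y, as.list(grid[g, ]), folds, seed)
  }, numeric(1))
  if (all(is.na(scores))) return(as.list(grid[1L, ]))
  best <- which.max(scores)   # ties -> first grid row
  as.list(grid[best, ])
}

#' Run a repeated-holdout classification experiment
#'
#' Implements the evaluation protocol: for each repeat, a stratified 90/10
#' train/test split; hyperparameters chosen by grid search with inner
#' 5-fold cross-validation on the training portion only; the winning
#' configuration refitted on the whole training split; accuracy and
#' weighted precision/recall/F1 measured on the held-out 10%; finally the
#' per-metric mean and SD over repeats. Feature standardisation (for the
#' scaled model families) is fitted on the training split only.
#'
#' @param table A `pd_features` tibble.
#' @param scheme Labelling scheme: `"pdhc"`, `"hy"` or `"updrs"`.
#' @param models Model families to evaluate (subset of
#'   `c("linear_nn", "svm", "logistic", "random_forest", "xgboost")`).
#' @param n_repeats Number of split-train-test repeats.
#' @param test_fraction Held-out fraction.
#' @param grids Hyperparameter grids, as [default_grids()].
#' @param seed Root seed; repeat `r` uses a derived child seed, so two runs
#'   with the same seed (and the same subjects) produce identical splits
#'   regardless of which feature columns are supplied.
#' @param feature_subset Optional regular expression selecting feature
#'   columns (e.g. `"^task2_"` for the tapping-only ablation).
#' @return A `pd_experiment`: list with `summary` (model x metric means and
#'   SDs), `repeats` (per-repeat metrics), `scheme`, `config`.
#' @export
run_experiment <- function(table, scheme = c("pdhc", "hy", "updrs"),
                           models = model_families(),
                           n_repeats = 100, test_fraction = 0.1,
                           grids = default_grids(), seed = 1,
                           feature_subset = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  models <- match.arg(models, model_families(), several.ok = TRUE)
  y <- scheme_labels(table, scheme)
  feats <- feature_columns(table)
  if (!is.null(feature_subset)) {
    feats <- grep(feature_subset, feats, value = TRUE)
    if (!length(feats)) abort(sprintf("no features match '%s'", feature_subset))
  }
  X <- as.matrix(table[, feats])
  if (length(unique(as.character(y))) < 2L) {
    abort("experiment needs at least two classes present")
  }
  records <- list()
  splits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- as.integer(child_seed(seed, r) %% 2147483646) + 1L
    set.seed(rs)
    test <- holdout_split(as.character(y), test_fraction)
    splits[[r]] <- test
    tr_y <- y[-test]
    if (length(unique(as.character(tr_y))) < 2L) {
      warn(sprintf("repeat %d skipped: training split has < 2 classes", r))
      next
    }
    for (m in models) {
      met <- tryCatch({
        params <- grid_search(m, X[-test, , drop = FALSE], tr_y,
                              grids[[m]], seed = rs)
        fit <- fit_pd_model(m, X[-test, , drop = FALSE], tr_y, params,
                            seed = rs)
        prob <- predict_pd_model(fit, X[test, , drop = FALSE])
        pred <- predicted_classes(prob, levels(y))
        evaluate_metrics(y[test], pred)
      }, error = function(e) {
        warn(sprintf("repeat %d, model %s skipped: %s", r, m,
                     conditionMessage(e)))
        NULL
      })
      if (is.null(met)) next
      records[[length(records) + 1L]] <- dplyr::bind_cols(
        tibble(repeat_id = r, model = m), met)
    }
  }
  repeats <- dplyr::bind_rows(records)
  summary <- repeats |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(scheme = scheme, summary = summary, repeats = repeats,
                 splits = splits, models = models,
                 config = list(n_repeats = n_repeats,
                               test_fraction = test_fraction, seed = seed,
                               feature_subset = feature_subset,
                               features = feats)),
            class = "pd_experiment")
}

#' @export
print.pd_experiment <- function(x, ...) {
  cat(sprintf("<pd_experiment scheme=%s, %d repeat(s), %d model(s)>\n",
              x$scheme, x$config$n_repeats, length(x$models)))
  acc <- dplyr::filter(x$summary, .data$metric == "accuracy")
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-14s accuracy %.3f (SD %.3f)\n",
                acc$model[i], acc$mean[i], acc$sd[i]))
  }
  invisible(x)
}

#' Tidy a classification experiment
#'
#' @param x A `pd_experiment`.
#' @param ... Unused.
#' @return Tibble with `model`, `metric`, `mean`, `sd`, `se`.
#' @export
tidy.pd_experiment <- function(x, ...) x$summary

#' One-row summary of a classification experiment
#'
#' @param x A `pd_experiment`.
#' @param ... Unused.
#' @return Tibble with the scheme, best model by mean accuracy, its mean
#'   accuracy and SD, and the repeat count.
#' @export
glance.pd_experiment <- function(x, ...) {
  acc <- dplyr::filter(x$summary, .data$metric == "accuracy") |>
    dplyr::arrange(dplyr::desc(.data$mean), .data$model)
  tibble(scheme = x$scheme, best_model = acc$model[1],
         accuracy = acc$mean[1], accuracy_sd = acc$sd[1],
         n_repeats = x$config$n_repeats)
}

#' Results-table layout of an experiment
#'
#' Models by metrics, formatted as `mean (SD)`.
#'
#' @param x A `pd_experiment`.
#' @return Tibble with one row per model.
#' @export
results_table <- function(x) {
  stopifnot(inherits(x, "pd_experiment"))
  x$summary |>
    dplyr::mutate(cell = sprintf("%.3f (%.3f)", .data$mean, .data$sd)) |>
    dplyr::select("model", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell") |>
    dplyr::select("model", "accuracy", "precision", "recall", "f1")
}

#' Plot a classification experiment
#'
#' Mean metric per model with +/- 1 SD error bars.
#'
#' @param object A `pd_experiment`.
#' @param metric Metric to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_experiment <- function(object, metric = "accuracy", ...) {
  dat <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$model, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = pmin(.data$mean + .data$sd, 1)),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("%s classification", object$scheme)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
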