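#' Tapping-task-only ablation experiment
#'
#' Runs the repeated-holdout experiment twice — once with all features and
#' once restricted to the alternating-tapping-task features — using the
#' same seed, so both arms see identical split sequences. Comparing the two
#' arms quantifies how much of the classifiers' performance the single
#' tapping task carries.
#'
#' @param table A `pd_features` tibble; must contain task-2 features.
#' @param scheme Labelling scheme.
#' @param models Model families.
#' @param n_repeats Repeats per arm.
#' @param seed Shared seed for both arms.
#' @param task Ablation task id (default 2).
#' @param ... Passed on to [run_experiment()].
#' @return A `pd_ablation`: list with experiments `all` and `task_only`,
#'   and `comparison`, a tibble of per-model mean accuracy with standard
#'   error for both arms.
#' @export
ablation_experiment <- function(table, scheme = c("pdhc", "hy", "updrs"),
                                models = model_families(), n_repeats = 100,
                                seed = 1, task = 2L, ...) {
  scheme <- match.arg(scheme)
  pattern <- sprintf("^task%d_", task)
  if (!any(grepl(pattern, feature_columns(table)))) {
    abort(sprintf("feature table has no task-%d features", task))
  }
  all_exp <- run_experiment(table, scheme, models = models,
                            n_repeats = n_repeats, seed = seed, ...)
  task_exp <- run_experiment(table, scheme, models = models,
                             n_repeats = n_repeats, seed = seed,
                             feature_subset = pattern, ...)
  comparison <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(all_exp$summary, .data$metric == "accuracy"),
                  features = "all"),
    dplyr::mutate(dplyr::filter(task_exp$summary, .data$metric == "accuracy"),
                  features = sprintf("task%d_only", task))
  ) |>
    dplyr::select("model", "features", "mean", "sd", "se")
  structure(list(all = all_exp, task_only = task_exp,
                 comparison = comparison, scheme = scheme, task = task),
            class = "pd_ablation")
}

#' @export
print.pd_ablation <- function(x, ...) {
  cat(sprintf("<pd_ablation scheme=%s, task %d>\n", x$scheme, x$task))
  print(x$comparison, n = Inf)
  invisible(x)
}

#' Tidy an ablation result
#'
#' @param x A `pd_ablation`.
#' @param ... Unused.
#' @return The per-model accuracy comparison tibble.
#' @export
tidy.pd_ablation <- function(x, ...) x$comparison

#' Plot an ablation comparison
#'
#' Mean holdout accuracy with standard-error bars, all features vs
#' task-only features, per model.
#'
#' @param object A `pd_ablation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_ablation <- function(object, ...) {
  ggplot2::ggplot(object$comparison,
                  ggplot2::aes(x = .data$model, y = .data$mean,
                               fill = .data$features)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = pmin(.data$mean + .data$se, 1)),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean holdout accuracy", fill = NULL,
                  title = sprintf("%s: all features vs task-%d only",
                                  object$scheme, object$task)) +
    ggplot2::theme_minimal()
}
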