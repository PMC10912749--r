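#' Shapley-value attributions for a fitted classifier
#'
#' Computes, for every explained sample and class, the additive feature
#' attributions \eqn{\varphi_j} of the explanation model
#' \eqn{g(x') = \varphi_0 + \sum_{j=1}^{M} \varphi_j x'_j}, where
#' \eqn{x' \in \{0,1\}^M} indicates feature presence. "Absence" of a
#' feature is modelled by substituting its value from a background
#' reference (the cohort median vector by default).
#'
#' For `M <= exact_max` features the Shapley values are computed by exact
#' enumeration of all feature subsets. Beyond that, antithetic permutation
#' sampling is used: each sampled permutation is paired with its reverse,
#' and marginal contributions are accumulated along each permutation.
#' Because contributions telescope along a permutation, local accuracy
#' \eqn{\varphi_0 + \sum_j \varphi_j = f(x)} holds exactly for every
#' explained sample under both estimators.
#'
#' @param model A fitted `pd_model` (e.g. from [fit_best_model()]), which
#'   must expose per-class probability scores; or a plain function mapping a
#'   numeric matrix to a numeric vector or per-class score matrix.
#' @param X Numeric matrix (samples x features) to explain.
#' @param background Background reference: a single row (numeric vector) or
#'   matrix whose column medians are taken; default `NULL` uses the column
#'   medians of `X`.
#' @param n_perm Number of sampled permutations (rounded up to an even
#'   number; half are reverses of the other half).
#' @param exact_max Feature-count threshold for exact enumeration.
#' @param seed Seed for permutation sampling.
#' @return A `pd_attributions`: list with `phi` (array samples x features x
#'   classes), `base` (per-class base value \eqn{\varphi_0}), `features`,
#'   `classes`, `method`.
#' @export
shapley_attributions <- function(model, X, background = NULL,
                                 n_perm = 40, exact_max = 12, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  M <- ncol(X)
  feats <- colnames(X) %||% paste0("x", seq_len(M))
  if (is.null(background)) {
    background <- apply(X, 2L, stats::median)
  } else if (is.matrix(background)) {
    background <- apply(background, 2L, stats::median)
  }
  stopifnot(length(background) == M)
  f <- if (inherits(model, "pd_model")) {
    function(mat) {
      colnames(mat) <- feats
      predict_pd_model(model, mat)
    }
  } else if (is.function(model)) {
    function(mat) {
      colnames(mat) <- feats
      out <- model(mat)
      if (is.null(dim(out))) out <- matrix(out, ncol = 1L)
      out
    }
  } else {
    abort("model must be a fitted pd_model or a prediction function")
  }
  base <- f(matrix(background, nrow = 1L))[1L, ]
  classes <- if (inherits(model, "pd_model")) model$levels
             else colnames(f(X[1L, , drop = FALSE])) %||%
               paste0("output", seq_along(base))
  K <- length(base)
  n <- nrow(X)
  phi <- array(0, dim = c(n, M, K), dimnames = list(NULL, feats, classes))

  if (M <= exact_max) {
    # Exact: phi_j = sum_S w(|S|) [v(S u j) - v(S)] over subsets S not
    # containing j, with w(k) = k! (M-k-1)! / M!.
    n_sub <- 2L^M
    masks <- matrix(FALSE, n_sub, M)
    for (j in seq_len(M)) {
      masks[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0L
    }
    sizes <- rowSums(masks)
    lw <- lgamma(seq_len(M)) + lgamma(M - seq_len(M) + 1L) - lgamma(M + 1L)
    w_of_size <- exp(lw)  # w_of_size[k] = (k-1)!(M-k)!/M! -> weight for |S| = k-1
    for (i in seq_len(n) ) {
      rows <- matrix(background, n_sub, M, byrow = TRUE)
      rows[masks] <- matrix(X[i, ], n_sub, M, byrow = TRUE)[masks]
      vals <- f(rows)   # n_sub x K
      for (j in seq_len(M)) {
        on <- masks[, j]
        idx_off <- which(!on)
        idx_on <- idx_off + 2L^(j - 1L)
        wts <- w_of_size[sizes[idx_off] + 1L]
        for (k in seq_len(K)) {
          phi[i, j, k] <- sum(wts * (vals[idx_on, k] - vals[idx_off, k]))
        }
      }
    }
    method <- "exact"
  } else {
    n_perm <- 2L * ceiling(n_perm / 2L)
    set.seed(seed)
    perms <- vector("list", n_perm)
    for (p in seq_len(n_perm / 2L)) {
      pm <- sample.int(M)
      perms[[2L * p - 1L]] <- pm
      perms[[2L * p]] <- rev(pm)
    }
    for (pm in perms) {
      # Incremental rows: prefix k of the permutation switched on.
      rows <- matrix(background, n * (M + 1L), M, byrow = TRUE)
      for (k in seq_len(M)) {
        jset <- pm[seq_len(k)]
        block <- seq.int((k * n) + 1L, (k + 1L) * n)
        rows[block, ] <- rows[block - n, ]
        rows[block, pm[k]] <- X[, pm[k]]
      }
      vals <- f(rows)  # (n*(M+1)) x K
      for (k in seq_len(M)) {
        prev <- vals[seq.int((k - 1L) * n + 1L, k * n), , drop = FALSE]
        cur <- vals[seq.int(k * n + 1L, (k + 1L) * n), , drop = FALSE]
        phi[, pm[k], ] <- phi[, pm[k], ] + (cur - prev) / n_perm
      }
    }
    method <- "permutation"
  }
  structure(list(phi = phi, base = base, features = feats,
                 classes = classes, method = method),
            class = "pd_attributions")
}

#' @export
print.pd_attributions <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<pd_attributions %d sample(s) x %d feature(s) x %d class(es), %s>\n",
              d[1], d[2], d[3], x$method))
  invisible(x)
}

#' Tidy Shapley attributions
#'
#' @param x A `pd_attributions`.
#' @param ... Unused.
#' @return Tibble with `sample`, `feature`, `class`, `phi`.
#' @export
tidy.pd_attributions <- function(x, ...) {
  d <- dim(x$phi)
  tidyr::expand_grid(sample = seq_len(d[1]), feature = x$features,
                     class = x$classes) |>
    dplyr::mutate(phi = as.vector(aperm(x$phi, c(3L, 2L, 1L))))
}

#' Global feature importance from Shapley attributions
#'
#' The global importance of a feature for a class is the mean absolute
#' Shapley value over all explained samples. The overall ranking sums the
#' per-class values; ties are broken lexicographically by feature name.
#'
#' @param att A `pd_attributions`.
#' @return A `pd_importance`: list with `per_class` (feature, class,
#'   mean_abs_shap) and `overall` (feature, importance, rank).
#' @export
global_importance <- function(att) {
  stopifnot(inherits(att, "pd_attributions"))
  d <- dim(att$phi)
  if (d[1] < 1L) abort("no explained samples")
  m <- apply(abs(att$phi), c(2L, 3L), mean)   # features x classes
  per_class <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
    stats::setNames(c("feature", "class", "mean_abs_shap"))
  overall <- tibble(feature = att$features, importance = unname(rowSums(m))) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(per_class = per_class, overall = overall),
            class = "pd_importance")
}

#' @export
print.pd_importance <- function(x, ...) {
  cat("<pd_importance> top features:\n")
  print(utils::head(x$overall, 10L))
  invisible(x)
}

#' Task importance from global feature importance
#'
#' The importance of a task is the sum of the mean absolute Shapley values
#' of its features that appear among the global top-`k` features (top 10 by
#' default: the effect sizes beyond the tenth feature fall off quickly, and
#' unrestricted sums would favour tasks with many weak features over tasks
#' with a few strong ones). Tasks contributing no top-`k` feature score 0.
#'
#' @param gi A `pd_importance` from [global_importance()].
#' @param k Number of top features included.
#' @param tasks Task ids to report (default 1--11).
#' @return Tibble with `task`, `importance` and the per-class breakdown in
#'   the attribute `per_class`.
#' @export
task_importance <- function(gi, k = 10, tasks = 1:11) {
  stopifnot(inherits(gi, "pd_importance"))
  top <- utils::head(gi$overall, k)
  top$task <- feature_task_map(top$feature)
  by_task <- top |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(importance = sum(.data$importance), .groups = "drop")
  out <- tibble(task = as.integer(tasks)) |>
    dplyr::left_join(by_task, by = "task") |>
    dplyr::mutate(importance = ifelse(is.na(.data$importance), 0,
                                      .data$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$task)
  pc <- gi$per_class |>
    dplyr::filter(.data$feature %in% top$feature) |>
    dplyr::mutate(task = feature_task_map(.data$feature)) |>
    dplyr::group_by(.data$task, .data$class) |>
    dplyr::summarise(importance = sum(.data$mean_abs_shap), .groups = "drop")
  attr(out, "per_class") <- pc
  out
}

#' Refit the best model of an experiment on the full cohort
#'
#' Selects the model family with the highest mean holdout accuracy, chooses
#' its hyperparameters by 5-fold cross-validation on the full data, and
#' refits on all subjects. This is the model the importance analysis
#' explains.
#'
#' @param experiment A `pd_experiment`.
#' @param table The `pd_features` table the experiment was run on.
#' @param grids Hyperparameter grids.
#' @param seed Seed.
#' @return A fitted `pd_model` with attribute `"method"` set.
#' @export
fit_best_model <- function(experiment, table, grids = default_grids(),
                           seed = 1) {
  best <- glance.pd_experiment(experiment)$best_model
  y <- scheme_labels(table, experiment$scheme)
  feats <- experiment$config$features
  X <- as.matrix(table[, feats])
  params <- grid_search(best, X, y, grids[[best]], seed = seed)
  fit_pd_model(best, X, y, params, seed = seed)
}

#' Feature and task importance of an experiment
#'
#' Convenience wrapper: refits the experiment's best model on the full
#' cohort, computes Shapley attributions for every subject, and aggregates
#' them into global feature importance and top-`k` task importance.
#'
#' @param table The `pd_features` table.
#' @param experiment A `pd_experiment` run on `table`.
#' @param n_perm Permutations for the Shapley estimator.
#' @param k Top-feature count for task importance.
#' @param seed Seed.
#' @return List with `model`, `attributions`, `global` and `task`.
#' @export
explain_experiment <- function(table, experiment, n_perm = 40, k = 10,
                               seed = 1) {
  model <- fit_best_model(experiment, table, seed = seed)
  X <- as.matrix(table[, experiment$config$features])
  att <- shapley_attributions(model, X, n_perm = n_perm, seed = seed)
  gi <- global_importance(att)
  list(model = model, attributions = att, global = gi,
       task = task_importance(gi, k = k))
}

#' Plot global feature importance
#'
#' @param object A `pd_importance`.
#' @param k Number of features shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_importance <- function(object, k = 10, ...) {
  top <- utils::head(object$overall, k)
  dat <- dplyr::filter(object$per_class, .data$feature %in% top$feature) |>
    dplyr::mutate(feature = factor(.data$feature, levels = rev(top$feature)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_abs_shap,
                                    y = .data$feature, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot task importance
#'
#' @param ti Tibble from [task_importance()].
#' @return A ggplot object.
#' @export
plot_task_importance <- function(ti) {
  dat <- dplyr::mutate(ti, task = factor(.data$task, levels = 1:11))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$task, y = .data$importance)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "task", y = "sum of top-10 mean |Shapley|") +
    ggplot2::theme_minimal()
}
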