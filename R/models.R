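# Internal unified interface over the five model families.
# fit_pd_model() returns a pd_model carrying everything predict needs;
# predict_pd_model() returns a probability matrix (columns = class levels).

model_families <- function() {
  c("linear_nn", "svm", "logistic", "random_forest", "xgboost")
}

needs_scaling <- function(method) {
  method %in% c("linear_nn", "svm", "logistic")
}

#' Default hyperparameter grids
#'
#' Small published grids searched by inner cross-validation: weight decay
#' for the single-layer linear network, cost and kernel for the SVM, ridge
#' penalty for logistic regression, `mtry` for the random forest, and tree
#' depth for gradient boosting.
#'
#' @return Named list of tibbles, one grid per model family.
#' @export
default_grids <- function() {
  list(
    linear_nn = tibble(decay = c(0, 0.01, 0.1)),
    svm = tidyr::expand_grid(cost = c(0.1, 1, 10),
                             kernel = c("linear", "radial")),
    logistic = tibble(lambda = c(0.001, 0.01, 0.1)),
    random_forest = tibble(mtry_frac = c(0.1, 0.33)),
    xgboost = tibble(max_depth = c(2L, 4L))
  )
}

# Fit one model family on a feature matrix. Classes absent from y are
# tolerated: the model is fitted on the observed classes and predicts zero
# probability for unseen ones.
fit_pd_model <- function(method, X, y, params = list(), seed = 1) {
  stopifnot(is.matrix(X), is.factor(y))
  levels_full <- levels(y)
  y <- droplevels(y)
  levels_obs <- levels(y)
  if (length(levels_obs) < 2L) abort("training data must contain >= 2 classes")
  scaled <- needs_scaling(method)
  center <- scale_sd <- NULL
  if (scaled) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2L, stats::sd)
    scale_sd[scale_sd == 0 | !is.finite(scale_sd)] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_sd, "/")
  }
  K <- length(levels_obs)
  set.seed(seed)
  fit <- switch(
    method,
    linear_nn = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, decay = params$decay %||% 0,
                     trace = FALSE, maxit = 200, MaxNWts = 100000)
    },
    svm = e1071::svm(X, y, kernel = params$kernel %||% "radial",
                     cost = params$cost %||% 1, probability = TRUE,
                     scale = FALSE),
    logistic = {
      fam <- if (K == 2L) "binomial" else "multinomial"
      lam <- params$lambda %||% 0.01
      # rare severity classes trip glmnet's small-class caution; expected here
      withCallingHandlers(
        glmnet::glmnet(X, y, family = fam, alpha = 0,
                       lambda = c(lam * 5, lam), standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8|dangerous ground", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    },
    random_forest = {
      frac <- params$mtry_frac %||% 0.33
      ranger::ranger(x = X, y = y, probability = TRUE, num.trees = 300,
                     mtry = max(1L, floor(frac * ncol(X))),
                     seed = seed, num.threads = 1L)
    },
    xgboost = xgboost::xgboost(X, y, nrounds = 50,
                               max_depth = params$max_depth %||% 4L,
                               learning_rate = 0.3, nthreads = 1L,
                               seed = seed %% 2147483647, verbosity = 0),
    abort(sprintf("unknown model family '%s'", method))
  )
  structure(list(method = method, fit = fit,
                 levels = levels_full, levels_obs = levels_obs,
                 center = center, scale_sd = scale_sd,
                 features = colnames(X), params = params),
            class = "pd_model")
}

# Probability matrix over the full class set (zero for unseen classes).
predict_pd_model <- function(object, X) {
  X <- X[, object$features, drop = FALSE]
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale_sd, "/")
  }
  K <- length(object$levels_obs)
  p <- switch(
    object$method,
    linear_nn = {
      df <- data.frame(X, check.names = FALSE)
      pr <- predict(object$fit, newdata = df, type = "probs")
      if (K == 2L) {
        pr <- cbind(1 - pr, pr)
      } else if (is.null(dim(pr))) {
        pr <- matrix(pr, nrow = 1L)
      }
      pr
    },
    svm = {
      pr <- attr(predict(object$fit, X, probability = TRUE), "probabilities")
      pr[, object$levels_obs, drop = FALSE]
    },
    logistic = {
      lam <- min(object$fit$lambda)
      pr <- predict(object$fit, newx = X, s = lam, type = "response")
      if (K == 2L) cbind(1 - pr[, 1], pr[, 1]) else pr[, , 1]
    },
    random_forest = {
      pr <- predict(object$fit, data = X, num.threads = 1L)$predictions
      pr[, object$levels_obs, drop = FALSE]
    },
    xgboost = {
      pr <- predict(object$fit, X, type = "response")
      if (K == 2L) cbind(1 - pr, pr)
      else pr[, object$levels_obs, drop = FALSE]
    }
  )
  p <- matrix(as.numeric(p), ncol = K)
  full <- matrix(0, nrow = nrow(p), ncol = length(object$levels),
                 dimnames = list(NULL, object$levels))
  full[, object$levels_obs] <- p
  full
}

predicted_classes <- function(prob, levels) {
  factor(levels[max.col(prob, ties.method = "first")], levels = levels)
}
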