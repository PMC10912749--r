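linear_fn <- function(w, intercept = 0) {
  function(mat) as.vector(intercept + mat %*% w)
}

test_that("exact enumeration recovers linear-model Shapley values", {
  # f(x) = 2*x1 + 3*x2, background at the origin, instance (1, 1)
  X <- matrix(c(1, 1), nrow = 1, dimnames = list(NULL, c("a", "b")))
  att <- shapley_attributions(linear_fn(c(2, 3)), X, background = c(0, 0))
  expect_equal(att$method, "exact")
  expect_equal(att$base, 0, ignore_attr = TRUE)
  expect_equal(as.vector(att$phi[1, , 1]), c(2, 3), tolerance = 1e-10)

  # general additive case: phi_j = w_j * (x_j - background_j), both paths
  set.seed(2)
  w <- rnorm(5)
  X5 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
  bg <- rnorm(5)
  att5 <- shapley_attributions(linear_fn(w, 1), X5, background = bg)
  expected <- sweep(X5, 2, bg) %*% diag(w)
  expect_equal(att5$phi[, , 1], expected, tolerance = 1e-6,
               ignore_attr = TRUE)

  att5p <- shapley_attributions(linear_fn(w, 1), X5, background = bg,
                                exact_max = 2, n_perm = 6, seed = 3)
  expect_equal(att5p$method, "permutation")
  expect_equal(att5p$phi[, , 1], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a single-feature model attributes the full output change", {
  f <- function(mat) sin(mat[, 1])
  X <- matrix(seq(-2, 2, length.out = 7), ncol = 1,
              dimnames = list(NULL, "x"))
  att <- shapley_attributions(f, X, background = 0.3)
  expect_equal(as.vector(att$phi[, 1, 1]), sin(X[, 1]) - sin(0.3),
               tolerance = 1e-12)
})

test_that("local accuracy holds exactly for fitted classifiers", {
  tab <- toy_feature_table(n_pd = 25, n_hc = 25, p = 15, effect = 1.5,
                           signal_cols = 1:3, seed = 4,
                           tasks = rep(1:5, 3))
  X <- as.matrix(tab[, pdmotor:::feature_columns(tab)])
  y <- scheme_labels(tab, "pdhc")

  for (method in c("xgboost", "logistic")) {
    fit <- pdmotor:::fit_pd_model(method, X, y, list(), seed = 1)
    att <- shapley_attributions(fit, X, n_perm = 8, seed = 2)
    expect_equal(att$method, "permutation")
    pr <- pdmotor:::predict_pd_model(fit, X)
    for (k in seq_along(att$classes)) {
      recon <- att$base[k] + rowSums(att$phi[, , k])
      expect_equal(recon, pr[, k], tolerance = 1e-8, ignore_attr = TRUE)
    }
  }

  # exact path on a small feature count
  tab8 <- tab[, c(pdmotor:::label_columns(),
                  pdmotor:::feature_columns(tab)[1:8])]
  X8 <- as.matrix(tab8[, 5:12])
  fit8 <- pdmotor:::fit_pd_model("xgboost", X8, y, list(), seed = 1)
  att8 <- shapley_attributions(fit8, X8[1:10, ])
  expect_equal(att8$method, "exact")
  pr8 <- pdmotor:::predict_pd_model(fit8, X8[1:10, ])
  recon8 <- att8$base[2] + rowSums(att8$phi[, , 2])
  expect_equal(recon8, pr8[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("duplicated feature columns share their attribution", {
  f <- function(mat) (mat[, 1] + mat[, 2]) * mat[, 3]
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("d1", "d2", "u")))
  X[, 2] <- X[, 1]
  att <- shapley_attributions(f, X, background = c(0, 0, 0))
  expect_equal(att$phi[, 1, 1], att$phi[, 2, 1], tolerance = 1e-10)

  # permutation path, padded to exceed the exact-enumeration cut-off
  Xp <- cbind(X, matrix(rnorm(10 * 11), 10, 11))
  colnames(Xp) <- c("d1", "d2", "u", paste0("pad", 1:11))
  fp <- function(mat) (mat[, 1] + mat[, 2]) * mat[, 3]
  attp <- shapley_attributions(fp, Xp, background = rep(0, 14),
                               n_perm = 300, seed = 6)
  gi <- global_importance(attp)
  imp <- gi$per_class$mean_abs_shap[match(c("d1", "d2"), gi$per_class$feature)]
  expect_equal(imp[1], imp[2], tolerance = 0.05)
})

test_that("global importance aggregates mean absolute attributions", {
  att <- structure(list(
    phi = array(c(1, -1, 0, 0), dim = c(2, 2, 1),
                dimnames = list(NULL, c("task1_a", "task2_b"), "PD")),
    base = 0.5, features = c("task1_a", "task2_b"), classes = "PD",
    method = "exact"), class = "pd_attributions")
  gi <- global_importance(att)
  expect_equal(gi$overall$importance[gi$overall$feature == "task1_a"], 1)
  expect_equal(gi$overall$importance[gi$overall$feature == "task2_b"], 0)

  zero <- att
  zero$phi[] <- 0
  expect_true(all(global_importance(zero)$overall$importance == 0))

  # random matrices against a direct mean-abs oracle; ties break by name
  set.seed(7)
  phi <- array(rnorm(60), dim = c(10, 3, 2),
               dimnames = list(NULL, c("task1_x", "task1_y", "task2_z"),
                               c("A", "B")))
  att2 <- structure(list(phi = phi, base = c(0, 0),
                         features = dimnames(phi)[[2]],
                         classes = c("A", "B"), method = "exact"),
                    class = "pd_attributions")
  gi2 <- global_importance(att2)
  for (j in 1:3) {
    oracle <- mean(abs(phi[, j, 1])) + mean(abs(phi[, j, 2]))
    expect_equal(gi2$overall$importance[gi2$overall$feature ==
                                          dimnames(phi)[[2]][j]],
                 oracle, tolerance = 1e-12)
  }

  tie <- att
  tie$phi[] <- c(1, 1, 1, 1)
  gtie <- global_importance(tie)
  expect_equal(gtie$overall$feature, c("task1_a", "task2_b"))  # lexicographic
})

test_that("task importance sums top-k features per task", {
  mk_gi <- function(features, importances, classes = "PD") {
    pc <- tibble::tibble(feature = features, class = classes,
                         mean_abs_shap = importances)
    overall <- tibble::tibble(feature = features, importance = importances) |>
      dplyr::arrange(dplyr::desc(importance), feature) |>
      dplyr::mutate(rank = dplyr::row_number())
    structure(list(per_class = pc, overall = overall),
              class = "pd_importance")
  }
  gi <- mk_gi(c("task1_a", "task1_b", "task1_c", "task2_d", "task3_e"),
              c(0.5, 0.2, 0.1, 0.3, 0.01))
  ti <- task_importance(gi, k = 4, tasks = 1:3)
  expect_equal(ti$importance[ti$task == 1], 0.8)
  expect_equal(ti$importance[ti$task == 2], 0.3)
  expect_equal(ti$importance[ti$task == 3], 0)   # not in the top 4

  # k beyond the feature count includes everything
  ti_all <- task_importance(gi, k = 99, tasks = 1:3)
  expect_equal(sum(ti_all$importance), sum(gi$overall$importance))

  bad <- mk_gi(c("task1_a", "other"), c(1, 2))
  expect_error(task_importance(bad), "task")
})

test_that("a planted signal feature ranks first in global importance", {
  set.seed(9)
  n <- 80
  group <- rep(c("PD", "HC"), each = n / 2)
  X <- matrix(rnorm(n * 13), n, 13)
  X[group == "PD", 7] <- X[group == "PD", 7] + 3
  colnames(X) <- sprintf("task%d_f%d", rep(1:4, length.out = 13), 1:13)
  y <- factor(group, levels = c("HC", "PD"))
  fit <- pdmotor:::fit_pd_model("xgboost", X, y, list(max_depth = 3), seed = 2)
  att <- shapley_attributions(fit, X, n_perm = 20, seed = 3)
  gi <- global_importance(att)
  expect_equal(gi$overall$feature[1], colnames(X)[7])
})
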