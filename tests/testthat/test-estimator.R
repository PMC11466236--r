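test_that("standardization uses the population-sd convention and flags constants", {
  # build a 3-node panel by hand
  cat3 <- catalog3()
  df <- tibble::tibble(subject_id = c("a", "b", "c"), gender = c(0L, 1L, 0L),
                       t1_N1 = c(0L, 2L, 4L), t1_D1 = c(1L, 2L, 3L),
                       t1_A1 = c(0L, 1L, 2L),
                       t2_N1 = c(1L, 2L, 3L), t2_D1 = c(0L, 4L, 2L),
                       t2_A1 = c(2L, 1L, 0L))
  pan <- as_clpn_panel(df, cat3)
  std <- standardize_scores(pan)
  expect_equal(std$t1[, "N1"], c(-1, 0, 1) * sqrt(3 / 2), ignore_attr = TRUE)
  expect_equal(colMeans(std$t1), c(N1 = 0, D1 = 0, A1 = 0))
  # idempotence up to floating error: re-scaling a standardized column
  z <- std$t1[, "N1"]
  expect_equal((z - mean(z)) / sqrt(mean((z - mean(z))^2)), z)
  df$t1_D1 <- c(2L, 2L, 2L)
  expect_error(standardize_scores(as_clpn_panel(df, cat3)), "D1",
               class = "clpnet_degenerate_column_error")
})

test_that("the penalty-free limit reproduces ordinary least squares", {
  set.seed(101)
  X <- matrix(rnorm(400 * 5), 400, 5)
  y <- X %*% c(0.4, -0.2, 0, 0.1, 0) + rnorm(400)
  fit <- fit_node_regression(y, X, lambda = 0)
  ols <- stats::coef(stats::lm(y ~ X))
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("fixed-penalty solutions agree with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 250; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] * 0.6 - X[, 3] * 0.4 + rnorm(n)
  for (lam in c(0.3, 0.08, 0.01)) {
    ours <- fit_node_regression(y, X, lambda = lam)
    ref <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                          thresh = 1e-12)
    expect_equal(unname(ours$coefficients), as.numeric(ref$beta),
                 tolerance = 1e-6)
    expect_equal(ours$intercept, as.numeric(ref$a0), tolerance = 1e-6)
  }
  # unpenalized covariate column survives a crushing penalty
  Xg <- cbind(X, cov1 = rep(c(0, 1), length.out = n))
  yg <- y + 0.8 * Xg[, "cov1"]
  big <- fit_node_regression(yg, Xg, penalty_free = p + 1, lambda = 5)
  expect_true(all(big$coefficients[1:p] == 0))
  expect_gt(big$coefficients[["cov1"]], 0.4)
})

test_that("every returned fit satisfies the L1 stationarity conditions", {
  set.seed(33)
  for (i in 1:5) {
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- X[, 1] * 0.5 + rnorm(200)
    fit <- fit_node_regression(y, X, config = clpn_config(cv_seed = i))
    expect_lt(fit$kkt, 1e-6)
  }
})

test_that("nonzero count is monotone along the decreasing penalty grid", {
  set.seed(9)
  for (i in 1:3) {
    X <- matrix(rnorm(150 * 8), 150, 8)
    y <- X %*% rnorm(8, sd = 0.3) + rnorm(150)
    n <- nrow(X)
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    G <- crossprod(Xc) / n
    cv <- as.numeric(crossprod(Xc, yc)) / n
    lambdas <- exp(seq(log(max(abs(cv))), log(max(abs(cv)) * 1e-4),
                       length.out = 60))
    path <- cpp_lasso_path_gram(G, cv, rep(1, 8), lambdas, 1e-7, 10000)
    nonzero <- colSums(path$beta != 0)
    expect_true(all(diff(nonzero) >= 0))
    expect_equal(nonzero[1], 0)   # grid starts at the all-zero penalty
  }
})

test_that("null data yields near-empty models, sparser under the one-SE rule", {
  nz_onese <- integer(0)
  nz_min <- integer(0)
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(500 * 24), 500, 24)
    y <- rnorm(500)
    f1 <- fit_node_regression(y, X, config = clpn_config(
      cv_seed = s, lambda_rule = "one_se"))
    f2 <- fit_node_regression(y, X, config = clpn_config(cv_seed = s))
    nz_onese <- c(nz_onese, sum(f1$coefficients != 0))
    nz_min <- c(nz_min, sum(f2$coefficients != 0))
  }
  # the conservative rule keeps at most a stray coefficient on pure noise
  expect_true(all(nz_onese <= 1))
  expect_gte(sum(nz_onese == 0), 5)
  # it is never denser than the CV-minimum rule, which stays sparse itself
  expect_true(all(nz_onese <= nz_min))
  expect_lt(mean(nz_min), 5)
})

test_that("a single strong signal is recovered at the CV-selected penalty", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(2000 * 10), 2000, 10)
    y <- 0.5 * X[, 1] + rnorm(2000, sd = 0.5)
    fit <- fit_node_regression(y, X, config = clpn_config(cv_seed = s))
    ok <- abs(fit$coefficients[1] - 0.5) < 0.1 &&
      sum(fit$coefficients[-1] != 0) <= 1
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the fitted CLPN has the right shape, covariates, and determinism", {
  truth <- default_ground_truth()
  sim <- simulate_panel(truth, 250, seed = 13)
  cfg <- clpn_config(cv_seed = 4)
  fit <- fit_clpn(sim$data, cfg)
  expect_s3_class(fit, "clpn_fit")
  expect_equal(dim(fit$W), c(24, 24))
  expect_equal(rownames(fit$covariate_coefs), "gender")
  expect_equal(length(fit$lambda_selected), 24)
  expect_lt(max(fit$kkt), 1e-6)
  expect_identical(fit_clpn(sim$data, cfg)$W, fit$W)

  boys <- fit_clpn(sim$data, cfg, group_filter = "boys")
  expect_null(boys$covariate_coefs)
  expect_equal(boys$n_subjects, sum(sim$data$gender == 0))
  expect_error(fit_clpn(sim$data, cfg, group_filter = 3),
               class = "clpnet_input_error")

  td <- tidy(fit)
  expect_equal(nrow(td), 576)
  expect_equal(sum(td$edge_type == "cross"), 552)
  gl <- glance(fit)
  expect_equal(gl$n_cross_edges, 552)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("edge summaries compute hand-checkable means", {
  cat24 <- default_catalog()
  net1 <- cross_lagged_network(diag(0.17, 24), cat24)
  es1 <- edge_summary(net1)
  expect_equal(es1$mean_abs_auto, 0.17)
  expect_equal(es1$mean_abs_cross, 0)
  expect_equal(es1$n_cross_edges, 552)

  es0 <- edge_summary(cross_lagged_network(matrix(0, 24, 24), cat24))
  expect_equal(es0$mean_abs_auto + es0$mean_abs_cross, 0)

  W3 <- matrix(0.05, 3, 3); diag(W3) <- c(0.1, 0.2, 0.3)
  es3 <- edge_summary(cross_lagged_network(W3, catalog3()))
  expect_equal(es3$mean_abs_auto, 0.2)
  expect_equal(es3$mean_abs_cross, 0.05)
  expect_equal(es3$n_cross_edges, 6)
})
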