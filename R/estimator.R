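#' Estimation configuration for the cross-lagged panel network
#'
#' @param standardize Z-score every symptom column within each wave before
#'   regression (population-sd convention, divisor `n`), so edge weights are
#'   comparable across items. Default `TRUE`.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param lambda_rule `"min"` (CV-error minimizer, default) or `"one_se"`.
#' @param lambda_grid_size Points on the log-spaced penalty grid, starting at
#'   the smallest penalty that zeroes all penalized coefficients (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest grid penalty
#'   (default 1e-4).
#' @param penalize_covariates Whether covariates are shrunk like symptom
#'   predictors (default `FALSE`: control variables are not penalized).
#' @param cv_seed Integer seed fixing the CV fold assignment.
#' @param tol Coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep (default 1e-7).
#' @param maxit Maximum coordinate-descent sweeps per penalty value.
#' @return A list of class `clpn_config`.
#' @export
clpn_config <- function(standardize = TRUE, cv_folds = 10,
                        lambda_rule = c("min", "one_se"),
                        lambda_grid_size = 100, lambda_min_ratio = 1e-4,
                        penalize_covariates = FALSE, cv_seed = 1,
                        tol = 1e-7, maxit = 10000) {
  lambda_rule <- match.arg(lambda_rule)
  if (cv_folds < 2) {
    rlang::abort("cv_folds must be >= 2", class = "clpnet_parameter_error")
  }
  structure(list(standardize = standardize, cv_folds = as.integer(cv_folds),
                 lambda_rule = lambda_rule,
                 lambda_grid_size = as.integer(lambda_grid_size),
                 lambda_min_ratio = lambda_min_ratio,
                 penalize_covariates = penalize_covariates,
                 cv_seed = as.integer(cv_seed), tol = tol,
                 maxit = as.integer(maxit)),
            class = "clpn_config")
}

#' Z-score the symptom columns of a panel, wave by wave
#'
#' Uses the population-sd convention (divisor `n`), so a column with values
#' `{0, 2, 4}` maps to `{-1.2247, 0, 1.2247}`. Per-column means and sds are
#' returned for back-mapping.
#'
#' @param data A `clpn_panel`.
#' @return A list with `t1`, `t2` (standardized numeric matrices) and
#'   `scaling` (tibble of wave, node_id, mean, sd).
#' @export
standardize_scores <- function(data) {
  stopifnot(inherits(data, "clpn_panel"))
  std_one <- function(m, wave) {
    mu <- colMeans(m)
    sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
    if (any(sd_pop == 0)) {
      bad <- colnames(m)[sd_pop == 0][1]
      rlang::abort(paste0("zero-variance column at wave ", wave, ": ", bad),
                   class = "clpnet_degenerate_column_error")
    }
    list(z = sweep(sweep(m, 2, mu), 2, sd_pop, "/"),
         scaling = tibble::tibble(wave = wave, node_id = colnames(m),
                                  mean = unname(mu), sd = unname(sd_pop)))
  }
  s1 <- std_one(score_matrix(data, 1), 1L)
  s2 <- std_one(score_matrix(data, 2), 2L)
  list(t1 = s1$z, t2 = s2$z, scaling = dplyr::bind_rows(s1$scaling, s2$scaling))
}

make_foldid <- function(n, k, cv_seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cv_seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Single nodewise lasso regression
#'
#' Minimizes `(1/2n) * RSS + lambda * sum(|penalized coefficients|)` by
#' cyclic coordinate descent, with the penalty chosen over a log-spaced grid
#' by K-fold cross-validation (folds fixed by `config$cv_seed`). Columns in
#' `penalty_free` carry no penalty. Solutions satisfy the L1 stationarity
#' (KKT) conditions to within 1e-6.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric predictor matrix (rows aligned with `y`).
#' @param penalty_free Integer indices of unpenalized columns of `X`.
#' @param config A [clpn_config()].
#' @param lambda Optional fixed penalty value(s) overriding CV selection
#'   (e.g., `lambda = 0` for the ordinary-least-squares limit).
#' @return A list with `coefficients`, `intercept`, `lambda`, `kkt`
#'   (stationarity violation of the returned fit) and, for CV fits, `cvm`
#'   and `lambda_grid`.
#' @export
fit_node_regression <- function(y, X, penalty_free = integer(0),
                                config = clpn_config(), lambda = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    rlang::abort("rows of X and y are not aligned",
                 class = "clpnet_input_error")
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    rlang::abort("non-finite values in X or y", class = "clpnet_input_error")
  }
  p <- ncol(X)
  pen <- rep(1, p)
  pen[penalty_free] <- 0
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))

  if (!is.null(lambda)) {
    n <- nrow(X)
    mx <- colMeans(X); my <- mean(y)
    Xc <- sweep(X, 2, mx); yc <- y - my
    G <- crossprod(Xc) / n
    cv <- as.numeric(crossprod(Xc, yc)) / n
    path <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
    fit <- cpp_lasso_path_gram(G, cv, pen, path, config$tol, config$maxit)
    b <- fit$beta[, length(path)]
    return(list(coefficients = stats::setNames(b, nm),
                intercept = my - sum(mx * b),
                lambda = path[length(path)],
                kkt = fit$kkt[length(path)]))
  }

  n <- nrow(X)
  if (n <= config$cv_folds) {
    rlang::abort("fewer rows than cross-validation folds",
                 class = "clpnet_input_error")
  }
  foldid <- make_foldid(n, config$cv_folds, config$cv_seed)
  fit <- cpp_cv_clpn(X, matrix(y, ncol = 1), foldid, pen,
                     config$lambda_grid_size, config$lambda_min_ratio,
                     as.integer(config$lambda_rule == "one_se"),
                     config$tol, config$maxit)
  list(coefficients = stats::setNames(as.numeric(fit$beta), nm),
       intercept = fit$a0[1],
       lambda = fit$lambda[1],
       kkt = fit$kkt[1],
       cvm = as.numeric(fit$cvm),
       lambda_grid = as.numeric(fit$lambda_grid))
}

#' Construct a cross-lagged network object from a weight matrix
#'
#' Mostly used to rebuild fitted networks from serialized files or to wrap
#' externally specified weight matrices (e.g., a ground-truth `B`) so they
#' can be passed to the centrality, bridge and comparison functions.
#'
#' @param W `n_nodes x n_nodes` weight matrix; entry `[i, j]` is the effect
#'   of wave-1 node `i` on wave-2 node `j` (diagonal = autoregressive).
#' @param catalog A [symptom_catalog()] matching `W`'s order.
#' @param covariate_coefs,intercepts,lambda_selected,config,n_subjects
#'   Optional fit metadata.
#' @return An object of class `clpn_fit`.
#' @export
cross_lagged_network <- function(W, catalog, covariate_coefs = NULL,
                                 intercepts = NULL, lambda_selected = NULL,
                                 config = NULL, n_subjects = NA_integer_) {
  W <- as.matrix(W)
  p <- nrow(catalog)
  if (nrow(W) != p || ncol(W) != p || !all(is.finite(W))) {
    rlang::abort("W must be a finite n_nodes x n_nodes matrix",
                 class = "clpnet_input_error")
  }
  dimnames(W) <- list(catalog$node_id, catalog$node_id)
  structure(list(W = W, covariate_coefs = covariate_coefs,
                 intercepts = intercepts, lambda_selected = lambda_selected,
                 config = config, catalog = catalog,
                 n_subjects = as.integer(n_subjects)),
            class = "clpn_fit")
}

#' Fit the cross-lagged panel network
#'
#' Regresses each wave-2 symptom on all wave-1 symptoms (L1-penalized) plus
#' covariates (unpenalized by default), assembling the directed weight
#' matrix column by column. Whole-sample fits include gender as a covariate;
#' when `group_filter` is set the model is fit on that subset and the gender
#' covariate is dropped.
#'
#' @param data A `clpn_panel`.
#' @param config A [clpn_config()].
#' @param group_filter Optional gender code (0/1) or group label
#'   (`"boys"`/`"girls"`) restricting the analysis set.
#' @param covariates Covariate column names for whole-sample fits
#'   (default `"gender"`).
#' @return A `clpn_fit`: weight matrix `W` (`[i, j]` = wave-1 node `i`
#'   predicting wave-2 node `j`), covariate coefficients, intercepts,
#'   selected penalties, config, catalog and `n_subjects`.
#' @export
#' @examples
#' sim <- simulate_panel(toy_ground_truth(), n_subjects = 200, seed = 1)
#' fit <- fit_clpn(sim$data, clpn_config(cv_seed = 1), covariates = NULL)
#' glance(fit)
fit_clpn <- function(data, config = clpn_config(), group_filter = NULL,
                     covariates = "gender") {
  stopifnot(inherits(data, "clpn_panel"))
  catalog <- attr(data, "catalog")

  if (!is.null(group_filter)) {
    code <- if (is.character(group_filter)) {
      match(group_filter, c("boys", "girls")) - 1L
    } else as.integer(group_filter)
    if (is.na(code) || !code %in% c(0L, 1L)) {
      rlang::abort("group_filter must be 0/1 or \"boys\"/\"girls\"",
                   class = "clpnet_input_error")
    }
    keep <- data$gender == code
    if (!any(keep)) {
      rlang::abort("no subjects left after group filtering",
                   class = "clpnet_input_error")
    }
    flagged <- attr(data, "flagged")
    data <- as_clpn_panel(tibble::as_tibble(unclass_panel(data))[keep, ],
                          catalog, flagged = flagged)
    covariates <- NULL
  }
  n <- nrow(data)
  if (n == 0) {
    rlang::abort("empty analysis set", class = "clpnet_input_error")
  }
  if (n <= config$cv_folds) {
    rlang::abort("fewer subjects than cross-validation folds",
                 class = "clpnet_input_error")
  }

  p <- nrow(catalog)
  if (isTRUE(config$standardize)) {
    std <- standardize_scores(data)
    X1 <- std$t1; Y2 <- std$t2
  } else {
    X1 <- score_matrix(data, 1) * 1.0
    Y2 <- score_matrix(data, 2) * 1.0
  }
  Xcov <- NULL
  if (length(covariates) > 0) {
    Xcov <- as.matrix(tibble::as_tibble(data)[, covariates, drop = FALSE])
    storage.mode(Xcov) <- "double"
  }
  X <- cbind(X1, Xcov)
  pen <- c(rep(1, p),
           rep(if (isTRUE(config$penalize_covariates)) 1 else 0,
               length(covariates)))

  foldid <- make_foldid(n, config$cv_folds, config$cv_seed)
  fit <- cpp_cv_clpn(X, Y2, foldid, pen,
                     config$lambda_grid_size, config$lambda_min_ratio,
                     as.integer(config$lambda_rule == "one_se"),
                     config$tol, config$maxit)
  if (fit$n_nonconverged > 0) {
    rlang::warn(paste0(fit$n_nonconverged,
                       " coordinate-descent path(s) hit the sweep limit"))
  }
  W <- fit$beta[seq_len(p), , drop = FALSE]
  covariate_coefs <- NULL
  if (length(covariates) > 0) {
    covariate_coefs <- fit$beta[p + seq_along(covariates), , drop = FALSE]
    dimnames(covariate_coefs) <- list(covariates, catalog$node_id)
  }
  out <- cross_lagged_network(
    W, catalog,
    covariate_coefs = covariate_coefs,
    intercepts = stats::setNames(as.numeric(fit$a0), catalog$node_id),
    lambda_selected = stats::setNames(as.numeric(fit$lambda),
                                      catalog$node_id),
    config = config, n_subjects = n)
  out$kkt <- stats::setNames(as.numeric(fit$kkt), catalog$node_id)
  out$group_filter <- group_filter
  out
}

#' Summary statistics of a fitted network's edge weights
#'
#' Mean absolute weight over the autoregressive diagonal and over the
#' cross-lagged off-diagonal, plus edge counts. Means are of absolute
#' weights and labelled as such.
#'
#' @param net A `clpn_fit`.
#' @return A one-row tibble: `mean_abs_auto`, `mean_abs_cross`,
#'   `n_cross_edges`, `n_nonzero_cross`.
#' @export
edge_summary <- function(net) {
  stopifnot(inherits(net, "clpn_fit"))
  W <- net$W
  off <- W[row(W) != col(W)]
  tibble::tibble(
    mean_abs_auto = mean(abs(diag(W))),
    mean_abs_cross = mean(abs(off)),
    n_cross_edges = length(off),
    n_nonzero_cross = sum(off != 0))
}

#' @export
print.clpn_fit <- function(x, ...) {
  es <- edge_summary(x)
  cat("Cross-lagged panel network: ", nrow(x$catalog), " symptoms, ",
      es$n_nonzero_cross, "/", es$n_cross_edges,
      " nonzero cross-lagged edges\n", sep = "")
  cat("  mean |autoregressive| = ", signif(es$mean_abs_auto, 3),
      ";  mean |cross-lagged| = ", signif(es$mean_abs_cross, 3), "\n",
      sep = "")
  if (!is.na(x$n_subjects)) {
    cat("  fitted on ", x$n_subjects, " subjects\n", sep = "")
  }
  invisible(x)
}

#' Tidy a fitted network into an edge-list tibble
#'
#' @param x A `clpn_fit`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `from_community`, `to_community`,
#'   `weight`, `edge_type` (`"auto"`/`"cross"`), one row per directed edge.
#' @exportS3Method generics::tidy
tidy.clpn_fit <- function(x, ...) {
  ids <- x$catalog$node_id
  comm <- catalog_communities(x$catalog)
  grid <- tidyr::expand_grid(from = ids, to = ids)
  grid$weight <- x$W[cbind(match(grid$from, ids), match(grid$to, ids))]
  grid$from_community <- unname(comm[grid$from])
  grid$to_community <- unname(comm[grid$to])
  grid$edge_type <- ifelse(grid$from == grid$to, "auto", "cross")
  grid[, c("from", "to", "from_community", "to_community", "weight",
           "edge_type")]
}

#' One-row summary of a fitted network
#'
#' @param x A `clpn_fit`.
#' @param ... Unused.
#' @return A one-row tibble combining [edge_summary()] with `n_subjects` and
#'   `n_nodes`.
#' @exportS3Method generics::glance
glance.clpn_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_nodes = nrow(x$catalog), n_subjects = x$n_subjects),
    edge_summary(x))
}

#' Heatmap of a fitted cross-lagged weight matrix
#'
#' @param object A `clpn_fit`.
#' @param ... Unused.
#' @return A ggplot: wave-1 predictors on rows, wave-2 outcomes on columns,
#'   fill by signed weight (red negative, green positive).
#' @exportS3Method ggplot2::autoplot
autoplot.clpn_fit <- function(object, ...) {
  ed <- tidy.clpn_fit(object)
  ids <- object$catalog$node_id
  ed$from <- factor(ed$from, levels = rev(ids))
  ed$to <- factor(ed$to, levels = ids)
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", midpoint = 0) +
    ggplot2::labs(x = "wave-2 outcome", y = "wave-1 predictor",
                  fill = "edge weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
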