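#' Bootstrap configuration for edge-weight accuracy
#'
#' @param n_iterations Number of bootstrap replicates (default 1000).
#' @param ci_level Confidence level of the percentile intervals
#'   (default 0.95).
#' @param master_seed Integer seed; per-replicate seeds are derived from it
#'   deterministically (see [simulate_panel()] for the derivation scheme).
#' @param refit_lambda Re-run the CV penalty selection inside each replicate
#'   (default `TRUE`, resampling the full procedure); `FALSE` keeps the
#'   full-sample penalties fixed for speed.
#' @return A list of class `boot_config`.
#' @export
boot_config <- function(n_iterations = 1000, ci_level = 0.95,
                        master_seed = 1, refit_lambda = TRUE) {
  if (n_iterations < 2) {
    rlang::abort("n_iterations must be >= 2",
                 class = "clpnet_parameter_error")
  }
  if (ci_level <= 0 || ci_level >= 1) {
    rlang::abort("ci_level must be in (0, 1)",
                 class = "clpnet_parameter_error")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 ci_level = ci_level,
                 master_seed = as.integer(master_seed),
                 refit_lambda = refit_lambda),
            class = "boot_config")
}

# percentile interval endpoints as order statistics of the replicate draws
percentile_ci <- function(sorted, level) {
  b <- length(sorted)
  alpha <- (1 - level) / 2
  k_lo <- max(1L, floor(alpha * b))
  k_hi <- min(b, ceiling((1 - alpha) * b))
  c(sorted[k_lo], sorted[k_hi])
}

#' Bootstrap confidence intervals for every edge weight
#'
#' Non-parametric subject resampling: each replicate draws `n` subjects with
#' replacement, re-fits the full CLPN (re-selecting the penalty when
#' `refit_lambda`), and records all `n_nodes^2` edge weights. Percentile
#' intervals are order statistics of the replicate distribution. Replicates
#' whose fit fails (e.g., a zero-variance column in a degenerate resample)
#' are dropped and counted, and the run aborts if more than 5% fail.
#'
#' @param data A `clpn_panel` with at least 10 subjects.
#' @param est_config A [clpn_config()].
#' @param bt_config A [boot_config()].
#' @param group_filter,covariates Passed to [fit_clpn()].
#' @return An object of class `clpn_boot`: `table` (tibble with one row per
#'   directed edge: `from`, `to`, `edge_type`, `estimate`, `ci_lower`,
#'   `ci_upper`, `prop_nonzero`), the replicate weight matrix, counts and
#'   the configs.
#' @export
bootstrap_edge_cis <- function(data, est_config = clpn_config(),
                               bt_config = boot_config(),
                               group_filter = NULL, covariates = "gender") {
  stopifnot(inherits(data, "clpn_panel"), inherits(bt_config, "boot_config"))
  full <- fit_clpn(data, est_config, group_filter = group_filter,
                   covariates = covariates)
  if (!is.null(group_filter)) {
    # bootstrap resamples within the filtered analysis set
    catalog <- attr(data, "catalog")
    code <- if (is.character(group_filter)) {
      match(group_filter, c("boys", "girls")) - 1L
    } else as.integer(group_filter)
    data <- as_clpn_panel(
      tibble::as_tibble(unclass_panel(data))[data$gender == code, ], catalog)
    covariates <- NULL
  }
  n <- nrow(data)
  if (n < 10) {
    rlang::abort("bootstrap needs an analysis set of at least 10 subjects",
                 class = "clpnet_input_error")
  }
  catalog <- attr(data, "catalog")
  p <- nrow(catalog)
  B <- bt_config$n_iterations
  seeds <- derive_seeds(bt_config$master_seed, B)

  # pre-extract score matrices once; replicates resample rows directly
  T1 <- score_matrix(data, 1) * 1.0
  T2 <- score_matrix(data, 2) * 1.0
  Xcov_all <- NULL
  if (length(covariates) > 0) {
    Xcov_all <- as.matrix(tibble::as_tibble(data)[, covariates,
                                                  drop = FALSE])
    storage.mode(Xcov_all) <- "double"
  }
  pen <- c(rep(1, p),
           rep(if (isTRUE(est_config$penalize_covariates)) 1 else 0,
               length(covariates)))
  zscore_cols <- function(m) {
    mu <- colMeans(m)
    sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
    if (any(sd_pop == 0)) return(NULL)   # degenerate resample
    sweep(sweep(m, 2, mu), 2, sd_pop, "/")
  }

  reps <- matrix(NA_real_, B, p * p)
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    W_b <- tryCatch({
      if (isTRUE(est_config$standardize)) {
        X1 <- zscore_cols(T1[idx, , drop = FALSE])
        Y2 <- zscore_cols(T2[idx, , drop = FALSE])
      } else {
        X1 <- T1[idx, , drop = FALSE]
        Y2 <- T2[idx, , drop = FALSE]
      }
      if (is.null(X1) || is.null(Y2)) NULL else {
        X <- cbind(X1, Xcov_all[idx, , drop = FALSE])
        if (bt_config$refit_lambda) {
          foldid <- make_foldid(n, est_config$cv_folds, seeds[b])
          sol <- cpp_cv_clpn(X, Y2, foldid, pen,
                             est_config$lambda_grid_size,
                             est_config$lambda_min_ratio,
                             as.integer(est_config$lambda_rule == "one_se"),
                             est_config$tol, est_config$maxit)
          sol$beta[seq_len(p), , drop = FALSE]
        } else {
          mx <- colMeans(X)
          Xc <- sweep(X, 2, mx)
          G <- crossprod(Xc) / n
          Wf <- matrix(0, p, p)
          for (j in seq_len(p)) {
            yc <- Y2[, j] - mean(Y2[, j])
            cv <- as.numeric(crossprod(Xc, yc)) / n
            lam <- full$lambda_selected[j]
            path <- unique(c(lam * 4, lam * 2, lam))
            sol <- cpp_lasso_path_gram(G, cv, pen, path, est_config$tol,
                                       est_config$maxit)
            Wf[, j] <- sol$beta[seq_len(p), length(path)]
          }
          Wf
        }
      }
    }, error = function(e) NULL)
    if (is.null(W_b)) { failed <- failed + 1L; next }
    reps[b, ] <- as.numeric(W_b)
  }
  if (failed > 0.05 * B) {
    rlang::abort(paste0(failed, " of ", B, " bootstrap replicates failed ",
                        "(> 5%); aborting"),
                 class = "clpnet_bootstrap_error")
  }
  if (failed > 0) {
    rlang::warn(paste0(failed, " bootstrap replicate(s) failed and were ",
                       "excluded"))
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  ids <- catalog$node_id
  # column-major order of W: "from" varies fastest within each outcome
  est <- as.numeric(full$W)
  ci <- apply(reps, 2, function(w) percentile_ci(sort(w),
                                                 bt_config$ci_level))
  tab <- tibble::tibble(
    from = rep(ids, times = p),
    to = rep(ids, each = p),
    edge_type = ifelse(rep(ids, times = p) == rep(ids, each = p),
                       "auto", "cross"),
    estimate = est,
    ci_lower = ci[1, ],
    ci_upper = ci[2, ],
    prop_nonzero = colMeans(reps != 0))

  structure(list(table = tab, replicates = reps,
                 n_iterations = B, n_failed = failed,
                 ci_level = bt_config$ci_level,
                 master_seed = bt_config$master_seed,
                 est_config = est_config, bt_config = bt_config,
                 catalog = catalog, full_fit = full),
            class = "clpn_boot")
}

#' @export
print.clpn_boot <- function(x, ...) {
  cat("Bootstrap edge-weight accuracy: ", x$n_iterations, " replicates (",
      x$n_failed, " failed), ", 100 * x$ci_level,
      "% percentile intervals\n", sep = "")
  cov0 <- mean(x$table$ci_lower <= 0 & x$table$ci_upper >= 0)
  cat("  ", round(100 * cov0, 1),
      "% of edge intervals include zero\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clpn_boot <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.clpn_boot <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations, n_failed = x$n_failed,
                 ci_level = x$ci_level,
                 mean_ci_width = mean(x$table$ci_upper - x$table$ci_lower))
}

#' Edges stable across bootstrap replicates
#'
#' @param table A `clpn_boot` object or its tidy edge table.
#' @param min_nonzero_prop Minimum proportion of replicates in which an edge
#'   must be nonzero (in `[0, 1]`).
#' @return The filtered edge tibble, sorted by `|estimate|` descending.
#' @export
edge_stability_report <- function(table, min_nonzero_prop) {
  if (inherits(table, "clpn_boot")) table <- table$table
  if (min_nonzero_prop < 0 || min_nonzero_prop > 1) {
    rlang::abort("min_nonzero_prop must be in [0, 1]",
                 class = "clpnet_input_error")
  }
  out <- table[table$prop_nonzero >= min_nonzero_prop, ]
  out[order(-abs(out$estimate), out$from, out$to), ]
}

#' Bootstrap CI plot for edge weights
#'
#' Edges ordered by point estimate, interval drawn around each; mirrors the
#' usual edge-accuracy plots of network psychometrics.
#'
#' @param object A `clpn_boot`.
#' @param top_n Show only the `top_n` edges by absolute estimate
#'   (default 50).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.clpn_boot <- function(object, top_n = 50, ...) {
  tab <- object$table
  tab <- tab[order(-abs(tab$estimate)), ]
  tab <- utils::head(tab, top_n)
  tab$edge <- paste0(tab$from, " %->% ", tab$to)
  tab$edge <- factor(tab$edge, levels = tab$edge[order(tab$estimate)])
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$edge)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1.2, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "edge weight (point estimate and bootstrap CI)",
                  y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
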