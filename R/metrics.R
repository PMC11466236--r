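#' Cross-lagged expected-influence centrality
#'
#' Out-EI of a node is the signed sum of its outgoing cross-lagged edge
#' weights; in-EI is the signed sum of its incoming cross-lagged weights.
#' Autoregressive (diagonal) edges are excluded from both, so the column
#' sums of out-EI and in-EI are identical (both equal the total off-diagonal
#' weight). Set `absolute = TRUE` for a strength-style variant using
#' absolute weights.
#'
#' @param net A `clpn_fit`.
#' @param absolute Use absolute edge weights instead of signed sums.
#' @return A tibble with `node_id`, `community`, `out_ei`, `in_ei`,
#'   `rank_out`, `rank_in` (rank 1 = largest value).
#' @export
expected_influence <- function(net, absolute = FALSE) {
  stopifnot(inherits(net, "clpn_fit"))
  W <- net$W
  diag(W) <- 0
  if (absolute) W <- abs(W)
  out_ei <- rowSums(W)
  in_ei <- colSums(W)
  tibble::tibble(
    node_id = net$catalog$node_id,
    community = net$catalog$community,
    out_ei = unname(out_ei),
    in_ei = unname(in_ei),
    rank_out = rank(-out_ei, ties.method = "min"),
    rank_in = rank(-in_ei, ties.method = "min"))
}

#' Strongest bridge edges between symptom communities
#'
#' Returns the cross-community directed edges from the `from` communities to
#' the `to` communities, ranked by absolute weight (descending; ties broken
#' lexicographically by from/to node id), truncated to `top_k`. Edges with
#' zero weight are dropped.
#'
#' @param net A `clpn_fit`.
#' @param from,to Character vectors of community labels.
#' @param top_k Maximum number of edges to return (default all).
#' @return A tibble with `from`, `to`, `weight`, `from_community`,
#'   `to_community`.
#' @export
#' @examples
#' truth <- default_ground_truth()
#' boys <- cross_lagged_network(truth$groups$boys$B, truth$catalog)
#' bridge_edges(boys, from = "NSSI", to = c("DEP", "ANX"), top_k = 3)
bridge_edges <- function(net, from, to, top_k = Inf) {
  stopifnot(inherits(net, "clpn_fit"))
  comms <- unique(net$catalog$community)
  bad <- setdiff(c(from, to), comms)
  if (length(bad) > 0 || length(from) == 0 || length(to) == 0) {
    rlang::abort("empty or unknown community selection",
                 class = "clpnet_input_error")
  }
  if (top_k < 1) {
    rlang::abort("top_k must be >= 1", class = "clpnet_input_error")
  }
  ed <- tidy.clpn_fit(net)
  ed <- ed[ed$from_community %in% from & ed$to_community %in% to &
             ed$from_community != ed$to_community & ed$weight != 0, ]
  ed <- ed[order(-abs(ed$weight), ed$from, ed$to), ]
  utils::head(ed[, c("from", "to", "weight", "from_community",
                     "to_community")], n = top_k)
}

#' Threshold a network's edges for display
#'
#' Keeps edges with `|weight| > min_abs` (strict inequality), preserving
#' sign and direction. The default 0.06 mirrors the usual display rule for
#' CLPN figures.
#'
#' @param net A `clpn_fit`.
#' @param min_abs Non-negative display threshold (default 0.06).
#' @return A tibble of retained edges (`from`, `to`, `weight`, `edge_type`,
#'   communities), ordered by `|weight|` descending with lexicographic
#'   tie-breaks.
#' @export
threshold_edges <- function(net, min_abs = 0.06) {
  stopifnot(inherits(net, "clpn_fit"))
  if (min_abs < 0) {
    rlang::abort("min_abs must be >= 0", class = "clpnet_input_error")
  }
  ed <- tidy.clpn_fit(net)
  ed <- ed[abs(ed$weight) > min_abs, ]
  ed[order(-abs(ed$weight), ed$from, ed$to), ]
}

#' Compare two fitted networks sharing a catalog
#'
#' Computes the Pearson correlation between the vectorized off-diagonal
#' (cross-lagged) weights, the percentage of each network's nonzero edges
#' that are also nonzero in the other, and the Jaccard similarity index over
#' directed nonzero edges. By default two edges match for the Jaccard count
#' only if they have the same direction AND the same sign
#' (`match = "sign"`); `match = "direction"` ignores sign.
#'
#' @param netA,netB `clpn_fit` objects over the same catalog.
#' @param match Jaccard edge-identity rule: `"sign"` (default) or
#'   `"direction"`.
#' @return A one-row tibble: `edge_correlation`, `overlap_pct_A_in_B`,
#'   `overlap_pct_B_in_A`, `jaccard`, `n_nonzero_A`, `n_nonzero_B`. Overlap
#'   and Jaccard are `NA` when a network has no nonzero edges.
#' @export
compare_networks <- function(netA, netB, match = c("sign", "direction")) {
  stopifnot(inherits(netA, "clpn_fit"), inherits(netB, "clpn_fit"))
  match <- match.arg(match)
  if (!identical(netA$catalog$node_id, netB$catalog$node_id)) {
    rlang::abort("networks do not share a catalog",
                 class = "clpnet_input_error")
  }
  WA <- netA$W; WB <- netB$W
  off <- row(WA) != col(WA)
  a <- WA[off]; b <- WB[off]
  edge_correlation <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    NA_real_
  } else stats::cor(a, b)

  nzA <- a != 0; nzB <- b != 0
  n_nonzero_A <- sum(nzA); n_nonzero_B <- sum(nzB)
  overlap_pct_A_in_B <- if (n_nonzero_A == 0) NA_real_ else {
    100 * sum(nzA & nzB) / n_nonzero_A
  }
  overlap_pct_B_in_A <- if (n_nonzero_B == 0) NA_real_ else {
    100 * sum(nzA & nzB) / n_nonzero_B
  }
  union_n <- sum(nzA | nzB)
  shared <- if (match == "sign") {
    sum(nzA & nzB & sign(a) == sign(b))
  } else {
    sum(nzA & nzB)
  }
  jaccard <- if (n_nonzero_A == 0 || n_nonzero_B == 0) {
    NA_real_   # undefined against an empty network
  } else shared / union_n

  tibble::tibble(edge_correlation = edge_correlation,
                 overlap_pct_A_in_B = overlap_pct_A_in_B,
                 overlap_pct_B_in_A = overlap_pct_B_in_A,
                 jaccard = jaccard,
                 n_nonzero_A = n_nonzero_A, n_nonzero_B = n_nonzero_B)
}

#' Write a fitted network to JSON
#'
#' Serializes the catalog, weight matrix, covariate coefficients,
#' intercepts and selected penalties; read back with [read_network_json()].
#'
#' @param net A `clpn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "clpn_fit"))
  obj <- list(
    catalog = tibble::as_tibble(net$catalog),
    W = unname(net$W),
    covariate_coefs = if (is.null(net$covariate_coefs)) NULL else {
      list(names = rownames(net$covariate_coefs),
           values = unname(net$covariate_coefs))
    },
    intercepts = as.numeric(net$intercepts),
    lambda_selected = as.numeric(net$lambda_selected),
    n_subjects = if (is.na(net$n_subjects)) NULL else net$n_subjects,
    config = if (is.null(net$config)) NULL else unclass(net$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted network from JSON
#'
#' @param path Path written by [write_network_json()].
#' @return A `clpn_fit`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  catalog <- symptom_catalog(obj$catalog)
  covariate_coefs <- NULL
  if (!is.null(obj$covariate_coefs)) {
    covariate_coefs <- matrix(unlist(obj$covariate_coefs$values),
                              nrow = length(obj$covariate_coefs$names),
                              byrow = FALSE)
    dimnames(covariate_coefs) <- list(obj$covariate_coefs$names,
                                      catalog$node_id)
  }
  cfg <- NULL
  if (!is.null(obj$config)) {
    cfg <- do.call(clpn_config, obj$config[names(obj$config) %in%
                                             names(formals(clpn_config))])
  }
  cross_lagged_network(
    as.matrix(obj$W), catalog,
    covariate_coefs = covariate_coefs,
    intercepts = if (length(obj$intercepts)) {
      stats::setNames(obj$intercepts, catalog$node_id)
    } else NULL,
    lambda_selected = if (length(obj$lambda_selected)) {
      stats::setNames(obj$lambda_selected, catalog$node_id)
    } else NULL,
    config = cfg,
    n_subjects = if (is.null(obj$n_subjects)) NA_integer_ else obj$n_subjects)
}

#' Export a thresholded network to GraphML
#'
#' Writes the directed network retained by [threshold_edges()] with `weight`
#' and `sign` edge attributes (negative edges flagged), plus node community
#' attributes, for use in external graph tools.
#'
#' @param net A `clpn_fit`.
#' @param path Output `.graphml` path.
#' @param min_abs Display threshold passed to [threshold_edges()].
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, min_abs = 0.06) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    rlang::abort("GraphML export requires the igraph package")
  }
  ed <- threshold_edges(net, min_abs)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = ed$from, to = ed$to, weight = ed$weight,
                   sign = ifelse(ed$weight < 0, "negative", "positive")),
    directed = TRUE,
    vertices = data.frame(name = net$catalog$node_id,
                          label = net$catalog$label,
                          community = net$catalog$community))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Lollipop chart of expected-influence centrality
#'
#' @param net A `clpn_fit`.
#' @param measure `"out_ei"` (default) or `"in_ei"`.
#' @param absolute Passed to [expected_influence()].
#' @return A ggplot.
#' @export
plot_centrality <- function(net, measure = c("out_ei", "in_ei"),
                            absolute = FALSE) {
  measure <- match.arg(measure)
  ei <- expected_influence(net, absolute = absolute)
  ei$node_id <- factor(ei$node_id,
                       levels = ei$node_id[order(ei[[measure]])])
  ggplot2::ggplot(ei, ggplot2::aes(x = .data[[measure]], y = .data$node_id,
                                   colour = .data$community)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data[[measure]],
                                       yend = .data$node_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = if (measure == "out_ei") {
      "cross-lagged out expected influence"
    } else "cross-lagged in expected influence", y = NULL) +
    ggplot2::theme_minimal()
}
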