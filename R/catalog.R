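#' Build a symptom catalog
#'
#' A symptom catalog is an ordered tibble of symptom nodes. Node order is
#' fixed and defines the row/column indexing of every weight matrix
#' downstream, so two objects built from the same catalog are always
#' index-compatible.
#'
#' @param nodes A data frame with columns `node_id`, `label`, `community`
#'   (one of `"NSSI"`, `"DEP"`, `"ANX"`), and optionally `scale_min`,
#'   `scale_max` (defaults 0 and 4).
#' @return A tibble of class `symptom_catalog` with columns `node_id`,
#'   `label`, `community`, `scale_min`, `scale_max`.
#' @export
#' @examples
#' cat24 <- default_catalog()
#' dplyr::count(cat24, community)
symptom_catalog <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("node_id", "label", "community")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("catalog is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "clpnet_schema_error")
  }
  if (!"scale_min" %in% names(nodes)) nodes$scale_min <- 0L
  if (!"scale_max" %in% names(nodes)) nodes$scale_max <- 4L
  nodes <- nodes[, c("node_id", "label", "community", "scale_min", "scale_max")]
  nodes$node_id <- as.character(nodes$node_id)
  nodes$label <- as.character(nodes$label)
  nodes$community <- as.character(nodes$community)
  nodes$scale_min <- as.integer(nodes$scale_min)
  nodes$scale_max <- as.integer(nodes$scale_max)
  if (anyDuplicated(nodes$node_id)) {
    rlang::abort("catalog node_id values must be unique",
                 class = "clpnet_validation_error")
  }
  bad <- setdiff(unique(nodes$community), c("NSSI", "DEP", "ANX"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown community label(s): ",
                        paste(bad, collapse = ", ")),
                 class = "clpnet_validation_error")
  }
  if (any(nodes$scale_min >= nodes$scale_max)) {
    rlang::abort("scale_min must be < scale_max for every node",
                 class = "clpnet_validation_error")
  }
  class(nodes) <- c("symptom_catalog", class(nodes))
  nodes
}

#' Default 24-node catalog (12 NSSI behaviors, 6 depression, 6 anxiety items)
#'
#' Node codes are N1--N12 (NSSI behavior frequency items), D1--D6 (BSI
#' depression subscale) and A1--A6 (BSI anxiety subscale), all on a 0--4
#' ordinal response scale. Items whose wording is established in the
#' literature carry a descriptive label; the rest carry placeholder labels
#' and can be overridden with a user catalog (see [read_catalog()]).
#'
#' @return A `symptom_catalog` tibble with 24 rows.
#' @export
default_catalog <- function() {
  labels <- c(
    N1 = "NSSI item 1", N2 = "NSSI item 2", N3 = "NSSI item 3",
    N4 = "NSSI item 4", N5 = "self-hitting", N6 = "self-biting",
    N7 = "NSSI item 7", N8 = "NSSI item 8", N9 = "self-cutting",
    N10 = "NSSI item 10", N11 = "rubbing skin", N12 = "carving",
    D1 = "indifference", D2 = "feeling blue", D3 = "depression item 3",
    D4 = "loneliness", D5 = "depression item 5", D6 = "worthlessness",
    A1 = "anxiety item 1", A2 = "anxiety item 2", A3 = "anxiety item 3",
    A4 = "feeling scared", A5 = "anxiety item 5", A6 = "feeling tension"
  )
  symptom_catalog(tibble::tibble(
    node_id = names(labels),
    label = unname(labels),
    community = rep(c("NSSI", "DEP", "ANX"), c(12L, 6L, 6L))
  ))
}

#' Read a symptom catalog from a YAML or JSON file
#'
#' The file holds a list of `{node_id, label, community}` records (plus
#' optional `scale_min`/`scale_max`), in node order.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` catalog file.
#' @return A `symptom_catalog` tibble.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("catalog file not found: ", path),
                 class = "clpnet_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.data.frame(raw)) return(symptom_catalog(raw))
  symptom_catalog(dplyr::bind_rows(lapply(raw, tibble::as_tibble)))
}

#' Number of assessed cross-lagged edges in a catalog
#'
#' A cross-lagged panel network over `n` symptoms has `n^2 - n` directed
#' cross-lagged (off-diagonal) edges; the 24-node default catalog yields 552.
#'
#' @param catalog A `symptom_catalog`.
#' @return Integer count of off-diagonal directed edges.
#' @export
#' @examples
#' count_cross_lagged_edges(default_catalog())  # 552
count_cross_lagged_edges <- function(catalog) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  n <- nrow(catalog)
  if (n == 0) {
    rlang::abort("catalog is empty", class = "clpnet_input_error")
  }
  as.integer(n^2 - n)
}

# internal: community membership lookup in catalog order
catalog_communities <- function(catalog) {
  stats::setNames(catalog$community, catalog$node_id)
}
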