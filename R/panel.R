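#' Construct a two-wave panel dataset from a data frame
#'
#' A `clpn_panel` is a tibble with one row per retained subject and columns
#' `subject_id`, `gender` (0 = boy, 1 = girl), and `t1_<node>`/`t2_<node>`
#' integer scores for every catalog node. Rows with missing or out-of-range
#' scores are flagged as incomplete and kept aside (listwise deletion), never
#' silently dropped: the flagged rows and counts travel with the object.
#'
#' @param data A data frame with the columns described above.
#' @param catalog A [symptom_catalog()]; defaults to [default_catalog()].
#' @param flagged Optional tibble of rows excluded by listwise deletion
#'   (used internally by [read_panel_csv()]).
#' @return A tibble of class `clpn_panel` containing the analysis set, with
#'   attributes `catalog`, `flagged` (excluded rows + reason) and `n_read`
#'   (rows seen before listwise deletion).
#' @export
as_clpn_panel <- function(data, catalog = default_catalog(), flagged = NULL) {
  data <- tibble::as_tibble(data)
  cols <- panel_columns(catalog)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("panel is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "clpnet_schema_error")
  }
  data <- data[, cols]
  data$subject_id <- as.character(data$subject_id)
  g <- data$gender
  if (any(is.na(g)) || !all(g %in% c(0, 1))) {
    bad <- which(is.na(g) | !(g %in% c(0, 1)))[1]
    rlang::abort(paste0("unknown gender code in row ", bad,
                        " (expected 0 = boy, 1 = girl)"),
                 class = "clpnet_validation_error")
  }
  data$gender <- as.integer(g)
  score_cols <- setdiff(cols, c("subject_id", "gender"))
  for (cl in score_cols) {
    v <- data[[cl]]
    if (any(is.na(v)) || any(v != round(v))) {
      bad <- which(is.na(v) | v != round(v))[1]
      rlang::abort(paste0("non-integer or missing score in column ", cl,
                          ", row ", bad),
                   class = "clpnet_validation_error")
    }
    rng <- node_range(catalog, sub("^t[12]_", "", cl))
    if (any(v < rng[1] | v > rng[2])) {
      bad <- which(v < rng[1] | v > rng[2])[1]
      rlang::abort(paste0("out-of-range score in column ", cl, ", row ", bad),
                   class = "clpnet_validation_error")
    }
    data[[cl]] <- as.integer(v)
  }
  flagged <- if (is.null(flagged)) {
    tibble::tibble(row = integer(), subject_id = character(),
                   reason = character())
  } else {
    tibble::as_tibble(flagged)
  }
  structure(data,
            catalog = catalog,
            flagged = flagged,
            n_read = nrow(data) + nrow(flagged),
            class = c("clpn_panel", class(data)))
}

panel_columns <- function(catalog) {
  c("subject_id", "gender",
    paste0("t1_", catalog$node_id), paste0("t2_", catalog$node_id))
}

node_range <- function(catalog, node_id) {
  i <- match(node_id, catalog$node_id)
  c(catalog$scale_min[i], catalog$scale_max[i])
}

#' Read a two-wave panel CSV
#'
#' Expects the wide format `subject_id, gender, t1_<node>..., t2_<node>...`
#' with a header. A missing required column raises a schema error naming the
#' column; a non-numeric or fractional score raises a validation error with
#' its row index; rows with blank or out-of-range scores are flagged
#' incomplete and excluded from the analysis set (listwise deletion), with
#' counts recorded on the returned object.
#'
#' @param path Path to a CSV file.
#' @param catalog A [symptom_catalog()]; defaults to [default_catalog()].
#' @return A `clpn_panel` (see [as_clpn_panel()]).
#' @export
read_panel_csv <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("panel file not found: ", path),
                 class = "clpnet_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  cols <- panel_columns(catalog)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("panel is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "clpnet_schema_error")
  }
  raw <- raw[, cols]
  score_cols <- setdiff(cols, c("subject_id", "gender"))

  g <- suppressWarnings(as.numeric(raw$gender))
  if (any(!is.na(raw$gender) & is.na(g)) ||
      any(!is.na(g) & !(g %in% c(0, 1)))) {
    bad <- which((!is.na(raw$gender) & is.na(g)) |
                   (!is.na(g) & !(g %in% c(0, 1))))[1]
    rlang::abort(paste0("unknown gender code in row ", bad,
                        " (expected 0 = boy, 1 = girl)"),
                 class = "clpnet_validation_error")
  }

  incomplete <- is.na(g)
  parsed <- list()
  for (cl in score_cols) {
    ch <- raw[[cl]]
    v <- suppressWarnings(as.numeric(ch))
    garbled <- !is.na(ch) & ch != "" & is.na(v)
    if (any(garbled)) {
      rlang::abort(paste0("non-numeric score in column ", cl, ", row ",
                          which(garbled)[1]),
                   class = "clpnet_validation_error")
    }
    fractional <- !is.na(v) & v != round(v)
    if (any(fractional)) {
      rlang::abort(paste0("non-integer score in column ", cl, ", row ",
                          which(fractional)[1]),
                   class = "clpnet_validation_error")
    }
    rng <- node_range(catalog, sub("^t[12]_", "", cl))
    incomplete <- incomplete | is.na(v) | v < rng[1] | v > rng[2]
    parsed[[cl]] <- v
  }

  keep <- !incomplete
  flagged <- tibble::tibble(
    row = which(incomplete),
    subject_id = as.character(raw$subject_id[incomplete]),
    reason = "missing or out-of-range score")
  analysis <- tibble::tibble(subject_id = as.character(raw$subject_id[keep]),
                             gender = as.integer(g[keep]))
  for (cl in score_cols) analysis[[cl]] <- as.integer(parsed[[cl]][keep])
  as_clpn_panel(analysis, catalog, flagged = flagged)
}

#' Write a panel dataset to CSV
#'
#' Writes the analysis set in the canonical wide format; re-reading the file
#' with [read_panel_csv()] reproduces the panel exactly (same subjects,
#' scores, and order).
#'
#' @param data A `clpn_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(data, path) {
  stopifnot(inherits(data, "clpn_panel"))
  readr::write_csv(tibble::as_tibble(unclass_panel(data)), path)
  invisible(path)
}

unclass_panel <- function(data) {
  out <- data
  class(out) <- setdiff(class(out), "clpn_panel")
  attr(out, "catalog") <- NULL
  attr(out, "flagged") <- NULL
  attr(out, "n_read") <- NULL
  out
}

#' Extract the integer score matrix for one wave
#'
#' @param data A `clpn_panel`.
#' @param wave 1 or 2.
#' @return An `n x n_nodes` integer matrix with node ids as column names.
#' @export
score_matrix <- function(data, wave) {
  stopifnot(inherits(data, "clpn_panel"), wave %in% c(1, 2))
  catalog <- attr(data, "catalog")
  cols <- paste0("t", wave, "_", catalog$node_id)
  m <- as.matrix(tibble::as_tibble(data)[, cols])
  colnames(m) <- catalog$node_id
  storage.mode(m) <- "integer"
  m
}

#' Proportion of subjects reporting any NSSI behavior at a wave
#'
#' A subject counts as reporting NSSI if at least one NSSI-community item is
#' above the scale minimum at the given wave.
#'
#' @param data A `clpn_panel`.
#' @param wave 1 or 2.
#' @return A proportion in `[0, 1]`.
#' @export
nssi_prevalence <- function(data, wave = 1) {
  stopifnot(inherits(data, "clpn_panel"))
  if (nrow(data) == 0) {
    rlang::abort("empty dataset", class = "clpnet_input_error")
  }
  catalog <- attr(data, "catalog")
  m <- score_matrix(data, wave)
  nssi <- catalog$node_id[catalog$community == "NSSI"]
  mean(rowSums(m[, nssi, drop = FALSE] > 0) > 0)
}

# truncate (not round) a percentage to two decimals; reproduces the usual
# reporting convention of sample-accounting tables
pct2 <- function(x) floor(x * 100) / 100

#' Sample-filtering (exclusion/retention) report
#'
#' Accounts for the path from invited to analyzed subjects. Percentages are
#' truncated to two decimals.
#'
#' @param n_invited Number of invited subjects.
#' @param exclusions Named integer vector or list mapping exclusion reason to
#'   count.
#' @param analyzed The analyzed `clpn_panel`.
#' @return A list of class `exclusion_report` with fields `n_invited`,
#'   `n_excluded`, `exclusion_reasons`, `n_analyzed`, `retention_pct`,
#'   `gender_counts`, `pct_boys`.
#' @export
#' @examples
#' sim <- simulate_panel(default_ground_truth(), n_subjects = 50, seed = 1)
#' # pretend 2 more subjects were invited but dropped out
#' # exclusion_report(52, c(dropout = 2), sim$data)
exclusion_report <- function(n_invited, exclusions, analyzed) {
  stopifnot(inherits(analyzed, "clpn_panel"))
  exclusions <- unlist(exclusions)
  n_excluded <- sum(exclusions)
  if (n_invited < n_excluded) {
    rlang::abort("n_invited is smaller than the total exclusions",
                 class = "clpnet_consistency_error")
  }
  n_analyzed <- nrow(analyzed)
  if (n_analyzed != n_invited - n_excluded) {
    rlang::abort(paste0("inconsistent counts: ", n_invited, " invited - ",
                        n_excluded, " excluded != ", n_analyzed, " analyzed"),
                 class = "clpnet_consistency_error")
  }
  gender_counts <- c(`0` = sum(analyzed$gender == 0L),
                     `1` = sum(analyzed$gender == 1L))
  structure(list(
    n_invited = as.integer(n_invited),
    n_excluded = as.integer(n_excluded),
    exclusion_reasons = exclusions,
    n_analyzed = as.integer(n_analyzed),
    retention_pct = pct2(100 * n_analyzed / n_invited),
    gender_counts = gender_counts,
    pct_boys = pct2(100 * gender_counts[["0"]] / n_analyzed)
  ), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion/retention report\n")
  cat("  invited: ", x$n_invited, "  excluded: ", x$n_excluded,
      "  analyzed: ", x$n_analyzed, "\n", sep = "")
  if (length(x$exclusion_reasons) > 0) {
    for (r in names(x$exclusion_reasons)) {
      cat("    - ", r, ": ", x$exclusion_reasons[[r]], "\n", sep = "")
    }
  }
  cat("  retention: ", sprintf("%.2f%%", x$retention_pct),
      "   boys: ", sprintf("%.2f%%", x$pct_boys),
      " (", x$gender_counts[["0"]], "/", x$n_analyzed, ")\n", sep = "")
  invisible(x)
}

#' @export
print.clpn_panel <- function(x, ...) {
  catalog <- attr(x, "catalog")
  flagged <- attr(x, "flagged")
  cat("Two-wave symptom panel: ", nrow(x), " subjects x ",
      nrow(catalog), " symptoms (", nrow(flagged),
      " row(s) flagged incomplete)\n", sep = "")
  NextMethod()
}
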