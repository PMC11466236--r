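#' @keywords internal
write_manifest <- function(out_dir, stage, inputs, seed, config) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("clpnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    inputs = inputs,
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Simulate a panel and write it to disk
#'
#' Wraps [simulate_panel()]: writes the panel CSV, the ground-truth JSON
#' side-file, and a run manifest; logs prevalence and group counts to
#' standard error.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [ground_truth_spec()] (default [default_ground_truth()]).
#' @param n_subjects Number of subjects (default 884).
#' @param seed Master integer seed (required).
#' @return Invisibly, a list with the written paths and the `clpn_sim`.
#' @export
run_simulate <- function(out_dir, spec = default_ground_truth(),
                         n_subjects = 884, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(spec, n_subjects, seed)
  panel_path <- file.path(out_dir, "panel.csv")
  truth_path <- file.path(out_dir, "ground_truth.json")
  write_panel_csv(sim$data, panel_path)
  write_ground_truth(spec, truth_path)
  prev <- nssi_prevalence(sim$data, wave = 1)
  message(sprintf("simulated %d subjects (%s); any-NSSI wave-1 prevalence %.1f%%",
                  n_subjects,
                  paste(names(table(sim$group_assignment)),
                        table(sim$group_assignment),
                        sep = "=", collapse = ", "),
                  100 * prev))
  write_manifest(out_dir, "simulate",
                 inputs = list(n_subjects = n_subjects),
                 seed = seed,
                 config = list(groups = names(spec$groups),
                               group_mix = as.list(spec$group_mix)))
  invisible(list(panel = panel_path, truth = truth_path, sim = sim))
}

#' Run the full CLPN analysis pipeline on a panel
#'
#' Mirrors the usual reporting order of a two-wave symptom-network study:
#' whole-sample network (gender as covariate), gender-specific networks,
#' expected-influence centrality, bridge-edge rankings (NSSI to
#' depression/anxiety, and anxiety to depression), similarity indices
#' between the gender networks, and (optionally) bootstrap edge intervals.
#' All artifacts are written to `out_dir` together with a manifest.
#'
#' @param panel A `clpn_panel` or a path to a panel CSV.
#' @param out_dir Output directory.
#' @param config A [clpn_config()].
#' @param bootstrap Optional [boot_config()]; `NULL` (default) skips the
#'   bootstrap stage.
#' @param display_threshold Display rule for the thresholded edge lists
#'   (default 0.06, strict).
#' @return Invisibly, a list with the fitted networks, centrality tables,
#'   bridge tables and comparison row.
#' @export
run_analyze <- function(panel, out_dir, config = clpn_config(),
                        bootstrap = NULL, display_threshold = 0.06) {
  if (is.character(panel)) panel <- read_panel_csv(panel)
  stopifnot(inherits(panel, "clpn_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  total <- fit_clpn(panel, config)
  boys <- fit_clpn(panel, config, group_filter = "boys")
  girls <- fit_clpn(panel, config, group_filter = "girls")
  fits <- list(total = total, boys = boys, girls = girls)

  for (nm in names(fits)) {
    write_network_json(fits[[nm]], file.path(out_dir,
                                             paste0("network_", nm, ".json")))
    readr::write_csv(threshold_edges(fits[[nm]], display_threshold),
                     file.path(out_dir, paste0("edges_", nm, ".csv")))
  }
  centrality <- purrr::imap(fits, function(f, nm) {
    dplyr::mutate(expected_influence(f), network = nm, .before = 1)
  })
  readr::write_csv(dplyr::bind_rows(centrality),
                   file.path(out_dir, "centrality.csv"))

  bridges <- purrr::imap(fits, function(f, nm) {
    dplyr::bind_rows(
      dplyr::mutate(bridge_edges(f, "NSSI", c("DEP", "ANX"), top_k = 3),
                    network = nm, bridge = "NSSI->DEP/ANX", .before = 1),
      dplyr::mutate(bridge_edges(f, "ANX", "DEP", top_k = 3),
                    network = nm, bridge = "ANX->DEP", .before = 1))
  })
  readr::write_csv(dplyr::bind_rows(bridges),
                   file.path(out_dir, "bridges.csv"))

  comparison <- compare_networks(boys, girls)
  jsonlite::write_json(as.list(comparison),
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)

  boot <- NULL
  if (!is.null(bootstrap)) {
    boot <- bootstrap_edge_cis(panel, config, bootstrap)
    readr::write_csv(boot$table, file.path(out_dir, "edge_cis.csv"))
  }

  summary_lines <- c(
    "CLPN analysis summary",
    sprintf("analysis set: %d subjects (%d boys / %d girls)",
            nrow(panel), sum(panel$gender == 0), sum(panel$gender == 1)),
    sprintf("whole-sample: %d/%d nonzero cross-lagged edges; mean |auto| %.3f, mean |cross| %.3f",
            edge_summary(total)$n_nonzero_cross,
            edge_summary(total)$n_cross_edges,
            edge_summary(total)$mean_abs_auto,
            edge_summary(total)$mean_abs_cross),
    sprintf("boys:  mean |auto| %.3f, mean |cross| %.3f",
            edge_summary(boys)$mean_abs_auto,
            edge_summary(boys)$mean_abs_cross),
    sprintf("girls: mean |auto| %.3f, mean |cross| %.3f",
            edge_summary(girls)$mean_abs_auto,
            edge_summary(girls)$mean_abs_cross),
    sprintf("boys vs girls: edge correlation %.3f, overlap (girls in boys) %.2f%%, Jaccard %.3f",
            comparison$edge_correlation, comparison$overlap_pct_B_in_A,
            comparison$jaccard))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  write_manifest(out_dir, "analyze",
                 inputs = list(n_subjects = nrow(panel)),
                 seed = config$cv_seed,
                 config = list(estimation = unclass(config),
                               bootstrap = if (is.null(bootstrap)) {
                                 NULL
                               } else unclass(bootstrap)))
  invisible(list(fits = fits, centrality = centrality, bridges = bridges,
                 comparison = comparison, bootstrap = boot))
}

#' Compare two serialized networks
#'
#' Reads two network JSON files (see [write_network_json()]), checks that
#' they share a catalog, and returns the similarity indices.
#'
#' @param pathA,pathB Paths to network JSON files.
#' @param out Optional path for a comparison JSON.
#' @return The one-row comparison tibble (see [compare_networks()]).
#' @export
run_compare <- function(pathA, pathB, out = NULL) {
  netA <- read_network_json(pathA)
  netB <- read_network_json(pathB)
  comparison <- compare_networks(netA, netB)
  message(sprintf("edge correlation %.3f; overlap A-in-B %.2f%%, B-in-A %.2f%%; Jaccard %.3f",
                  comparison$edge_correlation,
                  comparison$overlap_pct_A_in_B,
                  comparison$overlap_pct_B_in_A,
                  comparison$jaccard))
  if (!is.null(out)) {
    jsonlite::write_json(as.list(comparison), out, auto_unbox = TRUE,
                         digits = NA)
  }
  comparison
}
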