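#' Group-level generative parameters for a two-wave symptom panel
#'
#' The generative family is a latent multivariate normal with threshold
#' discretization: wave-1 latent scores are drawn from `t1_latent_corr`
#' (unit-variance marginals), wave-2 latents follow the linear cross-lagged
#' model `eta2 = t(B) %*% eta1 + noise`, and each latent is cut into the
#' ordinal 0--4 scale by per-node thresholds.
#'
#' @param B `n_nodes x n_nodes` weight matrix on the standardized latent
#'   scale; entry `[i, j]` is the effect of wave-1 node `i` on wave-2 node
#'   `j`, the diagonal holds autoregressive effects.
#' @param t1_latent_corr Symmetric positive-definite correlation matrix for
#'   the wave-1 latents.
#' @param thresholds `n_nodes x scale_max` matrix of strictly increasing
#'   cut-points per node; a latent value above the k-th cut-point scores at
#'   least k.
#' @param noise_sd Residual standard deviation of the wave-2 latents
#'   (default 1 on the standardized latent scale).
#' @return A list of class `group_params`.
#' @export
group_params <- function(B, t1_latent_corr, thresholds, noise_sd = 1) {
  B <- as.matrix(B)
  t1_latent_corr <- as.matrix(t1_latent_corr)
  thresholds <- as.matrix(thresholds)
  p <- nrow(B)
  if (ncol(B) != p || !all(is.finite(B))) {
    rlang::abort("B must be a finite square matrix",
                 class = "clpnet_parameter_error")
  }
  if (!isTRUE(all.equal(t1_latent_corr, t(t1_latent_corr))) ||
      any(abs(diag(t1_latent_corr) - 1) > 1e-8)) {
    rlang::abort("t1_latent_corr must be symmetric with unit diagonal",
                 class = "clpnet_parameter_error")
  }
  ch <- tryCatch(chol(t1_latent_corr), error = function(e) NULL)
  if (is.null(ch)) {
    rlang::abort("t1_latent_corr is not positive-definite",
                 class = "clpnet_parameter_error")
  }
  if (nrow(thresholds) != p ||
      any(apply(thresholds, 1, function(r) any(diff(r) <= 0)))) {
    rlang::abort("thresholds must have one strictly increasing row per node",
                 class = "clpnet_parameter_error")
  }
  if (noise_sd <= 0) {
    rlang::abort("noise_sd must be > 0", class = "clpnet_parameter_error")
  }
  structure(list(B = B, t1_latent_corr = t1_latent_corr,
                 thresholds = thresholds, noise_sd = noise_sd,
                 chol_corr = ch),
            class = "group_params")
}

#' Ground-truth specification for the panel simulator
#'
#' @param catalog A [symptom_catalog()].
#' @param groups Named list of [group_params()] (at most two groups; group
#'   order maps to the gender code 0, 1).
#' @param group_mix Positive weights per group (normalized to proportions).
#' @return A list of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(catalog, groups, group_mix = NULL) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  if (length(groups) < 1 || length(groups) > 2 || is.null(names(groups))) {
    rlang::abort("groups must be a named list of one or two group_params",
                 class = "clpnet_parameter_error")
  }
  p <- nrow(catalog)
  for (g in names(groups)) {
    if (!inherits(groups[[g]], "group_params") ||
        nrow(groups[[g]]$B) != p) {
      rlang::abort(paste0("group '", g, "' is not a valid group_params of ",
                          "dimension ", p),
                   class = "clpnet_parameter_error")
    }
  }
  if (is.null(group_mix)) {
    group_mix <- stats::setNames(rep(1, length(groups)), names(groups))
  }
  if (any(group_mix <= 0) || !setequal(names(group_mix), names(groups))) {
    rlang::abort("group_mix must be positive weights named after the groups",
                 class = "clpnet_parameter_error")
  }
  group_mix <- group_mix[names(groups)] / sum(group_mix)
  structure(list(catalog = catalog, groups = groups, group_mix = group_mix),
            class = "ground_truth_spec")
}

# P(any of k equicorrelated(rho) standard normals exceeds tau)
prob_any_exceeds <- function(tau, rho, k) {
  f <- function(z) {
    stats::dnorm(z) *
      stats::pnorm((tau - sqrt(rho) * z) / sqrt(1 - rho))^k
  }
  1 - stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
}

#' First-threshold calibration for zero-inflated NSSI items
#'
#' Solves for the common first cut-point of `k` equicorrelated latent items
#' such that the probability that at least one item scores above zero equals
#' `target_prev`. Exact for an equicorrelated block regardless of its
#' correlations with other communities.
#'
#' @param target_prev Target any-item prevalence (default 0.233).
#' @param rho Within-community latent correlation (default 0.4).
#' @param k Number of items in the community (default 12).
#' @return The calibrated cut-point (scalar).
#' @export
calibrate_nssi_threshold <- function(target_prev = 0.233, rho = 0.4, k = 12) {
  stats::uniroot(function(tau) prob_any_exceeds(tau, rho, k) - target_prev,
                 interval = c(0.5, 5), tol = 1e-9)$root
}

block_corr <- function(communities, within, between) {
  p <- length(communities)
  m <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ci <- communities[i]; cj <- communities[j]
      m[i, j] <- if (i == j) 1 else if (ci == cj) within[[ci]] else {
        key <- paste(sort(c(ci, cj)), collapse = "-")
        between[[key]]
      }
    }
  }
  m
}

#' Default two-group ground truth (boys/girls cross-lagged networks)
#'
#' Encodes the study conditions the package emulates: a 24-symptom catalog;
#' boys' network with strong negative lagged paths from self-cutting (N9) to
#' feeling blue (D2, -0.57), feeling tension (A6, -0.52) and indifference
#' (D1, -0.49), plus A6 -> D2 (0.23) and A4 -> D6 (0.14); girls' network
#' with A4 -> D1/D4/D6 (0.16/0.14/0.14) and carving/rubbing (N12/N11) ->
#' indifference D1 (-0.31/-0.21); autoregressive diagonals 0.12 (boys) and
#' 0.17 (girls); all other cross-lagged entries zero. Group mix 403:481.
#' NSSI thresholds are calibrated so any-NSSI wave-1 prevalence is 0.233.
#'
#' @param nssi_prev Target any-NSSI prevalence at wave 1 (default 0.233).
#' @return A `ground_truth_spec` with groups `boys` and `girls`.
#' @export
default_ground_truth <- function(nssi_prev = 0.233) {
  catalog <- default_catalog()
  p <- nrow(catalog)
  ids <- catalog$node_id
  corr <- block_corr(catalog$community,
                     within = list(NSSI = 0.4, DEP = 0.5, ANX = 0.5),
                     between = list(`DEP-NSSI` = 0.15, `ANX-NSSI` = 0.15,
                                    `ANX-DEP` = 0.3))
  tau <- calibrate_nssi_threshold(nssi_prev, rho = 0.4, k = 12)
  thr <- matrix(NA_real_, p, 4)
  nssi <- catalog$community == "NSSI"
  thr[nssi, ] <- matrix(tau + c(0, 0.7, 1.4, 2.1), sum(nssi), 4, byrow = TRUE)
  thr[!nssi, ] <- matrix(c(0.25, 1.15, 2.0, 2.7), sum(!nssi), 4, byrow = TRUE)

  edge_matrix <- function(diag_w, edges) {
    B <- matrix(0, p, p, dimnames = list(ids, ids))
    diag(B) <- diag_w
    for (e in edges) B[e[[1]], e[[2]]] <- e[[3]]
    B
  }
  B_boys <- edge_matrix(0.12, list(
    list("N9", "D2", -0.57), list("N9", "A6", -0.52), list("N9", "D1", -0.49),
    list("A6", "D2", 0.23), list("A4", "D6", 0.14)))
  B_girls <- edge_matrix(0.17, list(
    list("A4", "D1", 0.16), list("A4", "D4", 0.14), list("A4", "D6", 0.14),
    list("N12", "D1", -0.31), list("N11", "D1", -0.21)))

  ground_truth_spec(
    catalog,
    groups = list(
      boys = group_params(B_boys, corr, thr),
      girls = group_params(B_girls, corr, thr)),
    group_mix = c(boys = 403, girls = 481))
}

#' Compact six-node ground truth for desk-scale simulations
#'
#' A single-group, six-symptom (2 NSSI / 2 DEP / 2 ANX) sparse truth with
#' moderate discretization (balanced symmetric thresholds, no
#' zero-inflation), used for fast coverage and recovery experiments.
#'
#' @return A one-group `ground_truth_spec`.
#' @export
toy_ground_truth <- function() {
  catalog <- symptom_catalog(tibble::tibble(
    node_id = c("N1", "N2", "D1", "D2", "A1", "A2"),
    label = c("NSSI item 1", "NSSI item 2", "depression item 1",
              "depression item 2", "anxiety item 1", "anxiety item 2"),
    community = c("NSSI", "NSSI", "DEP", "DEP", "ANX", "ANX")))
  ids <- catalog$node_id
  corr <- block_corr(catalog$community,
                     within = list(NSSI = 0.4, DEP = 0.5, ANX = 0.5),
                     between = list(`DEP-NSSI` = 0.15, `ANX-NSSI` = 0.15,
                                    `ANX-DEP` = 0.3))
  B <- matrix(0, 6, 6, dimnames = list(ids, ids))
  diag(B) <- 0.45
  B["N1", "D1"] <- 0.35
  B["D1", "A1"] <- 0.30
  B["A2", "D2"] <- 0.25
  thr <- matrix(c(-1.5, -0.5, 0.5, 1.5), 6, 4, byrow = TRUE)
  ground_truth_spec(catalog, groups = list(all = group_params(B, corr, thr)),
                    group_mix = c(all = 1))
}

discretize_latent <- function(eta, thresholds) {
  score <- matrix(0L, nrow(eta), ncol(eta))
  for (k in seq_len(ncol(thresholds))) {
    score <- score + (eta > matrix(thresholds[, k], nrow(eta), ncol(eta),
                                   byrow = TRUE))
  }
  storage.mode(score) <- "integer"
  score
}

# deterministic sub-seed derivation: the master seed keys a stream of stage
# seeds, so group assignment, wave-1 latents and wave-2 noise are
# independently reproducible
derive_seeds <- function(master, n_stages) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n_stages)
}

#' Simulate a two-wave ordinal symptom panel from a ground truth
#'
#' For each subject: draw a group by the spec's mix, draw wave-1 latents from
#' the group's correlation matrix and discretize them to 0--4; form wave-2
#' latents as `t(B) %*% eta1` plus Gaussian noise and discretize the same
#' way. Fully deterministic given `(spec, n_subjects, seed)`.
#'
#' @param spec A [ground_truth_spec()].
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Master integer seed.
#' @param group Optional group name: simulate all subjects from that group
#'   (the group mix is ignored).
#' @return A list of class `clpn_sim` with elements `data` (a `clpn_panel`),
#'   `truth`, `group_assignment` and `seed`.
#' @export
#' @examples
#' sim <- simulate_panel(toy_ground_truth(), n_subjects = 100, seed = 7)
#' nssi_prevalence(sim$data, wave = 1)
simulate_panel <- function(spec, n_subjects, seed, group = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (n_subjects < 2) {
    rlang::abort("n_subjects must be >= 2", class = "clpnet_input_error")
  }
  p <- nrow(spec$catalog)
  gnames <- names(spec$groups)
  seeds <- derive_seeds(seed, 3)

  if (!is.null(group)) {
    if (!group %in% gnames) {
      rlang::abort(paste0("unknown group: ", group),
                   class = "clpnet_input_error")
    }
    assignment <- rep(group, n_subjects)
  } else {
    set.seed(seeds[1])
    assignment <- sample(gnames, n_subjects, replace = TRUE,
                         prob = spec$group_mix)
  }

  set.seed(seeds[2])
  Z1 <- matrix(stats::rnorm(n_subjects * p), n_subjects, p)
  set.seed(seeds[3])
  E <- matrix(stats::rnorm(n_subjects * p), n_subjects, p)

  t1 <- matrix(0L, n_subjects, p)
  t2 <- matrix(0L, n_subjects, p)
  for (g in gnames) {
    idx <- which(assignment == g)
    if (length(idx) == 0) next
    gp <- spec$groups[[g]]
    eta1 <- Z1[idx, , drop = FALSE] %*% gp$chol_corr
    eta2 <- eta1 %*% gp$B + E[idx, , drop = FALSE] * gp$noise_sd
    t1[idx, ] <- discretize_latent(eta1, gp$thresholds)
    t2[idx, ] <- discretize_latent(eta2, gp$thresholds)
  }

  gender <- match(assignment, gnames) - 1L
  df <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n_subjects)),
    gender = gender)
  for (j in seq_len(p)) df[[paste0("t1_", spec$catalog$node_id[j])]] <- t1[, j]
  for (j in seq_len(p)) df[[paste0("t2_", spec$catalog$node_id[j])]] <- t2[, j]

  structure(list(data = as_clpn_panel(df, spec$catalog),
                 truth = spec,
                 group_assignment = assignment,
                 seed = seed),
            class = "clpn_sim")
}

#' @export
print.clpn_sim <- function(x, ...) {
  cat("Simulated two-wave panel (seed ", x$seed, ")\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Serialize a ground-truth spec to JSON
#'
#' Matrices are written as nested arrays in catalog node order; the file can
#' be read back with [read_ground_truth()].
#'
#' @param spec A `ground_truth_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(spec, path) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  obj <- list(
    catalog = tibble::as_tibble(spec$catalog),
    group_mix = as.list(spec$group_mix),
    groups = lapply(spec$groups, function(gp) {
      list(B = unname(gp$B),
           t1_latent_corr = unname(gp$t1_latent_corr),
           thresholds = unname(gp$thresholds),
           noise_sd = gp$noise_sd)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth spec from JSON
#'
#' @param path Path written by [write_ground_truth()].
#' @return A `ground_truth_spec`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  catalog <- symptom_catalog(obj$catalog)
  ids <- catalog$node_id
  groups <- lapply(obj$groups, function(gp) {
    B <- as.matrix(gp$B); dimnames(B) <- list(ids, ids)
    group_params(B, as.matrix(gp$t1_latent_corr), as.matrix(gp$thresholds),
                 gp$noise_sd)
  })
  ground_truth_spec(catalog, groups, unlist(obj$group_mix))
}
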