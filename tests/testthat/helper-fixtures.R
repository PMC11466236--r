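# shared fixtures: all built in code at test time

# minimal catalogs for hand-computable cases
catalog3 <- function() {
  symptom_catalog(tibble::tibble(
    node_id = c("N1", "D1", "A1"),
    label = c("nssi one", "dep one", "anx one"),
    community = c("NSSI", "DEP", "ANX")))
}

catalog4 <- function() {
  symptom_catalog(tibble::tibble(
    node_id = c("a", "b", "c", "d"),
    label = paste("node", 1:4),
    community = c("NSSI", "DEP", "ANX", "DEP")))
}

# a random sparse directed network over a catalog
rand_network <- function(catalog = default_catalog(), density = 0.1,
                         seed = 1) {
  set.seed(seed)
  p <- nrow(catalog)
  W <- matrix(0, p, p)
  nz <- sample(p * p, max(1, round(density * p * p)))
  W[nz] <- round(stats::runif(length(nz), -1, 1), 3)
  cross_lagged_network(W, catalog)
}

# small valid hand-built panel (3 subjects, full catalog)
tiny_panel_df <- function(catalog = default_catalog(), n = 3, seed = 1) {
  set.seed(seed)
  df <- tibble::tibble(
    subject_id = paste0("S", seq_len(n)),
    gender = rep_len(c(0L, 1L), n))
  for (id in catalog$node_id) df[[paste0("t1_", id)]] <- sample(0:4, n, TRUE)
  for (id in catalog$node_id) df[[paste0("t2_", id)]] <- sample(0:4, n, TRUE)
  df
}

# qualifying ground-truth edges (|weight| >= 0.2) per group
strong_true_edges <- list(
  boys = list(c("N9", "D2"), c("N9", "A6"), c("N9", "D1"), c("A6", "D2")),
  girls = list(c("N12", "D1"), c("N11", "D1")))
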