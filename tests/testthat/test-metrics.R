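test_that("expected influence sums outgoing and incoming cross-lagged weights", {
  W <- matrix(0, 3, 3)
  W[1, ] <- c(0.5, 0.2, -0.3)   # diagonal excluded from both sums
  net <- cross_lagged_network(W, catalog3())
  ei <- expected_influence(net)
  expect_equal(ei$out_ei[ei$node_id == "N1"], -0.1)
  expect_equal(ei$in_ei[ei$node_id == "D1"], 0.2)

  zero <- expected_influence(cross_lagged_network(matrix(0, 3, 3),
                                                  catalog3()))
  expect_true(all(zero$out_ei == 0 & zero$in_ei == 0))

  truth <- default_ground_truth()
  boys <- cross_lagged_network(truth$groups$boys$B, truth$catalog)
  ei_boys <- expected_influence(boys)
  expect_equal(ei_boys$out_ei[ei_boys$node_id == "N9"],
               -0.57 - 0.52 - 0.49)
  # absolute-value variant for sensitivity analysis
  ei_abs <- expected_influence(boys, absolute = TRUE)
  expect_equal(ei_abs$out_ei[ei_abs$node_id == "N9"], 0.57 + 0.52 + 0.49)
})

test_that("total out-EI equals total in-EI on arbitrary networks", {
  for (s in 1:20) {
    net <- rand_network(density = stats::runif(1, 0.05, 0.5), seed = s)
    ei <- expected_influence(net)
    expect_equal(sum(ei$out_ei), sum(ei$in_ei))
    off <- net$W; diag(off) <- 0
    expect_equal(sum(ei$out_ei), sum(off))
  }
})

test_that("bridge ranking reproduces the ground-truth bridge ordering", {
  truth <- default_ground_truth()
  boys <- cross_lagged_network(truth$groups$boys$B, truth$catalog)
  top3 <- bridge_edges(boys, "NSSI", c("DEP", "ANX"), top_k = 3)
  expect_equal(top3$from, c("N9", "N9", "N9"))
  expect_equal(top3$to, c("D2", "A6", "D1"))
  expect_equal(top3$weight, c(-0.57, -0.52, -0.49))

  girls <- cross_lagged_network(truth$groups$girls$B, truth$catalog)
  top2 <- bridge_edges(girls, "NSSI", c("DEP", "ANX"), top_k = 2)
  expect_equal(top2$from, c("N12", "N11"))
  expect_equal(top2$to, c("D1", "D1"))
  expect_equal(top2$weight, c(-0.31, -0.21))

  # anxiety-to-depression bridges for boys
  ad <- bridge_edges(boys, "ANX", "DEP", top_k = 2)
  expect_equal(ad$from, c("A6", "A4"))
  expect_equal(ad$weight, c(0.23, 0.14))

  none <- cross_lagged_network(diag(0.3, 24), truth$catalog)
  expect_equal(nrow(bridge_edges(none, "NSSI", c("DEP", "ANX"))), 0)
  expect_error(bridge_edges(boys, character(0), "DEP"),
               class = "clpnet_input_error")
})

test_that("display thresholding is strict and sign-preserving", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- 0.06; W[1, 3] <- 0.061; W[2, 3] <- -0.2
  net <- cross_lagged_network(W, catalog3())
  kept <- threshold_edges(net, 0.06)
  expect_equal(nrow(kept), 2)
  expect_equal(sort(kept$weight), c(-0.2, 0.061))
  expect_equal(nrow(threshold_edges(net, 0)), 3)
  expect_equal(nrow(threshold_edges(cross_lagged_network(matrix(0, 3, 3),
                                                         catalog3()), 0)), 0)
  expect_error(threshold_edges(net, -0.1), class = "clpnet_input_error")
})

test_that("bridge and within-community edges partition the nonzero edge set", {
  for (s in c(2, 5)) {
    net <- rand_network(density = 0.15, seed = s)
    comms <- unique(net$catalog$community)
    bridges <- bridge_edges(net, comms, comms, top_k = Inf)
    all_edges <- threshold_edges(net, 0)
    within <- all_edges[all_edges$from_community == all_edges$to_community, ]
    expect_equal(nrow(bridges) + nrow(within), nrow(all_edges))
    expect_equal(
      dplyr::arrange(dplyr::bind_rows(
        bridges[, c("from", "to", "weight")],
        within[, c("from", "to", "weight")]), from, to),
      dplyr::arrange(all_edges[, c("from", "to", "weight")], from, to))
  }
})

test_that("comparison identities hold: self, sign-flip, and a hand-counted case", {
  net <- rand_network(density = 0.2, seed = 3)
  self <- compare_networks(net, net)
  expect_equal(self$edge_correlation, 1)
  expect_equal(self$overlap_pct_A_in_B, 100)
  expect_equal(self$overlap_pct_B_in_A, 100)
  expect_equal(self$jaccard, 1)

  flip <- cross_lagged_network(-net$W, net$catalog)
  anti <- compare_networks(net, flip)
  expect_equal(anti$edge_correlation, -1)
  expect_equal(anti$overlap_pct_A_in_B, 100)
  expect_equal(anti$jaccard, 0)
  # direction-only identity ignores the sign flip
  expect_equal(compare_networks(net, flip, match = "direction")$jaccard, 1)

  # A: a->b +, b->c +, c->a +;  B: a->b +, b->c -, d->a +
  WA <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  WB <- WA
  WA["a", "b"] <- 0.5; WA["b", "c"] <- 0.4; WA["c", "a"] <- 0.3
  WB["a", "b"] <- 0.2; WB["b", "c"] <- -0.4; WB["d", "a"] <- 0.6
  cmp <- compare_networks(cross_lagged_network(WA, catalog4()),
                          cross_lagged_network(WB, catalog4()))
  expect_equal(cmp$overlap_pct_A_in_B, 100 * 2 / 3)
  expect_equal(cmp$jaccard, 0.25)
})

test_that("jaccard is symmetric while overlap percentages are not", {
  a <- rand_network(density = 0.08, seed = 11)
  b <- rand_network(density = 0.2, seed = 12)
  ab <- compare_networks(a, b)
  ba <- compare_networks(b, a)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_equal(ab$overlap_pct_A_in_B, ba$overlap_pct_B_in_A)
  expect_false(isTRUE(all.equal(ab$overlap_pct_A_in_B,
                                ab$overlap_pct_B_in_A)))
  empty <- cross_lagged_network(matrix(0, 24, 24), a$catalog)
  cmp0 <- compare_networks(a, empty)
  expect_true(is.na(cmp0$jaccard) && is.na(cmp0$overlap_pct_B_in_A))
  expect_error(compare_networks(a, rand_network(catalog3(), seed = 1)),
               class = "clpnet_input_error")
})

test_that("networks round-trip through JSON and export to GraphML", {
  sim <- simulate_panel(toy_ground_truth(), 150, seed = 2)
  fit <- fit_clpn(sim$data, clpn_config(cv_seed = 2), covariates = NULL)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(fit, path)
  back <- read_network_json(path)
  expect_equal(back$W, fit$W)
  expect_equal(back$lambda_selected, fit$lambda_selected)
  expect_equal(compare_networks(fit, back)$jaccard, 1)

  skip_if_not_installed("igraph")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(fit, gml, min_abs = 0)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), nrow(threshold_edges(fit, 0)))
  expect_s3_class(plot_centrality(fit), "ggplot")
})
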