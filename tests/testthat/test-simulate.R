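test_that("default ground truth encodes the group-specific edge weights", {
  truth <- default_ground_truth()
  B_boys <- truth$groups$boys$B
  B_girls <- truth$groups$girls$B
  expect_equal(B_boys["N9", "D2"], -0.57)
  expect_equal(B_boys["N9", "A6"], -0.52)
  expect_equal(B_boys["N9", "D1"], -0.49)
  expect_equal(B_boys["A6", "D2"], 0.23)
  expect_equal(B_boys["A4", "D6"], 0.14)
  expect_equal(B_girls["A4", "D1"], 0.16)
  expect_equal(B_girls["A4", "D4"], 0.14)
  expect_equal(B_girls["A4", "D6"], 0.14)
  expect_equal(B_girls["N12", "D1"], -0.31)
  expect_equal(B_girls["N11", "D1"], -0.21)
  expect_true(all(diag(B_boys) == 0.12))
  expect_true(all(diag(B_girls) == 0.17))
  # all unlisted off-diagonal entries are zero
  listed_boys <- rbind(c("N9", "D2"), c("N9", "A6"), c("N9", "D1"),
                       c("A6", "D2"), c("A4", "D6"))
  off <- B_boys; diag(off) <- 0; off[listed_boys] <- 0
  expect_true(all(off == 0))
  expect_equal(unname(truth$group_mix), c(403, 481) / 884)
})

test_that("generative parameter validation catches degenerate inputs", {
  cat3 <- catalog3()
  B <- diag(0.3, 3)
  corr <- diag(3)
  thr <- matrix(c(-1, 0, 1, 2), 3, 4, byrow = TRUE)
  expect_s3_class(group_params(B, corr, thr), "group_params")
  badcorr <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(group_params(B, badcorr, thr),
               class = "clpnet_parameter_error")
  expect_error(group_params(B, corr, thr[, c(2, 1, 3, 4)]),
               class = "clpnet_parameter_error")
  expect_error(group_params(B, corr, thr, noise_sd = 0),
               class = "clpnet_parameter_error")
  expect_error(
    ground_truth_spec(cat3, list(a = group_params(B, corr, thr)),
                      group_mix = c(b = 1)),
    class = "clpnet_parameter_error")
  expect_error(simulate_panel(toy_ground_truth(), 1, seed = 1),
               class = "clpnet_input_error")
})

test_that("simulation is seed-deterministic and respects the ordinal scale", {
  toy <- toy_ground_truth()
  s1 <- simulate_panel(toy, 100, seed = 7)
  s2 <- simulate_panel(toy, 100, seed = 7)
  expect_identical(tibble::as_tibble(s1$data), tibble::as_tibble(s2$data))
  expect_identical(s1$group_assignment, s2$group_assignment)
  s3 <- simulate_panel(toy, 100, seed = 8)
  expect_false(identical(tibble::as_tibble(s1$data),
                         tibble::as_tibble(s3$data)))
  m1 <- score_matrix(s1$data, 1); m2 <- score_matrix(s1$data, 2)
  expect_true(all(m1 %in% 0:4) && all(m2 %in% 0:4))
  expect_equal(dim(m1), c(100, 6))
})

test_that("identity dynamics with vanishing noise reproduce wave 1 at wave 2", {
  toy <- toy_ground_truth()
  gp <- toy$groups$all
  ident <- ground_truth_spec(
    toy$catalog,
    list(all = group_params(diag(6), gp$t1_latent_corr, gp$thresholds,
                            noise_sd = 1e-6)),
    group_mix = c(all = 1))
  sim <- simulate_panel(ident, 500, seed = 21)
  agree <- mean(score_matrix(sim$data, 1) == score_matrix(sim$data, 2))
  expect_gt(agree, 0.999)
})

test_that("raising a positive cross-lagged weight raises the lagged partial association", {
  toy <- toy_ground_truth()
  gp <- toy$groups$all
  bump <- gp$B
  bump["N1", "D1"] <- 0.6   # up from 0.35
  spec_hi <- ground_truth_spec(
    toy$catalog,
    list(all = group_params(bump, gp$t1_latent_corr, gp$thresholds)),
    group_mix = c(all = 1))
  for (seed in 1:3) {
    lo <- simulate_panel(toy, 5000, seed = seed)
    hi <- simulate_panel(spec_hi, 5000, seed = seed)
    coef_at <- function(sim) {
      std <- standardize_scores(sim$data)
      fit_node_regression(std$t2[, "D1"], std$t1,
                          lambda = 0)$coefficients[["N1"]]
    }
    expect_gt(coef_at(hi), coef_at(lo))
  }
})

test_that("group assignment maps to gender codes and can be forced", {
  truth <- default_ground_truth()
  sim <- simulate_panel(truth, 200, seed = 5)
  expect_identical(sim$data$gender,
                   as.integer(sim$group_assignment == "girls"))
  boys <- simulate_panel(truth, 50, seed = 5, group = "boys")
  expect_true(all(boys$data$gender == 0L))
  expect_error(simulate_panel(truth, 50, seed = 5, group = "men"),
               class = "clpnet_input_error")
})

test_that("ground-truth specs round-trip through JSON", {
  truth <- default_ground_truth()
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$groups$boys$B, truth$groups$boys$B)
  expect_equal(back$groups$girls$thresholds, truth$groups$girls$thresholds)
  expect_equal(back$group_mix, truth$group_mix)
  # simulation from the round-tripped spec is identical
  expect_identical(
    tibble::as_tibble(simulate_panel(back, 50, seed = 3)$data),
    tibble::as_tibble(simulate_panel(truth, 50, seed = 3)$data))
})

test_that("NSSI threshold calibration hits the target prevalence analytically", {
  tau <- calibrate_nssi_threshold(0.233, rho = 0.4, k = 12)
  # invert: the probability at the calibrated cut-point equals the target
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((tau - sqrt(0.4) * z) / sqrt(0.6))^12
  p_any <- 1 - stats::integrate(f, -8, 8)$value
  expect_equal(p_any, 0.233, tolerance = 1e-6)
})
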