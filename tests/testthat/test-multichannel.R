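test_that("channel counting uses the highest occupied level", {
  id <- new_idealization(as.character(c(0, 1, 2, 3, 4, 1, 0)), rep(0.01, 7),
                         class_labels = as.character(0:4))
  expect_equal(count_channels(id), 4L)
  expect_equal(count_channels(new_idealization(c("0", "1"), c(1, 1))), 1L)
  expect_error(count_channels(new_idealization("0", 1)), "no openings")
})

test_that("a long simulated record reveals all three channels", {
  sch <- two_state_scheme(24.5, 25.5)     # Po = 0.49
  paths <- lapply(1:3, function(i)
    sample_dwell_path(sch, 60, seed = 300 + i))
  lev <- superpose_paths(paths, conducting = "O")
  expect_equal(count_channels(lev), 3L)
})

test_that("per-channel Po is the mean fraction of open channels", {
  expect_equal(per_channel_po(c(0.125, 0.375, 0.375, 0.125), 3), 0.5)
  expect_equal(per_channel_po(c(1, 0, 0, 0, 0), 4), 0)
  expect_error(per_channel_po(c(0.6, 0.5), 1), "sum to 1")
})

test_that("binomial predictions match the closed-form pmf", {
  # Binomial(3, 0.49) evaluated by hand
  expected <- c(0.132651, 0.382347, 0.367353, 0.117649)
  bt <- binomial_test(expected, 3, n_effective = 500, p_hat = 0.49)
  expect_equal(bt$predicted, expected, tolerance = 1e-9)
  expect_equal(bt$statistic, 0, tolerance = 1e-9)
  expect_equal(bt$df, 3L)              # p supplied, no pooling
  # estimated p costs one df
  bt2 <- binomial_test(expected, 3, n_effective = 500)
  expect_equal(bt2$p_hat, 0.49, tolerance = 1e-9)
  expect_equal(bt2$df, 2L)
  # sparse upper levels get pooled
  bt3 <- binomial_test(c(0.9, 0.09, 0.009, 0.001), 3, n_effective = 200)
  expect_lt(bt3$n_cells, 4L)
})

test_that("multilevel SKM recovers a noise-free staircase exactly", {
  cls <- rep(c(1L, 2L, 3L, 4L, 3L, 2L), each = 100)
  x <- (cls - 1L) * 6.3 + rnorm(length(cls), 0, 1e-8)
  skm <- multilevel_idealize(srk_trace(x, 10000, 30), 3, 6.3)
  expect_identical(skm$path, cls)
  # a channel that never opens leaves its level empty
  cls2 <- rep(c(1L, 2L, 1L), each = 200)
  skm2 <- multilevel_idealize(srk_trace((cls2 - 1L) * 6.3 +
                                          rnorm(600, 0, 0.2), 10000, 30),
                              2, 6.3)
  occ <- level_occupancies(skm2$idealization, 2)
  expect_equal(occ[["2"]], 0)
})

test_that("decoded level occupancies track the simulator truth", {
  sch <- two_state_scheme(24.5, 25.5)
  lad <- fixture_ladder()
  sim <- simulate_multichannel(multi_channel_spec(3), sch, lad,
                               fixture_acq(), fixture_noise(), 10, seed = 71)
  tr <- preprocess(sim$trace)
  skm <- multilevel_idealize(tr, 3, 6.3)
  occ_hat <- level_occupancies(skm$idealization, 3)
  occ_true <- level_occupancies(superpose_paths(sim$true_paths,
                                                conducting = "O"), 3)
  expect_lt(max(abs(occ_hat - occ_true)), 0.03)
  p_hat <- per_channel_po(occ_hat, 3)
  expect_lt(abs(p_hat - 0.49), 0.05)
})

test_that("the independence test is calibrated on independent channels", {
  sch <- two_state_scheme(24.5, 25.5)
  pv <- vapply(1:60, function(s) {
    paths <- lapply(1:3, function(i)
      sample_dwell_path(sch, 8, seed = 1000 + 3 * s + i))
    lev <- superpose_paths(paths, conducting = "O")
    occ <- level_occupancies(lev, 3)
    binomial_test(occ, 3, n_effective = nrow(lev) - 1L)$p_value
  }, numeric(1))
  expect_lt(mean(pv < 0.05), 0.18)   # near-nominal over 60 records
  expect_gt(mean(pv < 0.05), -0.01)
})

test_that("coupled channels are detected as non-binomial", {
  rej <- vapply(1:20, function(s) {
    lev <- sample_coupled_level_path(3, duration_s = 4, seed = 400 + s)
    occ <- level_occupancies(lev, 3)
    binomial_test(occ, 3, n_effective = min(nrow(lev) - 1L, 500))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})
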