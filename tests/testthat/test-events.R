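test_that("stripping absorbs sub-resolution events into their neighbours", {
  id <- new_idealization(c("C", "O", "C"), c(0.010, 0.0004, 0.010),
                         analysis_rate = 10000)
  out <- strip_short_events(id, 0.6)
  expect_equal(nrow(out), 1L)
  expect_identical(out$class, "C")
  expect_equal(out$duration_s, 0.0204)
  # a leading short event merges into the following event
  id2 <- new_idealization(c("O", "C"), c(0.0004, 0.010),
                          analysis_rate = 10000)
  out2 <- strip_short_events(id2, 0.6)
  expect_identical(out2$class, "C")
  expect_equal(out2$duration_s, 0.0104)
  # nothing below the cutoff: identity
  id3 <- new_idealization(c("C", "O", "C"), c(0.01, 0.002, 0.005),
                          analysis_rate = 10000)
  expect_equal(strip_short_events(id3, 0.6), id3)
})

test_that("stripping conserves duration exactly and is idempotent", {
  set.seed(77)
  for (i in 1:200) {
    id <- random_idealization()
    s1 <- strip_short_events(id, 0.6)
    expect_identical(sum(round(s1$duration_s * 10000)),
                     sum(round(id$duration_s * 10000)))
    s2 <- strip_short_events(s1, 0.6)
    expect_equal(s2, s1)
    if (nrow(s1) > 1) {
      expect_true(all(s1$duration_s * 1000 >= 0.6 - 1e-9))
      expect_true(all(s1$class[-1] != s1$class[-nrow(s1)]))
    }
  }
})

test_that("channel statistics follow the occupancy definitions", {
  id <- new_idealization(c("C", "O"), c(0.05, 0.05))
  st <- compute_stats(id)
  expect_equal(st$po_total, 0.5)
  expect_equal(unname(st$p_class[["O"]]), 0.5)
  expect_equal(st$full_open_contribution_pct, 100)
  id2 <- new_idealization(c("C", "S", "O"), c(0.06, 0.02, 0.02),
                          class_labels = c("C", "S", "O"))
  st2 <- compute_stats(id2)
  expect_equal(st2$po_total, 0.4)
  expect_equal(st2$full_open_contribution_pct, 50)
  expect_equal(sum(st2$p_class), 1, tolerance = 1e-9)
  # a channel that never conducts has undefined contribution
  st3 <- compute_stats(new_idealization("C", 1, class_labels = c("C", "S", "O")))
  expect_true(is.na(st3$full_open_contribution_pct))
  expect_equal(st3$po_total, 0)
})

test_that("Po on simulator true paths matches the stationary solution", {
  p <- srk_preset("ko")
  path <- sample_dwell_path(p$scheme, 180, seed = 55)
  st <- compute_stats(path_to_idealization(path))
  bm <- batch_means_se(path, c("S", "O"))
  po_analytic <- 1 - stationary_class_occupancy(p$scheme)[["C"]]
  expect_lt(abs(st$po_total - po_analytic), 3 * bm$se)
})

test_that("KO-like gating is less open and less full-open than WT-like", {
  po <- list()
  for (nm in c("wt", "ko")) {
    path <- sample_dwell_path(srk_preset(nm)$scheme, 120, seed = 60)
    po[[nm]] <- compute_stats(path_to_idealization(path))
  }
  expect_gt(po$wt$po_total, po$ko$po_total)
  expect_gt(po$wt$full_open_contribution_pct,
            po$ko$full_open_contribution_pct)
})

test_that("the substate-transit audit counts direct C-O jumps", {
  id <- new_idealization(c("C", "S", "O", "C", "S", "O", "S", "C"),
                         rep(0.01, 8))
  expect_equal(substate_transit_fraction(id), 1 - 1 / 4)  # one direct O->C
  id2 <- new_idealization(c("C", "S", "O", "S", "C"), rep(0.01, 5))
  expect_equal(substate_transit_fraction(id2), 1)
  expect_true(is.na(substate_transit_fraction(
    new_idealization(c("C", "S"), c(0.01, 0.01)))))
})

test_that("current-voltage regression recovers the conductance", {
  v <- c(-30, -20, -10, 10, 20, 30)
  fit <- fit_iv(v, 0.211 * v)
  expect_equal(fit$conductance_pS, 211, tolerance = 1e-9)
  fit2 <- fit_iv(c(-30, 30), c(-6.3, 6.3))
  expect_equal(fit2$conductance_pS, 210, tolerance = 1e-9)
  expect_equal(fit2$intercept_pA, 0, tolerance = 1e-9)
  expect_error(fit_iv(c(30, 30), c(6.3, 6.31)), "distinct")
  # OLS is unbiased: mean slope over noisy replicates within 1% of truth
  set.seed(91)
  v7 <- seq(-30, 30, by = 10)
  slopes <- replicate(300, fit_iv(v7, 0.210 * v7 + rnorm(7, 0, 0.2))$conductance_pS)
  expect_lt(abs(mean(slopes) - 210) / 210, 0.01)
})
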