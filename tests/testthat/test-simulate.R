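test_that("path sampling is deterministic under a seed and respects topology", {
  sch <- slow_scheme()
  p1 <- sample_dwell_path(sch, 5, seed = 11)
  p2 <- sample_dwell_path(sch, 5, seed = 11)
  expect_identical(p1, p2)
  expect_equal(sum(p1$duration_s), 5)
  expect_true(p1$censored[nrow(p1)])
  # no direct C-O transitions in any sampled path
  for (s in 1:10) {
    cl <- sample_dwell_path(sch, 3, seed = s)$class
    pairs <- paste(cl[-length(cl)], cl[-1])
    expect_false(any(pairs %in% c("C O", "O C")))
  }
})

test_that("symmetric two-state rates give half occupancy", {
  sch <- two_state_scheme(100, 100)
  path <- sample_dwell_path(sch, 100, seed = 2)
  bm <- batch_means_se(path, "O")
  expect_lt(abs(bm$mean - 0.5), 3 * bm$se + 0.02)
})

test_that("empirical class occupancy converges to the null-space solution", {
  # rates solved so that stationary P(O) = 0.3
  sch <- three_state_scheme(50, 50, 300 / 7, 50)
  expect_equal(stationary_class_occupancy(sch)[["O"]], 0.3, tolerance = 1e-9)
  path <- sample_dwell_path(sch, 300, seed = 7)
  bm <- batch_means_se(path, "O")
  expect_lt(abs(bm$mean - 0.3), 3 * bm$se)
})

test_that("absorbing states are refused", {
  Q <- matrix(c(0, 0, 5, -5), 2, 2, byrow = TRUE)
  sch <- gating_scheme(Q, c("C", "O"), initial_dist = c(0.5, 0.5))
  expect_error(sample_dwell_path(sch, 1, seed = 1), "absorbing")
})

test_that("a noise-only rendered trace has the requested baseline statistics", {
  path <- data.frame(state = "C", class = "C", start_s = 0, duration_s = 10,
                     censored = TRUE)
  attr(path, "duration") <- 10
  tr <- render_trace(path, fixture_ladder(), fixture_acq(),
                     noise_spec(0.5, substate_sd = 1), seed = 4)
  expect_lt(abs(mean(tr$samples)), 0.01)
  expect_lt(abs(sd(tr$samples) - 0.5) / 0.5, 0.02)
})

test_that("the full-open level obeys Ohm's law and survives filtering", {
  # 50 ms opening flanked by closures; 210 pS at +30 mV -> 6.3 pA
  path <- data.frame(state = c("C", "O", "C"), class = c("C", "O", "C"),
                     start_s = c(0, 0.05, 0.1), duration_s = c(0.05, 0.05, 0.05),
                     censored = c(FALSE, FALSE, TRUE))
  attr(path, "duration") <- 0.15
  tr <- render_trace(path, fixture_ladder(), fixture_acq(),
                     noise_spec(1e-6, substate_sd = 1e-6), seed = 1)
  mid <- tr$samples[round(0.075 * 20000)]   # middle of the pulse
  expect_lt(abs(mid - 6.3) / 6.3, 0.001)    # 1 kHz rise time << 50 ms
  expect_lt(abs(tr$samples[100]), 1e-3)     # baseline unaffected
})

test_that("rendering and multichannel simulation are seed-deterministic", {
  lad <- fixture_ladder(); acq <- fixture_acq(); nz <- fixture_noise()
  sch <- srk_preset("ko")$scheme
  spec <- multi_channel_spec(2, "independent")
  s1 <- simulate_multichannel(spec, sch, lad, acq, nz, 2, seed = 42)
  s2 <- simulate_multichannel(spec, sch, lad, acq, nz, 2, seed = 42)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$true_paths, s2$true_paths)
})

test_that("independent channels spend (1-p)^N of the time fully closed", {
  sch <- two_state_scheme(30, 70)          # p = 0.3
  spec <- multi_channel_spec(3, "independent")
  sim <- simulate_multichannel(spec, sch, fixture_ladder(), fixture_acq(),
                               fixture_noise(), 60, seed = 9)
  lev <- superpose_paths(sim$true_paths, conducting = "O")
  occ <- level_occupancies(lev, 3)
  expect_lt(abs(occ[["0"]] - 0.7^3), 0.03)
})

test_that("facilitated mode raises per-channel Po while independent mode does not", {
  p <- srk_preset("ko")
  lad <- fixture_ladder(); acq <- fixture_acq(); nz <- fixture_noise()
  po_of <- function(spec, seed) {
    sim <- simulate_multichannel(spec, p$scheme, lad, acq, nz, 60, seed = seed)
    mean(vapply(sim$true_paths, function(pp)
      sum(pp$duration_s[pp$class != "C"]) / 60, numeric(1)))
  }
  po1 <- po_of(multi_channel_spec(1, "facilitated", p$facilitation_factor), 21)
  po4f <- po_of(multi_channel_spec(4, "facilitated", p$facilitation_factor), 22)
  po4i <- po_of(multi_channel_spec(4, "independent"), 23)
  expect_gt(po4f, 4 * po1)        # strongly elevated
  expect_lt(abs(po4i - po1), 0.06)  # independent mode: same per-channel Po
})

test_that("two-species rendering is additive with the 25% amplitude convention", {
  lad <- fixture_ladder()
  k_sch <- k_scheme_full_po(0.28, 0.02)               # conducting Po 0.3
  ryr <- two_state_scheme(20, 80)                     # Po 0.2
  acq <- fixture_acq(filter_cutoff_hz = 4000)
  sim <- simulate_multispecies(k_sch, ryr, lad, acq, fixture_noise(), 60,
                               seed = 12)
  expect_equal(sim$ryr_amplitude_pA, 4 * 6.3)         # 25.2 pA at +30 mV
  # time with both species conducting ~ product of independent Po
  kp <- sim$true_paths$k[[1]]; rp <- sim$true_paths$ryr
  k_cond <- kp$class != "C"
  both <- 0
  k_ends <- kp$start_s + kp$duration_s
  for (i in which(rp$class == "O")) {
    lo <- rp$start_s[i]; hi <- lo + rp$duration_s[i]
    ov <- pmax(pmin(k_ends, hi) - pmax(kp$start_s, lo), 0)
    both <- both + sum(ov[k_cond])
  }
  po_k_emp <- sum(kp$duration_s[k_cond]) / 60
  po_r_emp <- sum(rp$duration_s[rp$class == "O"]) / 60
  expect_lt(abs(both / 60 - po_k_emp * po_r_emp), 0.02)
  expect_lt(abs(both / 60 - 0.3 * 0.2), 0.05)
  expect_error(simulate_multispecies(k_sch, k_sch, lad, acq, fixture_noise(),
                                     1), "two-class")
})

test_that("a silent RyR leaves the trace statistically identical to K+-only", {
  lad <- fixture_ladder()
  k_sch <- slow_scheme()
  ryr_silent <- two_state_scheme(1e-9, 1e6)    # never opens in practice
  acq <- fixture_acq(filter_cutoff_hz = 4000)
  sim <- simulate_multispecies(k_sch, ryr_silent, lad, acq, fixture_noise(),
                               20, seed = 5)
  expect_true(all(sim$true_paths$ryr$class == "C"))
  kp <- sim$true_paths$k[[1]]
  expected_mean <- (sum(kp$duration_s[kp$class == "S"]) * 3.15 +
                    sum(kp$duration_s[kp$class == "O"]) * 6.3) / 20
  expect_lt(abs(mean(sim$trace$samples) - expected_mean), 0.05)
})

test_that("the coupled-gating oracle co-opens channels beyond binomial", {
  lev <- sample_coupled_level_path(3, duration_s = 20, seed = 8)
  occ <- level_occupancies(lev, 3)
  p <- per_channel_po(occ, 3)
  # modal switching inflates the extreme levels relative to Binomial(3, p)
  expect_gt(occ[["0"]] + occ[["3"]],
            dbinom(0, 3, p) + dbinom(3, 3, p) + 0.05)
})
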