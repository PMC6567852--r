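test_that("preprocessing leaves a constant trace unchanged and halves its length", {
  tr <- srk_trace(rep(6.3, 20000), 20000, 30)
  out <- preprocess(tr, 1000, 10000)
  expect_equal(length(out$samples), 10000)
  expect_equal(out$samples, rep(6.3, 10000), tolerance = 1e-9)
  expect_equal(out$sampling_rate_hz, 10000)
  # odd length decimates to ceiling(n/2)
  tr_odd <- srk_trace(rep(1, 20001), 20000, 30)
  expect_equal(length(preprocess(tr_odd)$samples), 10001)
  expect_error(preprocess(tr, 1000, 40000), "exceeds")
  expect_error(preprocess(tr, 12000, 10000), "Nyquist")
})

test_that("filtered white noise SD matches the coefficient-sum oracle", {
  coefs <- gaussian_fir_coefs(1000, 20000)
  expect_equal(sum(coefs), 1, tolerance = 1e-12)
  expected_ratio <- sqrt(sum(coefs^2))   # independent oracle for SD shrinkage
  set.seed(31)
  x <- rnorm(4e5)
  tr <- preprocess(srk_trace(x, 20000, 30), 1000, 20000)
  expect_lt(abs(sd(tr$samples) - expected_ratio) / expected_ratio, 0.02)
})

test_that("segmental k-means recovers a noise-free square wave exactly", {
  cls <- rep(rep(c(1L, 2L), 10), each = 50)
  x <- c(0, 6.3)[cls] + rnorm(length(cls), 0, 1e-8)
  tr <- srk_trace(x, 10000, 30)
  skm <- skm_idealize(tr, class_means = c(0.5, 5), class_labels = c("C", "O"),
                      constraint = "none")
  expect_identical(skm$path, cls)
  expect_equal(nrow(skm$idealization), 20L)
})

test_that("SKM agrees with exhaustive path enumeration on tiny traces", {
  set.seed(17)
  for (case in 1:25) {
    n <- sample(6:10, 1)
    mu <- sort(runif(3, -4, 4))
    mu <- mu + c(0, 1, 2)              # enforce separation
    sg <- runif(3, 0.4, 1.2)
    truth <- sample(1:3, n, replace = TRUE)
    x <- mu[truth] + rnorm(n, 0, sg[truth])
    skm <- skm_idealize(srk_trace(x, 1), class_means = mu, class_sds = sg,
                        constraint = "none")
    oracle <- enumerate_best_path(x, skm$emission$mean, skm$emission$sd,
                                  log(skm$trans_probs), skm$log_init)
    expect_identical(skm$path, as.integer(oracle$path))
  }
})

test_that("SKM keeps the substate constraint exactly and improves the likelihood", {
  path <- sample_dwell_path(slow_scheme(), 10, seed = 23)
  tr <- preprocess(render_trace(path, fixture_ladder(), fixture_acq(),
                                fixture_noise(), seed = 24))
  skm <- skm_idealize(tr, class_means = c(0, 3.15, 6.3),
                      constraint = "substate")
  em <- skm$emission
  expect_identical(em$mean[2], (em$mean[1] + em$mean[3]) / 2)
  expect_identical(em$sd[2], 0.5 * (em$mean[2] - em$mean[1]))
  expect_true(all(diff(em$mean) > 0))      # C < S < O ordering
  # joint log-likelihood non-decreasing across iterations (tiny slack for
  # the transition-count smoothing)
  ll <- skm$loglik
  if (length(ll) > 1)
    expect_true(all(diff(ll) > -1e-4 * abs(ll[-length(ll)])))
  expect_true(skm$converged)
})

test_that("idealization accuracy on realistic traces exceeds 95 percent", {
  path <- sample_dwell_path(slow_scheme(), 20, seed = 31)
  tr <- preprocess(render_trace(path, fixture_ladder(), fixture_acq(),
                                fixture_noise(0.6), seed = 32))
  skm <- skm_idealize(tr, class_means = c(0, 3.15, 6.3),
                      constraint = "substate")
  truth <- sample_true_classes(path, 10000)
  expect_gt(mean(decoded_classes(skm$idealization) == truth), 0.95)
})

test_that("half-amplitude threshold idealization works on clean and noisy traces", {
  # noise-free alternation: Po equals the duty cycle exactly
  x <- rep(rep(c(0, 25.2), times = c(300, 100)), 10)
  tr <- srk_trace(x, 10000, 30)
  id <- threshold_idealize(tr, 0, 25.2)
  st <- compute_stats(id)
  expect_equal(st$po_total, 0.25, tolerance = 1e-12)
  # everywhere below the midpoint: one all-closed event
  id2 <- threshold_idealize(srk_trace(rep(1, 1000), 10000, 30), 0, 25.2)
  expect_equal(nrow(id2), 1L)
  expect_identical(id2$class, "C")
  expect_error(threshold_idealize(tr, 5, 5), "differ")
  # simulated RyR-like trace at Po 0.2, amplitude 25.2, SD 1
  ryr <- two_state_scheme(20, 80)
  p <- sample_dwell_path(ryr, 30, seed = 41)
  lad <- structure(list(g_full_pS = 840, holding_mV = 30,
                        class_amplitudes = c(C = 0, S = 12.6, O = 25.2)),
                   class = "conductance_ladder")
  tr3 <- render_trace(p, lad, fixture_acq(filter_cutoff_hz = 4000),
                      noise_spec(1, substate_sd = 1), seed = 42)
  po_true <- sum(p$duration_s[p$class == "O"]) / 30
  po_est <- compute_stats(threshold_idealize(tr3, 0, 25.2))$po_total
  expect_lt(abs(po_est - po_true), 0.02)
})
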