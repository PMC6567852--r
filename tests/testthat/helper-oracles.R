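# Independent oracles and shared fixtures for the test suite.

# Exhaustive maximum-likelihood path: enumerates all K^n class paths and
# scores the same joint likelihood the decoder maximizes. Only usable for
# tiny traces; deliberately independent of the package's dynamic program.
enumerate_best_path <- function(x, means, sds, logtrans, loginit) {
  n <- length(x)
  K <- length(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logemis <- vapply(seq_len(K), function(k) dnorm(x, means[k], sds[k], log = TRUE),
                    numeric(n))
  ll <- loginit[paths[, 1L]]
  for (t in seq_len(n)) ll <- ll + logemis[t, ][paths[, t]]
  for (t in 2:n) ll <- ll + logtrans[cbind(paths[, t - 1L], paths[, t])]
  best <- which.max(ll)
  list(path = unname(paths[best, ]), loglik = ll[best])
}

# Batch-means standard error of a time-average computed from an event path.
batch_means_se <- function(path, target_class, n_batches = 10) {
  dur <- attr(path, "duration")
  edges <- seq(0, dur, length.out = n_batches + 1)
  ends <- path$start_s + path$duration_s
  po <- vapply(seq_len(n_batches), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    overlap <- pmax(pmin(ends, hi) - pmax(path$start_s, lo), 0)
    sum(overlap[path$class %in% target_class]) / (hi - lo)
  }, numeric(1))
  list(mean = mean(po), se = sd(po) / sqrt(n_batches))
}

# Standard single-channel recording fixtures at +30 mV.
fixture_ladder <- function() conductance_ladder(210, 30)
fixture_noise <- function(baseline = 0.6)
  noise_spec(baseline, ladder = fixture_ladder())
fixture_acq <- function(...) acquisition_spec(...)

# Scheme with mean dwells well above the 2 ms resolution limit, used for
# idealization-accuracy checks.
slow_scheme <- function() three_state_scheme(20, 60, 40, 25)

# K+ scheme with chosen full-open and (brief) substate stationary occupancy;
# multispecies records are filtered at 4 kHz where substates are poorly
# resolved, so generators for those scenarios keep substate dwells short and
# rare, as in the recordings the composite level model was designed for.
k_scheme_full_po <- function(po_o, po_s = 0.02, rate_scale = 1) {
  pc <- 1 - po_o - po_s
  b <- 200 * rate_scale; c <- 800 * rate_scale
  a <- b * po_s / pc
  d <- c * po_s / po_o
  three_state_scheme(a, b, c, d)
}

# Random idealization for stripping properties.
random_idealization <- function(n_events = 40, rate = 10000) {
  k <- sample(2:3, 1)
  labels <- c("C", "S", "O")[seq_len(k)]
  cl <- sample(labels, n_events, replace = TRUE)
  d <- sample(1:40, n_events, replace = TRUE) / rate   # 0.1 to 4 ms at 10 kHz
  new_idealization(cl, d, analysis_rate = rate, class_labels = labels)
}

# Per-sample class sequence of a decoded idealization on its analysis grid.
decoded_classes <- function(ideal) {
  rate <- attr(ideal, "analysis_rate")
  rep(ideal$class, round(ideal$duration_s * rate))
}
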