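#' Sample a gating path from a scheme
#'
#' Draws a continuous-time Markov path: dwell times are exponential with rate
#' `-Q[i,i]` and the successor state is drawn proportionally to `Q[i,j]`. The
#' final dwell is truncated at `duration_s` and flagged as censored.
#'
#' @param scheme a `gating_scheme`.
#' @param duration_s path duration in seconds (> 0).
#' @param seed optional integer seed; identical seeds give identical paths.
#' @return A data.frame with columns `state`, `class`, `start_s`,
#'   `duration_s`, `censored`, carrying attributes `duration` and
#'   `class_order`.
#' @export
sample_dwell_path <- function(scheme, duration_s, seed = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"),
            is_scalar_number(duration_s), duration_s > 0)
  with_seed(seed, sample_dwell_path_(scheme, duration_s))
}

# Samples from the current RNG stream (internal; lets composite simulators
# draw several paths plus noise from one seeded stream).
sample_dwell_path_ <- function(scheme, duration_s) {
  Q <- scheme$Q
  K <- nrow(Q)
  lam <- -diag(Q)
  if (any(lam <= 0))
    stop("absorbing state in Q: every state needs a positive exit rate")
  jump <- Q
  diag(jump) <- 0
  jump <- jump / lam
  n_guess <- max(64L, as.integer(ceiling(duration_s * max(lam) * 1.3)) + 16L)
  st <- integer(n_guess); dw <- numeric(n_guess)
  s <- sample.int(K, 1L, prob = scheme$initial_dist)
  t <- 0; i <- 0L
  while (t < duration_s) {
    i <- i + 1L
    if (i > length(st)) {
      st <- c(st, integer(length(st)))
      dw <- c(dw, numeric(length(dw)))
    }
    d <- rexp(1L, lam[s])
    st[i] <- s
    dw[i] <- d
    t <- t + d
    if (t < duration_s) s <- sample.int(K, 1L, prob = jump[s, ])
  }
  st <- st[seq_len(i)]; dw <- dw[seq_len(i)]
  censored <- c(rep(FALSE, i - 1L), TRUE)
  dw[i] <- dw[i] - (t - duration_s)   # truncate at the record end
  starts <- cumsum(c(0, dw[-i]))
  out <- data.frame(state = scheme$state_ids[st],
                    class = scheme$classes[st],
                    start_s = starts, duration_s = dw,
                    censored = censored, stringsAsFactors = FALSE)
  attr(out, "duration") <- duration_s
  attr(out, "class_order") <- scheme$class_order
  out
}

# Class label of each sample at `rate` Hz for a dwell path.
path_sample_classes <- function(path, rate) {
  dur <- attr(path, "duration") %||% sum(path$duration_s)
  n <- as.integer(round(dur * rate))
  ends <- cumsum(path$duration_s)
  counts <- diff(c(0L, as.integer(round(ends * rate))))
  counts[counts < 0L] <- 0L
  cls <- rep(path$class, counts)
  length(cls) <- n                      # guard against rounding at the tail
  if (anyNA(cls)) cls[is.na(cls)] <- path$class[nrow(path)]
  cls
}

#' Ground-truth class of every sample
#'
#' Samples a dwell path on the digitizer grid, giving the true conductance
#' class of each sample of a rendered trace. Used to score idealization
#' accuracy against simulator truth.
#'
#' @param path a dwell path from [sample_dwell_path()].
#' @param rate sampling rate in Hz.
#' @return character vector of class labels, one per sample.
#' @export
sample_true_classes <- function(path, rate) path_sample_classes(path, rate)

#' Render a gating path into a noisy digitized trace
#'
#' The noiseless class-amplitude waveform is Gaussian-filtered at the
#' recording cutoff (so event edges have the finite rise time of the
#' acquisition chain) and Gaussian noise with the class SD — baseline for the
#' closed and full-open classes, the larger substate SD while in S — is added
#' at the digitization rate.
#'
#' @param path a dwell path from [sample_dwell_path()].
#' @param ladder a `conductance_ladder`.
#' @param acq an `acquisition_spec`.
#' @param noise a `noise_spec`.
#' @param seed optional integer seed.
#' @return An `srk_trace` at the digitization rate.
#' @export
render_trace <- function(path, ladder, acq, noise, seed = NULL) {
  stopifnot(inherits(ladder, "conductance_ladder"),
            inherits(acq, "acquisition_spec"), inherits(noise, "noise_spec"))
  with_seed(seed, render_trace_(path, ladder, acq, noise))
}

render_trace_ <- function(path, ladder, acq, noise) {
  fs <- acq$digitization_rate_hz
  if (acq$filter_cutoff_hz >= fs / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  cls <- path_sample_classes(path, fs)
  mu <- unname(ladder$class_amplitudes[cls])
  mu <- apply_fir(mu, gaussian_fir_coefs(acq$filter_cutoff_hz, fs))
  sdv <- ifelse(cls == "S", noise$substate_sd, noise$baseline_sd)
  srk_trace(mu + rnorm(length(mu)) * sdv, fs, ladder$holding_mV)
}

#' Multichannel simulation settings
#'
#' In `independent` mode every channel gates from the base scheme. In
#' `facilitated` mode the opening rates of every channel are scaled by
#' `facilitation_factor^(n_channels - 1)` before simulation; channels still
#' gate on independent random streams (rate scaling only, no state coupling),
#' so level occupancies remain binomial at the shifted per-channel open
#' probability.
#'
#' @param n_channels integer >= 1.
#' @param mode `"independent"` or `"facilitated"`.
#' @param facilitation_factor dimensionless multiplier >= 1.
#' @return An object of class `multi_channel_spec`.
#' @export
multi_channel_spec <- function(n_channels = 1L,
                               mode = c("independent", "facilitated"),
                               facilitation_factor = 1) {
  mode <- match.arg(mode)
  stopifnot(is_scalar_number(n_channels), n_channels >= 1,
            n_channels == round(n_channels),
            is_scalar_number(facilitation_factor), facilitation_factor >= 1)
  structure(list(n_channels = as.integer(n_channels), mode = mode,
                 facilitation_factor = facilitation_factor),
            class = "multi_channel_spec")
}

#' Simulate a bilayer containing several identical channels
#'
#' Channels gate independently (after any facilitation rate scaling); their
#' filtered unitary currents are summed and one shared additive Gaussian
#' noise process (a single amplifier/bilayer noise source) is overlaid. The
#' per-channel ground-truth paths are retained.
#'
#' @param spec a `multi_channel_spec`.
#' @param scheme base single-channel `gating_scheme`.
#' @param ladder a `conductance_ladder`.
#' @param acq an `acquisition_spec`.
#' @param noise a `noise_spec`.
#' @param duration_s record duration in seconds.
#' @param seed optional integer seed; rendering twice with the same seed and
#'   specs is bit-identical.
#' @return A list of class `srk_sim` with elements `trace`, `true_paths`
#'   (one dwell path per channel), `scheme_used`, `spec` and `seed`.
#' @export
simulate_multichannel <- function(spec, scheme, ladder, acq, noise,
                                  duration_s, seed = NULL) {
  stopifnot(inherits(spec, "multi_channel_spec"),
            inherits(scheme, "gating_scheme"))
  s <- if (spec$mode == "facilitated")
    spec$facilitation_factor^(spec$n_channels - 1L) else 1
  sch <- if (s != 1) scale_opening_rates(scheme, s) else scheme
  with_seed(seed, {
    paths <- lapply(seq_len(spec$n_channels), function(i)
      sample_dwell_path_(sch, duration_s))
    fs <- acq$digitization_rate_hz
    if (acq$filter_cutoff_hz >= fs / 2)
      stop("filter cutoff must be below the Nyquist frequency")
    n <- as.integer(round(duration_s * fs))
    mu <- numeric(n)
    var_extra <- numeric(n)
    dv <- max(noise$substate_sd^2 - noise$baseline_sd^2, 0)
    for (p in paths) {
      cls <- path_sample_classes(p, fs)
      mu <- mu + unname(ladder$class_amplitudes[cls])
      var_extra <- var_extra + dv * (cls == "S")
    }
    mu <- apply_fir(mu, gaussian_fir_coefs(acq$filter_cutoff_hz, fs))
    sdv <- sqrt(noise$baseline_sd^2 + var_extra)
    trace <- srk_trace(mu + rnorm(n) * sdv, fs, ladder$holding_mV)
    structure(list(trace = trace, true_paths = paths, scheme_used = sch,
                   spec = spec, seed = seed),
              class = "srk_sim")
  })
}

#' Simulate a bilayer containing K+ channels and one ryanodine receptor
#'
#' Currents are additive: each K+ channel contributes its class amplitude and
#' the RyR contributes `ryr_amplitude_pA` while open (default four times the
#' K+ full-open amplitude, matching the observation that the K+ full-open
#' current is about 25% of the RyR open current). Ground-truth paths for each
#' species are retained.
#'
#' @param k_schemes list of `gating_scheme`s, one per K+ channel (>= 1).
#' @param ryr_scheme a two-class `gating_scheme` for the single RyR.
#' @param ladder a `conductance_ladder` for the K+ channels.
#' @param acq an `acquisition_spec`; mixed-species records are conventionally
#'   filtered at 4 kHz to resolve RyR events.
#' @param noise a `noise_spec`.
#' @param duration_s record duration (s).
#' @param ryr_amplitude_pA RyR open-level amplitude; default
#'   `4 * amplitude(O)`.
#' @param seed optional integer seed.
#' @return An `srk_sim` with `true_paths$k` (list) and `true_paths$ryr`.
#' @export
simulate_multispecies <- function(k_schemes, ryr_scheme, ladder, acq, noise,
                                  duration_s, ryr_amplitude_pA = NULL,
                                  seed = NULL) {
  if (inherits(k_schemes, "gating_scheme")) k_schemes <- list(k_schemes)
  if (length(k_schemes) < 1L) stop("at least one K+ channel is required")
  if (!inherits(ryr_scheme, "gating_scheme") ||
      length(unique(ryr_scheme$classes)) != 2L)
    stop("exactly one two-class RyR scheme is supported")
  amp_o <- ladder$class_amplitudes[["O"]]
  if (is.null(ryr_amplitude_pA)) ryr_amplitude_pA <- 4 * amp_o
  if (abs(ryr_amplitude_pA) <= abs(amp_o))
    stop("the RyR open amplitude must exceed the K+ full-open amplitude")
  with_seed(seed, {
    k_paths <- lapply(k_schemes, sample_dwell_path_, duration_s = duration_s)
    ryr_path <- sample_dwell_path_(ryr_scheme, duration_s)
    fs <- acq$digitization_rate_hz
    n <- as.integer(round(duration_s * fs))
    mu <- numeric(n)
    var_extra <- numeric(n)
    dv <- max(noise$substate_sd^2 - noise$baseline_sd^2, 0)
    for (p in k_paths) {
      cls <- path_sample_classes(p, fs)
      mu <- mu + unname(ladder$class_amplitudes[cls])
      var_extra <- var_extra + dv * (cls == "S")
    }
    ryr_cls <- path_sample_classes(ryr_path, fs)
    mu <- mu + ryr_amplitude_pA * (ryr_cls == "O")
    mu <- apply_fir(mu, gaussian_fir_coefs(acq$filter_cutoff_hz, fs))
    sdv <- sqrt(noise$baseline_sd^2 + var_extra)
    trace <- srk_trace(mu + rnorm(n) * sdv, fs, ladder$holding_mV)
    structure(list(trace = trace,
                   true_paths = list(k = k_paths, ryr = ryr_path),
                   ryr_amplitude_pA = ryr_amplitude_pA, seed = seed),
              class = "srk_sim")
  })
}

#' Exact superposition of per-channel paths into a level path
#'
#' Combines the ground-truth dwell paths of several channels into the exact
#' occupancy-level path (number of channels in a conducting class at each
#' instant), without sampling error.
#'
#' @param paths list of dwell paths.
#' @param conducting classes counted as conducting (default `c("S", "O")`).
#' @return An `srk_idealization` whose classes are `"0" ... "N"`.
#' @export
superpose_paths <- function(paths, conducting = c("S", "O")) {
  stopifnot(length(paths) >= 1L)
  dur <- attr(paths[[1L]], "duration") %||% sum(paths[[1L]]$duration_s)
  times <- 0
  deltas <- 0
  level0 <- 0L
  for (p in paths) {
    cond <- p$class %in% conducting
    level0 <- level0 + as.integer(cond[1L])
    chg <- which(diff(cond) != 0L) + 1L
    if (length(chg)) {
      times <- c(times, p$start_s[chg])
      deltas <- c(deltas, ifelse(cond[chg], 1L, -1L))
    }
  }
  ord <- order(times)
  times <- times[ord]; deltas <- deltas[ord]
  lev <- cumsum(deltas)          # times[1] == 0 with delta 0 -> lev[1] == 0
  lev <- lev + level0
  dwell <- diff(c(times, dur))
  keep <- dwell > 0
  new_idealization(class = as.character(lev[keep]), duration_s = dwell[keep],
                   analysis_rate = NA_real_,
                   class_labels = as.character(0:length(paths)))
}

#' Modal coupled-gating level generator (cooperativity oracle)
#'
#' Reference generator of explicitly coupled channels used to check the power
#' of the binomial independence test: all channels share a hidden gating mode
#' that switches between a low and a high open probability, so channels
#' co-open and their level occupancies are overdispersed relative to the
#' binomial prediction at the marginal open probability. Simulated as a
#' discrete-time chain on a fine grid.
#'
#' @param n_channels number of channels.
#' @param po_low,po_high per-channel open probability in the two modes.
#' @param mode_switch_hz switching rate between modes (each direction).
#' @param channel_tau_s per-channel gating relaxation time (s).
#' @param duration_s record duration (s).
#' @param dt_s time step (s), default 1 ms.
#' @param seed optional integer seed.
#' @return An `srk_idealization` of the occupancy-level path, classes
#'   `"0" ... "N"`.
#' @export
sample_coupled_level_path <- function(n_channels, po_low = 0.18, po_high = 0.8,
                                      mode_switch_hz = 5, channel_tau_s = 0.02,
                                      duration_s = 4, dt_s = 1e-3, seed = NULL) {
  stopifnot(n_channels >= 1, po_low > 0, po_low < 1, po_high > 0, po_high < 1)
  with_seed(seed, {
    n_steps <- as.integer(round(duration_s / dt_s))
    p_switch <- mode_switch_hz * dt_s
    mode <- integer(n_steps)        # 0 = low, 1 = high
    mode[1L] <- rbinom(1L, 1L, 0.5)
    flips <- runif(n_steps) < p_switch
    for (t in 2:n_steps) mode[t] <- if (flips[t]) 1L - mode[t - 1L] else mode[t - 1L]
    p_open <- ifelse(mode == 1L, po_high, po_low)
    # per-channel two-state chain: opening prob p/tau*dt, closing (1-p)/tau*dt
    open_pr <- pmin(p_open / channel_tau_s * dt_s, 1)
    close_pr <- pmin((1 - p_open) / channel_tau_s * dt_s, 1)
    states <- matrix(0L, n_steps, n_channels)
    states[1L, ] <- rbinom(n_channels, 1L, p_open[1L])
    u <- matrix(runif(n_steps * n_channels), n_steps, n_channels)
    for (t in 2:n_steps) {
      prev <- states[t - 1L, ]
      pr <- ifelse(prev == 1L, 1 - close_pr[t], open_pr[t])
      states[t, ] <- as.integer(u[t, ] < pr)
    }
    lev <- rowSums(states)
    r <- rle(lev)
    new_idealization(class = as.character(r$values),
                     duration_s = r$lengths * dt_s,
                     analysis_rate = 1 / dt_s,
                     class_labels = as.character(0:n_channels))
  })
}
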