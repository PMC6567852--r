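#' Count channels from a level idealization
#'
#' The number of channels in a bilayer is taken as the highest occupied open
#' level — in practice established during a maximal-activation segment at
#' strongly positive potentials at the end of an experiment; in simulation
#' any sufficiently long segment serves.
#'
#' @param ideal an `srk_idealization` whose classes are occupancy levels
#'   `"0", "1", ...`.
#' @return integer channel count.
#' @export
count_channels <- function(ideal) {
  stopifnot(inherits(ideal, "srk_idealization"))
  lev <- suppressWarnings(as.integer(ideal$class))
  if (anyNA(lev)) stop("classes must be numeric occupancy levels")
  n <- max(lev)
  if (n < 1L) stop("no openings observed; channel count undefined")
  n
}

#' Time-weighted occupancy of each level
#'
#' @param ideal an `srk_idealization` with numeric level classes.
#' @param n_channels number of channels N; occupancies are returned for
#'   levels `0..N`.
#' @return named numeric vector `P_0 ... P_N` summing to 1.
#' @export
level_occupancies <- function(ideal, n_channels) {
  stopifnot(inherits(ideal, "srk_idealization"), n_channels >= 1L)
  lev <- suppressWarnings(as.integer(ideal$class))
  if (anyNA(lev) || any(lev < 0L) || any(lev > n_channels))
    stop("classes must be levels within 0..n_channels")
  p <- vapply(0:n_channels, function(k)
    sum(ideal$duration_s[lev == k]), numeric(1))
  p <- p / sum(p)
  names(p) <- as.character(0:n_channels)
  p
}

#' Idealize a multichannel record over equally spaced levels
#'
#' Segmental k-means over the N+1 occupancy levels of N identical channels
#' (substate classes are omitted in multichannel records, where the merged
#' sublevel cannot be resolved between channels). Level classes are labelled
#' `"0" ... "N"`.
#'
#' @param trace an `srk_trace` (preprocessed).
#' @param n_channels number of channels N (>= 2).
#' @param unit_amplitude_pA single-channel full-open amplitude in pA.
#' @param baseline_pA zero-current level (default 0).
#' @param ... further arguments to [skm_idealize()].
#' @return An `srk_skm` whose idealization has level classes.
#' @export
multilevel_idealize <- function(trace, n_channels, unit_amplitude_pA,
                                baseline_pA = 0, ...) {
  stopifnot(n_channels >= 2L)
  means <- baseline_pA + (0:n_channels) * unit_amplitude_pA
  skm_idealize(trace, class_means = means,
               class_labels = as.character(0:n_channels),
               constraint = "none", ...)
}

#' Per-channel open probability from level occupancies
#'
#' The mean fraction of channels open: `p_hat = sum(k * P_k) / N`.
#'
#' @param occupancies occupancy vector `P_0 ... P_N` (sums to 1).
#' @param n_channels number of channels N.
#' @return per-channel open probability.
#' @export
per_channel_po <- function(occupancies, n_channels) {
  if (n_channels < 1) stop("n_channels must be at least 1")
  if (length(occupancies) != n_channels + 1L)
    stop("need one occupancy per level 0..N")
  if (abs(sum(occupancies) - 1) > 1e-6)
    stop("occupancies must sum to 1")
  sum((0:n_channels) * occupancies) / n_channels
}

#' Binomial independence test on level occupancies
#'
#' Compares observed level occupancies with the Binomial(N, p) prediction for
#' independent identical channels. The deviation statistic is a chi-square
#' over levels computed on an effective number of independent observations,
#' taken as the number of dwell-level transition events (not samples, which
#' are autocorrelated).
#'
#' Time-averaged occupancies of N independently gating two-state channels are
#' not a plain multinomial sample: the occupancy residual decomposes into the
#' orthogonal-polynomial (Krawtchouk) modes of the binomial weight, and the
#' mode of degree m relaxes m times faster than a single channel, so its
#' variance relative to the multinomial value at `n_effective` draws is
#' `4 N p (1 - p) / m`. The statistic scales each squared mode accordingly,
#' restoring the nominal chi-square null (exactly, in the two-state
#' independent limit). Estimating p from the same record removes the
#' degree-1 mode, leaving `N - 1` degrees of freedom (`N` when `p_hat` is
#' supplied). When any expected count falls below 5 the classical pooled
#' cell-count chi-square is used instead (approximate, conservative for
#' occupancy data near p = 1/2).
#'
#' @param observed occupancy vector `P_0 ... P_N`.
#' @param n_channels number of channels N.
#' @param n_effective effective number of independent dwell events.
#' @param p_hat per-channel open probability; estimated from `observed` via
#'   [per_channel_po()] when `NULL`.
#' @return A list of class `srk_binom_test`: `observed`, `predicted`,
#'   `p_hat`, `p_estimated`, `statistic`, `df`, `p_value`, `n_effective`,
#'   `method`.
#' @export
binomial_test <- function(observed, n_channels, n_effective, p_hat = NULL) {
  stopifnot(is_scalar_number(n_effective), n_effective > 0)
  if (length(observed) != n_channels + 1L)
    stop("need one occupancy per level 0..N")
  N <- as.integer(n_channels)
  p_estimated <- is.null(p_hat)
  if (p_estimated) p_hat <- per_channel_po(observed, N)
  predicted <- dbinom(0:N, N, p_hat)
  out <- list(observed = observed, predicted = predicted, p_hat = p_hat,
              p_estimated = p_estimated, n_effective = n_effective)
  if (min(predicted * n_effective) >= 5 && p_hat > 0 && p_hat < 1) {
    # mode-calibrated statistic on the full level vector
    r <- observed - predicted
    phi <- krawtchouk_basis(N, predicted)
    u <- as.numeric(crossprod(phi, r))
    m_first <- if (p_estimated) 3L else 2L   # columns are degrees 0..N
    m_idx <- seq.int(m_first, N + 1L)
    degrees <- m_idx - 1L
    ratio <- 4 * N * p_hat * (1 - p_hat) / degrees
    statistic <- n_effective * sum(u[m_idx]^2 / ratio)
    df <- length(m_idx)
    out$method <- "mode"
    out$n_cells <- N + 1L
  } else {
    # sparse levels: classical pooled cell-count chi-square
    obs_cnt <- observed * n_effective
    exp_cnt <- predicted * n_effective
    while (length(exp_cnt) > 2L && min(exp_cnt) < 5) {
      i <- which.min(exp_cnt)
      j <- if (i == 1L) 2L
           else if (i == length(exp_cnt)) i - 1L
           else if (exp_cnt[i - 1L] <= exp_cnt[i + 1L]) i - 1L else i + 1L
      lo <- min(i, j); hi <- max(i, j)
      exp_cnt <- c(exp_cnt[seq_len(lo - 1L)], exp_cnt[lo] + exp_cnt[hi],
                   exp_cnt[-seq_len(hi)])
      obs_cnt <- c(obs_cnt[seq_len(lo - 1L)], obs_cnt[lo] + obs_cnt[hi],
                   obs_cnt[-seq_len(hi)])
    }
    statistic <- sum((obs_cnt - exp_cnt)^2 / exp_cnt)
    df <- max(length(exp_cnt) - 1L - as.integer(p_estimated), 1L)
    out$method <- "pooled"
    out$n_cells <- length(exp_cnt)
  }
  out$statistic <- statistic
  out$df <- df
  out$p_value <- pchisq(statistic, df, lower.tail = FALSE)
  structure(out, class = "srk_binom_test")
}

# Orthonormal polynomial basis over levels 0..N under the binomial weight:
# column m+1 holds the degree-m polynomial phi_m evaluated at 0..N, with
# sum(w * phi_a * phi_b) = delta_ab. Gram-Schmidt on monomials is ample for
# the small N of bilayer records.
krawtchouk_basis <- function(N, w) {
  k <- 0:N
  V <- outer(k, 0:N, `^`)
  phi <- matrix(0, N + 1L, N + 1L)
  for (m in 0:N) {
    v <- V[, m + 1L]
    if (m > 0L) for (l in 0:(m - 1L))
      v <- v - sum(w * v * phi[, l + 1L]) * phi[, l + 1L]
    nrm <- sqrt(sum(w * v^2))
    phi[, m + 1L] <- if (nrm > 1e-12) v / nrm else 0
  }
  phi
}

#' @export
print.srk_binom_test <- function(x, ...) {
  cat(sprintf("Binomial occupancy test: p_hat = %.3f%s\n", x$p_hat,
              if (x$p_estimated) " (estimated)" else ""))
  print(round(rbind(observed = x$observed, predicted = x$predicted), 4))
  cat(sprintf("X^2 = %.2f on %d df (n_eff = %.0f), p = %.4f\n",
              x$statistic, x$df, x$n_effective, x$p_value))
  invisible(x)
}
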