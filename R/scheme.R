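#' Continuous-time Markov gating scheme
#'
#' A gating scheme is a continuous-time Markov chain over kinetic states, each
#' state assigned to a conductance class. It is the ground truth used by the
#' simulator and the reference model for idealization. Rows of the generator
#' matrix `Q` must sum to zero and off-diagonal entries (rates, in 1/s) must be
#' non-negative.
#'
#' @param Q square numeric generator matrix (1/s).
#' @param classes character vector mapping each state to a conductance class
#'   (e.g. `"C"`, `"S"`, `"O"`), in ascending conductance order of first
#'   appearance unless `class_order` is given.
#' @param state_ids optional state labels.
#' @param initial_dist optional initial probability vector; defaults to the
#'   stationary distribution of `Q`.
#' @param class_order optional character vector giving the conductance classes
#'   in ascending conductance order.
#' @return An object of class `gating_scheme`.
#' @export
gating_scheme <- function(Q, classes, state_ids = NULL, initial_dist = NULL,
                          class_order = NULL) {
  Q <- as.matrix(Q)
  K <- nrow(Q)
  if (ncol(Q) != K) stop("Q must be square")
  if (length(classes) != K) stop("one conductance class per state is required")
  off <- Q
  diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal rates in Q must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    stop("rows of Q must sum to zero")
  if (is.null(state_ids)) state_ids <- paste0("s", seq_len(K))
  if (is.null(class_order)) class_order <- unique(classes)
  if (!all(classes %in% class_order)) stop("classes must appear in class_order")
  if (is.null(initial_dist)) {
    initial_dist <- stationary_dist(Q)
  } else {
    if (length(initial_dist) != K || any(initial_dist < 0))
      stop("initial_dist must be a probability vector over the states")
    if (abs(sum(initial_dist) - 1) > 1e-12)
      stop("initial_dist must sum to 1 within 1e-12")
  }
  structure(
    list(Q = Q, classes = as.character(classes), state_ids = state_ids,
         initial_dist = as.numeric(initial_dist),
         class_order = as.character(class_order)),
    class = "gating_scheme")
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat(sprintf("Gating scheme: %d states (%s)\n", nrow(x$Q),
              paste(x$state_ids, collapse = ", ")))
  cat("Classes:", paste(x$classes, collapse = ", "), "\n")
  cat("Stationary class occupancies:\n")
  print(round(stationary_class_occupancy(x), 4))
  invisible(x)
}

#' Linear closed-substate-open scheme for an SR K+ channel
#'
#' Builds the linear three-state scheme C <-> S <-> O in which all traffic
#' between the closed and full-open classes passes through the merged noisy
#' subconductance class; direct C <-> O rates are structurally zero.
#'
#' @param c_to_s,s_to_c,s_to_o,o_to_s transition rates in 1/s.
#' @return A `gating_scheme` with states C, S, O.
#' @export
three_state_scheme <- function(c_to_s, s_to_c, s_to_o, o_to_s) {
  rates <- c(c_to_s, s_to_c, s_to_o, o_to_s)
  if (!all(vapply(rates, is_scalar_number, TRUE)) || any(rates <= 0))
    stop("all four rates must be positive numbers")
  Q <- matrix(c(
    -c_to_s,           c_to_s,          0,
    s_to_c,  -(s_to_c + s_to_o),   s_to_o,
    0,                 o_to_s,    -o_to_s), 3, 3, byrow = TRUE)
  gating_scheme(Q, classes = c("C", "S", "O"), state_ids = c("C", "S", "O"),
                class_order = c("C", "S", "O"))
}

#' Two-state open/closed scheme
#'
#' Minimal closed <-> open scheme, used for the ryanodine receptor and for
#' simple level-generating channels.
#'
#' @param opening_rate,closing_rate rates in 1/s.
#' @return A `gating_scheme` with states C and O.
#' @export
two_state_scheme <- function(opening_rate, closing_rate) {
  if (opening_rate <= 0 || closing_rate <= 0) stop("rates must be positive")
  Q <- matrix(c(-opening_rate, opening_rate,
                closing_rate, -closing_rate), 2, 2, byrow = TRUE)
  gating_scheme(Q, classes = c("C", "O"), state_ids = c("C", "O"),
                class_order = c("C", "O"))
}

#' Stationary distribution of a generator matrix
#'
#' Solves pi Q = 0 with sum(pi) = 1 (the null-space solution) by least squares
#' on the augmented system.
#'
#' @param Q a generator matrix or a `gating_scheme`.
#' @return numeric vector of stationary state probabilities.
#' @export
stationary_dist <- function(Q) {
  if (inherits(Q, "gating_scheme")) Q <- Q$Q
  K <- nrow(Q)
  A <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop("Q has no non-negative stationary distribution")
  pi / sum(pi)
}

#' Stationary occupancy of each conductance class
#'
#' @param scheme a `gating_scheme`.
#' @return named numeric vector of class occupancies in conductance order.
#' @export
stationary_class_occupancy <- function(scheme) {
  pi <- stationary_dist(scheme)
  occ <- vapply(scheme$class_order,
                function(cl) sum(pi[scheme$classes == cl]), numeric(1))
  occ
}

#' Scale the opening rates of a scheme
#'
#' Multiplies every rate that moves the channel toward a higher conductance
#' class (e.g. C->S and S->O) by `factor`, the mechanism used for facilitated
#' multichannel gating. Closing rates are untouched.
#'
#' @param scheme a `gating_scheme`.
#' @param factor multiplier, >= 0.
#' @return A rescaled `gating_scheme`.
#' @export
scale_opening_rates <- function(scheme, factor) {
  stopifnot(inherits(scheme, "gating_scheme"), is_scalar_number(factor),
            factor >= 0)
  rank <- match(scheme$classes, scheme$class_order)
  Q <- scheme$Q
  K <- nrow(Q)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j && rank[j] > rank[i]) Q[i, j] <- Q[i, j] * factor
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  gating_scheme(Q, scheme$classes, scheme$state_ids, initial_dist = NULL,
                class_order = scheme$class_order)
}

#' Conductance ladder for a K+ channel
#'
#' Mean current levels for the closed, merged-substate and full-open classes.
#' The full-open amplitude follows Ohm's law, `g_full * V * 1e-3` pA (pS, mV),
#' and the substate sits exactly midway between closed and full open.
#'
#' @param g_full_pS full-open single-channel conductance in pS.
#' @param holding_mV holding potential in mV.
#' @return An object of class `conductance_ladder` with `class_amplitudes`
#'   (pA) for C, S and O.
#' @export
conductance_ladder <- function(g_full_pS, holding_mV) {
  stopifnot(is_scalar_number(g_full_pS), g_full_pS > 0,
            is_scalar_number(holding_mV))
  amp_o <- g_full_pS * holding_mV * 1e-3
  structure(
    list(g_full_pS = g_full_pS, holding_mV = holding_mV,
         class_amplitudes = c(C = 0, S = 0.5 * amp_o, O = amp_o)),
    class = "conductance_ladder")
}

#' Recording noise specification
#'
#' Baseline Gaussian noise applies to the closed and full-open classes; the
#' merged substate is rendered with a larger SD fixed, by convention, at half
#' the substate amplitude.
#'
#' @param baseline_sd baseline noise SD in pA (> 0).
#' @param substate_sd substate-class SD in pA; defaults to
#'   `0.5 * |amplitude(S)|` when `ladder` is supplied.
#' @param ladder optional `conductance_ladder` used for the default.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_sd, substate_sd = NULL, ladder = NULL) {
  stopifnot(is_scalar_number(baseline_sd), baseline_sd > 0)
  if (is.null(substate_sd)) {
    if (is.null(ladder)) stop("supply substate_sd or a ladder to derive it")
    substate_sd <- 0.5 * abs(ladder$class_amplitudes[["S"]])
  }
  stopifnot(is_scalar_number(substate_sd), substate_sd > 0)
  structure(list(baseline_sd = baseline_sd, substate_sd = substate_sd),
            class = "noise_spec")
}

#' Acquisition settings
#'
#' @param digitization_rate_hz sampling rate of the digitizer (default 20 kHz).
#' @param filter_cutoff_hz -3 dB cutoff of the Gaussian recording filter
#'   (default 1 kHz; use 4 kHz for mixed-species records).
#' @param analysis_rate_hz rate traces are resampled to before idealization
#'   (default 10 kHz); must divide the digitization rate.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(digitization_rate_hz = 20000,
                             filter_cutoff_hz = 1000,
                             analysis_rate_hz = 10000) {
  stopifnot(is_scalar_number(digitization_rate_hz), digitization_rate_hz > 0,
            is_scalar_number(filter_cutoff_hz), filter_cutoff_hz > 0,
            is_scalar_number(analysis_rate_hz), analysis_rate_hz > 0)
  if (analysis_rate_hz > digitization_rate_hz)
    stop("analysis_rate_hz must not exceed digitization_rate_hz")
  if (filter_cutoff_hz >= digitization_rate_hz / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  structure(list(digitization_rate_hz = digitization_rate_hz,
                 filter_cutoff_hz = filter_cutoff_hz,
                 analysis_rate_hz = analysis_rate_hz),
            class = "acquisition_spec")
}

#' Shipped gating presets
#'
#' Calibration fixtures for a WT-like channel (high open probability, long
#' full openings, no facilitation) and a KO-like channel (low open
#' probability, brief and frequent substate openings, facilitated gating when
#' several channels are present). Rates are package fixtures tuned so the
#' stationary statistics are in the physiological range for SR K+ channels,
#' not measurements.
#'
#' @param name `"wt"` or `"ko"`.
#' @return list with elements `name`, `scheme` (`gating_scheme`),
#'   `facilitation_factor`, and `g_full_pS`.
#' @examples
#' p <- srk_preset("ko")
#' stationary_class_occupancy(p$scheme)
#' @export
srk_preset <- function(name = c("wt", "ko")) {
  name <- match.arg(name)
  if (name == "wt") {
    list(name = "wt",
         scheme = three_state_scheme(14.1, 105, 20, 20 / 3),
         facilitation_factor = 1,
         g_full_pS = 210.8)
  } else {
    list(name = "ko",
         scheme = three_state_scheme(23.7, 313, 20, 25),
         facilitation_factor = 2,
         g_full_pS = 211.1)
  }
}
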