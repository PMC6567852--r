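#' Digitized current trace
#'
#' The universal I/O currency: a vector of current samples in pA plus
#' acquisition metadata.
#'
#' @param samples numeric vector of currents in pA (finite).
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param holding_potential_mv holding potential in mV (may be `NA`).
#' @return An object of class `srk_trace`.
#' @export
srk_trace <- function(samples, sampling_rate_hz, holding_potential_mv = NA_real_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("a trace needs at least one sample")
  if (any(!is.finite(samples))) stop("trace samples must be finite")
  stopifnot(is_scalar_number(sampling_rate_hz), sampling_rate_hz > 0)
  structure(list(samples = samples,
                 sampling_rate_hz = sampling_rate_hz,
                 holding_potential_mv = as.numeric(holding_potential_mv)),
            class = "srk_trace")
}

#' @export
print.srk_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples at %g kHz (%.3f s), V = %s mV\n",
              length(x$samples), x$sampling_rate_hz / 1000,
              length(x$samples) / x$sampling_rate_hz,
              ifelse(is.na(x$holding_potential_mv), "?",
                     format(x$holding_potential_mv))))
  cat(sprintf("  mean %.3f pA, sd %.3f pA\n", mean(x$samples), sd(x$samples)))
  invisible(x)
}

#' Gaussian filter coefficients
#'
#' FIR coefficients of the standard Gaussian impulse response used in
#' single-channel electrophysiology, truncated at +/- 4 sigma and normalized
#' to unit sum. The time-domain sigma is set from the -3 dB cutoff as
#' `sigma_t = 0.1325 / fc`.
#'
#' @param cutoff_hz -3 dB cutoff frequency (Hz).
#' @param sampling_rate_hz sampling rate (Hz); the cutoff must be below
#'   Nyquist.
#' @return numeric vector of odd length, summing to 1.
#' @export
gaussian_fir_coefs <- function(cutoff_hz, sampling_rate_hz) {
  stopifnot(is_scalar_number(cutoff_hz), cutoff_hz > 0,
            is_scalar_number(sampling_rate_hz), sampling_rate_hz > 0)
  if (cutoff_hz >= sampling_rate_hz / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  sigma <- 0.1325 * sampling_rate_hz / cutoff_hz   # in samples
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- seq.int(-h, h)
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)
}

# Zero-phase FIR smoothing with edge replication.
apply_fir <- function(x, coefs) {
  n <- length(x)
  h <- (length(coefs) - 1L) %/% 2L
  if (h == 0L) return(x * coefs)
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  y <- stats::filter(xp, coefs, method = "convolution", sides = 2L)
  as.numeric(y[(h + 1L):(h + n)])
}

#' Filter and resample a trace before idealization
#'
#' Applies a zero-phase Gaussian digital filter at `filter_cutoff_hz` and then
#' decimates to `analysis_rate_hz` (which must divide the input rate), the
#' standard conditioning applied to bilayer records before segmental k-means
#' idealization. The mean of a long constant segment is unchanged.
#'
#' @param trace an `srk_trace`.
#' @param filter_cutoff_hz -3 dB Gaussian cutoff (Hz).
#' @param analysis_rate_hz output sampling rate (Hz).
#' @return A filtered, decimated `srk_trace`.
#' @export
preprocess <- function(trace, filter_cutoff_hz = 1000, analysis_rate_hz = 10000) {
  stopifnot(inherits(trace, "srk_trace"))
  fs <- trace$sampling_rate_hz
  if (analysis_rate_hz > fs)
    stop("analysis rate exceeds the trace sampling rate")
  if (filter_cutoff_hz >= fs / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  factor <- fs / analysis_rate_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop("analysis rate must divide the sampling rate")
  factor <- as.integer(round(factor))
  y <- apply_fir(trace$samples, gaussian_fir_coefs(filter_cutoff_hz, fs))
  if (factor > 1L) y <- y[seq.int(1L, length(y), by = factor)]
  srk_trace(y, analysis_rate_hz, trace$holding_potential_mv)
}
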