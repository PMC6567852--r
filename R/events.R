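#' Strip events shorter than a resolution cutoff
#'
#' Scans left to right: each event shorter than `cutoff_ms` is deleted and
#' its duration is appended to the preceding surviving event (a leading short
#' event, which has no predecessor, is merged into the following event);
#' adjacent same-class events are merged. Total duration is conserved exactly
#' — when the idealization carries an analysis rate the arithmetic is done in
#' integer sample counts — and the operation is idempotent.
#'
#' @param ideal an `srk_idealization`.
#' @param cutoff_ms resolution cutoff in ms (default 0.6, the conventional
#'   stripping threshold for these records).
#' @return A stripped `srk_idealization`.
#' @export
strip_short_events <- function(ideal, cutoff_ms = 0.6) {
  stopifnot(inherits(ideal, "srk_idealization"), cutoff_ms >= 0)
  rate <- attr(ideal, "analysis_rate")
  cl <- ideal$class
  n <- length(cl)
  use_samples <- is.finite(rate)
  if (use_samples) {
    d <- as.numeric(round(ideal$duration_s * rate))
    cutoff <- cutoff_ms * 1e-3 * rate
  } else {
    d <- ideal$duration_s
    cutoff <- cutoff_ms * 1e-3
  }
  out_cl <- character(n); out_d <- numeric(n)
  top <- 0L
  carry <- 0
  for (i in seq_len(n)) {
    if (d[i] < cutoff) {
      if (top > 0L) out_d[top] <- out_d[top] + d[i]
      else carry <- carry + d[i]      # leading short events merge forward
    } else {
      di <- d[i] + carry
      carry <- 0
      if (top > 0L && out_cl[top] == cl[i]) {
        out_d[top] <- out_d[top] + di
      } else {
        top <- top + 1L
        out_cl[top] <- cl[i]
        out_d[top] <- di
      }
    }
  }
  if (top == 0L) {      # degenerate: every event below the cutoff
    top <- 1L
    out_cl[1L] <- cl[which.max(d)]
    out_d[1L] <- carry
    carry <- 0
  } else if (carry > 0) {
    out_d[top] <- out_d[top] + carry
  }
  out_cl <- out_cl[seq_len(top)]
  out_d <- out_d[seq_len(top)]
  if (use_samples) out_d <- out_d / rate
  new_idealization(out_cl, out_d, analysis_rate = rate,
                   class_labels = attr(ideal, "class_labels"))
}

#' Single-channel statistics from an idealization
#'
#' Time-weighted class occupancies, total open probability (occupancy of any
#' conducting class), the percentage contribution of the full-open class to
#' the total open probability, and per-class mean open times and event
#' frequencies. The first and last events border the record and are treated
#' as censored: they count toward occupancy but are excluded from mean dwell
#' times and event frequencies.
#'
#' @param ideal an `srk_idealization` from a record with a single channel.
#' @param closed_class label of the non-conducting class (default `"C"`).
#' @param open_class label of the full-open class (default `"O"`).
#' @return A list of class `srk_stats`: `po_total`, `p_class`,
#'   `full_open_contribution_pct` (`NA` when the channel never conducts),
#'   `mot_ms`, `event_freq_hz`, `record_duration_s`, `n_events`.
#' @export
compute_stats <- function(ideal, closed_class = "C", open_class = "O") {
  stopifnot(inherits(ideal, "srk_idealization"))
  labels <- attr(ideal, "class_labels") %||% unique(ideal$class)
  dur <- attr(ideal, "total_duration")
  time_in <- vapply(labels, function(cl)
    sum(ideal$duration_s[ideal$class == cl]), numeric(1))
  p_class <- time_in / dur
  po_total <- 1 - unname(p_class[closed_class])
  contribution <- if (po_total > 0 && open_class %in% labels)
    100 * unname(p_class[open_class]) / po_total else NA_real_
  n <- nrow(ideal)
  interior <- if (n > 2L) seq.int(2L, n - 1L) else integer(0)
  cl_i <- ideal$class[interior]
  d_i <- ideal$duration_s[interior]
  mot_ms <- vapply(labels, function(cl) {
    dd <- d_i[cl_i == cl]
    if (length(dd)) mean(dd) * 1000 else NA_real_
  }, numeric(1))
  event_freq_hz <- vapply(labels, function(cl) sum(cl_i == cl) / dur,
                          numeric(1))
  structure(list(po_total = po_total, p_class = p_class,
                 full_open_contribution_pct = contribution,
                 mot_ms = mot_ms, event_freq_hz = event_freq_hz,
                 record_duration_s = dur, n_events = n),
            class = "srk_stats")
}

#' @export
print.srk_stats <- function(x, ...) {
  cat(sprintf("Po_total %.3f over %.1f s (%d events)\n",
              x$po_total, x$record_duration_s, x$n_events))
  cat("Occupancies:", paste(sprintf("%s=%.3f", names(x$p_class), x$p_class),
                            collapse = ", "), "\n")
  if (!is.na(x$full_open_contribution_pct))
    cat(sprintf("Full-open contribution to Po_total: %.1f%%\n",
                x$full_open_contribution_pct))
  invisible(x)
}

#' Fraction of open/close transitions passing through the substate
#'
#' Audits the decoded event sequence: of all entries into and exits from the
#' full-open class, what fraction go via the subconductance class rather than
#' jumping directly between closed and full open. The linear gating model
#' predicts a fraction near 1.
#'
#' @param ideal an `srk_idealization` with classes C/S/O.
#' @return fraction in `[0, 1]`, or `NA` when the open class is never
#'   entered or left.
#' @export
substate_transit_fraction <- function(ideal, closed_class = "C",
                                      open_class = "O") {
  cl <- ideal$class
  if (length(cl) < 2L) return(NA_real_)
  a <- cl[-length(cl)]
  b <- cl[-1L]
  o_moves <- sum(xor(a == open_class, b == open_class))
  if (o_moves == 0L) return(NA_real_)
  direct <- sum((a == closed_class & b == open_class) |
                (a == open_class & b == closed_class))
  1 - direct / o_moves
}

#' Single-channel conductance by linear regression
#'
#' Ordinary least-squares fit of unitary current (pA) against holding
#' potential (mV); the slope is returned in pS.
#'
#' @param voltage_mV holding potentials (>= 2 distinct values).
#' @param current_pA unitary current amplitudes.
#' @return A list of class `srk_iv`: `conductance_pS`, `intercept_pA`,
#'   `r_squared`, and the underlying `lm` fit.
#' @export
fit_iv <- function(voltage_mV, current_pA) {
  stopifnot(length(voltage_mV) == length(current_pA))
  if (length(unique(voltage_mV)) < 2L)
    stop("at least two distinct potentials are required")
  fit <- lm(current_pA ~ voltage_mV)
  ss_tot <- sum((current_pA - mean(current_pA))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(conductance_pS = unname(coef(fit)[2L]) * 1000,
                 intercept_pA = unname(coef(fit)[1L]),
                 r_squared = r2,
                 fit = fit),
            class = "srk_iv")
}

#' @export
print.srk_iv <- function(x, ...) {
  cat(sprintf("Conductance %.1f pS (intercept %.3f pA, R^2 %.4f)\n",
              x$conductance_pS, x$intercept_pA, x$r_squared))
  invisible(x)
}
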