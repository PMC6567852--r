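#' Logarithmic dwell-time histogram
#'
#' Bins dwell times uniformly in log10(time), the display convention under
#' which each exponential component of a lifetime distribution appears as a
#' peak at its time constant (the square-root-of-count ordinate is left to
#' plotting).
#'
#' @param dwells_ms positive dwell times in ms.
#' @param bins_per_decade bins per decade of time (default 10).
#' @return A list of class `srk_loghist`: `breaks_log10`, `mids_ms`,
#'   `counts`, `bins_per_decade`. Counts sum to `length(dwells_ms)`.
#' @export
log_bin <- function(dwells_ms, bins_per_decade = 10) {
  dwells_ms <- as.numeric(dwells_ms)
  if (length(dwells_ms) == 0L) stop("no dwell times supplied")
  if (any(dwells_ms <= 0)) stop("dwell times must be positive")
  lt <- log10(dwells_ms)
  w <- 1 / bins_per_decade
  lo <- floor(min(lt) / w) * w
  hi <- ceiling(max(lt) / w) * w
  if (hi <= lo) hi <- lo + w
  breaks <- seq(lo, hi, by = w)
  counts <- tabulate(pmin(pmax(floor((lt - lo) / w) + 1L, 1L),
                          length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  structure(list(breaks_log10 = breaks,
                 mids_ms = 10^(breaks[-length(breaks)] + w / 2),
                 counts = counts, bins_per_decade = bins_per_decade,
                 n = length(dwells_ms)),
            class = "srk_loghist")
}

#' Sample dwell times from a left-truncated exponential mixture
#'
#' Draws from the mixture with the given time constants and (untruncated)
#' areas, conditioned on exceeding `left_censor_ms`: components are selected
#' with their truncation-adjusted weights and dwells are the cutoff plus an
#' exponential excess (memorylessness makes this exact).
#'
#' @param n number of dwells.
#' @param tau_ms component time constants in ms (ascending not required).
#' @param area component mixing fractions of the untruncated mixture.
#' @param left_censor_ms truncation point (default 0).
#' @param seed optional integer seed.
#' @return numeric vector of dwell times in ms, all `>= left_censor_ms`.
#' @export
rexp_mixture <- function(n, tau_ms, area, left_censor_ms = 0, seed = NULL) {
  stopifnot(length(tau_ms) == length(area), all(tau_ms > 0), all(area > 0))
  area <- area / sum(area)
  with_seed(seed, {
    w <- area * exp(-left_censor_ms / tau_ms)
    comp <- sample.int(length(tau_ms), n, replace = TRUE, prob = w / sum(w))
    left_censor_ms + rexp(n, rate = 1 / tau_ms[comp])
  })
}

#' Maximum-likelihood exponential-mixture fit of dwell times
#'
#' Fits a k-component exponential mixture to raw (unbinned) dwell times with
#' explicit left-truncation at `left_censor_ms`, the resolution cutoff used
#' for event stripping: the truncated mixture is exactly a mixture of the
#' same time constants on the excess `t - t0` with reweighted areas, so EM is
#' run on the shifted dwells and the areas are mapped back to the
#' untruncated scale. Multiple seeded starts with log-spaced initial time
#' constants guard against local maxima; an optional warm start (used by
#' [select_num_components()]) guarantees the fitted log-likelihood is
#' non-decreasing in k.
#'
#' For `k = 1` the maximum-likelihood solution is the closed form
#' `tau = mean(t) - t0`.
#'
#' @param dwells_ms dwell times in ms, all `>= left_censor_ms`.
#' @param k number of exponential components (>= 1); requires
#'   `length(dwells_ms) >= 5 * k`.
#' @param left_censor_ms truncation point in ms (default 0.6).
#' @param n_starts number of EM starts (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param warm_start optional list with `tau_ms` and `area_truncated` used as
#'   an additional EM start.
#' @param seed optional integer seed controlling the random starts.
#' @return A list of class `srk_expmix`: `k`, `tau_ms` (ascending), `area`
#'   (untruncated-scale, sums to 1), `area_truncated`, `loglik`, `converged`,
#'   `n`, `left_censor_ms`.
#' @export
fit_exp_mixture <- function(dwells_ms, k, left_censor_ms = 0.6,
                            n_starts = 10L, max_iter = 1000L, tol = 1e-10,
                            warm_start = NULL, seed = NULL) {
  t <- as.numeric(dwells_ms)
  if (any(t <= 0)) stop("dwell times must be positive")
  if (any(t < left_censor_ms - 1e-12))
    stop("dwell times below the truncation point")
  n <- length(t)
  if (n < 5L * k)
    stop("too few dwells to identify ", k, " components (need >= 5k)")
  y <- pmax(t - left_censor_ms, 0)
  if (k == 1L) {
    tau <- mean(y)
    ll <- sum(-log(tau) - y / tau)
    return(structure(list(k = 1L, tau_ms = tau, area = 1,
                          area_truncated = 1, loglik = ll, converged = TRUE,
                          n = n, left_censor_ms = left_censor_ms),
                     class = "srk_expmix"))
  }
  em_run <- function(tau0, a0) {
    tau <- pmax(tau0, 1e-8)
    a <- a0 / sum(a0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      logf <- vapply(seq_len(k),
                     function(j) log(a[j]) - log(tau[j]) - y / tau[j],
                     numeric(n))
      lse <- row_logsumexp(logf)
      ll <- sum(lse)
      r <- exp(logf - lse)
      a <- pmax(colMeans(r), 1e-12)
      a <- a / sum(a)
      sw <- colSums(r)
      tau <- pmax(colSums(r * y) / sw, 1e-8)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(tau = tau, a = a, loglik = ll, converged = converged)
  }
  starts <- with_seed(seed, {
    lo <- log(max(quantile(c(y[y > 0], 1e-4), 0.02), 1e-4))
    hi <- log(max(quantile(y, 0.98), 2e-4))
    if (hi <= lo) hi <- lo + 1
    lapply(seq_len(n_starts), function(s) {
      base <- seq(lo, hi, length.out = k)
      jit <- if (s == 1L) 0 else runif(k, -0.5, 0.5) * (hi - lo) / k
      list(tau = exp(base + jit), a = rep(1 / k, k))
    })
  })
  if (!is.null(warm_start))
    starts <- c(list(list(tau = warm_start$tau_ms,
                          a = warm_start$area_truncated)), starts)
  best <- NULL
  for (s in starts) {
    fit <- em_run(s$tau, s$a)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$tau)
  tau <- best$tau[ord]
  a_trunc <- best$a[ord]
  # untruncated-scale areas: a_j proportional to a'_j * exp(t0 / tau_j)
  la <- log(a_trunc) + left_censor_ms / tau
  a <- exp(la - max(la))
  a <- a / sum(a)
  structure(list(k = as.integer(k), tau_ms = tau, area = a,
                 area_truncated = a_trunc, loglik = best$loglik,
                 converged = best$converged, n = n,
                 left_censor_ms = left_censor_ms),
            class = "srk_expmix")
}

#' @export
print.srk_expmix <- function(x, ...) {
  cat(sprintf("%d-component exponential mixture (n = %d, logLik %.2f%s)\n",
              x$k, x$n, x$loglik,
              if (x$converged) "" else ", not converged"))
  print(data.frame(tau_ms = round(x$tau_ms, 3),
                   area_pct = round(100 * x$area, 1)))
  invisible(x)
}

#' Select the number of exponential components by likelihood ratio
#'
#' Fits mixtures of increasing order and applies a sequential log-likelihood
#' ratio test: `2 * (logLik(k+1) - logLik(k))` is referred to a chi-square
#' distribution with 2 degrees of freedom per added component, stopping at
#' the first non-significant improvement. Each fit of order k+1 is warm-
#' started from the accepted order-k fit, so log-likelihoods are
#' non-decreasing in k by construction.
#'
#' @param dwells_ms dwell times in ms.
#' @param k_max largest order to consider.
#' @param alpha test level (default 0.05).
#' @param left_censor_ms truncation point in ms.
#' @param df_per_component chi-square df per added component (default 2: one
#'   time constant plus one area).
#' @param seed optional integer seed for the EM starts.
#' @param ... further arguments to [fit_exp_mixture()].
#' @return A list of class `srk_ksel`: `k_opt`, `fits` (all fitted orders),
#'   `tests` (data.frame of k, loglik, statistic, p_value).
#' @export
select_num_components <- function(dwells_ms, k_max, alpha = 0.05,
                                  left_censor_ms = 0.6,
                                  df_per_component = 2, seed = NULL, ...) {
  stopifnot(k_max >= 1L)
  fits <- list()
  tests <- data.frame(k = integer(0), loglik = numeric(0),
                      statistic = numeric(0), p_value = numeric(0))
  k_opt <- 1L
  fit_k <- fit_exp_mixture(dwells_ms, 1L, left_censor_ms = left_censor_ms,
                           seed = seed, ...)
  fits[[1L]] <- fit_k
  tests <- rbind(tests, data.frame(k = 1L, loglik = fit_k$loglik,
                                   statistic = NA_real_, p_value = NA_real_))
  k <- 1L
  while (k < k_max) {
    warm <- split_component(fit_k)
    fit_next <- tryCatch(
      fit_exp_mixture(dwells_ms, k + 1L, left_censor_ms = left_censor_ms,
                      warm_start = warm, seed = seed, ...),
      error = function(e) NULL)
    if (is.null(fit_next)) {
      warning("order-", k + 1L, " fit failed; keeping k = ", k)
      break
    }
    stat <- 2 * (fit_next$loglik - fit_k$loglik)
    p <- pchisq(max(stat, 0), df = df_per_component, lower.tail = FALSE)
    fits[[k + 1L]] <- fit_next
    tests <- rbind(tests, data.frame(k = k + 1L, loglik = fit_next$loglik,
                                     statistic = stat, p_value = p))
    if (p >= alpha) break
    k <- k + 1L
    k_opt <- k
    fit_k <- fit_next
  }
  structure(list(k_opt = k_opt, fits = fits, tests = tests,
                 alpha = alpha), class = "srk_ksel")
}

# Warm start for order k+1: duplicate the largest-area component with areas
# halved; the initial mixture density is unchanged, so EM cannot fall below
# the order-k log-likelihood.
split_component <- function(fit) {
  j <- which.max(fit$area_truncated)
  tau <- c(fit$tau_ms, fit$tau_ms[j] * 1.000001)
  a <- if (fit$k == 1L) 1 else fit$area_truncated
  a <- c(a, 0)
  a[length(a)] <- a[j] / 2
  a[j] <- a[j] / 2
  list(tau_ms = tau, area_truncated = a / sum(a))
}

#' @export
print.srk_ksel <- function(x, ...) {
  cat(sprintf("Optimal number of components: %d (LLR, alpha = %g)\n",
              x$k_opt, x$alpha))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
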