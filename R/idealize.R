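#' Idealized event sequence
#'
#' An idealization is a time-ordered sequence of (class, duration) events
#' tiling the record with no gaps or overlaps; adjacent events always differ
#' in class. When produced from sampled data, durations are integer multiples
#' of the analysis sample interval.
#'
#' @param class character vector of class labels, one per event.
#' @param duration_s event durations in seconds (> 0).
#' @param analysis_rate sampling rate the events derive from (Hz), or `NA`
#'   for continuous-time (ground-truth) events.
#' @param class_labels full set of class labels in conductance order.
#' @param start_s optional start times; computed from durations if missing.
#' @return An object of class `srk_idealization`: a data.frame with columns
#'   `class`, `start_s`, `duration_s` and attributes `analysis_rate`,
#'   `total_duration`, `class_labels`.
#' @export
new_idealization <- function(class, duration_s, analysis_rate = NA_real_,
                             class_labels = NULL, start_s = NULL) {
  class <- as.character(class)
  duration_s <- as.numeric(duration_s)
  if (length(class) != length(duration_s) || length(class) == 0L)
    stop("class and duration_s must be non-empty and of equal length")
  if (any(duration_s <= 0)) stop("event durations must be positive")
  # merge any adjacent same-class events so the invariant holds
  if (length(class) > 1L) {
    grp <- cumsum(c(1L, as.integer(class[-1L] != class[-length(class)])))
    if (max(grp) < length(class)) {
      duration_s <- as.numeric(tapply(duration_s, grp, sum))
      class <- class[!duplicated(grp)]
    }
  }
  if (is.null(start_s)) start_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  out <- data.frame(class = class, start_s = start_s, duration_s = duration_s,
                    stringsAsFactors = FALSE)
  attr(out, "analysis_rate") <- analysis_rate
  attr(out, "total_duration") <- sum(duration_s)
  attr(out, "class_labels") <- class_labels %||% unique(class)
  structure(out, class = c("srk_idealization", "data.frame"))
}

#' Convert a simulated dwell path to an idealization
#'
#' Merges consecutive same-class states of a ground-truth path into events;
#' the result can be analysed exactly like a decoded idealization.
#'
#' @param path a dwell path from [sample_dwell_path()].
#' @return An `srk_idealization`.
#' @export
path_to_idealization <- function(path) {
  new_idealization(path$class, path$duration_s, analysis_rate = NA_real_,
                   class_labels = attr(path, "class_order"))
}

# Compress a 1-based per-sample class path into an idealization.
path_to_events <- function(path_idx, labels, rate) {
  r <- rle(path_idx)
  new_idealization(class = labels[r$values], duration_s = r$lengths / rate,
                   analysis_rate = rate, class_labels = labels)
}

#' Segmental k-means idealization
#'
#' Iterates Viterbi decoding (Gaussian emissions, Markov transitions) with
#' re-estimation of the free emission parameters from the assigned samples
#' and of the transition matrix from path counts, until the decoded path is
#' unchanged on two successive iterations (the path-stability stopping rule)
#' or `max_iter` is reached. With `constraint = "substate"` (the
#' merged-substate convention for SR K+ channels) the substate mean is pinned
#' midway between the closed and full-open means and its SD to one-half the
#' substate amplitude; those parameters are re-derived from the fitted C/O
#' classes each iteration, never free-fit. Direct transitions between
#' non-adjacent classes stay decodable with small probability, so substate
#' transit can be audited rather than assumed.
#'
#' @param trace an `srk_trace` (already preprocessed).
#' @param class_means strictly increasing initial class means (pA).
#' @param class_sds initial class SDs; a sensible default is derived from the
#'   level spacing.
#' @param class_labels labels in the order of `class_means`; defaults to
#'   C/S/O for three classes, `"0" ... "K-1"` otherwise.
#' @param constraint `"substate"` (3 classes), `"none"` (all free) or
#'   `"fixed"` (no emission re-estimation).
#' @param max_iter maximum SKM iterations (default 100).
#' @param self_prob initial self-transition probability (default 0.99:
#'   dwells are much longer than the sample interval).
#' @param pseudocount transition-count smoothing added to every cell.
#' @param min_class_n classes assigned fewer samples than this keep their
#'   previous emission parameters.
#' @return A list of class `srk_skm`: `idealization`, `emission` (data.frame
#'   of class, mean, sd), `trans_probs`, `trans_counts`, `loglik` (joint
#'   log-likelihood per iteration), `iterations`, `converged`.
#' @export
skm_idealize <- function(trace, class_means, class_sds = NULL,
                         class_labels = NULL,
                         constraint = c("substate", "none", "fixed"),
                         max_iter = 100L, self_prob = 0.99,
                         pseudocount = 0.5, min_class_n = 20L) {
  stopifnot(inherits(trace, "srk_trace"))
  constraint <- match.arg(constraint)
  K <- length(class_means)
  if (K < 2L) stop("at least two classes are required")
  x <- trace$samples
  if (length(x) < K) stop("fewer samples than classes")
  ord <- order(class_means)
  if (any(ord != seq_len(K))) {   # re-sort allowed at initialization only
    class_means <- class_means[ord]
    if (!is.null(class_sds)) class_sds <- class_sds[ord]
    if (!is.null(class_labels)) class_labels <- class_labels[ord]
  }
  if (any(diff(class_means) <= 0))
    stop("initial class means must be strictly ordered")
  if (is.null(class_labels)) {
    class_labels <- if (K == 3L && constraint == "substate") c("C", "S", "O")
                    else as.character(seq_len(K) - 1L)
  }
  if (constraint == "substate" && K != 3L)
    stop("the substate constraint applies to a three-class model")
  if (is.null(class_sds))
    class_sds <- rep(max(min(diff(class_means)) / 4, 1e-3), K)
  mu <- as.numeric(class_means)
  sg <- pmax(as.numeric(class_sds), 1e-4)
  if (constraint == "substate") {
    mu[2L] <- (mu[1L] + mu[3L]) / 2
    sg[2L] <- 0.5 * (mu[2L] - mu[1L])
  }
  P <- matrix((1 - self_prob) / (K - 1L), K, K)
  diag(P) <- self_prob
  logP <- log(P)
  logpi <- rep(-log(K), K)
  n <- length(x)
  ll_trace <- numeric(0)
  path_prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    logemis <- vapply(seq_len(K),
                      function(k) dnorm(x, mu[k], sg[k], log = TRUE),
                      numeric(n))
    path <- .viterbi_decode(logemis, logP, logpi)
    from <- path[-n]; to <- path[-1L]
    ll <- logpi[path[1L]] + sum(logemis[cbind(seq_len(n), path)]) +
      sum(logP[cbind(from, to)])
    ll_trace <- c(ll_trace, ll)
    if (!is.null(path_prev) && identical(path, path_prev)) {
      converged <- TRUE
      break
    }
    path_prev <- path
    # --- re-estimation ---
    if (constraint != "fixed") {
      for (k in seq_len(K)) {
        if (constraint == "substate" && k == 2L) next
        idx <- path == k
        nk <- sum(idx)
        if (nk >= min_class_n) {
          mu[k] <- mean(x[idx])
          sg[k] <- max(sd(x[idx]), 1e-4)
          if (!is.finite(sg[k])) sg[k] <- 1e-4
        }
      }
      if (constraint == "substate") {
        mu[2L] <- (mu[1L] + mu[3L]) / 2
        sg[2L] <- 0.5 * (mu[2L] - mu[1L])
      }
    }
    cnt <- matrix(tabulate((from - 1L) * K + to, nbins = K * K), K, K,
                  byrow = TRUE)
    P <- (cnt + pseudocount) / (rowSums(cnt) + K * pseudocount)
    logP <- log(P)
    ini <- numeric(K); ini[path[1L]] <- 1
    logpi <- log((ini + pseudocount / K) / (1 + pseudocount))
  }
  if (!converged) {
    # final decode so the returned path is optimal under the returned model
    logemis <- vapply(seq_len(K),
                      function(k) dnorm(x, mu[k], sg[k], log = TRUE),
                      numeric(n))
    path <- .viterbi_decode(logemis, logP, logpi)
    warning("segmental k-means did not converge within max_iter; ",
            "returning the best path")
  }
  from <- path[-n]; to <- path[-1L]
  cnt <- matrix(tabulate((from - 1L) * K + to, nbins = K * K), K, K,
                byrow = TRUE)
  dimnames(cnt) <- list(class_labels, class_labels)
  structure(list(
    idealization = path_to_events(path, class_labels, trace$sampling_rate_hz),
    path = path,
    emission = data.frame(class = class_labels, mean = mu, sd = sg,
                          stringsAsFactors = FALSE),
    trans_probs = structure(P, dimnames = list(class_labels, class_labels)),
    trans_counts = cnt,
    log_init = logpi,
    loglik = ll_trace,
    iterations = iter,
    converged = converged), class = "srk_skm")
}

#' @export
print.srk_skm <- function(x, ...) {
  cat(sprintf("Segmental k-means fit: %d events, %d iterations (%s)\n",
              nrow(x$idealization), x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$emission)
  invisible(x)
}

#' Half-amplitude threshold idealization
#'
#' The established 50% threshold method: a sample is classed open when it
#' lies beyond the midpoint between the closed and open levels
#' (direction-aware, so it works at negative potentials too).
#'
#' @param trace an `srk_trace`.
#' @param closed_level,open_level level currents in pA (must differ).
#' @return An `srk_idealization` with classes `"C"` and `"O"`.
#' @export
threshold_idealize <- function(trace, closed_level, open_level) {
  stopifnot(inherits(trace, "srk_trace"))
  if (open_level == closed_level) stop("levels must differ")
  thr <- (closed_level + open_level) / 2
  open <- if (open_level > closed_level) trace$samples > thr
          else trace$samples < thr
  path_to_events(as.integer(open) + 1L, c("C", "O"), trace$sampling_rate_hz)
}
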