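#' Write a trace to disk
#'
#' Two on-disk forms: `csv` (columns `time_s`, `current_pA`, six decimals)
#' and `raw` (little-endian float32 samples plus a JSON sidecar
#' `<path>.json` carrying the acquisition metadata; lossless for float32).
#'
#' @param trace an `srk_trace`.
#' @param path output file path.
#' @param format `"csv"` or `"raw"`.
#' @param seed optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "raw"), seed = NULL) {
  stopifnot(inherits(trace, "srk_trace"))
  format <- match.arg(format)
  if (format == "csv") {
    n <- length(trace$samples)
    df <- data.frame(
      time_s = sprintf("%.6f", (seq_len(n) - 1L) / trace$sampling_rate_hz),
      current_pA = sprintf("%.6f", trace$samples))
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
    meta <- list(n_samples = length(trace$samples),
                 sampling_rate_hz = trace$sampling_rate_hz,
                 holding_potential_mv = trace$holding_potential_mv,
                 units = "pA")
    if (!is.null(seed)) meta$seed <- seed
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a trace from disk
#'
#' @param path file written by [write_trace()].
#' @param format `"csv"` or `"raw"`.
#' @return An `srk_trace`.
#' @export
read_trace <- function(path, format = c("csv", "raw")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.table(path, header = TRUE, sep = ",")
    if (!all(c("time_s", "current_pA") %in% names(df)))
      stop("csv trace needs time_s and current_pA columns")
    dt <- diff(df$time_s)
    rate <- 1 / stats::median(dt)
    srk_trace(df$current_pA, rate)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n_file <- file.info(path)$size / 4
    if (!isTRUE(all.equal(as.numeric(meta$n_samples), n_file)))
      stop("sample count in sidecar does not match the raw file")
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    x <- readBin(con, numeric(), n = meta$n_samples, size = 4L,
                 endian = "little")
    srk_trace(x, meta$sampling_rate_hz,
              meta$holding_potential_mv %||% NA_real_)
  }
}

#' Write an idealization as a QuB-style dwell (.dwt) file
#'
#' One segment header (`Segment: 1 Dwells: n`) followed by one
#' `class<TAB>duration_ms` line per event, durations to 0.1 ms. Class labels
#' are written as 0-based indices into the idealization's class labels.
#'
#' @param ideal an `srk_idealization`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dwt <- function(ideal, path) {
  stopifnot(inherits(ideal, "srk_idealization"))
  labels <- attr(ideal, "class_labels")
  idx <- match(ideal$class, labels) - 1L
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("Segment: 1 Dwells: %d", nrow(ideal)), con)
  writeLines(sprintf("%d\t%.1f", idx, ideal$duration_s * 1000), con)
  invisible(path)
}

#' Read a QuB-style dwell (.dwt) file
#'
#' @param path file written by [write_dwt()] (or exported from QuB).
#' @param class_labels labels mapped onto the 0-based class indices; default
#'   `c("C", "S", "O")` truncated/extended as needed.
#' @return An `srk_idealization` (durations carry 0.1 ms resolution).
#' @export
read_dwt <- function(path, class_labels = c("C", "S", "O")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty dwell file")
  if (!grepl("^Segment:", lines[1L])) stop("missing segment header")
  body <- lines[-1L]
  if (length(body) == 0L) stop("dwell file has no events")
  parts <- strsplit(body, "\t")
  idx <- as.integer(vapply(parts, `[[`, "", 1L))
  dur <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(idx) || anyNA(dur)) stop("malformed dwell line")
  if (any(dur <= 0)) stop("negative or zero duration in dwell file")
  need <- max(idx) + 1L
  if (length(class_labels) < need)
    class_labels <- c(class_labels,
                      as.character(seq.int(length(class_labels), need - 1L)))
  new_idealization(class_labels[idx + 1L], dur / 1000,
                   analysis_rate = 10000, class_labels = class_labels)
}

#' Write an idealization as a TSV event table
#'
#' @param ideal an `srk_idealization`.
#' @param path output path.
#' @param channel_id identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(ideal, path, channel_id = 1L) {
  df <- data.frame(channel_id = channel_id, class = ideal$class,
                   start_s = sprintf("%.7f", ideal$start_s),
                   duration_s = sprintf("%.7f", ideal$duration_s))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate-idealize-analyse pipeline; a config
#' round-trips through JSON unchanged, and every stochastic run records its
#' seed.
#'
#' @param seed integer RNG seed.
#' @param preset `"wt"` or `"ko"` gating preset.
#' @param n_channels channels in the bilayer.
#' @param mode `"independent"` or `"facilitated"`.
#' @param facilitation_factor opening-rate multiplier; defaults to the
#'   preset's value.
#' @param duration_s record duration (default 180 s, the conventional Po
#'   measurement window).
#' @param holding_potential_mv holding potential.
#' @param baseline_sd_pA baseline recording noise SD.
#' @param digitization_rate_hz,filter_cutoff_hz,analysis_rate_hz acquisition
#'   settings.
#' @param strip_cutoff_ms stripping cutoff (default 0.6 ms).
#' @param llr_alpha level of the likelihood-ratio component test.
#' @param bins_per_decade log-histogram resolution.
#' @param k_max largest mixture order considered.
#' @param out_dir optional output directory for reports.
#' @return A list of class `srk_config`.
#' @export
run_config <- function(seed = 1L, preset = c("ko", "wt"), n_channels = 1L,
                       mode = c("independent", "facilitated"),
                       facilitation_factor = NULL, duration_s = 180,
                       holding_potential_mv = 30, baseline_sd_pA = 0.6,
                       digitization_rate_hz = 20000, filter_cutoff_hz = 1000,
                       analysis_rate_hz = 10000, strip_cutoff_ms = 0.6,
                       llr_alpha = 0.05, bins_per_decade = 10, k_max = 6L,
                       out_dir = NULL) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  if (is.null(facilitation_factor))
    facilitation_factor <- srk_preset(preset)$facilitation_factor
  cfg <- list(seed = as.integer(seed), preset = preset,
              n_channels = as.integer(n_channels), mode = mode,
              facilitation_factor = facilitation_factor,
              duration_s = duration_s,
              holding_potential_mv = holding_potential_mv,
              baseline_sd_pA = baseline_sd_pA,
              digitization_rate_hz = digitization_rate_hz,
              filter_cutoff_hz = filter_cutoff_hz,
              analysis_rate_hz = analysis_rate_hz,
              strip_cutoff_ms = strip_cutoff_ms,
              llr_alpha = llr_alpha, bins_per_decade = bins_per_decade,
              k_max = as.integer(k_max))
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  structure(cfg, class = "srk_config")
}

#' @rdname run_config
#' @param config an `srk_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON form; stamped into every output file a run
#' produces so results trace back to their configuration.
#'
#' @param config an `srk_config`.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}
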