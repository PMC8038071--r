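#' Physiological channel
#'
#' A single uniformly sampled channel of a driving recording.  Recognised
#' channel names are `"FGSR"` and `"HGSR"` (galvanic skin response in
#' microsiemens-like units), `"HR"` (heart rate in bpm) and `"MARKER"`
#' (piecewise-constant stress-level code).
#'
#' @param values numeric vector of samples (non-empty).
#' @param fs sampling rate in Hz (positive).
#' @param name channel name, one of `"FGSR"`, `"HGSR"`, `"HR"`, `"MARKER"`.
#' @return an object of class `contrp_channel`: a list with elements
#'   `name`, `values`, `fs`.
#' @export
channel <- function(values, fs, name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% CHANNEL_NAMES)
    abort_data(sprintf("unknown channel name '%s'", paste(name, collapse = ",")))
  if (!is.numeric(values) || length(values) == 0L)
    abort_data(sprintf("channel '%s': values must be a non-empty numeric vector", name))
  if (!is_scalar_num(fs) || fs <= 0)
    abort_data(sprintf("channel '%s': fs must be a positive number", name))
  structure(list(name = name, values = as.double(values), fs = as.double(fs)),
            class = "contrp_channel")
}

CHANNEL_NAMES <- c("FGSR", "HGSR", "HR", "MARKER")
SIGNAL_CHANNELS <- c("FGSR", "HGSR", "HR")

# duration in seconds of one channel
channel_duration <- function(ch) length(ch$values) / ch$fs

#' @export
print.contrp_channel <- function(x, ...) {
  cat(sprintf("<channel %s: %d samples @ %.4g Hz, %.1f s>\n",
              x$name, length(x$values), x$fs, channel_duration(x)))
  invisible(x)
}

# kind -> stress level mapping is fixed by the driving protocol
PERIOD_KINDS <- c(rest = "low", highway = "medium", city = "high")
# marker level codes: 0 = low (rest), 1 = medium (highway), 2 = high (city)
MARKER_CODES <- c(rest = 0, highway = 1, city = 2)

#' Stress periods table
#'
#' Builds a validated table of driving periods.  Each period is a half-open
#' interval `[start_s, end_s)` of one road condition; the stress level is
#' implied by the kind (rest = low, highway = medium, city = high).
#'
#' @param kind character vector in `c("rest", "highway", "city")`.
#' @param start_s,end_s numeric vectors of period boundaries in seconds.
#' @return a `data.frame` with columns `kind`, `start_s`, `end_s`, `level`,
#'   time-ordered and non-overlapping.
#' @export
stress_periods <- function(kind, start_s, end_s) {
  if (length(kind) == 0L) abort_data("at least one period is required")
  kind <- as.character(kind)
  if (!all(kind %in% names(PERIOD_KINDS)))
    abort_data(sprintf("unknown period kind(s): %s",
                       paste(setdiff(kind, names(PERIOD_KINDS)), collapse = ", ")))
  start_s <- as.double(start_s); end_s <- as.double(end_s)
  if (length(start_s) != length(kind) || length(end_s) != length(kind))
    abort_data("kind, start_s, end_s must have equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)) || any(end_s <= start_s))
    abort_data("periods must satisfy end_s > start_s")
  p <- data.frame(kind = kind, start_s = start_s, end_s = end_s,
                  level = unname(PERIOD_KINDS[kind]),
                  stringsAsFactors = FALSE)
  p <- p[order(p$start_s), , drop = FALSE]
  rownames(p) <- NULL
  if (nrow(p) > 1L && any(p$start_s[-1L] < p$end_s[-nrow(p)] - 1e-9))
    abort_data("periods must be non-overlapping")
  p
}

#' Driving recording
#'
#' Bundle of named channels plus period annotations for one subject session.
#'
#' @param id recording identifier, e.g. `"drive06"`.
#' @param channels named list of [channel()] objects.
#' @param periods periods table as returned by [stress_periods()], or `NULL`
#'   if a `MARKER` channel carries the annotation.
#' @return an object of class `contrp_recording` with elements `id`,
#'   `channels`, `periods` and `missing_channels` (signal channels absent
#'   from this recording, reported rather than fatal).
#' @export
recording <- function(id, channels, periods = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort_data("recording id must be a non-empty string")
  if (!is.list(channels) || length(channels) == 0L)
    abort_data("channels must be a non-empty named list")
  nm <- vapply(channels, function(ch) ch$name, character(1))
  names(channels) <- nm
  if (anyDuplicated(nm)) abort_data("duplicate channel names")
  # durations must agree to within one sample period of the coarser channel
  dur <- vapply(channels, channel_duration, numeric(1))
  per <- vapply(channels, function(ch) 1 / ch$fs, numeric(1))
  for (i in seq_along(dur)) for (j in seq_along(dur)) {
    if (abs(dur[i] - dur[j]) > max(per[i], per[j]) + 1e-9)
      abort_data(sprintf(
        "channel durations inconsistent: %s %.3fs vs %s %.3fs",
        nm[i], dur[i], nm[j], dur[j]))
  }
  if (is.null(periods) && "MARKER" %in% nm) {
    mk <- channels[["MARKER"]]
    periods <- parse_marker(mk, channel_duration(mk))
  }
  if (!is.null(periods)) {
    periods <- stress_periods(periods$kind, periods$start_s, periods$end_s)
  }
  missing <- setdiff(SIGNAL_CHANNELS, nm)
  structure(list(id = id, channels = channels, periods = periods,
                 missing_channels = missing),
            class = "contrp_recording")
}

#' @export
print.contrp_recording <- function(x, ...) {
  cat(sprintf("<recording %s: %d channel(s)>\n", x$id, length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %-6s %8d samples @ %7.4g Hz  (%.1f s)\n",
                ch$name, length(ch$values), ch$fs, channel_duration(ch)))
  if (length(x$missing_channels))
    cat("  missing signal channels:", paste(x$missing_channels, collapse = ", "), "\n")
  if (!is.null(x$periods)) {
    cat(sprintf("  %d period(s):\n", nrow(x$periods)))
    for (i in seq_len(nrow(x$periods)))
      cat(sprintf("    %-7s [%8.1f, %8.1f) s  stress=%s\n",
                  x$periods$kind[i], x$periods$start_s[i],
                  x$periods$end_s[i], x$periods$level[i]))
  }
  invisible(x)
}

#' Parse a marker channel into stress periods
#'
#' The marker is a piecewise-constant channel whose value codes the stress
#' level of the current period: 0 = rest (low), 1 = highway (medium),
#' 2 = city (high).  Contiguous runs of one code become one period; the
#' periods tile `[0, total_duration_s)`.
#'
#' @param marker a `MARKER` [channel()].
#' @param total_duration_s recording duration in seconds; the final period is
#'   closed at this time.
#' @return a periods table (see [stress_periods()]).
#' @export
parse_marker <- function(marker, total_duration_s) {
  if (!inherits(marker, "contrp_channel")) abort_data("marker must be a channel")
  v <- marker$values
  if (length(v) == 0L) abort_data("empty marker channel")
  codes <- round(v)
  if (any(abs(v - codes) > 1e-6) || !all(codes %in% MARKER_CODES))
    abort_data("marker values must be level codes 0 (rest), 1 (highway), 2 (city)")
  r <- rle(codes)
  ends_idx <- cumsum(r$lengths)               # 1-based last sample of each run
  starts_idx <- c(0L, ends_idx[-length(ends_idx)])  # 0-based first sample
  kind <- names(MARKER_CODES)[match(r$values, MARKER_CODES)]
  start_s <- starts_idx / marker$fs
  end_s <- c(start_s[-1L], total_duration_s)
  stress_periods(kind, start_s, end_s)
}

#' Render stress periods as a marker channel
#'
#' Inverse of [parse_marker()]: emits the piecewise-constant code-valued
#' marker channel for a period tiling.
#'
#' @param periods periods table (see [stress_periods()]).
#' @param fs marker sampling rate in Hz.
#' @param total_duration_s recording duration; defaults to the last period end.
#' @return a `MARKER` [channel()].
#' @export
render_marker <- function(periods, fs, total_duration_s = max(periods$end_s)) {
  n <- round(total_duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  idx <- findInterval(t, periods$start_s)  # periods tile from 0, so idx >= 1
  if (any(idx < 1L)) abort_data("periods must start at 0 to render a marker")
  channel(unname(MARKER_CODES[periods$kind[idx]]), fs, "MARKER")
}

#' Read a recording directory
#'
#' A recording directory contains `manifest.csv` (columns `channel,file`),
#' one two-column CSV per channel (`time_s,value`, strictly increasing
#' timestamps) and optionally `periods.csv` (`kind,start_s,end_s`).  Native
#' sampling rates are inferred from the timestamps, which tolerates the
#' 33-35 Hz variability of real GSR recordings.  If `periods.csv` is absent
#' the `MARKER` channel must be present and is parsed with [parse_marker()].
#'
#' @param path directory path.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) abort_io(sprintf("no such directory: %s", path))
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) abort_format(sprintf("missing manifest.csv in %s", path))
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (!all(c("channel", "file") %in% names(man)))
    abort_format("manifest.csv must have columns channel,file")
  chans <- list()
  for (i in seq_len(nrow(man))) {
    nm <- man$channel[i]
    if (!nm %in% CHANNEL_NAMES) abort_data(sprintf("unknown channel name '%s'", nm))
    f <- file.path(path, man$file[i])
    if (!file.exists(f)) abort_io(sprintf("missing channel file %s", f))
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!all(c("time_s", "value") %in% names(d)))
      abort_format(sprintf("%s must have columns time_s,value", f))
    if (nrow(d) == 0L) abort_data(sprintf("zero-length channel file %s", f))
    tt <- d$time_s
    if (nrow(d) >= 2L && any(diff(tt) <= 0))
      abort_data(sprintf("non-monotone timestamps in %s", f))
    fs <- if (nrow(d) >= 2L) 1 / stats::median(diff(tt)) else 1
    chans[[nm]] <- channel(d$value, fs, nm)
  }
  pf <- file.path(path, "periods.csv")
  periods <- NULL
  if (file.exists(pf)) {
    pd <- utils::read.csv(pf, stringsAsFactors = FALSE)
    if (!all(c("kind", "start_s", "end_s") %in% names(pd)))
      abort_format("periods.csv must have columns kind,start_s,end_s")
    periods <- stress_periods(pd$kind, pd$start_s, pd$end_s)
  } else if (!"MARKER" %in% names(chans)) {
    abort_format(sprintf(
      "%s has neither periods.csv nor a MARKER channel", path))
  }
  recording(basename(normalizePath(path)), chans, periods)
}

#' Write a recording directory
#'
#' Writes the directory layout read by [read_recording()].  Refuses to write
#' a recording that has neither periods nor a `MARKER` channel, since it
#' could not be labeled on re-read.  Channel values are written with enough
#' digits to round-trip to 1e-9.
#'
#' @param rec a [recording()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "contrp_recording")) abort_data("rec must be a recording")
  if (is.null(rec$periods) && !"MARKER" %in% names(rec$channels))
    abort_data("recording has neither periods nor a MARKER channel; refusing to write")
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort_io(sprintf("cannot create directory %s", path))
  man <- data.frame(channel = character(0), file = character(0))
  for (ch in rec$channels) {
    fn <- paste0(tolower(ch$name), ".csv")
    tt <- (seq_along(ch$values) - 1L) / ch$fs
    df <- data.frame(time_s = sprintf("%.12g", tt),
                     value = sprintf("%.12g", ch$values))
    utils::write.csv(df, file.path(path, fn), row.names = FALSE, quote = FALSE)
    man <- rbind(man, data.frame(channel = ch$name, file = fn))
  }
  utils::write.csv(man, file.path(path, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(rec$periods)) {
    pd <- rec$periods[, c("kind", "start_s", "end_s")]
    pd$start_s <- sprintf("%.12g", pd$start_s)
    pd$end_s <- sprintf("%.12g", pd$end_s)
    utils::write.csv(pd, file.path(path, "periods.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
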