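#' Preprocessing configuration
#'
#' Parameters of the raw-signal conditioning chain.  The chain (in fixed
#' order) is: resample to `target_fs`, median filter, z-normalize, cut into
#' `window_s`-second windows with `overlap_fraction` overlap, label windows
#' from the period annotation.
#'
#' @param target_fs common sampling rate in Hz all channels are brought to
#'   (default 16).
#' @param median_kernel odd number of samples in the spike-removal median
#'   filter (default 5, about 0.31 s at 16 Hz).
#' @param window_s window length in seconds; 10 and 30 are the supported
#'   short-term lengths (default 30).
#' @param overlap_fraction fraction of a window shared with its successor,
#'   in `[0, 1)` (default 0.5).
#' @return an object of class `contrp_preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 16, median_kernel = 5,
                              window_s = 30, overlap_fraction = 0.5) {
  if (!is_scalar_num(target_fs) || target_fs <= 0)
    abort_config("target_fs must be positive")
  if (!is_count(median_kernel) || median_kernel %% 2 == 0)
    abort_config("median_kernel must be an odd positive integer")
  if (!is_scalar_num(window_s) || window_s <= 0)
    abort_config("window_s must be positive")
  w <- window_s * target_fs
  if (abs(w - round(w)) > 1e-9)
    abort_config("window_s * target_fs must be an integer sample count")
  if (!is_scalar_num(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1)
    abort_config("overlap_fraction must be in [0, 1)")
  structure(list(target_fs = as.double(target_fs),
                 median_kernel = as.integer(median_kernel),
                 window_s = as.double(window_s),
                 overlap_fraction = as.double(overlap_fraction)),
            class = "contrp_preprocess_config")
}

#' Resample a channel to a target rate
#'
#' Downsampling (e.g. 33-35 Hz GSR to 16 Hz) first applies a zero-phase
#' Butterworth anti-alias low-pass (order 4, cutoff 0.8 of the new Nyquist)
#' and then linearly interpolates onto the uniform target grid; upsampling
#' (e.g. 1 Hz HR to 16 Hz) linearly interpolates directly.  A channel
#' already at the target rate is returned unchanged.
#'
#' @param ch a [channel()] with at least 2 samples.
#' @param target_fs target rate in Hz.
#' @return a [channel()] at `target_fs` with `round(duration * target_fs)`
#'   samples.
#' @export
resample_channel <- function(ch, target_fs) {
  if (!inherits(ch, "contrp_channel")) abort_data("ch must be a channel")
  if (length(ch$values) < 2L) abort_data("resample needs at least 2 samples")
  if (!is_scalar_num(target_fs) || target_fs <= 0)
    abort_config("target_fs must be positive")
  if (abs(ch$fs - target_fs) < 1e-9) return(ch)
  x <- ch$values
  n <- length(x)
  t_in <- (seq_len(n) - 1L) / ch$fs
  if (ch$fs > target_fs && n >= 24L) {
    # anti-alias before decimating; cutoff at 0.8 of the target Nyquist
    bf <- signal::butter(4, 0.8 * target_fs / ch$fs, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  n_out <- round(n / ch$fs * target_fs)
  t_out <- (seq_len(n_out) - 1L) / target_fs
  y <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
  channel(y, target_fs, ch$name)
}

#' Median filter a channel
#'
#' Sliding odd-width median with reflected (edge-replicating) boundary
#' handling; removes isolated spikes from poor electrode contact or motion
#' without smearing signal edges.
#'
#' @param ch a [channel()].
#' @param kernel odd window width in samples, at most `length(ch$values)`.
#' @return a filtered [channel()] of identical length and rate.
#' @export
median_filter_channel <- function(ch, kernel) {
  if (!inherits(ch, "contrp_channel")) abort_data("ch must be a channel")
  if (!is_count(kernel) || kernel %% 2 == 0)
    abort_config("kernel must be an odd positive integer")
  n <- length(ch$values)
  if (kernel > n) abort_config("kernel wider than the signal")
  if (kernel == 1L) return(ch)
  p <- (kernel - 1L) / 2L
  x <- ch$values
  padded <- c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1L):n]))
  y <- stats::runmed(padded, kernel, endrule = "keep")[(p + 1L):(p + n)]
  channel(as.double(y), ch$fs, ch$name)
}

#' Z-normalize a channel
#'
#' Rescales to zero mean and unit population standard deviation (denominator
#' n), making amplitudes comparable across subjects and electrode placements.
#'
#' @param ch a non-constant [channel()].
#' @return the standardized [channel()].
#' @export
znorm_channel <- function(ch) {
  if (!inherits(ch, "contrp_channel")) abort_data("ch must be a channel")
  x <- ch$values
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) abort_data("constant channel cannot be z-normalized")
  channel((x - mu) / sd_pop, ch$fs, ch$name)
}

#' Cut a channel into overlapping windows
#'
#' Windows of `window_s` seconds starting at 0 and stepping by
#' `window_s * (1 - overlap_fraction)`; trailing partial windows are
#' dropped.  The channel must already be at `cfg$target_fs`.
#'
#' @param ch a [channel()] at the target rate.
#' @param cfg a [preprocess_config()].
#' @return a list with `start_s` (numeric vector of window starts) and
#'   `values` (matrix, one row per window).  Zero rows when the signal is
#'   shorter than one window.
#' @export
segment_channel <- function(ch, cfg) {
  if (!inherits(ch, "contrp_channel")) abort_data("ch must be a channel")
  if (abs(ch$fs - cfg$target_fs) > 1e-9)
    abort_data("channel must be resampled to target_fs before segmenting")
  w <- as.integer(round(cfg$window_s * cfg$target_fs))
  step_s <- cfg$window_s * (1 - cfg$overlap_fraction)
  step <- step_s * cfg$target_fs
  if (abs(step - round(step)) > 1e-9)
    abort_config("window step must be an integer sample count")
  step <- as.integer(round(step))
  n <- length(ch$values)
  if (n < w)
    return(list(start_s = numeric(0),
                values = matrix(numeric(0), nrow = 0, ncol = w)))
  starts <- seq.int(0L, n - w, by = step)
  vals <- t(vapply(starts,
                   function(s) ch$values[(s + 1L):(s + w)],
                   numeric(w)))
  list(start_s = starts / cfg$target_fs, values = vals)
}

#' Label windows from the period annotation
#'
#' A window fully inside a rest period is `relaxed`; fully inside a city
#' period it is `stressed`.  Windows inside highway (medium-stress) periods
#' and windows overlapping any period boundary are discarded — the task is
#' the two-class low-vs-high contrast and transition windows have no single
#' ground truth.
#'
#' @param windows output of [segment_channel()].
#' @param periods periods table (see [stress_periods()]).
#' @param window_s window length in seconds.
#' @param channel_name,recording_id metadata attached to each segment.
#' @return a list of `contrp_segment` objects (elements `values`, `channel`,
#'   `label`, `recording_id`, `start_s`); discarded windows are absent.
#' @export
label_segments <- function(windows, periods, window_s,
                           channel_name = "FGSR", recording_id = "") {
  lab <- label_windows(windows$start_s, window_s, periods)
  keep <- which(!is.na(lab))
  lapply(keep, function(i) {
    structure(list(values = windows$values[i, ],
                   channel = channel_name,
                   label = lab[i],
                   recording_id = recording_id,
                   start_s = windows$start_s[i]),
              class = "contrp_segment")
  })
}

# label per window start: "relaxed", "stressed" or NA (discard)
label_windows <- function(start_s, window_s, periods) {
  vapply(start_s, function(s) {
    e <- s + window_s
    inside <- periods$start_s <= s + 1e-9 & e <= periods$end_s + 1e-9
    if (!any(inside)) return(NA_character_)   # straddles a boundary
    kind <- periods$kind[which(inside)[1L]]
    switch(kind, rest = "relaxed", city = "stressed",
           NA_character_)                     # highway: discarded
  }, character(1))
}

#' Full preprocessing chain for one recording
#'
#' Applies resample, median filter and z-normalization to each of FGSR,
#' HGSR and HR, segments them on a common window grid, and labels windows
#' from the recording's periods.  Labeling is identical across channels, so
#' the result is one labeled multi-channel window per kept start time.
#'
#' @param rec a [recording()] containing the three signal channels and
#'   periods.
#' @param cfg a [preprocess_config()].
#' @return a list of labeled windows; each has `channels` (named list of
#'   numeric vectors), `label`, `recording_id`, `start_s`, plus an attribute
#'   `"config"` carrying `cfg`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  if (!inherits(rec, "contrp_recording")) abort_data("rec must be a recording")
  if (length(rec$missing_channels))
    abort_data(sprintf("recording %s is missing channel(s): %s", rec$id,
                       paste(rec$missing_channels, collapse = ", ")))
  if (is.null(rec$periods))
    abort_data(sprintf("recording %s has no period annotation", rec$id))
  segs <- lapply(SIGNAL_CHANNELS, function(nm) {
    ch <- rec$channels[[nm]]
    ch <- resample_channel(ch, cfg$target_fs)
    ch <- median_filter_channel(ch, cfg$median_kernel)
    ch <- znorm_channel(ch)
    segment_channel(ch, cfg)
  })
  names(segs) <- SIGNAL_CHANNELS
  # channels can differ by one trailing window when native durations differ
  # by a fraction of a sample; use the common prefix of the window grid
  n_win <- min(vapply(segs, function(s) length(s$start_s), integer(1)))
  if (n_win == 0L) return(structure(list(), config = cfg))
  start_s <- segs[[1L]]$start_s[seq_len(n_win)]
  lab <- label_windows(start_s, cfg$window_s, rec$periods)
  keep <- which(!is.na(lab))
  out <- lapply(keep, function(i) {
    list(channels = lapply(segs, function(s) s$values[i, ]),
         label = lab[i], recording_id = rec$id, start_s = start_s[i])
  })
  structure(out, config = cfg)
}

#' Random undersampling of the majority class
#'
#' Discards randomly chosen majority-class sample triples until both classes
#' have `min(class counts)` members.  Selection is deterministic given
#' `seed`; input order of the retained samples is preserved.
#'
#' @param triples list of sample triples (see [make_sample_triples()]);
#'   anything with a `label` element works.
#' @param seed integer seed for the random selection.
#' @return the balanced subset of `triples`.
#' @export
undersample_triples <- function(triples, seed) {
  labs <- vapply(triples, function(s) s$label, character(1))
  n_s <- sum(labs == "stressed"); n_r <- sum(labs == "relaxed")
  if (n_s == 0L || n_r == 0L)
    abort_data("both classes must be present to undersample")
  n_keep <- min(n_s, n_r)
  keep <- seq_along(triples)
  maj <- if (n_s > n_r) "stressed" else "relaxed"
  if (n_s != n_r) {
    idx_maj <- which(labs == maj)
    kept_maj <- with_seed(seed, sample(idx_maj, n_keep))
    keep <- sort(c(which(labs != maj), kept_maj))
  }
  triples[keep]
}
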