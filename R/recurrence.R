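#' Time-delay embedding configuration
#'
#' @param m embedding dimension (default 3).
#' @param tau time delay in samples at the 16 Hz working rate, i.e. units of
#'   0.0625 s (default 2).
#' @return an object of class `contrp_embedding_config`.
#' @export
embedding_config <- function(m = 3, tau = 2) {
  if (!is_count(m)) abort_config("m must be a positive integer")
  if (!is_count(tau)) abort_config("tau must be a positive integer")
  structure(list(m = as.integer(m), tau = as.integer(tau)),
            class = "contrp_embedding_config")
}

#' Time-delay embedding of a scalar series
#'
#' Maps `x` into its m-dimensional delay vectors
#' `(x[i], x[i + tau], ..., x[i + (m-1) tau])`, the standard phase-space
#' reconstruction of a scalar observable.
#'
#' @param x numeric vector of length `N > (m-1) * tau`.
#' @param cfg an [embedding_config()].
#' @return a matrix with `M = N - (m-1) * tau` rows (delay vectors) and `m`
#'   columns.
#' @export
embed_delay <- function(x, cfg = embedding_config()) {
  n <- length(x)
  m <- cfg$m; tau <- cfg$tau
  M <- n - (m - 1L) * tau
  if (M < 1L)
    abort_data(sprintf("series too short: N=%d <= (m-1)*tau=%d", n, (m - 1L) * tau))
  out <- matrix(0, nrow = M, ncol = m)
  for (j in seq_len(m)) out[, j] <- x[(seq_len(M)) + (j - 1L) * tau]
  out
}

#' Continuous recurrence plot of a segment
#'
#' The continuous recurrence plot (Cont-RP) of a series is the full matrix
#' of pairwise Euclidean distances between its delay-embedded states — a
#' recurrence plot without the classical distance threshold, so the degree
#' of recurrence is kept instead of a binary flag.
#'
#' @param x numeric vector (a preprocessed segment) or a `contrp_segment`.
#' @param cfg an [embedding_config()].
#' @return an object of class `contrp_rp`: list with `D` (M x M symmetric
#'   non-negative matrix, zero diagonal), `m`, `tau`.
#' @export
cont_rp <- function(x, cfg = embedding_config()) {
  if (inherits(x, "contrp_segment")) x <- x$values
  E <- embed_delay(x, cfg)
  D <- as.matrix(stats::dist(E))
  dimnames(D) <- NULL
  structure(list(D = D, m = cfg$m, tau = cfg$tau), class = "contrp_rp")
}

#' @export
print.contrp_rp <- function(x, ...) {
  cat(sprintf("<Cont-RP %dx%d (m=%d, tau=%d), distances in [%.4g, %.4g]>\n",
              nrow(x$D), ncol(x$D), x$m, x$tau, min(x$D), max(x$D)))
  invisible(x)
}

#' Rescale a Cont-RP to the unit interval
#'
#' Per-plot min-max rescaling to `[0, 1]` used to condition CNN inputs; a
#' constant (all-zero) plot maps to all zeros.
#'
#' @param rp a [cont_rp()] object or a plain distance matrix.
#' @return a numeric matrix with values in `[0, 1]`.
#' @export
rp_to_image <- function(rp) {
  D <- if (inherits(rp, "contrp_rp")) rp$D else rp
  lo <- min(D); hi <- max(D)
  if (hi - lo == 0) return(matrix(0, nrow(D), ncol(D)))
  (D - lo) / (hi - lo)
}

#' Build (FGSR, HGSR, HR) Cont-RP sample triples for a recording
#'
#' Runs the preprocessing chain, then converts each labeled window's three
#' channels into Cont-RP images of equal side
#' `window_s * 16 - (m-1) * tau` (156 for 10 s windows, 476 for 30 s).
#' By default the raw distance matrices are used: the signals are already
#' z-normalized per recording, so distances are in comparable units across
#' recordings, and the overall distance magnitude of a window (quiescent
#' versus eventful) is itself a discriminative cue that per-plot min-max
#' rescaling would erase.
#'
#' @param rec a [recording()].
#' @param pre_cfg a [preprocess_config()].
#' @param emb_cfg an [embedding_config()].
#' @param rescale min-max rescale each plot to `[0,1]` (default `FALSE`;
#'   see above).
#' @return list of `contrp_triple` objects: `rp_fgsr`, `rp_hgsr`, `rp_hr`
#'   (matrices), `label` (`"stressed"`/`"relaxed"`), `recording_id`,
#'   `start_s`.
#' @export
make_sample_triples <- function(rec, pre_cfg = preprocess_config(),
                                emb_cfg = embedding_config(),
                                rescale = FALSE) {
  wins <- preprocess_recording(rec, pre_cfg)
  lapply(wins, function(w) {
    rps <- lapply(w$channels[SIGNAL_CHANNELS], function(v) {
      rp <- cont_rp(v, emb_cfg)
      if (rescale) rp_to_image(rp) else rp$D
    })
    structure(list(rp_fgsr = rps$FGSR, rp_hgsr = rps$HGSR, rp_hr = rps$HR,
                   label = w$label, recording_id = w$recording_id,
                   start_s = w$start_s),
              class = "contrp_triple")
  })
}

# labels of a triple list as 0/1 numeric (stressed = 1)
triple_y <- function(triples) {
  as.numeric(vapply(triples, function(s) s$label, character(1)) == "stressed")
}

# side length of the (square) plots of one triple, with consistency check
triple_side <- function(s) {
  sides <- c(nrow(s$rp_fgsr), nrow(s$rp_hgsr), nrow(s$rp_hr))
  if (length(unique(sides)) != 1L)
    abort_data("triple has plots of unequal side")
  sides[1L]
}
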