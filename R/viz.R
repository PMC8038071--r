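# colormap used for recurrence-plot rendering: low = dark blue, high = yellow
rp_colormap <- function() {
  grDevices::colorRamp(c("#440154", "#414487", "#2A788E", "#22A884",
                         "#7AD151", "#FDE725"), space = "rgb")
}

#' Render a continuous recurrence plot to a PNG image
#'
#' One pixel per matrix entry (side M for an M x M plot), colored with a
#' perceptual dark-blue-to-yellow map after min-max scaling.  Rendering is
#' deterministic.
#'
#' @param rp a [cont_rp()] object or a numeric matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_rp_image <- function(rp, path) {
  img <- rp_to_image(rp)
  rgb01 <- rp_colormap()(as.vector(img)) / 255
  arr <- array(rgb01, dim = c(nrow(img), ncol(img), 3))
  ok <- tryCatch({ png::writePNG(arr, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write PNG to %s", path))
  invisible(path)
}

# perplexity calibration: binary search the Gaussian bandwidth per point
tsne_p_matrix <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:64) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { h <- 0 }
      else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))   # Shannon entropy
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- exp(-d * beta) / max(sum(exp(-d * beta)), .Machine$double.xmin)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Nonlinear 2-D embedding of representation vectors
#'
#' Exact t-SNE (O(n^2)) of the 768-dimensional pre-head representation
#' vectors, used to inspect whether learned features separate stressed from
#' relaxed samples.  Initialization is a scaled PCA projection, so the
#' embedding is deterministic given `seed` (the seed is only consumed in
#' the degenerate all-identical-points fallback).  If `plot_file` is given,
#' a scatter plot is written with stressed samples in red and relaxed in
#' green.
#'
#' @param representations numeric matrix, one row per sample (>= 3 rows).
#' @param labels optional character labels (`"stressed"`/`"relaxed"`) used
#'   only for plot coloring.
#' @param seed integer seed for the random initialization.
#' @param perplexity t-SNE perplexity; default `min(30, (n - 1) / 3)`.
#' @param n_iter gradient-descent iterations (default 500).
#' @param plot_file optional PNG path for the colored scatter plot.
#' @return an `n x 2` matrix of embedding coordinates.
#' @export
embed_2d <- function(representations, labels = NULL, seed = 1,
                     perplexity = NULL, n_iter = 500, plot_file = NULL) {
  X <- as.matrix(representations)
  n <- nrow(X)
  if (n < 3L) abort_data("embed_2d needs at least 3 points")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  if (perplexity <= 0 || 3 * perplexity > n - 1)
    abort_config("perplexity must satisfy 0 < 3 * perplexity <= n - 1")
  X <- scale(X, center = TRUE, scale = FALSE)
  if (ncol(X) > 50) {  # standard PCA pre-reduction
    X <- stats::prcomp(X, rank. = 50, center = FALSE)$x
  }
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_p_matrix(D2, perplexity)
  # PCA initialization (scaled small, the standard choice): deterministic,
  # and exact duplicates start coincident and stay coincident by symmetry
  pc <- stats::prcomp(X, rank. = 2, center = FALSE)$x
  if (stats::sd(pc[, 1]) > 0) {
    Y <- pc / stats::sd(pc[, 1]) * 1e-4
  } else {
    Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  }
  G <- matrix(1, n, 2)          # adaptive gains
  dY_prev <- matrix(0, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    mult <- if (it <= 100) 12 else 1      # early exaggeration
    mom <- if (it <= 250) 0.5 else 0.8
    d2y <- as.matrix(stats::dist(Y))^2
    Qn <- 1 / (1 + d2y); diag(Qn) <- 0
    Z <- sum(Qn)
    Q <- pmax(Qn / Z, 1e-12)
    L <- (mult * P - Q) * Qn
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    G <- ifelse(sign(grad) != sign(dY_prev), G + 0.2, G * 0.8)
    G[G < 0.01] <- 0.01
    dY_prev <- mom * dY_prev - eta * G * grad
    Y <- Y + dY_prev
    Y <- sweep(Y, 2, colMeans(Y))
  }
  if (!is.null(plot_file)) {
    cols <- if (is.null(labels)) rep("grey30", n) else
      ifelse(labels == "stressed", "red", "green3")
    grDevices::png(plot_file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
    plot(Y[, 1], Y[, 2], col = cols, pch = 19,
         xlab = "dim 1", ylab = "dim 2",
         main = "2-D embedding of representation vectors")
    graphics::legend("topright", legend = c("stressed", "relaxed"),
                     col = c("red", "green3"), pch = 19)
  }
  Y
}
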