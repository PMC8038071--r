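# shared fixtures, all generated in code

# short 7-period route for fast pipeline tests
short_route <- function(scale = 1) {
  data.frame(kind = c("rest", "city", "highway", "city", "highway", "city", "rest"),
             duration_s = scale * c(50, 40, 20, 40, 20, 40, 50),
             stringsAsFactors = FALSE)
}

# desk-scale study conditions for the end-to-end synthetic experiment:
# large stress contrast, small sensor noise, 1.5x short route
e2e_sim_config <- function(seed, stress_contrast = 5) {
  sim_config(seed = seed, route = short_route(1.5),
             stress_contrast = stress_contrast,
             gsr_noise_sd = 0.02, hr_noise_sd = 1)
}

e2e_arch <- function() arch_config(c(8, 16, 32, 64, 64))

e2e_train_config <- function(seed) {
  train_config(learning_rate = 0.005, batch_size = 4, epochs = 5, seed = seed)
}

# tiny random image triples for fast model tests (no physiological content)
random_triples <- function(n, side = 32, seed = 1, labels = NULL, id = "r1") {
  with_seed2(seed, lapply(seq_len(n), function(i) {
    lab <- if (is.null(labels)) ifelse(i %% 2 == 0, "stressed", "relaxed")
      else labels[i]
    structure(list(rp_fgsr = matrix(stats::runif(side * side), side, side),
                   rp_hgsr = matrix(stats::runif(side * side), side, side),
                   rp_hr = matrix(stats::runif(side * side), side, side),
                   label = lab, recording_id = id, start_s = i),
              class = "contrp_triple")
  }))
}

# image triples whose class is trivially separable (bright vs dark blocks),
# spread over several pseudo-recordings
separable_triples <- function(n_per_rec, n_rec = 2, side = 32, seed = 1) {
  with_seed2(seed, {
    out <- list()
    for (r in seq_len(n_rec)) {
      for (i in seq_len(n_per_rec)) {
        lab <- if (i %% 2 == 0) "stressed" else "relaxed"
        base <- if (lab == "stressed") 0.8 else 0.2
        mk <- function() matrix(base + stats::rnorm(side * side, 0, 0.05), side, side)
        out[[length(out) + 1L]] <- structure(
          list(rp_fgsr = mk(), rp_hgsr = mk(), rp_hr = mk(),
               label = lab, recording_id = sprintf("rec%02d", r),
               start_s = i),
          class = "contrp_triple")
      }
    }
    out
  })
}

# local-seed evaluation that restores the caller's RNG state
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

triple_labels <- function(triples) vapply(triples, function(s) s$label, character(1))
triple_ids <- function(triples) vapply(triples, function(s) s$recording_id, character(1))
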