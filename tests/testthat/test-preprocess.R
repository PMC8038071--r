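# signal conditioning: resampling, median filtering, normalization,
# windowing, labeling, undersampling

test_that("resampling hits the target rate and sample count", {
  ch <- channel(sin(seq_len(960) / 7), 32, "FGSR")   # 30 s @ 32 Hz
  out <- resample_channel(ch, 16)
  expect_equal(out$fs, 16)
  expect_equal(length(out$values), 480L)             # duration x 16

  # already at 16 Hz: untouched
  ch16 <- channel(rnorm(160), 16, "HGSR")
  expect_equal(resample_channel(ch16, 16)$values, ch16$values, tolerance = 1e-9)

  # constant 1 Hz channel upsampled stays constant
  out <- resample_channel(channel(rep(3.5, 30), 1, "HR"), 16)
  expect_equal(length(out$values), 480L)
  expect_true(all(abs(out$values - 3.5) < 1e-9))

  expect_error(resample_channel(channel(1, 1, "HR"), 16),
               class = "contrp_data_error")
})

test_that("resampling preserves duration across random rates", {
  for (seed in 1:10) {
    ch <- with_seed2(seed, {
      fs <- runif(1, 0.5, 40)
      channel(rnorm(max(2, round(fs * runif(1, 5, 40)))), fs, "FGSR")
    })
    out <- resample_channel(ch, 16)
    expect_lte(abs(length(out$values) / 16 - length(ch$values) / ch$fs), 1 / 16)
  }
})

test_that("median filter removes spikes and keeps monotone ramps", {
  spike <- channel(c(0, 0, 100, 0, 0), 1, "FGSR")
  expect_equal(median_filter_channel(spike, 3)$values, rep(0, 5))

  ramp <- channel(c(1, 2, 3, 4, 5), 1, "FGSR")
  expect_equal(median_filter_channel(ramp, 3)$values, c(1, 2, 3, 4, 5))

  const <- channel(rep(2.2, 40), 16, "HGSR")
  expect_equal(median_filter_channel(const, 5)$values, const$values)

  expect_error(median_filter_channel(ramp, 2), class = "contrp_config_error")
  expect_error(median_filter_channel(ramp, 7), class = "contrp_config_error")
})

test_that("median filter output stays within the input range", {
  for (seed in 1:10) {
    ch <- with_seed2(seed, channel(rnorm(200), 16, "FGSR"))
    out <- median_filter_channel(ch, 5)
    expect_equal(length(out$values), 200L)
    expect_gte(min(out$values), min(ch$values))
    expect_lte(max(out$values), max(ch$values))
  }
})

test_that("z-normalization yields mean 0 and unit population SD", {
  out <- znorm_channel(channel(c(1, 2, 3), 1, "HR"))
  expect_equal(out$values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)

  x <- rnorm(500, 10, 4)
  z <- znorm_channel(channel(x, 16, "FGSR"))$values
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)

  # idempotent on standardized input, invariant to positive affine maps
  z2 <- znorm_channel(channel(z, 16, "FGSR"))$values
  expect_equal(z2, z, tolerance = 1e-9)
  za <- znorm_channel(channel(3.7 * x + 11, 16, "FGSR"))$values
  expect_equal(za, z, tolerance = 1e-9)

  expect_error(znorm_channel(channel(rep(1, 10), 1, "HR")),
               class = "contrp_data_error")
})

test_that("segmentation follows the 50%-overlap window grid", {
  cfg <- preprocess_config(window_s = 30)
  s <- segment_channel(channel(rnorm(60 * 16), 16, "FGSR"), cfg)
  expect_equal(s$start_s, c(0, 15, 30))
  expect_equal(ncol(s$values), 480L)

  expect_equal(length(segment_channel(channel(rnorm(30 * 16), 16, "FGSR"), cfg)$start_s), 1L)
  expect_equal(length(segment_channel(channel(rnorm(29 * 16), 16, "FGSR"), cfg)$start_s), 0L)

  # adjacent windows share exactly half their samples
  ch <- channel(rnorm(45 * 16), 16, "FGSR")
  s <- segment_channel(ch, cfg)
  expect_equal(s$values[1, 241:480], s$values[2, 1:240])
})

test_that("window labels follow period kind and boundary exclusion", {
  periods <- stress_periods(c("rest", "city", "highway"),
                            c(0, 100, 160), c(100, 160, 220))
  expect_equal(label_windows(0, 30, periods), "relaxed")     # inside rest
  expect_equal(label_windows(70, 30, periods), "relaxed")    # touches boundary from inside
  expect_equal(label_windows(90, 30, periods), NA_character_)  # straddles 100 s
  expect_equal(label_windows(110, 30, periods), "stressed")  # inside city
  expect_equal(label_windows(170, 30, periods), NA_character_) # highway discarded
})

test_that("no labeled window ever contains a period boundary", {
  for (seed in 1:25) {
    p <- with_seed2(seed, {
      n <- sample(2:7, 1)
      ends <- cumsum(sample(20:90, n, replace = TRUE))
      stress_periods(sample(c("rest", "highway", "city"), n, replace = TRUE),
                     c(0, ends[-n]), ends)
    })
    total <- max(p$end_s)
    starts <- seq(0, total - 30, by = 5)
    lab <- label_windows(starts, 30, p)
    boundaries <- p$start_s[-1]
    for (i in which(!is.na(lab))) {
      inside <- boundaries > starts[i] & boundaries < starts[i] + 30
      expect_false(any(inside))
    }
  }
})

test_that("undersampling balances classes deterministically", {
  tr <- random_triples(14, side = 8,
                       labels = rep(c("stressed", "relaxed"), c(10, 4)))
  out <- undersample_triples(tr, seed = 5)
  expect_equal(unname(table(triple_labels(out))["stressed"]), 4L)
  expect_equal(unname(table(triple_labels(out))["relaxed"]), 4L)
  # retained samples are a subset of the input
  expect_true(all(vapply(out, function(s) s$start_s, numeric(1)) %in%
                    vapply(tr, function(s) s$start_s, numeric(1))))
  # deterministic given the seed
  out2 <- undersample_triples(tr, seed = 5)
  expect_identical(vapply(out2, function(s) s$start_s, numeric(1)),
                   vapply(out, function(s) s$start_s, numeric(1)))
  # balanced input is untouched
  bal <- random_triples(8, side = 8)
  expect_equal(triple_labels(undersample_triples(bal, 1)), triple_labels(bal))
  # single-class input is an error
  expect_error(undersample_triples(random_triples(4, side = 8,
                                                  labels = rep("stressed", 4)), 1),
               class = "contrp_data_error")
})

test_that("preprocess_recording runs the full chain and labels windows", {
  rec <- generate_recording(sim_config(seed = 3, route = short_route()), "p1")
  wins <- preprocess_recording(rec, preprocess_config(window_s = 10))
  expect_gt(length(wins), 10)
  for (w in wins[c(1, length(wins))]) {
    expect_setequal(names(w$channels), c("FGSR", "HGSR", "HR"))
    expect_equal(length(w$channels$FGSR), 160L)
    expect_true(w$label %in% c("stressed", "relaxed"))
    expect_equal(w$recording_id, "p1")
  }
  # both classes appear and highway windows are gone: the 20 s highway
  # periods cannot contain a full in-period 10 s window labeled anything
  expect_setequal(unique(vapply(wins, function(w) w$label, character(1))),
                  c("stressed", "relaxed"))
})

test_that("preprocess configuration is validated", {
  expect_error(preprocess_config(median_kernel = 4), class = "contrp_config_error")
  expect_error(preprocess_config(window_s = 10.3), class = "contrp_config_error")
  expect_error(preprocess_config(overlap_fraction = 1), class = "contrp_config_error")
})
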