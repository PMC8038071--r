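# multimodal CNN: architecture contracts, forward/backward, training

small_arch <- function() arch_config(c(2, 3, 4, 3, 2))

test_that("architecture configuration enforces the five-block contract", {
  a <- arch_config()
  expect_equal(a$block_filters, c(32L, 64L, 128L, 256L, 256L))
  expect_equal(a$convs_per_block, c(2L, 2L, 3L, 3L, 3L))
  expect_equal(a$branch_feature_dim, 256L)
  expect_equal(a$repr_dim, 768L)
  expect_error(arch_config(c(8, 16, 32)), class = "contrp_config_error")
})

test_that("parameter count matches the closed-form per-layer formula", {
  for (filters in list(c(32, 64, 128, 256, 256), c(2, 3, 4, 3, 2))) {
    arch <- arch_config(filters)
    model <- build_model(arch, seed = 1)
    cpb <- arch$convs_per_block
    expected <- 0
    c_in <- 1
    for (b in 1:5) for (k in seq_len(cpb[b])) {
      expected <- expected + (9 * c_in + 1) * filters[b]
      c_in <- filters[b]
    }
    expected <- 3 * expected + (3 * filters[5] + 1)  # 3 branches + head
    expect_equal(count_parameters(model), expected)
  }
})

test_that("branch features and concatenated representation have the stated dims", {
  model <- build_model(small_arch(), seed = 2)
  tr <- random_triples(3, side = 32)
  repr <- extract_representation(model, tr)
  expect_equal(dim(repr), c(3L, 6L))  # 3 x branch_feature_dim(2) x 3 branches
  p <- predict_cnn(model, tr)
  expect_true(all(p$p > 0 & p$p < 1))
})

test_that("all-zero input still yields probabilities strictly inside (0,1)", {
  model <- build_model(small_arch(), seed = 3)
  z <- matrix(0, 32, 32)
  tr <- list(structure(list(rp_fgsr = z, rp_hgsr = z, rp_hr = z,
                            label = "relaxed", recording_id = "r", start_s = 0),
                       class = "contrp_triple"))
  p <- predict_cnn(model, tr)$p
  expect_gt(p, 0); expect_lt(p, 1)
})

test_that("representation is head-independent and permutation-equivariant", {
  model <- build_model(small_arch(), seed = 4)
  tr <- random_triples(4, side = 32, seed = 11)
  repr <- extract_representation(model, tr)
  # reinitializing the head leaves the representation untouched
  model2 <- model
  model2$head <- list(w = rnorm(length(model$head$w)), b = 1.3)
  expect_identical(extract_representation(model2, tr), repr)
  # permuting the batch permutes the rows identically
  perm <- c(3, 1, 4, 2)
  expect_identical(extract_representation(model, tr[perm]), repr[perm, ])
})

test_that("zeroing one branch input changes only that branch's block", {
  model <- build_model(small_arch(), seed = 5)
  tr <- random_triples(1, side = 32, seed = 12)
  repr0 <- extract_representation(model, tr)
  fd <- small_arch()$branch_feature_dim
  blocks <- list(fgsr = 1:fd, hgsr = fd + 1:fd, hr = 2 * fd + 1:fd)
  for (ch in names(blocks)) {
    tz <- tr
    slot <- paste0("rp_", ch)
    tz[[1]][[slot]] <- matrix(0, 32, 32)
    reprz <- extract_representation(model, tz)
    other <- setdiff(seq_len(3 * fd), blocks[[ch]])
    expect_identical(reprz[, other], repr0[, other])
    expect_false(isTRUE(all.equal(reprz[, blocks[[ch]]], repr0[, blocks[[ch]]])))
  }
})

test_that("mismatched plot sides within a batch are rejected", {
  tr <- c(random_triples(1, side = 32), random_triples(1, side = 36))
  model <- build_model(small_arch(), seed = 6)
  expect_error(extract_representation(model, tr), class = "contrp_data_error")
})

test_that("backpropagated gradients match central finite differences", {
  tr <- random_triples(6, side = 32, seed = 7)
  arch <- arch_config(c(2, 3, 4, 3, 2))
  m0 <- build_model(arch, seed = 5)
  loss_at <- function(m) {
    # lr = 0: the epoch-1 trace is the mean loss at the current weights
    train_cnn(m, tr, train_config(learning_rate = 0, epochs = 1,
                                  batch_size = 6, seed = 1))$loss[1]
  }
  lr <- 1e-3
  m1 <- train_cnn(m0, tr, train_config(learning_rate = lr, epochs = 1,
                                       batch_size = 6, seed = 1))$model
  h <- 1e-3
  check_one <- function(get, set) {
    ga <- (get(m0) - get(m1)) / lr          # analytic gradient via SGD step
    i <- which.max(abs(ga))
    mp <- set(m0, i, get(m0)[i] + h); mm <- set(m0, i, get(m0)[i] - h)
    gn <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    expect_equal(ga[i], gn, tolerance = 0.05)
  }
  check_one(function(m) m$head$w,
            function(m, i, v) { m$head$w[i] <- v; m })
  for (br in c("fgsr", "hgsr", "hr")) {
    for (li in c(1, 7)) {
      check_one(function(m) m$branches[[br]][[li]]$W,
                function(m, i, v) { m$branches[[br]][[li]]$W[i] <- v; m })
    }
  }
})

test_that("training is a seeded, reproducible no-op at zero epochs", {
  tr <- separable_triples(6, n_rec = 1, seed = 8)
  model <- build_model(small_arch(), seed = 9)
  fit0 <- train_cnn(model, tr, train_config(epochs = 0))
  expect_identical(fit0$model, model)
  expect_identical(fit0$loss, numeric(0))

  cfg <- train_config(learning_rate = 0.05, epochs = 3, seed = 21)
  f1 <- train_cnn(model, tr, cfg)
  f2 <- train_cnn(model, tr, cfg)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$model$head$w, f2$model$head$w)
  expect_identical(f1$model$branches$fgsr[[1]]$W, f2$model$branches$fgsr[[1]]$W)

  # fixed model + fixed input: reproducible probabilities
  p1 <- predict_cnn(f1$model, tr)$p
  p2 <- predict_cnn(f1$model, tr)$p
  expect_equal(p1, p2, tolerance = 1e-6)

  expect_error(train_cnn(model, tr[triple_labels(tr) == "stressed"], cfg),
               class = "contrp_data_error")
})

test_that("an easy separable task is learned with decreasing loss", {
  tr <- separable_triples(12, n_rec = 2, seed = 10)   # 24 samples
  model <- build_model(arch_config(c(4, 4, 8, 8, 8)), seed = 11)
  fit <- train_cnn(model, tr, train_config(learning_rate = 0.05, epochs = 6,
                                           batch_size = 4, seed = 12))
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])  # strict endpoint decrease
  p <- predict_cnn(fit$model, tr)
  expect_gte(mean(p$label == triple_labels(tr)), 0.95)
})

test_that("probability 0.5 ties break toward stressed", {
  model <- build_model(small_arch(), seed = 13)
  model$head$w[] <- 0; model$head$b <- 0        # forces p = 0.5 exactly
  p <- predict_cnn(model, random_triples(2, side = 32))
  expect_equal(p$p, c(0.5, 0.5))
  expect_equal(p$label, c("stressed", "stressed"))
})
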