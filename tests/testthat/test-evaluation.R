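# metrics, AUC, leave-one-recording-out CV, grid search

test_that("metric formulas match direct substitution", {
  cm <- structure(list(tp = 50L, tn = 40L, fp = 5L, fn = 5L), class = "contrp_cm")
  m <- cm_metrics(cm)
  expect_equal(m$accuracy, 90)
  expect_equal(m$precision, 1000 / 11)   # 50/55 x 100%
  expect_equal(m$recall, 1000 / 11)
  expect_equal(m$f1, 10 / 11)
  # per-class values swap roles
  expect_equal(m$per_class$precision[m$per_class$class == "relaxed"], 800 / 9)

  perfect <- confusion_matrix(rep(c("stressed", "relaxed"), 5),
                              rep(c("stressed", "relaxed"), 5))
  mp <- cm_metrics(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$f1, 1)

  # 0/0 denominators are undefined, not zero
  none <- structure(list(tp = 0L, tn = 8L, fp = 0L, fn = 2L), class = "contrp_cm")
  expect_true(is.na(cm_metrics(none)$precision))
  empty <- structure(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L), class = "contrp_cm")
  expect_error(cm_metrics(empty), class = "contrp_data_error")
})

test_that("F1 equals 2PR/(P+R) for every reported row", {
  for (seed in 1:10) {
    cm <- with_seed2(seed, structure(as.list(setNames(sample(1:30, 4, TRUE),
                                                      c("tp", "tn", "fp", "fn"))),
                                     class = "contrp_cm"))
    m <- cm_metrics(cm)
    for (i in 1:2) {
      P <- m$per_class$precision[i] / 100
      R <- m$per_class$recall[i] / 100
      expect_equal(m$per_class$f1[i], 2 * P * R / (P + R))
    }
  }
})

test_that("rank AUC behaves like the Mann-Whitney statistic", {
  labs <- rep(c("stressed", "relaxed"), each = 10)
  expect_equal(auc_rank(c(rnorm(10, 5), rnorm(10, -5)), labs), 1)
  s <- with_seed2(3, rnorm(2000))
  l <- rep(c("stressed", "relaxed"), 1000)
  a <- auc_rank(s, l)
  expect_lt(abs(a - 0.5), 0.05)
  flipped <- ifelse(l == "stressed", "relaxed", "stressed")
  expect_equal(auc_rank(s, l) + auc_rank(s, flipped), 1)
  expect_error(auc_rank(rnorm(5), rep("stressed", 5)), class = "contrp_data_error")
})

test_that("leave-one-recording-out folds partition the samples", {
  tr <- unlist(lapply(sprintf("rec%02d", 1:9), function(id)
    random_triples(3, side = 8, id = id)), recursive = FALSE)
  folds <- loro_split(tr)
  expect_equal(length(folds), 9L)
  for (f in folds) {
    expect_length(intersect(f$train_idx, f$test_idx), 0)
    expect_setequal(c(f$train_idx, f$test_idx), seq_along(tr))
    expect_true(all(triple_ids(tr[f$test_idx]) == f$test_id))
    expect_false(f$test_id %in% triple_ids(tr[f$train_idx]))
  }
  expect_setequal(vapply(folds, function(f) f$test_id, character(1)),
                  unique(triple_ids(tr)))
  expect_error(loro_split(random_triples(4, side = 8)),
               class = "contrp_config_error")

  # minimal two-recording case: complementary folds
  tr2 <- c(random_triples(2, side = 8, id = "a"),
           random_triples(2, side = 8, id = "b"))
  f2 <- loro_split(tr2)
  expect_equal(length(f2), 2L)
  expect_setequal(f2[[1]]$train_idx, f2[[2]]$test_idx)
})

cv_fixture <- function() {
  tr <- separable_triples(10, n_rec = 3, side = 32, seed = 31)
  run_cv(tr, arch_config(c(4, 4, 8, 8, 8)),
         train_config(learning_rate = 0.05, epochs = 6, batch_size = 4, seed = 31),
         balance_mode = "fold")
}

test_that("cross-validated report aggregates fold matrices exactly", {
  rep <- cv_fixture()
  expect_equal(length(rep$per_fold), 3L)
  sums <- Reduce(function(a, b) mapply(`+`, a, b),
                 lapply(rep$per_fold, function(f) unclass(f$cm)[c("tp", "tn", "fp", "fn")]))
  expect_identical(as.integer(sums),
                   as.integer(unlist(unclass(rep$aggregated)[c("tp", "tn", "fp", "fn")])))
  total <- rep$aggregated$tp + rep$aggregated$tn + rep$aggregated$fp + rep$aggregated$fn
  expect_equal(total, 30L)  # every sample evaluated exactly once
  # overall accuracy is recomputed from the aggregated matrix
  expect_equal(rep$overall$accuracy,
               100 * (rep$aggregated$tp + rep$aggregated$tn) / total, tolerance = 1e-9)
  expect_setequal(vapply(rep$per_fold, function(f) f$recording_id, character(1)),
                  c("rec01", "rec02", "rec03"))
  # the easy task is solved across held-out recordings
  expect_gte(rep$overall$accuracy, 90)
})

test_that("fold balance mode never trains on held-out recording samples", {
  rep <- cv_fixture()
  for (f in rep$per_fold) {
    expect_false(f$recording_id %in% f$train_samples$recording_id)
  }
})

test_that("grid search is exhaustive with deterministic tie-breaking", {
  tr <- separable_triples(10, n_rec = 2, side = 32, seed = 41)
  g1 <- data.frame(learning_rate = 0.05, batch_size = 4, epochs = 2)
  res <- grid_search(tr, g1, arch_config(c(4, 4, 8, 8, 8)), base_seed = 41)
  expect_equal(res$best$learning_rate, 0.05)
  expect_equal(nrow(res$table), 1L)

  g2 <- data.frame(learning_rate = c(0, 0.05), batch_size = 4, epochs = 6)
  res2 <- grid_search(tr, g2, arch_config(c(4, 4, 8, 8, 8)), base_seed = 41)
  expect_equal(nrow(res2$table), 2L)
  # lr = 0 cannot learn; it is never selected when the alternative beats it
  acc0 <- res2$table$accuracy[res2$table$learning_rate == 0]
  accl <- res2$table$accuracy[res2$table$learning_rate == 0.05]
  expect_gt(accl, acc0)
  expect_equal(res2$best$learning_rate, 0.05)

  expect_error(grid_search(tr, data.frame()), class = "contrp_config_error")
})
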