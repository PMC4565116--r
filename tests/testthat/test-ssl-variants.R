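# Tiny but complete runs of every variant; sample_size is set to the pool
# size where a single-iteration run is wanted.

test_that("shared variants append the pooled batch P to every subset", {
  v <- make_ssl_views(n_pos = 30, degree = 5, seed = 5)  # pool of 150
  fit <- ssl_ensemble(v, "CTEO", N = 5, sample_size = 150, seed = 1)
  expect_equal(nrow(fit$ledger), 1L)
  if (fit$ledger$shortfall == 0) {
    # P holds 2N positives + 2N negatives; every subset grows by 4N = 20
    expect_equal(unname(fit$growth[1, ]), rep(20L, 5))
  }
  expect_length(fit$selected, fit$ledger$selected)

  fit_p <- ssl_ensemble(v, "STEP", N = 5, sample_size = 150, seed = 1)
  expect_equal(unname(fit_p$growth[1, ]), rep(10L, 5))  # 2N positives
  app <- lapply(fit_p$subsets, function(s) s$y[-seq_len(s$n_init)])
  expect_true(all(unlist(app) == "positive"))
})

test_that("distributed variants give each subset its own unique instances", {
  v <- make_ssl_views(n_pos = 30, degree = 5, seed = 6)
  fit <- ssl_ensemble(v, "CTEOD", N = 5, sample_size = 150, seed = 2)
  if (fit$ledger$shortfall == 0) {
    expect_equal(unname(fit$growth[1, ]), rep(4L, 5))
  }
  appended <- lapply(fit$subsets, function(s) s$idx[-seq_len(s$n_init)])
  expect_equal(anyDuplicated(unlist(appended)), 0L)

  fit_pd <- ssl_ensemble(v, "STEPD", N = 5, sample_size = 150, seed = 2)
  expect_equal(unname(fit_pd$growth[1, ]), rep(2L, 5))
  appended <- lapply(fit_pd$subsets, function(s) s$idx[-seq_len(s$n_init)])
  expect_equal(anyDuplicated(unlist(appended)), 0L)
  expect_length(unlist(appended), 10L)  # 2N unique positives
  labs <- unlist(lapply(fit_pd$subsets, function(s) s$y[-seq_len(s$n_init)]))
  expect_true(all(labs == "positive"))
})

test_that("positive-and-negative variants keep subsets exactly balanced", {
  v <- make_ssl_views(n_pos = 30, degree = 5, seed = 7)
  for (variant in c("STEO", "STEOD")) {
    fit <- ssl_ensemble(v, variant, N = 5, sample_size = 50, seed = 3)
    for (s in fit$subsets) {
      expect_equal(sum(s$y == "positive"), sum(s$y == "negative"))
    }
  }
})

test_that("every unlabeled instance is consumed at most once", {
  v <- make_ssl_views(n_pos = 30, degree = 5, seed = 8)
  for (variant in c("STEO", "CTEPD")) {
    fit <- ssl_ensemble(v, variant, N = 5, sample_size = 40, seed = 4)
    expect_equal(length(fit$selected) + fit$n_discarded + fit$pool_remaining,
                 fit$pool_initial)
    expect_equal(anyDuplicated(fit$selected), 0L)
    expect_equal(fit$pool_remaining, 0L)  # loop runs until exhaustion
  }
})

test_that("a fixed seed fixes the whole run bit-exactly", {
  v <- make_ssl_views(n_pos = 25, degree = 4, seed = 9)
  for (variant in c("STEPD", "CTEO")) {
    f1 <- ssl_ensemble(v, variant, N = 4, seed = 11)
    f2 <- ssl_ensemble(v, variant, N = 4, seed = 11)
    expect_identical(f1$subsets, f2$subsets)
    expect_identical(f1$ledger, f2$ledger)
    expect_identical(predict(f1, v), predict(f2, v))
  }
})

test_that("N defaults to the imbalance degree of the labeled set", {
  v <- make_ssl_views(n_pos = 20, degree = 5, n_labeled_pos = 4,
                      n_labeled_neg = 20, seed = 10)
  fit <- ssl_ensemble(v, "LBE", seed = 1)
  expect_equal(fit$N, 5L)
})

test_that("ensemble scores average the member posteriors", {
  v <- make_ssl_views(n_pos = 20, degree = 3, n_labeled_pos = 10,
                      n_labeled_neg = 10, seed = 12)
  lab <- which(v$label != "unlabeled")
  train <- subset_views(v, lab)
  # single-subset supervised ensemble == plain combined-view NB
  fit1 <- ssl_ensemble(train, "LBE", N = 1, seed = 5)
  x <- cbind(v$view1, v$view2)
  m <- fit1$models[[1]]$combined
  expect_equal(predict(fit1, v), unname(predict(m, x)[, "positive"]))
  # N identical subsets (recycling from a tiny negative pool) stay in [0,1]
  fit3 <- ssl_ensemble(train, "LBE", N = 3, seed = 5)
  s <- predict(fit3, v)
  expect_true(all(s >= 0 & s <= 1))
  # mean of the member scores reproduces the ensemble score
  per_model <- sapply(fit3$models, function(mods)
    predict(mods$combined, x)[, "positive"])
  expect_equal(unname(rowMeans(per_model)), unname(predict(fit3, v)))
})

test_that("an empty unlabeled pool reduces every variant to its supervised
           ensemble", {
  v <- make_ssl_views(n_pos = 20, degree = 3, n_labeled_pos = 6,
                      n_labeled_neg = 18, seed = 13)
  lab <- subset_views(v, which(v$label != "unlabeled"))
  base <- ssl_ensemble(lab, "LBE", N = 3, seed = 7)
  s_lbe <- predict(base, v)
  for (variant in c("STEO", "STEP", "STEOD", "STEPD")) {
    fit <- ssl_ensemble(lab, variant, N = 3, seed = 7)
    expect_identical(predict(fit, v), s_lbe)
  }
})

test_that("labeled data lacking a class is rejected", {
  v <- make_ssl_views(seed = 14)
  v$label[v$label == "negative"] <- "unlabeled"
  expect_error(ssl_ensemble(v, "LBE", N = 2), "both classes")
})
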