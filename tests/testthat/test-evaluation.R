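test_that("average precision matches hand-computed and degenerate cases", {
  # perfect ranking
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1),
                     c("positive", "positive", "negative", "negative"))$auprc, 1)
  # alternating hits: AP = 0.5 * 1 + 0.5 * (2/3) = 5/6
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auprc, 5 / 6)
  # single-class input is rejected
  expect_error(auprc(c(0.1, 0.2), c(1, 1)), "both")
})

test_that("average precision equals the exhaustive rank-walk oracle", {
  set.seed(13)
  for (trial in 1:25) {
    n <- sample(4:20, 1)
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # rounding forces frequent ties
    expect_equal(auprc(scores, labels)$auprc, oracle_auprc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("tied constant scores follow the stable original-order ranking", {
  labels <- rep(c("negative", "positive"), 10)
  got <- auprc(rep(0.5, 20), labels)$auprc
  expect_equal(got, oracle_auprc(rep(0.5, 20), labels), tolerance = 1e-12)
})

test_that("the PR curve has non-decreasing recall and valid area", {
  set.seed(3)
  pr <- auprc(runif(50), sample(c("positive", "negative"), 50, TRUE))
  expect_true(all(diff(pr$recall) >= 0))
  expect_gte(pr$auprc, 0)
  expect_lte(pr$auprc, 1)
})

test_that("random scores give average precision near the prevalence", {
  set.seed(29)
  ap <- replicate(20, {
    labels <- rep(c("positive", "negative"), times = c(200, 800))
    auprc(runif(1000), labels)$auprc
  })
  expect_equal(mean(ap), 0.2, tolerance = 0.03)
})

test_that("cross-validation folds are a stratified partition", {
  labels <- rep(c("positive", "negative"), times = c(100, 900))
  plan <- make_cv_plan(labels, k = 10, labeled_fraction = 0.01, seed = 1)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:1000)        # disjoint cover
  for (f in plan$folds) {
    expect_equal(length(f$test), 100L)
    expect_equal(sum(labels[f$test] == "positive"), 10L)
    # labeled + unlabeled partition the training folds
    expect_equal(sort(c(f$test, f$labeled, f$unlabeled)), 1:1000)
    expect_length(intersect(f$labeled, f$unlabeled), 0L)
  }
})

test_that("the labeled split preserves the class ratio at the 1% budget", {
  # 10,000 instances at 1-to-9: each training set has 9,000 instances,
  # 1% -> 90 labeled: 9 positives, 81 negatives
  labels <- rep(c("positive", "negative"), times = c(1000, 9000))
  plan <- make_cv_plan(labels, k = 10, labeled_fraction = 0.01, seed = 2)
  for (f in plan$folds) {
    expect_length(f$labeled, 90L)
    expect_equal(sum(labels[f$labeled] == "positive"), 9L)
  }
})

test_that("the labeled split always keeps at least one positive", {
  labels <- rep(c("positive", "negative"), times = c(10, 990))
  plan <- make_cv_plan(labels, k = 10, labeled_fraction = 0.005, seed = 3)
  n_pos <- vapply(plan$folds, function(f)
    sum(labels[f$labeled] == "positive"), integer(1))
  expect_true(all(n_pos >= 1L))
  expect_error(make_cv_plan(rep(c("positive", "negative"), c(5, 100)), k = 10),
               "fewer than k")
})

test_that("cv plans are reproducible under a fixed seed", {
  labels <- rep(c("positive", "negative"), times = c(50, 450))
  expect_identical(make_cv_plan(labels, 5, 0.02, seed = 7),
                   make_cv_plan(labels, 5, 0.02, seed = 7))
})

test_that("the paired t-test matches the textbook statistic", {
  a <- c(0.5, 0.4, 0.8, 0.6)
  b <- a - c(0.2, -0.1, 0.3, 0.0)
  d <- c(0.2, -0.1, 0.3, 0.0)
  tt <- paired_ttest_twotailed(a, b)
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$p, p_hand, tolerance = 1e-12)
})

test_that("the paired t-test handles degenerate difference vectors", {
  a <- c(0.3, 0.4, 0.5)
  expect_true(paired_ttest_twotailed(a, a)$degenerate)
  tt <- paired_ttest_twotailed(a + 0.1, a)
  expect_equal(tt$p, 0)
  expect_true(is.infinite(tt$t) && tt$t > 0)
})

test_that("the paired t-test is sign-symmetric", {
  set.seed(17)
  a <- runif(8)
  b <- runif(8)
  ab <- paired_ttest_twotailed(a, b)
  ba <- paired_ttest_twotailed(b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, -ba$t)
})

test_that("a small experiment grid produces valid paired cells", {
  res <- run_experiment(list(n_pos = 40, window_length = 41,
                             dimer_start = 20, signal = 0.9),
                        degrees = c(2, 4), variants = "STEPD",
                        k = 3, labeled_fraction = 0.1, replicates = 2,
                        N = 2, target_iterations = 10, seed = 5)
  expect_equal(dim(res$mean), c(2L, 2L))
  expect_true(all(res$mean >= 0 & res$mean <= 1))
  expect_true(all(is.na(res$marks[, "LBE"])))
  expect_true(all(res$marks[, "STEPD"] %in% 0:2))
  expect_equal(dim(res$folds), c(2L, 2L, 2L, 3L))
})

test_that("results grids serialize deterministically", {
  res <- run_experiment(list(n_pos = 30, window_length = 31,
                             dimer_start = 15, signal = 0.9),
                        degrees = 3, variants = "STEPD", k = 2,
                        labeled_fraction = 0.2, N = 2,
                        target_iterations = 5, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(res, p1)
  write_results_tsv(res, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  tab <- utils::read.delim(p1, check.names = FALSE)
  expect_equal(tab[["Imbal.Degree"]], "1-to-3")
  mpath <- withr::local_tempfile(fileext = ".json")
  results_manifest(res, mpath)
  doc <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  expect_equal(nrow(doc$per_fold), 2 * 2)
})
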