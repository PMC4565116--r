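test_that("Laplace-smoothed conditionals and posteriors match hand counts", {
  # one positive with category A(=1), one negative with category C(=2),
  # alpha = 1, 4 categories:
  #   P(A|pos) = (1+1)/(1+4) = 0.4,  P(A|neg) = (0+1)/(1+4) = 0.2
  x <- matrix(c(1L, 2L), ncol = 1)
  m <- categorical_nb(x, c("positive", "negative"), n_cat = 4, alpha = 1)
  expect_equal(unname(exp(m$log_cond[1, "positive"])), 0.4)
  expect_equal(unname(exp(m$log_cond[1, "negative"])), 0.2)
  expect_equal(exp(unname(m$log_prior)), c(0.5, 0.5))

  # posterior for a test instance with value A:
  #   0.4*0.5 / (0.4*0.5 + 0.2*0.5) = 2/3
  post <- predict(m, matrix(1L, ncol = 1))
  expect_equal(unname(post[1, "positive"]), 2 / 3)
  expect_equal(rowSums(post), 1, tolerance = 1e-12)
})

test_that("fitting requires both classes and valid category values", {
  x <- matrix(1:4, ncol = 2)
  expect_error(categorical_nb(x, c("positive", "positive"), n_cat = 4),
               "missing: negative")
  expect_error(categorical_nb(x, c("positive", "negative"), n_cat = 2),
               "1:n_cat")
})

test_that("log-space posteriors equal brute-force linear products", {
  set.seed(7)
  for (trial in 1:10) {
    F <- sample(1:10, 1)
    n_cat <- sample(2:6, F, replace = TRUE)
    n <- 12
    x <- vapply(n_cat, function(k) sample.int(k, n, replace = TRUE),
                integer(n))
    y <- rep(c("positive", "negative"), each = n / 2)
    m <- categorical_nb(x, y, n_cat = n_cat, alpha = 1)
    x_new <- vapply(n_cat, function(k) sample.int(k, 1), integer(1))
    got <- predict(m, matrix(x_new, nrow = 1))
    want <- oracle_nb_posterior(x, y, x_new, n_cat, alpha = 1)
    expect_equal(unname(got[1, "negative"]), unname(want["negative"]),
                 tolerance = 1e-9)
    expect_equal(unname(got[1, "positive"]), unname(want["positive"]),
                 tolerance = 1e-9)
  }
})

test_that("posteriors agree with an independent Naive Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  n <- 40
  x <- cbind(sample.int(4L, n, replace = TRUE),
             sample.int(4L, n, replace = TRUE),
             sample.int(3L, n, replace = TRUE))
  y <- rep(c("positive", "negative"), length.out = n)
  n_cat <- c(4L, 4L, 3L)
  m <- categorical_nb(x, y, n_cat = n_cat, alpha = 1)

  df <- as.data.frame(lapply(seq_len(3), function(j) {
    factor(x[, j], levels = seq_len(n_cat[j]))
  }))
  names(df) <- paste0("f", 1:3)
  ref <- e1071::naiveBayes(df, factor(y), laplace = 1)
  got <- predict(m, x)
  want <- predict(ref, df, type = "raw")
  expect_equal(got[, "positive"], unname(want[, "positive"]),
               tolerance = 1e-9)
})

test_that("posterior is invariant under consistent feature permutation", {
  set.seed(3)
  n <- 10
  x <- cbind(sample.int(4L, n, TRUE), sample.int(3L, n, TRUE),
             sample.int(5L, n, TRUE))
  y <- rep(c("positive", "negative"), 5)
  perm <- c(3L, 1L, 2L)
  m1 <- categorical_nb(x, y, n_cat = c(4, 3, 5))
  m2 <- categorical_nb(x[, perm], y, n_cat = c(4, 3, 5)[perm])
  x_new <- matrix(c(2L, 1L, 4L), nrow = 1)
  expect_equal(predict(m1, x_new), predict(m2, x_new[, perm, drop = FALSE]))
})

test_that("heavy smoothing pulls posteriors toward the class prior", {
  set.seed(5)
  x <- matrix(sample.int(4L, 30, TRUE), ncol = 3)
  y <- rep(c("positive", "negative"), 5)
  m_big <- categorical_nb(x, y, n_cat = 4, alpha = 1e8)
  post <- predict(m_big, matrix(c(1L, 2L, 3L), nrow = 1))
  expect_equal(unname(post[1, "positive"]), 0.5, tolerance = 1e-6)
})

test_that("identical class conditionals give the prior back", {
  x <- matrix(rep(1:2, each = 2), ncol = 1)  # both classes see {1, 2}
  y <- c("positive", "negative", "positive", "negative")
  m <- categorical_nb(x, y, n_cat = 4)
  expect_equal(predict(m, matrix(2L))[1, ], c(negative = 0.5, positive = 0.5))
})

test_that("alpha = 0 predictions error on categories unseen in both classes", {
  x <- matrix(c(1L, 2L), ncol = 1)
  m <- categorical_nb(x, c("positive", "negative"), n_cat = 4, alpha = 0)
  expect_error(predict(m, matrix(3L)), "zero probability")
})

test_that("JSON serialization round-trips a model exactly", {
  set.seed(9)
  x <- matrix(sample.int(4L, 24, TRUE), ncol = 2)
  y <- rep(c("positive", "negative"), 6)
  m <- categorical_nb(x, y, n_cat = 4, alpha = 0.5, view = "view1")
  path <- withr::local_tempfile(fileext = ".json")
  nb_to_json(m, path)
  m2 <- nb_from_json(path)
  expect_equal(m2$log_cond, m$log_cond)
  expect_equal(m2$log_prior, m$log_prior)
  expect_equal(predict(m2, x), predict(m, x))
})
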