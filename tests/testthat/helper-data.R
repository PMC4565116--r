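# Shared fixtures, all generated in code.

# A tiny labeled + unlabeled splice_views set for ensemble tests.
make_ssl_views <- function(n_pos = 20, degree = 5, n_labeled_pos = 5,
                           n_labeled_neg = 25, window_length = 21,
                           dimer_start = 10, signal = 0.8, seed = 42) {
  rec <- simulate_splice_data(n_pos = n_pos, degree = degree,
                              window_length = window_length,
                              dimer_start = dimer_start,
                              signal = signal, seed = seed)
  v <- encode_views(rec)
  keep <- c(which(v$label == "positive")[seq_len(n_labeled_pos)],
            which(v$label == "negative")[seq_len(n_labeled_neg)])
  v$label[-keep] <- "unlabeled"
  v
}


# Brute-force categorical NB oracle: counts and normalizes probabilities in
# linear space, entirely independent of the package implementation.
oracle_nb_posterior <- function(x_train, y_train, x_new, n_cat, alpha = 1) {
  classes <- c("negative", "positive")
  n_cat <- rep_len(n_cat, ncol(x_train))
  prior <- vapply(classes, function(cl) mean(y_train == cl), numeric(1))
  joint <- vapply(classes, function(cl) {
    rows <- which(y_train == cl)
    p <- prior[cl]
    for (j in seq_len(ncol(x_train))) {
      cnt <- sum(x_train[rows, j] == x_new[j])
      p <- p * (cnt + alpha) / (length(rows) + alpha * n_cat[j])
    }
    p
  }, numeric(1))
  joint / sum(joint)
}

# Exhaustive average-precision oracle: walks the stably ranked list and
# accumulates (R_k - R_{k-1}) * P_k term by term.
oracle_auprc <- function(scores, labels) {
  y <- labels == "positive" | labels == 1 | labels == TRUE
  ord <- order(-scores, seq_along(scores))  # stable: ties by original index
  ap <- 0
  r_prev <- 0
  tp <- 0
  for (k in seq_along(ord)) {
    if (y[ord[k]]) {
      tp <- tp + 1
      r_k <- tp / sum(y)
      p_k <- tp / k
      ap <- ap + (r_k - r_prev) * p_k
      r_prev <- r_k
    }
  }
  ap
}
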