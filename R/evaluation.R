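# Evaluation protocol -------------------------------------------------------
#
# Minority-class area under the precision-recall curve, computed as
# step-wise average precision (no linear interpolation between PR points,
# which is invalid for precision-recall curves), over stratified k-fold
# cross-validation where only a small fraction of each training fold keeps
# its labels. Paired two-tailed t-tests compare each semi-supervised
# variant against the supervised lower-bound ensemble fold by fold.

#' Area under the precision-recall curve (average precision)
#'
#' Instances are ranked by decreasing score, ties broken by original index
#' (stable), and AP = sum over positive-hit ranks k of
#' (R_k - R_\{k-1\}) * P_k — the step-wise area, with no interpolation.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels true labels (`"positive"`/`"negative"`, logical, or 0/1);
#'   both classes must be present.
#' @return a `pr_curve` object: list with `recall`, `precision` (one point
#'   per rank), `auprc`, `n_pos`, `n_neg`.
#' @examples
#' pr <- auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
#' pr$auprc  # 5/6
#' @export
auprc <- function(scores, labels) {
  y <- normalize_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("labels must contain both a positive and a negative instance")
  }
  ord <- order(scores, seq_along(scores), decreasing = c(TRUE, FALSE),
               method = "radix")
  hit <- y[ord]
  tp <- cumsum(hit)
  precision <- tp / seq_along(hit)
  recall <- tp / n_pos
  ap <- sum(precision[hit]) / n_pos
  structure(list(recall = recall, precision = precision, auprc = ap,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pr_curve")
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("positive", "negative"))
    if (length(bad)) stop("unexpected label(s): ", paste(bad, collapse = ", "))
    labels == "positive"
  } else {
    as.logical(labels)
  }
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve: auPRC = %.4f (%d positives, %d negatives)\n",
              x$auprc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  plot(x$recall, x$precision, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Recall", ylab = "Precision",
       main = sprintf("auPRC = %.3f", x$auprc), ...)
  graphics::abline(h = x$n_pos / (x$n_pos + x$n_neg), lty = 3)
  invisible(x)
}

#' Stratified cross-validation plan with a small labeled split
#'
#' Builds a stratified k-fold partition. Within each training set (the
#' other k-1 folds), a labeled subset of `floor(labeled_fraction * n_train)`
#' instances is drawn with the class ratio preserved (positives rounded,
#' but at least one); the remainder of the training set becomes the
#' unlabeled pool, its labels to be masked at fit time.
#'
#' @param labels class labels of the full dataset (`"positive"` /
#'   `"negative"`); every class needs at least `k` members.
#' @param k number of folds, default 10.
#' @param labeled_fraction fraction of each training set that keeps its
#'   labels, default 0.01.
#' @param seed optional integer seed (global RNG state restored on exit).
#' @return a `cv_plan`: list of `k` folds, each with integer index vectors
#'   `test`, `labeled`, `unlabeled`.
#' @export
make_cv_plan <- function(labels, k = 10, labeled_fraction = 0.01, seed = NULL) {
  y <- normalize_labels(labels)
  k <- as.integer(k)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  fold_of <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has %d members, fewer than k = %d folds",
                   if (cls) "positive" else "negative", length(idx), k))
    }
    idx <- idx[sample.int(length(idx), length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    y_tr <- y[train]
    n_lab <- floor(labeled_fraction * length(train))
    n_lab_pos <- max(1L, round(n_lab * mean(y_tr)))
    n_lab_neg <- max(0L, n_lab - n_lab_pos)
    tr_pos <- train[y_tr]
    tr_neg <- train[!y_tr]
    lab <- c(tr_pos[sample.int(length(tr_pos), min(n_lab_pos, length(tr_pos)))],
             tr_neg[sample.int(length(tr_neg), min(n_lab_neg, length(tr_neg)))])
    list(test = test, labeled = sort(lab), unlabeled = sort(setdiff(train, lab)))
  })
  structure(list(folds = folds, k = k, labeled_fraction = labeled_fraction,
                 n = length(y)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  n_lab <- vapply(x$folds, function(f) length(f$labeled), integer(1))
  cat(sprintf("cv_plan: %d folds over %d instances, labeled fraction %.3g (%d-%d labeled per fold)\n",
              x$k, x$n, x$labeled_fraction, min(n_lab), max(n_lab)))
  invisible(x)
}

#' Two-tailed paired t-test on per-fold performance
#'
#' Classical paired t on the differences `a - b` with n - 1 degrees of
#' freedom. Degenerate inputs are handled explicitly: all-zero differences
#' are reported as not significant (there is nothing to test), and
#' constant non-zero differences give p = 0 with an infinite statistic.
#'
#' @param a,b equal-length numeric vectors (length >= 2), e.g. per-fold
#'   auPRC of a semi-supervised variant and of the supervised baseline.
#' @return list with `t`, `p`, `df`, `mean_diff` and `degenerate`.
#' @export
paired_ttest_twotailed <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (all(d == 0)) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = 0, degenerate = TRUE))
  }
  stderr <- stats::sd(d) / sqrt(length(d))
  if (stderr < 10 * .Machine$double.eps * abs(mean(d))) {
    # numerically constant non-zero differences: the statistic diverges
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = FALSE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

experiment_subseed <- function(seed, replicate, degree, fold = 0L) {
  ((as.double(seed) * 7919 + replicate * 104729 + degree * 1299709 +
      fold * 15485863) %% 2147483629) + 1
}

#' Run the full imbalance-by-variant experiment grid
#'
#' For every imbalance degree, builds the (nested) dataset, lays out a
#' stratified CV plan with a small labeled split, trains every requested
#' variant on each fold (identical seeds across variants, so runs are
#' paired), scores the held-out fold and records the minority-class auPRC.
#' With `replicates > 1`, the whole procedure repeats on freshly simulated
#' datasets and cell values average fold means over replicates; per-cell
#' significance marks count the replicates in which the paired t-test
#' against the supervised baseline is significant.
#'
#' @param data either a `splice_records` base dataset with enough negatives
#'   for the largest degree, or a list of arguments for
#'   [simulate_splice_data()] (without `degree`/`seed`, which the grid
#'   supplies) used to simulate one base per replicate.
#' @param degrees integer vector of imbalance degrees (rows of the grid).
#' @param variants character vector of methods (columns); `"LBE"` is added
#'   automatically as the baseline.
#' @param k,labeled_fraction see [make_cv_plan()].
#' @param replicates number of replicate datasets (simulation input only).
#' @param N subsets per ensemble; default `NULL` uses each degree as N.
#' @param alpha,tau_low,target_iterations,k_per_class passed to
#'   [ssl_ensemble()].
#' @param seed master seed; every subordinate seed derives from it.
#' @param alpha_sig significance level for the t-test marks, default 0.05.
#' @return an `ssl_results` object: mean-auPRC matrix (`mean`), significance
#'   counts (`marks`), the full per-fold array (`folds`), and the manifest
#'   of derived seeds.
#' @export
run_experiment <- function(data, degrees, variants = setdiff(SSL_VARIANTS, "LBE"),
                           k = 10, labeled_fraction = 0.01, replicates = 1,
                           N = NULL, alpha = 1, tau_low = 0.7,
                           target_iterations = 50, k_per_class = 2L,
                           seed = 1, alpha_sig = 0.05) {
  variants <- match.arg(variants, SSL_VARIANTS, several.ok = TRUE)
  methods <- unique(c("LBE", variants))
  degrees <- sort(as.integer(degrees))
  simulate_base <- !inherits(data, "splice_records")
  if (!simulate_base && replicates > 1) {
    stop("replicates > 1 requires a simulation configuration as 'data'")
  }
  res <- array(NA_real_,
               dim = c(length(degrees), length(methods), replicates, k),
               dimnames = list(paste0("1-to-", degrees), methods,
                               paste0("rep", seq_len(replicates)),
                               paste0("fold", seq_len(k))))
  seeds <- list()
  for (r in seq_len(replicates)) {
    base_seed <- experiment_subseed(seed, r, 0L)
    base <- if (simulate_base) {
      do.call(simulate_splice_data,
              c(data, list(degree = max(degrees), seed = base_seed)))
    } else data
    series <- nest_imbalance_series(base, degrees,
                                    seed = experiment_subseed(seed, r, 1L, 1L))
    for (d_i in seq_along(degrees)) {
      d <- degrees[d_i]
      ds <- series[[d_i]]
      views <- encode_views(ds)
      plan_seed <- experiment_subseed(seed, r, d)
      plan <- make_cv_plan(ds$label, k = k,
                           labeled_fraction = labeled_fraction,
                           seed = plan_seed)
      seeds[[paste0("rep", r, "_1-to-", d)]] <- plan_seed
      for (f in seq_len(k)) {
        fold <- plan$folds[[f]]
        train_idx <- c(fold$labeled, fold$unlabeled)
        train <- subset_views(views, train_idx)
        train$label[seq_along(train$label) > length(fold$labeled)] <- "unlabeled"
        test <- subset_views(views, fold$test)
        fit_seed <- experiment_subseed(seed, r, d, f)
        for (m in methods) {
          fit <- ssl_ensemble(train, variant = m,
                              N = if (is.null(N)) d else N,
                              alpha = alpha, tau_low = tau_low,
                              target_iterations = target_iterations,
                              k_per_class = k_per_class, seed = fit_seed)
          sc <- predict(fit, test)
          res[d_i, m, r, f] <- auprc(sc, test$label)$auprc
        }
      }
    }
  }
  # mean over folds per replicate, then over replicates
  fold_means <- apply(res, c(1, 2, 3), mean)
  grid_mean <- apply(fold_means, c(1, 2), mean)
  marks <- matrix(NA_integer_, length(degrees), length(methods),
                  dimnames = dimnames(grid_mean))
  pvals <- array(NA_real_, dim = c(length(degrees), length(methods), replicates),
                 dimnames = dimnames(res)[1:3])
  for (d_i in seq_along(degrees)) {
    for (m in setdiff(methods, "LBE")) {
      sig <- 0L
      for (r in seq_len(replicates)) {
        tt <- paired_ttest_twotailed(res[d_i, m, r, ], res[d_i, "LBE", r, ])
        pvals[d_i, m, r] <- tt$p
        if (!tt$degenerate && tt$p < alpha_sig) sig <- sig + 1L
      }
      marks[d_i, m] <- sig
    }
  }
  structure(list(mean = grid_mean, marks = marks, folds = res,
                 fold_means = fold_means, pvalues = pvals,
                 degrees = degrees, methods = methods,
                 replicates = replicates, alpha_sig = alpha_sig,
                 config = list(k = k, labeled_fraction = labeled_fraction,
                               N = N, alpha = alpha, tau_low = tau_low,
                               target_iterations = target_iterations,
                               k_per_class = k_per_class, seed = seed),
                 seeds = seeds),
            class = "ssl_results")
}

mark_suffix <- function(m, r) {
  if (is.na(m)) ""
  else if (r >= 1 && m == r) "*"
  else if (r >= 2 && m == r - 1) "†"
  else if (r >= 3 && m == r - 2) "◇"
  else ""
}

format_results_grid <- function(x) {
  g <- x$mean
  out <- matrix("", nrow(g), ncol(g), dimnames = dimnames(g))
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      out[i, j] <- paste0(sprintf("%.3f", g[i, j]),
                          mark_suffix(x$marks[i, j], x$replicates))
    }
  }
  out
}

#' @export
print.ssl_results <- function(x, ...) {
  cat(sprintf("ssl_results: %d degrees x %d methods, %d folds, %d replicate(s)\n",
              length(x$degrees), length(x$methods), x$config$k, x$replicates))
  cat("mean minority-class auPRC (marks: significant vs LBE in */all, †/all-1, ◇/all-2 replicates)\n")
  print(format_results_grid(x), quote = FALSE)
  invisible(x)
}

#' Write a results grid as TSV
#'
#' One row per imbalance degree, one column per method; cell values are the
#' mean auPRC formatted to three decimals with significance-mark suffixes.
#' The output is deterministic: identical results write identical bytes.
#'
#' @param x an `ssl_results` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  stopifnot(inherits(x, "ssl_results"))
  g <- format_results_grid(x)
  df <- data.frame(Imbal.Degree = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(colnames(df), collapse = "\t"),
               apply(df, 1L, paste, collapse = "\t")), con)
  invisible(path)
}

#' Write the experiment manifest as JSON
#'
#' Records the configuration, master seed, all derived seeds and the full
#' per-fold auPRC values, sufficient to reproduce the grid bit-exactly.
#'
#' @param x an `ssl_results` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
results_manifest <- function(x, path) {
  stopifnot(inherits(x, "ssl_results"))
  folds <- as.data.frame.table(x$folds, responseName = "auprc",
                               stringsAsFactors = FALSE)
  names(folds) <- c("degree", "method", "replicate", "fold", "auprc")
  doc <- list(format = "spliceSSL-results", version = 1L,
              config = x$config, seeds = x$seeds,
              degrees = x$degrees, methods = x$methods,
              replicates = x$replicates,
              per_fold = folds)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
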