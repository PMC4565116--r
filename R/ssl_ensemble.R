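# Semi-supervised balanced-subset ensembles --------------------------------
#
# The eight variants share one loop: draw a subsample U of the unlabeled
# pool; refit every subclassifier on its current balanced subset; let each
# subclassifier pick its most confidently predicted instances from U; route
# the picks either into a shared batch P appended to every subset, or
# directly into the picking subclassifier's own subset; discard the rest of
# U; repeat until the pool is exhausted.
#
#   variant  learner      selection        routing
#   CTEO     co-training  2 pos + 2 neg    shared       growth 4N / subset
#   STEO     self-train   2 pos + 2 neg    shared       growth 4N
#   CTEP     co-training  2 pos            shared       growth 2N
#   STEP     self-train   2 pos            shared       growth 2N
#   CTEOD    co-training  2 pos + 2 neg    distributed  growth 4
#   STEOD    self-train   2 pos + 2 neg    distributed  growth 4
#   CTEPD    co-training  2 pos            distributed  growth 2
#   STEPD    self-train   2 pos            distributed  growth 2
#   LBE      supervised baseline: no loop, no unlabeled data
#
# Positive-only ("P") variants implement dynamic balancing: under heavy
# imbalance, pseudo-positives counteract the scarcity of the minority class.

SSL_VARIANTS <- c("LBE", "CTEO", "STEO", "CTEP", "STEP",
                  "CTEOD", "STEOD", "CTEPD", "STEPD")

#' Balanced labeled subsets for ensemble members
#'
#' Each subset receives every positive instance plus an equal number of
#' negatives. While enough negatives remain they are partitioned across
#' subsets without replacement; once exhausted, further subsets draw from
#' fresh shuffles of the full negative pool, so no negative is reused more
#' than `ceiling(N * p / n)` times.
#'
#' @param y labels (`"positive"` / `"negative"`) of the labeled instances.
#' @param N number of subsets.
#' @param seed optional integer; when supplied the RNG state is set (and
#'   restored afterwards) so the subsets are reproducible in isolation.
#' @return list of `N` integer index vectors into `y`, positives first.
#' @export
make_balanced_subsets <- function(y, N, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  y <- as.character(y)
  pos <- which(y == "positive")
  neg <- which(y == "negative")
  p <- length(pos)
  n <- length(neg)
  if (p == 0L || n == 0L) stop("need at least one positive and one negative")
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  need <- N * p
  dealt <- integer(0)
  while (length(dealt) < need) {
    take <- min(n, need - length(dealt))
    dealt <- c(dealt, neg[sample.int(n, n)][seq_len(take)])
  }
  lapply(seq_len(N), function(i) {
    c(pos, dealt[((i - 1L) * p + 1L):(i * p)])
  })
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw a subsample from the unlabeled pool
#'
#' Removes up to `S` instances uniformly at random, without replacement;
#' repeated calls exhaust the pool. An empty pool yields an empty sample,
#' which terminates the semi-supervised loop.
#'
#' @param pool integer vector of available instance indices.
#' @param S sample size.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return list with `sample` (drawn indices) and `pool` (remainder).
#' @export
draw_unlabeled_sample <- function(pool, S, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  S <- as.integer(S)
  if (S < 0L) stop("S must be >= 0")
  take <- min(S, length(pool))
  if (take == 0L) return(list(sample = integer(0), pool = pool))
  picked <- sample.int(length(pool), take)
  list(sample = pool[picked], pool = pool[-picked])
}

#' Self-training pseudo-label selection
#'
#' Ranks candidates by their positive-class posterior and takes the top
#' `k_per_class` as pseudo-positives and, in `"pos_and_neg"` mode, the
#' bottom `k_per_class` as pseudo-negatives. Ties break toward the lowest
#' candidate index; ranking is always by positive posterior, so the
#' augmentation rate stays fixed even when no candidate's predicted label
#' is positive.
#'
#' @param post_pos numeric vector of positive-class posteriors, one per
#'   candidate.
#' @param mode `"pos_and_neg"` or `"pos_only"`.
#' @param k_per_class instances to select per class (default 2).
#' @return list with integer vectors `positive` and `negative` of selected
#'   candidate positions (negative empty in `"pos_only"` mode).
#' @export
select_self <- function(post_pos, mode = c("pos_and_neg", "pos_only"),
                        k_per_class = 2L) {
  mode <- match.arg(mode)
  m <- length(post_pos)
  if (m == 0L) return(list(positive = integer(0), negative = integer(0)))
  ord <- order(post_pos, seq_len(m), decreasing = c(TRUE, FALSE),
               method = "radix")
  pos_pick <- ord[seq_len(min(k_per_class, m))]
  neg_pick <- integer(0)
  if (mode == "pos_and_neg") {
    rest <- setdiff(order(post_pos, seq_len(m), method = "radix"), pos_pick)
    neg_pick <- rest[seq_len(min(k_per_class, length(rest)))]
  }
  list(positive = pos_pick, negative = neg_pick)
}

#' Co-training pseudo-label selection
#'
#' An instance is admissible only when the two view classifiers agree on
#' its label. For each view and each requested class, the pick is the
#' admissible instance of that predicted class which maximizes the view's
#' confidence among those the *other* view labels with low confidence
#' (posterior of the agreed class at most `tau_low`): one view teaches the
#' other what it cannot yet see. When no admissible instance clears the
#' threshold, the pick falls back to the highest-confidence admissible
#' instance of that class; when no admissible instance of the class exists
#' at all, the slot stays empty — agreement between the views is a hard
#' requirement, never overridden. Threshold fallbacks and unfilled slots
#' are counted and reported in the run ledger.
#'
#' @param post1,post2 positive-class posteriors from the view-1 and view-2
#'   classifiers, one per candidate.
#' @param mode `"pos_and_neg"` or `"pos_only"`.
#' @param tau_low low-confidence cutoff in (0, 1], default 0.7.
#' @return list with `positive` and `negative` candidate positions (up to 2
#'   each: one per view), `fallbacks` (threshold-relaxation count) and
#'   `shortfall` (slots left empty for lack of an admissible instance).
#' @export
select_co <- function(post1, post2, mode = c("pos_and_neg", "pos_only"),
                      tau_low = 0.7) {
  mode <- match.arg(mode)
  m <- length(post1)
  stopifnot(length(post2) == m, tau_low > 0, tau_low <= 1)
  picks_pos <- integer(0)
  picks_neg <- integer(0)
  fb <- 0L
  shortfall <- 0L
  if (m == 0L) {
    return(list(positive = picks_pos, negative = picks_neg,
                fallbacks = 0L,
                shortfall = if (mode == "pos_only") 2L else 4L))
  }
  taken <- logical(m)
  lab1 <- post1 >= 0.5
  lab2 <- post2 >= 0.5
  classes <- if (mode == "pos_only") "positive" else c("positive", "negative")
  pick_one <- function(view, class) {
    own <- if (view == 1L) post1 else post2
    other <- if (view == 1L) post2 else post1
    if (class == "negative") {
      own <- 1 - own
      other <- 1 - other
    }
    avail <- !taken
    adm <- avail & (lab1 == lab2) &
      (if (class == "positive") lab1 else !lab1)
    primary <- adm & other <= tau_low
    cand <- if (any(primary)) {
      primary
    } else if (any(adm)) {
      fb <<- fb + 1L
      adm
    } else {
      shortfall <<- shortfall + 1L
      return(NA_integer_)
    }
    score <- ifelse(cand, own, -Inf)
    i <- which.max(score)  # which.max is stable: lowest index on ties
    taken[i] <<- TRUE
    i
  }
  for (view in 1:2) {
    for (class in classes) {
      i <- pick_one(view, class)
      if (is.na(i)) next
      if (class == "positive") picks_pos <- c(picks_pos, i)
      else picks_neg <- c(picks_neg, i)
    }
  }
  list(positive = picks_pos, negative = picks_neg, fallbacks = fb,
       shortfall = shortfall)
}

variant_traits <- function(variant) {
  list(ct = variant %in% c("CTEO", "CTEP", "CTEOD", "CTEPD"),
       pos_only = variant %in% c("CTEP", "STEP", "CTEPD", "STEPD"),
       distributed = variant %in% c("CTEOD", "STEOD", "CTEPD", "STEPD"))
}

fit_subset_models <- function(ct, X1, X2, Xc, nc1, nc2, ncc, idx, ylab, alpha) {
  if (ct) {
    list(view1 = categorical_nb(X1[idx, , drop = FALSE], ylab, nc1, alpha, "view1"),
         view2 = categorical_nb(X2[idx, , drop = FALSE], ylab, nc2, alpha, "view2"))
  } else {
    list(combined = categorical_nb(Xc[idx, , drop = FALSE], ylab, ncc, alpha, "combined"))
  }
}

#' Fit a semi-supervised balanced-subset ensemble
#'
#' The central fitting function. Labeled instances in `data` (labels
#' `"positive"` / `"negative"`) form the seed set; instances labelled
#' `"unlabeled"` form the pool consumed by the semi-supervised iterations.
#' `variant = "LBE"` fits the supervised Lower Bound Ensemble, which
#' ignores the pool entirely; the eight semi-supervised variants run the
#' pseudo-labeling loop described in the package vignette. After the pool
#' is exhausted every subclassifier is refit once on its final subset.
#'
#' @param data a `splice_views` object (or `splice_records`, encoded on the
#'   fly) containing labeled and unlabeled instances.
#' @param variant one of `"LBE"`, `"CTEO"`, `"STEO"`, `"CTEP"`, `"STEP"`,
#'   `"CTEOD"`, `"STEOD"`, `"CTEPD"`, `"STEPD"`.
#' @param N number of balanced subsets; defaults to the imbalance degree of
#'   the labeled set (negatives per positive, rounded, at least 1).
#' @param alpha Laplace smoothing weight for the base learners.
#' @param tau_low low-confidence cutoff for the co-training agreement rule.
#' @param target_iterations the unlabeled subsample size is chosen as
#'   `ceiling(|pool| / target_iterations)` so that the loop runs about this
#'   many times (default 50).
#' @param sample_size explicit subsample size `S`, overriding
#'   `target_iterations`.
#' @param k_per_class pseudo-labels per class per self-training
#'   subclassifier (default 2, matching the co-training augmentation rate).
#' @param seed integer seed fixing subsets, subsamples and selections; the
#'   global RNG state is restored on exit.
#' @return an object of class `ssl_ensemble` with components `models` (per
#'   subset: a combined-view model, or a view-1/view-2 pair for co-training
#'   variants), `subsets` (final instance indices and labels, with
#'   `n_init` marking the seed portion), `ledger` (per-iteration counts),
#'   `growth` (iterations x N matrix of appended counts) and bookkeeping
#'   (`selected`, `n_discarded`, `pool_remaining`, `config`).
#' @examples
#' rec <- simulate_splice_data(n_pos = 15, degree = 3, window_length = 21,
#'                             dimer_start = 10, seed = 1)
#' v <- encode_views(rec)
#' v$label[31:60] <- "unlabeled"   # hide half the instances from the learner
#' fit <- ssl_ensemble(v, "CTEOD", N = 3, seed = 1)
#' head(predict(fit, v))
#' @export
ssl_ensemble <- function(data, variant = "LBE", N = NULL, alpha = 1,
                         tau_low = 0.7, target_iterations = 50,
                         sample_size = NULL, k_per_class = 2L, seed = NULL) {
  if (inherits(data, "splice_records")) data <- encode_views(data)
  stopifnot(inherits(data, "splice_views"))
  variant <- match.arg(variant, SSL_VARIANTS)
  tr <- variant_traits(variant)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }

  lab <- which(data$label %in% c("positive", "negative"))
  pool <- which(data$label == "unlabeled")
  y_lab <- data$label[lab]
  n_pos <- sum(y_lab == "positive")
  n_neg <- sum(y_lab == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop("labeled data must contain both classes")
  }
  if (is.null(N)) N <- max(1L, as.integer(round(n_neg / n_pos)))
  N <- as.integer(N)

  X1 <- data$view1
  X2 <- data$view2
  Xc <- cbind(X1, X2)
  a <- nchar(data$alphabet)
  nc1 <- rep(a, ncol(X1))
  nc2 <- rep(a^3, ncol(X2))
  ncc <- c(nc1, nc2)

  sub_idx <- make_balanced_subsets(y_lab, N)
  subsets <- lapply(sub_idx, function(ix) {
    list(idx = lab[ix], y = y_lab[ix], n_init = length(ix))
  })

  ledger <- list()
  growth <- NULL
  selected_all <- integer(0)
  n_discarded <- 0L
  pool0 <- length(pool)

  if (variant != "LBE" && pool0 > 0L) {
    S <- if (!is.null(sample_size)) as.integer(sample_size)
         else as.integer(ceiling(pool0 / target_iterations))
    drawn <- draw_unlabeled_sample(pool, S)
    U <- drawn$sample
    pool <- drawn$pool
    iter <- 0L
    while (length(U) > 0L) {
      iter <- iter + 1L
      remaining <- U
      P_idx <- integer(0)
      P_y <- character(0)
      appended <- integer(N)
      fb_iter <- 0L
      short_iter <- 0L
      for (i in seq_len(N)) {
        mods <- fit_subset_models(tr$ct, X1, X2, Xc, nc1, nc2, ncc,
                                  subsets[[i]]$idx, subsets[[i]]$y, alpha)
        if (length(remaining) == 0L) next
        if (tr$ct) {
          p1 <- predict(mods$view1, X1[remaining, , drop = FALSE])[, "positive"]
          p2 <- predict(mods$view2, X2[remaining, , drop = FALSE])[, "positive"]
          sel <- select_co(p1, p2,
                           mode = if (tr$pos_only) "pos_only" else "pos_and_neg",
                           tau_low = tau_low)
          fb_iter <- fb_iter + sel$fallbacks
          short_iter <- short_iter + sel$shortfall
        } else {
          pp <- predict(mods$combined, Xc[remaining, , drop = FALSE])[, "positive"]
          sel <- select_self(pp,
                             mode = if (tr$pos_only) "pos_only" else "pos_and_neg",
                             k_per_class = k_per_class)
        }
        local <- c(sel$positive, sel$negative)
        if (length(local) == 0L) next
        glob <- remaining[local]
        labs <- c(rep("positive", length(sel$positive)),
                  rep("negative", length(sel$negative)))
        remaining <- remaining[-local]
        selected_all <- c(selected_all, glob)
        if (tr$distributed) {
          subsets[[i]]$idx <- c(subsets[[i]]$idx, glob)
          subsets[[i]]$y <- c(subsets[[i]]$y, labs)
          appended[i] <- appended[i] + length(glob)
        } else {
          P_idx <- c(P_idx, glob)
          P_y <- c(P_y, labs)
        }
      }
      if (!tr$distributed && length(P_idx)) {
        for (i in seq_len(N)) {
          subsets[[i]]$idx <- c(subsets[[i]]$idx, P_idx)
          subsets[[i]]$y <- c(subsets[[i]]$y, P_y)
          appended[i] <- appended[i] + length(P_idx)
        }
      }
      n_discarded <- n_discarded + length(remaining)
      ledger[[iter]] <- data.frame(
        iteration = iter, U_size = length(U),
        selected = length(U) - length(remaining),
        discarded = length(remaining),
        fallback_threshold = fb_iter,
        shortfall = short_iter)
      growth <- rbind(growth, appended)
      drawn <- draw_unlabeled_sample(pool, S)
      U <- drawn$sample
      pool <- drawn$pool
    }
  }

  models <- lapply(subsets, function(s) {
    fit_subset_models(tr$ct, X1, X2, Xc, nc1, nc2, ncc, s$idx, s$y, alpha)
  })

  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(iteration = integer(0), U_size = integer(0),
               selected = integer(0), discarded = integer(0),
               fallback_threshold = integer(0), shortfall = integer(0))
  rownames(ledger) <- NULL
  if (!is.null(growth)) rownames(growth) <- NULL

  structure(list(variant = variant, N = N, models = models,
                 subsets = subsets, ledger = ledger, growth = growth,
                 selected = unique(selected_all),
                 n_discarded = n_discarded,
                 pool_initial = pool0, pool_remaining = length(pool),
                 window_length = data$window_length,
                 alphabet = data$alphabet,
                 config = list(variant = variant, N = N, alpha = alpha,
                               tau_low = tau_low,
                               target_iterations = target_iterations,
                               sample_size = sample_size,
                               k_per_class = k_per_class, seed = seed)),
            class = "ssl_ensemble")
}

#' Ensemble scores for new instances
#'
#' The positive-class posteriors of every subclassifier (N combined-view
#' models for self-training and the supervised baseline; 2N view models for
#' co-training variants) are combined by arithmetic averaging.
#'
#' @param object an `ssl_ensemble` fit.
#' @param newdata a `splice_views` or `splice_records` object.
#' @param ... unused.
#' @return numeric vector of positive-class scores in \[0, 1\].
#' @export
predict.ssl_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "splice_records")) newdata <- encode_views(newdata)
  stopifnot(inherits(newdata, "splice_views"))
  if (!identical(newdata$alphabet, object$alphabet) ||
      ncol(newdata$view1) != object$window_length) {
    stop("newdata does not match the ensemble's feature layout")
  }
  Xc <- cbind(newdata$view1, newdata$view2)
  scores <- rep(0, length(newdata$id))
  k <- 0L
  for (mods in object$models) {
    for (m in mods) {
      X <- switch(m$view, view1 = newdata$view1, view2 = newdata$view2,
                  combined = Xc)
      scores <- scores + predict(m, X)[, "positive"]
      k <- k + 1L
    }
  }
  scores / k
}

#' @export
print.ssl_ensemble <- function(x, ...) {
  n_models <- sum(lengths(x$models))
  cat(sprintf("ssl_ensemble: variant %s, N = %d (%d Naive Bayes models)\n",
              x$variant, x$N, n_models))
  cat(sprintf("iterations: %d, pseudo-labeled: %d, discarded: %d, pool left: %d of %d\n",
              nrow(x$ledger), length(x$selected), x$n_discarded,
              x$pool_remaining, x$pool_initial))
  invisible(x)
}

#' @export
summary.ssl_ensemble <- function(object, ...) {
  sizes <- vapply(object$subsets, function(s) length(s$idx), integer(1))
  n_pos <- vapply(object$subsets, function(s) sum(s$y == "positive"), integer(1))
  out <- list(variant = object$variant, N = object$N,
              iterations = nrow(object$ledger),
              subset_size = sizes, subset_positives = n_pos,
              pseudo_labeled = length(object$selected),
              discarded = object$n_discarded,
              fallbacks = colSums(object$ledger[, c("fallback_threshold",
                                                    "shortfall"),
                                                drop = FALSE]),
              config = object$config)
  class(out) <- "summary.ssl_ensemble"
  out
}

#' @export
print.summary.ssl_ensemble <- function(x, ...) {
  cat(sprintf("ssl_ensemble %s: N = %d, %d semi-supervised iterations\n",
              x$variant, x$N, x$iterations))
  cat("final subset sizes: ", paste(x$subset_size, collapse = ", "), "\n")
  cat("positives per subset:", paste(x$subset_positives, collapse = ", "), "\n")
  cat(sprintf("pseudo-labeled %d instances, discarded %d\n",
              x$pseudo_labeled, x$discarded))
  if (x$iterations > 0) {
    cat(sprintf("co-training: %d threshold fallbacks, %d unfilled slots\n",
                x$fallbacks[["fallback_threshold"]],
                x$fallbacks[["shortfall"]]))
  }
  invisible(x)
}

#' Serialize an ensemble run to a JSON manifest
#'
#' Records the configuration, seed and per-iteration ledger so a run can be
#' audited and reproduced.
#'
#' @param object an `ssl_ensemble` fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
ensemble_manifest <- function(object, path) {
  stopifnot(inherits(object, "ssl_ensemble"))
  doc <- list(format = "spliceSSL-run", version = 1L,
              config = object$config,
              pool_initial = object$pool_initial,
              pool_remaining = object$pool_remaining,
              pseudo_labeled = length(object$selected),
              discarded = object$n_discarded,
              ledger = object$ledger)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
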