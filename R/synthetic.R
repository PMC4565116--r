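# Synthetic acceptor-site data ---------------------------------------------
#
# A position-specific probability model that emulates the two properties
# the classifiers exploit in real acceptor windows: a fixed "AG" dimer at a
# known offset (present in decoys too, by construction of the negative
# class), and a positional composition signal around the dimer in true
# sites only — chiefly the pyrimidine-rich polypyrimidine tract immediately
# upstream of the acceptor. A single signal-strength parameter interpolates
# between pure background (s = 0, classes indistinguishable) and the full
# consensus-like profile (s = 1).

#' Position probability matrix for synthetic acceptor sites
#'
#' Builds a 4 x L matrix of per-position nucleotide probabilities. Outside
#' the dimer, row `p = (1 - signal) * background + signal * profile`, where
#' the profile has a pyrimidine-rich tract (C/T probability 0.85) over the
#' 20 positions upstream of the dimer and a mild G-leaning consensus over
#' the 3 positions downstream; everywhere else the profile equals the
#' background. The dimer positions are deterministic: "A" then "G".
#'
#' @param window_length window size L, default 141.
#' @param dimer_start 1-based start of the "AG" dimer, default 61.
#' @param signal signal strength s in \[0, 1\], default 0.6.
#' @param background length-4 nucleotide probabilities (A, C, G, T),
#'   default uniform.
#' @return an `acceptor_pwm` matrix with rownames A, C, G, T.
#' @export
acceptor_pwm <- function(window_length = 141, dimer_start = 61, signal = 0.6,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  L <- as.integer(window_length)
  d <- as.integer(dimer_start)
  if (d + 1L > L) stop("dimer_start + 1 must not exceed the window length")
  if (signal < 0 || signal > 1) stop("signal must lie in [0, 1]")
  background <- background / sum(background)
  pwm <- matrix(background, nrow = 4L, ncol = L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  tract <- c(A = 0.075, C = 0.425, G = 0.075, T = 0.425)
  downstream <- c(A = 0.25, C = 0.15, G = 0.45, T = 0.15)
  up <- seq(max(1L, d - 20L), d - 1L)
  if (d > 1L) pwm[, up] <- (1 - signal) * background + signal * tract
  down <- seq(d + 2L, min(L, d + 4L))
  if (d + 2L <= L) pwm[, down] <- (1 - signal) * background + signal * downstream
  pwm[, d] <- c(1, 0, 0, 0)
  pwm[, d + 1L] <- c(0, 0, 1, 0)
  structure(pwm, dimer_start = d, signal = signal, class = "acceptor_pwm")
}

#' @export
print.acceptor_pwm <- function(x, ...) {
  cat(sprintf("acceptor_pwm: %d positions, AG dimer at %d-%d, signal %.2f\n",
              ncol(x), attr(x, "dimer_start"), attr(x, "dimer_start") + 1L,
              attr(x, "signal")))
  invisible(x)
}

sample_seq_matrix <- function(n, pwm) {
  L <- ncol(pwm)
  nt <- rownames(pwm)
  cols <- lapply(seq_len(L), function(j) {
    nt[sample.int(4L, n, replace = TRUE, prob = pwm[, j])]
  })
  do.call(paste0, cols)
}

#' Simulate a labeled splice-site dataset with controlled imbalance
#'
#' Positives are drawn from the acceptor position probability matrix;
#' negatives are decoys: background-composition windows that also carry the
#' "AG" dimer at the same offset. The positive-to-negative ratio is
#' 1-to-`degree`.
#'
#' @param n_pos number of positive windows (>= 1).
#' @param degree imbalance degree: negatives are `degree * n_pos` (>= 1).
#' @param window_length,dimer_start,signal,background see [acceptor_pwm()].
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit.
#' @return a `splice_records` data frame with positives first; the
#'   generating configuration is attached as attribute `sim_config`.
#' @export
simulate_splice_data <- function(n_pos, degree, window_length = 141,
                                 dimer_start = 61, signal = 0.6,
                                 background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                                 seed = NULL) {
  n_pos <- as.integer(n_pos)
  degree <- as.integer(degree)
  if (n_pos < 1L) stop("n_pos must be >= 1")
  if (degree < 1L) stop("degree must be >= 1")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  pwm_pos <- acceptor_pwm(window_length, dimer_start, signal, background)
  pwm_neg <- acceptor_pwm(window_length, dimer_start, 0, background)
  n_neg <- degree * n_pos
  seqs <- c(sample_seq_matrix(n_pos, pwm_pos), sample_seq_matrix(n_neg, pwm_neg))
  rec <- splice_records(
    seqs,
    id = c(sprintf("pos_%05d", seq_len(n_pos)), sprintf("neg_%05d", seq_len(n_neg))),
    label = c(rep("positive", n_pos), rep("negative", n_neg)),
    window_length = window_length, dimer_start = dimer_start)
  attr(rec, "sim_config") <- list(n_pos = n_pos, degree = degree,
                                  window_length = window_length,
                                  dimer_start = dimer_start, signal = signal,
                                  background = as.numeric(background),
                                  seed = seed)
  rec
}

#' Nested series of datasets over increasing imbalance degrees
#'
#' All datasets in the series share the full positive set; the negative
#' sets are nested by inclusion, so the 1-to-10 dataset contains every
#' instance of the 1-to-5 dataset. The dataset at degree `d` has exactly
#' `d` negatives per positive.
#'
#' @param records a `splice_records` base dataset with at least
#'   `max(degrees)` negatives per positive.
#' @param degrees increasing integer vector of imbalance degrees.
#' @param seed optional integer seed for the negative shuffle.
#' @return named list of `splice_records`, one per degree.
#' @export
nest_imbalance_series <- function(records, degrees, seed = NULL) {
  stopifnot(inherits(records, "splice_records"))
  degrees <- sort(as.integer(degrees))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  pos <- which(records$label == "positive")
  neg <- which(records$label == "negative")
  p <- length(pos)
  if (p == 0L) stop("base dataset has no positives")
  short <- degrees[degrees * p > length(neg)]
  if (length(short)) {
    stop(sprintf("not enough negatives for degree 1-to-%d (need %d, have %d)",
                 short[1L], short[1L] * p, length(neg)))
  }
  neg <- neg[sample.int(length(neg), length(neg))]
  out <- lapply(degrees, function(d) {
    idx <- c(pos, neg[seq_len(d * p)])
    ds <- records[idx, , drop = FALSE]
    class(ds) <- class(records)
    attr(ds, "window_length") <- attr(records, "window_length")
    attr(ds, "dimer_start") <- attr(records, "dimer_start")
    attr(ds, "alphabet") <- attr(records, "alphabet")
    ds
  })
  names(out) <- paste0("1-to-", degrees)
  out
}
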