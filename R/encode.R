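# Feature views ------------------------------------------------------------
#
# Two static categorical views of each window feed the classifiers:
#   view1: one feature per position, category = the nucleotide there
#          (L features, 4 categories each; 5 under the fifth-letter policy)
#   view2: one feature per overlapping 3-mer start, category = the 3-mer
#          (L - 2 features, 64 categories each)
# Co-training trains one subclassifier per view; self-training and the
# supervised baseline use the concatenation of both views.

#' Encode a single sequence as the nucleotide/position view
#'
#' @param sequence a DNA string over `alphabet`.
#' @param alphabet character string of allowed letters, `"ACGT"` by default.
#' @return integer vector of length `nchar(sequence)` with values in
#'   `1:nchar(alphabet)`; names give the letters.
#' @export
encode_nucleotide_view <- function(sequence, alphabet = "ACGT") {
  letters <- strsplit(toupper(sequence), "")[[1L]]
  alph <- strsplit(alphabet, "")[[1L]]
  code <- match(letters, alph)
  if (anyNA(code)) {
    pos <- which(is.na(code))[1L]
    stop(sprintf("invalid character '%s' at position %d", letters[pos], pos))
  }
  names(code) <- letters
  code
}

#' Encode a single sequence as the 3-mer/position view
#'
#' Overlapping 3-mers with step 1; the category index enumerates the
#' `a^3` possible 3-mers in lexicographic order of the alphabet.
#'
#' @inheritParams encode_nucleotide_view
#' @return integer vector of length `nchar(sequence) - 2`; names give the
#'   3-mers.
#' @export
encode_trimer_view <- function(sequence, alphabet = "ACGT") {
  L <- nchar(sequence)
  if (L < 3L) stop("sequence must have length >= 3 for the 3-mer view")
  v1 <- encode_nucleotide_view(sequence, alphabet)
  a <- nchar(alphabet)
  idx <- seq_len(L - 2L)
  code <- a^2 * (v1[idx] - 1L) + a * (v1[idx + 1L] - 1L) + v1[idx + 2L]
  names(code) <- paste0(names(v1)[idx], names(v1)[idx + 1L], names(v1)[idx + 2L])
  code
}

#' Encode a set of windows into both feature views
#'
#' @param records a `splice_records` data frame.
#' @return a `splice_views` object: list with `id`, `label`, integer
#'   matrices `view1` (n x L) and `view2` (n x (L-2)), the window length and
#'   the alphabet. Row order follows `records`.
#' @export
encode_views <- function(records) {
  stopifnot(inherits(records, "splice_records"))
  L <- attr(records, "window_length")
  alphabet <- attr(records, "alphabet")
  if (is.null(alphabet)) alphabet <- "ACGT"
  a <- nchar(alphabet)
  n <- nrow(records)
  if (n > 0 && L < 3L) stop("window length must be >= 3 to build the 3-mer view")
  alph <- strsplit(alphabet, "")[[1L]]
  if (n == 0L) {
    v1 <- matrix(integer(0), 0L, max(L, 0L))
    v2 <- matrix(integer(0), 0L, max(L - 2L, 0L))
  } else {
    letters <- unlist(strsplit(records$sequence, ""), use.names = FALSE)
    code <- match(letters, alph)
    if (anyNA(code)) {
      flat <- which(is.na(code))[1L]
      rec <- (flat - 1L) %/% L + 1L
      stop(sprintf("record '%s' contains a character outside '%s'",
                   records$id[rec], alphabet))
    }
    v1 <- matrix(code, nrow = n, ncol = L, byrow = TRUE)
    i <- seq_len(L - 2L)
    v2 <- a^2 * (v1[, i, drop = FALSE] - 1L) +
      a * (v1[, i + 1L, drop = FALSE] - 1L) + v1[, i + 2L, drop = FALSE]
  }
  structure(list(id = records$id,
                 label = records$label,
                 view1 = v1,
                 view2 = v2,
                 window_length = L,
                 alphabet = alphabet),
            class = "splice_views")
}

#' @export
print.splice_views <- function(x, ...) {
  cat(sprintf("splice_views: %d instances, view1 %d x %d categories, view2 %d x %d categories\n",
              length(x$id), ncol(x$view1), nchar(x$alphabet),
              ncol(x$view2), nchar(x$alphabet)^3))
  cat(sprintf("labels: %d positive, %d negative, %d unlabeled\n",
              sum(x$label == "positive"), sum(x$label == "negative"),
              sum(x$label == "unlabeled")))
  invisible(x)
}

#' Recover the sequences from the nucleotide/position view
#'
#' The nucleotide view is a lossless encoding; this inverts it.
#'
#' @param views a `splice_views` object.
#' @return character vector of sequences.
#' @export
decode_view1 <- function(views) {
  stopifnot(inherits(views, "splice_views"))
  alph <- strsplit(views$alphabet, "")[[1L]]
  apply(views$view1, 1L, function(r) paste(alph[r], collapse = ""))
}

# Feature matrix for one view; attaches per-feature category counts.
# view = "view1" | "view2" | "combined" (view1 followed by view2).
view_matrix <- function(views, view = c("combined", "view1", "view2")) {
  view <- match.arg(view)
  a <- nchar(views$alphabet)
  x <- switch(view,
              view1 = views$view1,
              view2 = views$view2,
              combined = cbind(views$view1, views$view2))
  n_cat <- switch(view,
                  view1 = rep(a, ncol(views$view1)),
                  view2 = rep(a^3, ncol(views$view2)),
                  combined = c(rep(a, ncol(views$view1)),
                               rep(a^3, ncol(views$view2))))
  attr(x, "n_cat") <- n_cat
  x
}

#' Row subset of an encoded dataset
#'
#' @param views a `splice_views` object.
#' @param idx integer indices of the instances to keep.
#' @param mask if `TRUE`, the returned labels are all `"unlabeled"` —
#'   convenient for building the unlabeled pool of a training split.
#' @return a `splice_views` object with the selected rows.
#' @export
subset_views <- function(views, idx, mask = FALSE) {
  out <- views
  out$id <- views$id[idx]
  out$label <- if (mask) rep("unlabeled", length(idx)) else views$label[idx]
  out$view1 <- views$view1[idx, , drop = FALSE]
  out$view2 <- views$view2[idx, , drop = FALSE]
  out
}

#' Export encoded instances as TSV
#'
#' Writes one row per instance: id, label, then the view1 and view2
#' category indices tab-separated. Intended for debugging and
#' cross-language checks.
#'
#' @param views a `splice_views` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_views_tsv <- function(views, path) {
  stopifnot(inherits(views, "splice_views"))
  df <- data.frame(id = views$id, label = views$label,
                   views$view1, views$view2, check.names = FALSE)
  colnames(df) <- c("id", "label",
                    paste0("nt", seq_len(ncol(views$view1))),
                    paste0("mer", seq_len(ncol(views$view2))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
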