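#' Splice-site sequence windows
#'
#' A `splice_records` object is a data frame with columns `id`, `sequence`
#' and `label` holding fixed-length DNA windows centred on a candidate
#' acceptor site. The positive class are true acceptor splice sites, the
#' negative class decoy "AG" occurrences; instances whose class is unknown
#' are labelled `"unlabeled"` and form the pool available to the
#' semi-supervised ensembles.
#'
#' @param sequence character vector of DNA sequences, all of the same length.
#' @param id character vector of record identifiers (generated if `NULL`).
#' @param label character vector with values `"positive"`, `"negative"` or
#'   `"unlabeled"`; recycled if length 1. Defaults to `"unlabeled"`.
#' @param window_length expected sequence length; defaults to the length of
#'   the first sequence.
#' @param dimer_start 1-based position at which the acceptor "AG" dimer must
#'   start, or `NULL` to skip the dimer check. Every true site and every
#'   decoy carries the dimer, so the check applies to all records.
#' @param iupac how to treat non-ACGT characters: `"reject"` (default)
#'   raises an error; `"fifth"` collapses any IUPAC ambiguity code to a
#'   fifth symbol `N`, enlarging the category set of every downstream
#'   feature accordingly.
#' @return a `splice_records` data frame.
#' @seealso [read_splice_fasta()], [encode_views()], [simulate_splice_data()]
#' @export
splice_records <- function(sequence, id = NULL, label = "unlabeled",
                           window_length = NULL, dimer_start = NULL,
                           iupac = c("reject", "fifth")) {
  iupac <- match.arg(iupac)
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (is.null(id)) id <- sprintf("seq_%04d", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("record ids must be unique")
  label <- rep_len(as.character(label), n)
  bad_lab <- setdiff(unique(label), c("positive", "negative", "unlabeled"))
  if (length(bad_lab)) {
    stop("invalid label(s): ", paste(bad_lab, collapse = ", "))
  }
  if (n > 0) {
    if (is.null(window_length)) window_length <- nchar(sequence[1L])
    len <- nchar(sequence)
    if (any(len != window_length)) {
      off <- which(len != window_length)[1L]
      stop(sprintf("record '%s' has length %d, expected window length %d",
                   id[off], len[off], window_length))
    }
    if (iupac == "fifth") {
      sequence <- gsub("[RYSWKMBDHVN]", "N", sequence)
      alph <- "ACGTN"
    } else {
      alph <- "ACGT"
    }
    bad <- grep(sprintf("[^%s]", alph), sequence)
    if (length(bad)) {
      ch <- regmatches(sequence[bad[1L]],
                       regexpr(sprintf("[^%s]", alph), sequence[bad[1L]]))
      stop(sprintf("record '%s' contains invalid character '%s'",
                   id[bad[1L]], ch))
    }
    if (!is.null(dimer_start)) {
      if (dimer_start + 1L > window_length) {
        stop("dimer_start + 1 exceeds the window length")
      }
      dimer <- substr(sequence, dimer_start, dimer_start + 1L)
      if (any(dimer != "AG")) {
        off <- which(dimer != "AG")[1L]
        stop(sprintf(
          "record '%s' lacks the acceptor 'AG' dimer at positions %d-%d",
          id[off], dimer_start, dimer_start + 1L))
      }
    }
  } else if (is.null(window_length)) {
    window_length <- 0L
  }
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("splice_records", "data.frame")
  attr(out, "window_length") <- as.integer(window_length)
  attr(out, "dimer_start") <- if (is.null(dimer_start)) NA_integer_ else as.integer(dimer_start)
  attr(out, "alphabet") <- if (iupac == "fifth") "ACGTN" else "ACGT"
  out
}

#' Read splice-site windows from a FASTA file
#'
#' Reads fixed-length candidate acceptor windows. Class labels are taken
#' from the FASTA headers via regular expressions: the first rule that
#' matches assigns the label, otherwise the record is `"unlabeled"`.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param window_length required sequence length (default 141).
#' @param dimer_start 1-based start of the "AG" dimer (default 61); `NULL`
#'   disables the check.
#' @param label_rule named list of regular expressions with elements
#'   `positive` and `negative`, matched case-insensitively against the
#'   header description (everything after the id token); records whose
#'   description matches neither become `"unlabeled"`.
#' @param iupac see [splice_records()].
#' @return a `splice_records` data frame in file order.
#' @export
read_splice_fasta <- function(path, window_length = 141, dimer_start = 61,
                              label_rule = list(positive = "\\+1|pos",
                                                negative = "-1|neg"),
                              iupac = c("reject", "fifth")) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- head_lines[nzchar(trimws(head_lines))]
  if (length(nonblank) && !startsWith(nonblank[1L], ">")) {
    line_no <- which(nzchar(trimws(head_lines)))[1L]
    stop(sprintf("malformed FASTA: line %d does not start a record", line_no))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    return(splice_records(character(0), window_length = window_length))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  label <- rep("unlabeled", length(set))
  label[grepl(label_rule$negative, desc, ignore.case = TRUE)] <- "negative"
  label[grepl(label_rule$positive, desc, ignore.case = TRUE)] <- "positive"
  splice_records(as.character(set), id = ids, label = label,
                 window_length = window_length, dimer_start = dimer_start,
                 iupac = iupac)
}

#' Write splice-site windows to FASTA
#'
#' Headers carry the record id followed by its label, so that
#' [read_splice_fasta()] with the default label rule round-trips the labels.
#'
#' @param records a `splice_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_splice_fasta <- function(records, path) {
  stopifnot(inherits(records, "splice_records"))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- paste(records$id, records$label)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @export
print.splice_records <- function(x, ...) {
  cat(sprintf("splice_records: %d windows of length %d (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), attr(x, "window_length"),
              sum(x$label == "positive"), sum(x$label == "negative"),
              sum(x$label == "unlabeled")))
  if (nrow(x) > 0) {
    show <- utils::head(x, 4L)
    show$sequence <- paste0(substr(show$sequence, 1L, 24L), "...")
    print.data.frame(show, row.names = FALSE)
  }
  invisible(x)
}
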