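# Categorical Naive Bayes --------------------------------------------------
#
# The base learner for every ensemble member. Features are categorical with
# category sets fixed at fit time (4 per nucleotide feature, 64 per 3-mer
# feature), conditionals are Laplace-smoothed, and all probability
# accumulation happens in log space: the combined view has 280 features and
# linear-space products underflow.

#' Fit a categorical Naive Bayes classifier
#'
#' Class priors are maximum-likelihood frequencies of the training labels;
#' per-feature conditional category probabilities are Laplace-smoothed with
#' weight `alpha` over a category set fixed in advance (not inferred from
#' the data), so that unseen categories keep positive probability whenever
#' `alpha > 0`.
#'
#' @param x integer matrix, one row per instance; column `j` takes values in
#'   `1:n_cat[j]`.
#' @param y class labels, `"positive"` / `"negative"`; both classes must be
#'   present.
#' @param n_cat integer vector of category-set sizes, recycled over columns.
#'   Defaults to the `n_cat` attribute of `x` (set by [view_matrix()]).
#' @param alpha Laplace smoothing weight, default 1 (add-one).
#' @param view tag recording which feature view the model was fit on.
#' @return an object of class `categorical_nb`.
#' @examples
#' x <- matrix(c(1L, 2L), ncol = 1)
#' m <- categorical_nb(x, c("positive", "negative"), n_cat = 4)
#' exp(m$log_cond[1, ])  # P(category 1 | class) = (1+1)/(1+4), (0+1)/(1+4)
#' @export
categorical_nb <- function(x, y, n_cat = attr(x, "n_cat"), alpha = 1,
                           view = "combined") {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  n <- nrow(x)
  F <- ncol(x)
  if (is.null(n_cat)) stop("n_cat must be supplied (or attached to x)")
  n_cat <- as.integer(rep_len(n_cat, F))
  if (alpha < 0) stop("alpha must be >= 0")
  y <- as.character(y)
  classes <- c("negative", "positive")
  if (!all(y %in% classes)) stop("labels must be 'positive' or 'negative'")
  counts_y <- c(negative = sum(y == "negative"), positive = sum(y == "positive"))
  if (any(counts_y == 0L)) {
    stop("both classes must be present in the training data; missing: ",
         names(counts_y)[counts_y == 0L])
  }
  if (n > 0 && (min(x) < 1L || any(x > rep(n_cat, each = n)))) {
    stop("feature values must lie in 1:n_cat for every column")
  }
  offset <- c(0L, cumsum(n_cat))[seq_len(F)]
  total <- sum(n_cat)
  # category counts per class, one tabulate pass per class over flat indices
  flat <- x + rep(offset, each = n)
  log_cond <- matrix(NA_real_, total, 2L, dimnames = list(NULL, classes))
  denom_per_cell <- rep.int(NA_real_, total)
  for (c_i in seq_along(classes)) {
    rows <- y == classes[c_i]
    cnt <- tabulate(flat[rows, , drop = FALSE], nbins = total)
    denom <- rep.int(counts_y[c_i] + alpha * n_cat, n_cat)
    log_cond[, c_i] <- log(cnt + alpha) - log(denom)
  }
  structure(list(view = view,
                 classes = classes,
                 log_prior = log(counts_y / n),
                 log_cond = log_cond,
                 n_cat = n_cat,
                 offset = offset,
                 alpha = alpha,
                 n_train = n),
            class = "categorical_nb")
}

# Per-class log joint (log prior + log likelihood) for an integer matrix.
nb_log_joint <- function(object, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  F <- ncol(x)
  if (F != length(object$n_cat)) {
    stop(sprintf("dimension mismatch: model has %d features, data has %d",
                 length(object$n_cat), F))
  }
  flat <- x + rep(object$offset, each = n)
  ll <- matrix(0, n, 2L, dimnames = list(NULL, object$classes))
  for (c_i in 1:2) {
    ll[, c_i] <- object$log_prior[c_i] +
      rowSums(matrix(object$log_cond[flat, c_i], n, F))
  }
  ll
}

#' Posterior class probabilities from a categorical Naive Bayes model
#'
#' @param object a `categorical_nb` model.
#' @param newdata integer matrix with the same feature layout as the
#'   training data.
#' @param type `"posterior"` (default) for an n x 2 matrix of normalized
#'   class probabilities, `"class"` for predicted labels (posterior >= 0.5
#'   predicts positive), `"log_joint"` for unnormalized per-class log
#'   probabilities.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.categorical_nb <- function(object, newdata,
                                   type = c("posterior", "class", "log_joint"),
                                   ...) {
  type <- match.arg(type)
  ll <- nb_log_joint(object, newdata)
  if (type == "log_joint") return(ll)
  if (any(!is.finite(ll[, 1L]) & !is.finite(ll[, 2L]))) {
    stop("instance has zero probability under both classes ",
         "(unseen category with alpha = 0)")
  }
  m <- pmax(ll[, 1L], ll[, 2L])
  w <- exp(ll - m)
  post <- w / rowSums(w)
  if (type == "class") {
    return(ifelse(post[, "positive"] >= 0.5, "positive", "negative"))
  }
  post
}

#' @export
print.categorical_nb <- function(x, ...) {
  cat(sprintf("categorical_nb (%s view): %d features, alpha = %g, trained on %d instances\n",
              x$view, length(x$n_cat), x$alpha, x$n_train))
  cat(sprintf("priors: negative %.3f, positive %.3f\n",
              exp(x$log_prior[1L]), exp(x$log_prior[2L])))
  invisible(x)
}

#' Serialize / restore a categorical Naive Bayes model as JSON
#'
#' A versioned plain-text representation of the priors, smoothed
#' conditional tables and category layout.
#'
#' @param model a `categorical_nb` object.
#' @param path file path.
#' @return `nb_to_json` returns `path` invisibly; `nb_from_json` returns the
#'   restored model.
#' @export
nb_to_json <- function(model, path) {
  stopifnot(inherits(model, "categorical_nb"))
  doc <- list(format = "spliceSSL-nb", version = 1L,
              view = model$view, alpha = model$alpha,
              n_train = model$n_train, n_cat = model$n_cat,
              log_prior = as.numeric(model$log_prior),
              log_cond_negative = model$log_cond[, "negative"],
              log_cond_positive = model$log_cond[, "positive"])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nb_to_json
#' @export
nb_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "spliceSSL-nb")) {
    stop("not a spliceSSL Naive Bayes document: ", path)
  }
  n_cat <- as.integer(doc$n_cat)
  structure(list(view = doc$view,
                 classes = c("negative", "positive"),
                 log_prior = stats::setNames(as.numeric(doc$log_prior),
                                             c("negative", "positive")),
                 log_cond = cbind(negative = doc$log_cond_negative,
                                  positive = doc$log_cond_positive),
                 n_cat = n_cat,
                 offset = c(0L, cumsum(n_cat))[seq_along(n_cat)],
                 alpha = doc$alpha,
                 n_train = doc$n_train),
            class = "categorical_nb")
}
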