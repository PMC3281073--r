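#' Draw random feature subspaces
#'
#' Draws `r` independent subsets of `m` distinct feature positions, each
#' sampled uniformly without replacement from `1:p` (repeats across subsets
#' are allowed). Subsets are canonicalised to increasing order.
#'
#' @param p Total feature count.
#' @param m Subspace size, `1 <= m <= p`.
#' @param r Number of subsets.
#' @return Integer matrix with `r` rows and `m` columns, one subset per row.
#' @export
draw_feature_subsets <- function(p, m, r) {
  p <- as.integer(p); m <- as.integer(m); r <- as.integer(r)
  if (m < 1 || m > p)
    stop("subspace size m (", m, ") must lie in [1, p = ", p, "]",
         call. = FALSE)
  if (r < 1) stop("ensemble size r must be >= 1", call. = FALSE)
  out <- matrix(0L, nrow = r, ncol = m)
  for (i in seq_len(r)) out[i, ] <- sort(sample.int(p, m))
  out
}

#' Fit a Random KNN ensemble
#'
#' Builds the Random KNN classifier: `r` base KNN classifiers, each on a
#' random `m`-feature subspace of the training data, combined at prediction
#' time by majority-of-majority voting (each base classifier takes the
#' majority of its `k` nearest neighbours; the ensemble takes the majority
#' of the `r` base votes). Samples are never bootstrapped — KNN is a stable
#' base learner, so resampling the cases is unnecessary; diversity comes
#' from the feature subspaces alone.
#'
#' @param dataset An [rknn_dataset] used as the training set.
#' @param params An [rknn_params]; `k`, `r`, `m` and `seed` are used here.
#' @return An object of class `rknn_model` holding the subsets and a
#'   reference to the training data.
#' @seealso [predict.rknn_model()], [compute_supports()]
#' @examples
#' d <- synthetic_dataset(n = 30, p = 50, n_informative = 5, seed = 1)$dataset
#' fit <- rknn(d, rknn_params(r = 100, seed = 1))
#' mean(predict(fit, d$X) == as.character(d$y))
#' @export
rknn <- function(dataset, params = rknn_params()) {
  stopifnot(inherits(dataset, "rknn_dataset"), inherits(params, "rknn_params"))
  maybe_set_seed(params)
  p <- ncol(dataset$X)
  m <- effective_m(params, p)
  subsets <- draw_feature_subsets(p, m, params$r)
  structure(
    list(params = params, m = m, subsets = subsets, dataset = dataset),
    class = "rknn_model"
  )
}

#' @export
print.rknn_model <- function(x, ...) {
  cat("Random KNN model: r =", nrow(x$subsets), "base classifiers, m =",
      x$m, "features each, k =", x$params$k, "\n")
  cat("  trained on", nrow(x$dataset$X), "samples x", ncol(x$dataset$X),
      "features,", nlevels(x$dataset$y), "classes\n")
  invisible(x)
}

#' Predict with a Random KNN ensemble
#'
#' Each base classifier votes for every query row via KNN on its subspace,
#' using the entire training set as the neighbour pool; the final label is
#' the majority over the `r` base votes, with ties broken by canonical
#' label order.
#'
#' @param object An `rknn_model` from [rknn()].
#' @param newdata Numeric matrix with the same columns (count and order) as
#'   the training features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.rknn_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  train <- object$dataset
  if (ncol(newdata) != ncol(train$X))
    stop("newdata has ", ncol(newdata), " columns but the model was trained",
         " on ", ncol(train$X), call. = FALSE)
  levs <- levels(train$y)
  pred <- .rknn_votes_cpp(train$X, as.integer(train$y) - 1L, newdata,
                          object$subsets - 1L, object$params$k, length(levs))
  levs[pred + 1L]
}
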