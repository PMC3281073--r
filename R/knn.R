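#' Majority vote over a set of labels
#'
#' Returns the most frequent label; ties are broken by canonical label order
#' (the first tied label in sorted order wins), so the vote is deterministic.
#'
#' @param labels Non-empty vector of labels (character or factor).
#' @param levels Optional label universe fixing the canonical order;
#'   defaults to the sorted distinct labels present.
#' @return A single label (character).
#' @examples
#' majority_vote(c("A", "A", "B")) # "A"
#' majority_vote(c("A", "B"))      # tie -> "A"
#' @export
majority_vote <- function(labels, levels = NULL) {
  if (length(labels) == 0) stop("cannot vote over an empty label set",
                                call. = FALSE)
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels))
  cnt <- table(factor(labels, levels = levels))
  levels[which.max(cnt)] # which.max takes the first maximum: canonical order
}

canonicalize_subset <- function(subset, p) {
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("feature subset must be non-empty",
                                call. = FALSE)
  if (anyNA(subset) || any(subset < 1 | subset > p))
    stop("feature subset indices must lie in [1, ", p, "]", call. = FALSE)
  if (anyDuplicated(subset)) stop("feature subset has duplicate indices",
                                  call. = FALSE)
  sort(subset)
}

#' k-nearest-neighbour classification on a feature subset
#'
#' Deterministic KNN: each query row is assigned the majority label of its
#' `k` nearest base rows under Euclidean distance restricted to the columns
#' in `subset`. Distance ties at the k-th neighbour are broken by `base_ids`
#' (ascending), so the neighbour set is unique and independent of base row
#' order; vote ties are broken by canonical label order.
#'
#' @param base_X Numeric matrix of base (training) rows.
#' @param base_y Labels for `base_X` rows (character or factor).
#' @param query_X Numeric matrix of rows to classify; same column count as
#'   `base_X`.
#' @param k Positive integer, `k <= nrow(base_X)`.
#' @param subset Integer vector of column positions to use; defaults to all
#'   columns.
#' @param base_ids Integer tie-break identifiers for the base rows; defaults
#'   to row position.
#' @return Character vector of predicted labels, one per query row.
#' @examples
#' X <- matrix(c(0, 1, 2, 3), ncol = 1)
#' knn_classify(X, c("A", "A", "B", "B"), matrix(1.4), k = 3) # "A"
#' @export
knn_classify <- function(base_X, base_y, query_X, k,
                         subset = seq_len(ncol(base_X)),
                         base_ids = seq_len(nrow(base_X))) {
  if (!is.matrix(base_X)) base_X <- as.matrix(base_X)
  if (!is.matrix(query_X)) query_X <- as.matrix(query_X)
  if (ncol(query_X) != ncol(base_X))
    stop("query and base matrices must have the same number of columns",
         call. = FALSE)
  if (length(base_y) != nrow(base_X))
    stop("`base_y` length must match nrow(base_X)", call. = FALSE)
  if (!(is.numeric(k) && length(k) == 1 && k >= 1 && k == floor(k)))
    stop("`k` must be a single positive integer", call. = FALSE)
  if (k > nrow(base_X))
    stop("k (", k, ") exceeds the number of base samples (", nrow(base_X),
         ")", call. = FALSE)
  subset <- canonicalize_subset(subset, ncol(base_X))
  levs <- if (is.factor(base_y)) levels(base_y) else sort(unique(as.character(base_y)))
  ycode <- as.integer(factor(as.character(base_y), levels = levs)) - 1L
  pred <- .knn_predict_cpp(base_X, ycode, query_X, as.integer(k),
                           subset - 1L, length(levs), as.integer(base_ids))
  levs[pred + 1L]
}
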