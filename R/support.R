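#' Partition samples into base and query halves
#'
#' Splits `1:n` into a base half of size `ceiling(n/2)` (the neighbour pool
#' gets the extra sample when `n` is odd) and a query half with the rest.
#'
#' @param n Sample count, `n >= 2`.
#' @return List with integer vectors `base` and `query` (each sorted),
#'   disjoint and jointly covering `1:n`.
#' @export
partition_samples <- function(n) {
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 samples to partition", call. = FALSE)
  nb <- as.integer(ceiling(n / 2))
  base <- sort(sample.int(n, nb))
  list(base = base, query = setdiff(seq_len(n), base))
}

#' Compute feature supports by bidirectional voting
#'
#' Builds `r` base KNN classifiers, each on a random `m`-feature subspace.
#' For each one, the samples are split into a base half and a query half
#' (afresh per classifier under `partition_mode = "dynamic"`, once for all
#' under `"fixed"`); the query half is classified against the base half and
#' the classifier's accuracy recorded. Each classifier's accuracy is then
#' credited back to every feature it used: a feature's *support* is the mean
#' accuracy over the base classifiers containing it, and its *multiplicity*
#' is how many contained it. Features appearing in no classifier get
#' support `NA` (undefined), never 0.
#'
#' @param dataset An [rknn_dataset].
#' @param params An [rknn_params].
#' @param subsets Optional pre-specified integer matrix of subsets
#'   (`r` rows; 1-based column positions), bypassing random drawing —
#'   intended for inspection and exact-value testing.
#' @param partitions Optional pre-specified list of partitions as returned
#'   by [partition_samples()], one per classifier (recycled if length 1).
#' @return An object of class `rknn_supports`: a data frame with columns
#'   `feature_id`, `multiplicity`, `support`, plus attributes `acc`
#'   (per-classifier accuracies), `mean_acc`, `m`, `r`, `k`,
#'   `partition_mode`.
#' @examples
#' d <- synthetic_dataset(n = 40, p = 100, n_informative = 5, seed = 7)$dataset
#' s <- compute_supports(d, rknn_params(r = 200, seed = 7))
#' head(rank_features(s))
#' @export
compute_supports <- function(dataset, params = rknn_params(),
                             subsets = NULL, partitions = NULL) {
  stopifnot(inherits(dataset, "rknn_dataset"), inherits(params, "rknn_params"))
  maybe_set_seed(params)
  n <- nrow(dataset$X); p <- ncol(dataset$X)
  nb <- as.integer(ceiling(n / 2))
  if (params$k > nb)
    stop("k (", params$k, ") exceeds the base half size (", nb,
         "); use a smaller k or more samples", call. = FALSE)
  if (is.null(subsets)) {
    m <- effective_m(params, p)
    subsets <- draw_feature_subsets(p, m, params$r)
  } else {
    if (!is.matrix(subsets)) subsets <- matrix(subsets, nrow = 1)
    if (nrow(subsets) < 1) stop("need at least one subset", call. = FALSE)
    rows <- lapply(seq_len(nrow(subsets)),
                   function(i) canonicalize_subset(subsets[i, ], p = p))
    subsets <- do.call(rbind, rows)
    m <- ncol(subsets)
  }
  r <- nrow(subsets)
  if (is.null(partitions)) {
    base_idx <- if (params$partition_mode == "fixed") {
      matrix(partition_samples(n)$base, nrow = r, ncol = nb, byrow = TRUE)
    } else {
      do.call(rbind, lapply(seq_len(r),
                            function(i) partition_samples(n)$base))
    }
  } else {
    if (length(partitions) == 1) partitions <- rep(partitions, r)
    if (length(partitions) != r)
      stop("need one partition per classifier (or a single one to share)",
           call. = FALSE)
    base_idx <- do.call(rbind, lapply(partitions, function(pt) {
      b <- sort(as.integer(pt$base))
      if (length(b) != nb || any(b < 1 | b > n) || anyDuplicated(b))
        stop("each partition's base half must be ", nb,
             " distinct sample positions in [1, ", n, "]", call. = FALSE)
      b
    }))
  }
  acc <- .support_acc_cpp(dataset$X, as.integer(dataset$y) - 1L,
                          subsets - 1L, base_idx - 1L,
                          params$k, nlevels(dataset$y))
  mult <- tabulate(as.integer(subsets), nbins = p)
  ssum <- numeric(p)
  for (i in seq_len(r)) {
    js <- subsets[i, ]
    ssum[js] <- ssum[js] + acc[i]
  }
  support <- ifelse(mult > 0, ssum / pmax(mult, 1L), NA_real_)
  out <- data.frame(feature_id = dataset$feature_ids,
                    multiplicity = mult, support = support,
                    stringsAsFactors = FALSE)
  structure(out, class = c("rknn_supports", "data.frame"),
            acc = acc, mean_acc = mean(acc), m = m, r = r,
            k = params$k, partition_mode = params$partition_mode)
}

#' @export
print.rknn_supports <- function(x, ...) {
  cat("Feature supports: p =", nrow(x), " r =", attr(x, "r"),
      " m =", attr(x, "m"), "\n")
  cat("  ensemble mean accuracy:", format(attr(x, "mean_acc"), digits = 4),
      "\n")
  top <- rank_features(x)
  print.data.frame(utils::head(top, 5))
  invisible(x)
}

#' Rank features by support
#'
#' Orders features by support (descending); ties are broken by higher
#' multiplicity, then by feature id order (the column order of the
#' dataset), so the ranking is a deterministic total order. Features with
#' undefined support (multiplicity 0) are appended last, flagged with
#' `rank = NA`.
#'
#' @param supports An [rknn_supports] object (or a data frame with columns
#'   `feature_id`, `multiplicity`, `support`).
#' @return Data frame sorted by rank with columns `feature_id`,
#'   `multiplicity`, `support`, `rank`.
#' @export
rank_features <- function(supports) {
  stopifnot(all(c("feature_id", "multiplicity", "support") %in%
                  names(supports)))
  if (all(is.na(supports$support)))
    stop("no feature has defined support; increase r or m", call. = FALSE)
  defined <- !is.na(supports$support)
  idx <- seq_len(nrow(supports))
  o_def <- idx[defined][order(-supports$support[defined],
                              -supports$multiplicity[defined],
                              idx[defined])]
  o_undef <- idx[!defined]
  out <- as.data.frame(supports)[c(o_def, o_undef),
                                 c("feature_id", "multiplicity", "support")]
  out$rank <- c(seq_along(o_def), rep(NA_integer_, length(o_undef)))
  rownames(out) <- NULL
  out
}

#' Write a support ranking as TSV
#'
#' Columns `feature_id`, `multiplicity`, `support`, `rank`; undefined
#' supports are written as `NA` with a blank rank. Output is byte-stable
#' for a fixed seed.
#'
#' @param supports An [rknn_supports] object.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_supports <- function(supports, path) {
  rk <- rank_features(supports)
  rk$support <- ifelse(is.na(rk$support), "NA", sprintf("%.17g", rk$support))
  rk$rank <- ifelse(is.na(rk$rank), "", as.character(rk$rank))
  utils::write.table(rk, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
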