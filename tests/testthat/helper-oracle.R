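# Independent brute-force reference implementations. These deliberately use
# plain double loops and all-pairs distance matrices, sharing no code with
# the package's kernel.

# All-pairs Euclidean KNN with (distance, id) neighbour tie-break and
# canonical-label vote tie-break.
bf_knn <- function(base_X, base_y, query_X, k, cols = seq_len(ncol(base_X)),
                   ids = seq_len(nrow(base_X))) {
  base_y <- as.character(base_y)
  levs <- sort(unique(base_y))
  out <- character(nrow(query_X))
  for (q in seq_len(nrow(query_X))) {
    d <- numeric(nrow(base_X))
    for (b in seq_len(nrow(base_X)))
      d[b] <- sqrt(sum((query_X[q, cols] - base_X[b, cols])^2))
    ord <- order(d, ids)
    nb <- base_y[ord[seq_len(k)]]
    cnt <- vapply(levs, function(L) sum(nb == L), integer(1))
    out[q] <- levs[which.max(cnt)]
  }
  out
}

# Count-and-argmax majority with canonical-order ties.
bf_majority <- function(labels) {
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  cnt <- vapply(levs, function(L) sum(labels == L), integer(1))
  levs[which.max(cnt)]
}

# Loop-based support bookkeeping from explicit subsets/partitions.
bf_supports <- function(dataset, subsets, partitions, k) {
  X <- dataset$X
  y <- as.character(dataset$y)
  p <- ncol(X)
  acc <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    b <- partitions[[i]]$base
    q <- setdiff(seq_len(nrow(X)), b)
    pred <- bf_knn(X[b, , drop = FALSE], y[b], X[q, , drop = FALSE],
                   k, cols = subsets[[i]], ids = b)
    acc[i] <- mean(pred == y[q])
  }
  mult <- integer(p)
  ssum <- numeric(p)
  for (i in seq_along(subsets)) {
    for (j in subsets[[i]]) {
      mult[j] <- mult[j] + 1L
      ssum[j] <- ssum[j] + acc[i]
    }
  }
  list(acc = acc, multiplicity = mult,
       support = ifelse(mult > 0, ssum / pmax(mult, 1), NA_real_))
}

# Random small classification dataset for property tests.
random_dataset <- function(n, p, classes = 2) {
  y <- c(LETTERS[seq_len(classes)],
         sample(LETTERS[seq_len(classes)], n - classes, replace = TRUE))
  rknn_dataset(matrix(rnorm(n * p), n, p), sample(y))
}
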