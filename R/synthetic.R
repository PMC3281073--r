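#' Generate a "small n, large p" dataset with planted informative features
#'
#' Emulates the structure of benchmark gene-expression matrices: tens to a
#' couple of hundred samples, thousands of features, a handful of classes
#' (possibly unbalanced), and only a small planted subset of features that
#' carries class information. Noise features are independent standard
#' normals; each planted feature gets a class-dependent mean offset, with
#' the class means laid out on a grid of spacing `shift` (in noise-sd
#' units) centred at zero. `shift = 0` makes the planted features
#' indistinguishable from noise.
#'
#' @param n Samples (typical regime 40–200).
#' @param p Features (typical regime 2,000–15,000; scale down for tests).
#' @param classes Number of classes, 2–26.
#' @param n_informative Number of planted class-informative features.
#' @param shift Between-class mean separation in noise-sd units, `>= 0`.
#' @param class_proportions Optional positive weights (one per class,
#'   normalised internally) for unbalanced designs; default balanced.
#' @param exact_counts If `TRUE`, class sizes are fixed exactly at
#'   `round(n * proportions)` (largest-remainder rounding) instead of
#'   sampled, for experiments needing exact control.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `dataset` (an [rknn_dataset]) and `informative`
#'   (character vector of the planted feature ids).
#' @examples
#' sim <- synthetic_dataset(n = 60, p = 500, n_informative = 10, seed = 1)
#' sim$dataset
#' sim$informative
#' @export
synthetic_dataset <- function(n = 100, p = 2000, classes = 2,
                              n_informative = 20, shift = 1.5,
                              class_proportions = NULL,
                              exact_counts = FALSE, seed = NULL) {
  stopifnot(n >= classes, p >= 1, classes >= 2, classes <= 26,
            n_informative >= 0, n_informative <= p, shift >= 0)
  if (!is.null(seed)) set.seed(seed)
  labs <- LETTERS[seq_len(classes)]
  if (is.null(class_proportions)) class_proportions <- rep(1, classes)
  if (length(class_proportions) != classes || any(class_proportions <= 0))
    stop("`class_proportions` must be ", classes, " positive weights",
         call. = FALSE)
  prop <- class_proportions / sum(class_proportions)
  if (exact_counts) {
    counts <- floor(n * prop)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(n * prop - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    if (any(counts == 0))
      stop("`class_proportions` leave at least one class empty at n = ", n,
           call. = FALSE)
    y <- sample(rep(labs, counts))
  } else {
    for (try in 1:1000) {
      y <- sample(labs, n, replace = TRUE, prob = prop)
      if (length(unique(y)) == classes) break
    }
    if (length(unique(y)) < classes)
      stop("could not draw all ", classes, " classes at n = ", n,
           "; use `exact_counts = TRUE` or larger n", call. = FALSE)
  }
  width <- max(5, nchar(p))
  feature_ids <- sprintf("g%0*d", width, seq_len(p))
  informative <- sort(sample.int(p, n_informative))
  X <- matrix(stats::rnorm(n * p), n, p)
  if (n_informative > 0 && shift > 0) {
    class_means <- (seq_len(classes) - (classes + 1) / 2) * shift
    offsets <- class_means[match(y, labs)]
    X[, informative] <- X[, informative] + offsets
  }
  list(dataset = rknn_dataset(X, y, feature_ids = feature_ids),
       informative = feature_ids[informative])
}

#' A fixed 8 x 6 two-class dataset for exact-value tests
#'
#' Small integer-valued dataset whose pairwise distances can be checked by
#' hand; samples s1–s4 are class A, s5–s8 class B. Features f1 and f2
#' separate the classes; f3–f6 are uninformative. Used for exact-value
#' tests of the KNN engine and the support bookkeeping.
#'
#' @return An [rknn_dataset] with 8 samples, 6 features, 2 classes.
#' @export
tiny_fixture <- function() {
  X <- matrix(c(
    # f1 f2 f3 f4 f5 f6
    0, 0, 1, 5, 2, 1,   # s1 A
    1, 0, 2, 1, 9, 3,   # s2 A
    0, 1, 8, 4, 3, 5,   # s3 A
    1, 1, 3, 7, 1, 2,   # s4 A
    4, 5, 2, 6, 8, 4,   # s5 B
    5, 4, 7, 2, 4, 9,   # s6 B
    4, 4, 5, 3, 6, 6,   # s7 B
    5, 5, 4, 8, 5, 7    # s8 B
  ), nrow = 8, byrow = TRUE)
  rknn_dataset(X, rep(c("A", "B"), each = 4),
               feature_ids = paste0("f", 1:6),
               sample_ids = paste0("s", 1:8))
}
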