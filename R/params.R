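#' Random KNN parameters
#'
#' Bundles the tuning parameters shared by [compute_supports()], [rknn()],
#' [rknn_fs()] and [loocv_external()].
#'
#' Defaults follow the conventional protocol for "small n, large p"
#' expression data: a small neighbour count (`k = 3`; `k = 1` is the other
#' common choice), a large ensemble (`r = 2000`), and subspaces of size
#' `m = round(sqrt(p))`, which maximises diversity between the random feature
#' subsets. `m = NULL` keeps the square-root rule active, so `m` is
#' recomputed from the current feature count at every elimination step;
#' an explicit integer `m` is held fixed (capped at the current `p`).
#'
#' @param k Positive integer; neighbours consulted by each base KNN.
#' @param r Positive integer; number of base classifiers in the ensemble.
#' @param m `NULL` for the `round(sqrt(p))` rule, or a positive integer
#'   subspace size.
#' @param q Proportion of features dropped per geometric-stage iteration,
#'   in (0, 1).
#' @param d Positive integer; features dropped per linear-stage iteration.
#' @param partition_mode `"dynamic"` (fresh base/query half-split per base
#'   classifier) or `"fixed"` (one split shared by all `r` classifiers).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param min_dim Positive integer floor on the retained feature count
#'   during backward elimination.
#'
#' @return An object of class `rknn_params`.
#' @examples
#' rknn_params(k = 1, r = 500)
#' @export
rknn_params <- function(k = 3, r = 2000, m = NULL, q = 0.2, d = 1,
                        partition_mode = c("dynamic", "fixed"),
                        seed = NULL, min_dim = 4) {
  partition_mode <- match.arg(partition_mode)
  stopifnot(
    "`k` must be a single positive integer" =
      is.numeric(k) && length(k) == 1 && k >= 1 && k == floor(k),
    "`r` must be a single positive integer" =
      is.numeric(r) && length(r) == 1 && r >= 1 && r == floor(r),
    "`d` must be a single positive integer" =
      is.numeric(d) && length(d) == 1 && d >= 1 && d == floor(d),
    "`min_dim` must be a single positive integer" =
      is.numeric(min_dim) && length(min_dim) == 1 && min_dim >= 1 &&
        min_dim == floor(min_dim)
  )
  if (!(is.numeric(q) && length(q) == 1 && q > 0 && q < 1))
    stop("`q` must be a proportion strictly between 0 and 1, got ", q,
         call. = FALSE)
  if (!is.null(m) &&
      !(is.numeric(m) && length(m) == 1 && m >= 1 && m == floor(m)))
    stop("`m` must be NULL (sqrt rule) or a single positive integer",
         call. = FALSE)
  if (!is.null(seed)) {
    if (!(is.numeric(seed) && length(seed) == 1 && seed == floor(seed)))
      stop("`seed` must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(
    list(k = as.integer(k), r = as.integer(r),
         m = if (is.null(m)) NULL else as.integer(m),
         q = q, d = as.integer(d), partition_mode = partition_mode,
         seed = seed, min_dim = as.integer(min_dim)),
    class = "rknn_params"
  )
}

#' @export
print.rknn_params <- function(x, ...) {
  cat("Random KNN parameters\n")
  cat("  k =", x$k, " r =", x$r,
      " m =", if (is.null(x$m)) "round(sqrt(p))" else x$m, "\n")
  cat("  q =", x$q, " d =", x$d, " min_dim =", x$min_dim, "\n")
  cat("  partition:", x$partition_mode,
      " seed:", if (is.null(x$seed)) "<current RNG>" else x$seed, "\n")
  invisible(x)
}

# Effective subspace size at the current feature count.
effective_m <- function(params, p) {
  m <- if (is.null(params$m)) max(1L, as.integer(round(sqrt(p)))) else params$m
  min(m, p)
}

# Seed the RNG from params if a seed was given; otherwise continue the
# current stream (used when a caller has already seeded a run).
maybe_set_seed <- function(params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  invisible(NULL)
}

# Derive a child seed from a master seed and an index (splitmix-style
# integer mixing, kept within 31 bits so it is a valid set.seed() value).
# Folds of a cross-validation get independent, order-free streams this way.
derive_seed <- function(seed, index) {
  x <- (as.double(seed) + as.double(index) * 2654435769) %% 2147483647
  x <- (x * 48271) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(if (x == 0) 1 else x)
}
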