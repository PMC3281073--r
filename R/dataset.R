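#' Construct a labelled expression dataset
#'
#' The core container shared by all Random KNN routines: an `n x p` numeric
#' matrix of samples by features plus one categorical label per sample.
#' Labels are stored as a factor whose levels are the distinct labels in
#' sorted order; this canonical order is the deterministic tie-break used by
#' every vote in the package. Missing or non-finite values are rejected
#' outright — impute before import if needed.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param y Vector of class labels, one per row of `X`; coerced to character.
#' @param feature_ids Character vector of unique feature identifiers;
#'   defaults to `colnames(X)` or `f1..fp`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `rownames(X)` or `s1..sn`.
#'
#' @return An object of class `rknn_dataset`: a list with elements `X`
#'   (matrix with ids as dimnames), `y` (factor, canonically ordered
#'   levels), `feature_ids`, `sample_ids`.
#' @examples
#' d <- rknn_dataset(matrix(rnorm(20), 4, 5), c("a", "a", "b", "b"))
#' d
#' @export
rknn_dataset <- function(X, y, feature_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (p < 1) stop("dataset must have at least one feature", call. = FALSE)
  if (length(y) != n)
    stop("length of `y` (", length(y), ") does not match nrow(X) (", n, ")",
         call. = FALSE)
  bad <- which(!is.finite(X))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(X))
    stop("X contains ", length(bad), " missing/non-finite value(s); first at ",
         "row ", rc[1], ", column ", rc[2],
         " — missing values are rejected, not imputed", call. = FALSE)
  }
  y <- as.character(y)
  if (anyNA(y) || any(!nzchar(y)))
    stop("labels must be non-missing, non-empty strings", call. = FALSE)
  levs <- sort(unique(y))
  if (length(levs) < 2)
    stop("at least 2 distinct classes are required, found ", length(levs),
         call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- colnames(X)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != p || anyDuplicated(feature_ids))
    stop("`feature_ids` must be ", p, " unique strings", call. = FALSE)
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("`sample_ids` must be ", n, " unique strings", call. = FALSE)
  dimnames(X) <- list(sample_ids, feature_ids)
  structure(
    list(X = X, y = factor(y, levels = levs),
         feature_ids = feature_ids, sample_ids = sample_ids),
    class = "rknn_dataset"
  )
}

#' @export
print.rknn_dataset <- function(x, ...) {
  tab <- table(x$y)
  cat("rknn_dataset: ", nrow(x$X), " samples x ", ncol(x$X), " features, ",
      nlevels(x$y), " classes\n", sep = "")
  cat("  class sizes:",
      paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.rknn_dataset <- function(x) dim(x$X)

#' Restrict a dataset to a subset of features or samples
#'
#' @param dataset An [rknn_dataset].
#' @param features Character vector of feature ids, or integer column
#'   positions; `NULL` keeps all. Original column order is preserved.
#' @param samples Character vector of sample ids, or integer row positions;
#'   `NULL` keeps all.
#' @return A validated `rknn_dataset`.
#' @export
subset_dataset <- function(dataset, features = NULL, samples = NULL) {
  stopifnot(inherits(dataset, "rknn_dataset"))
  fi <- seq_along(dataset$feature_ids)
  if (!is.null(features)) {
    fi <- if (is.character(features)) {
      match(features, dataset$feature_ids)
    } else as.integer(features)
    if (anyNA(fi) || any(fi < 1 | fi > ncol(dataset$X)))
      stop("unknown feature(s) requested", call. = FALSE)
    fi <- sort(unique(fi))
  }
  si <- seq_along(dataset$sample_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, dataset$sample_ids)
    } else as.integer(samples)
    if (anyNA(si) || any(si < 1 | si > nrow(dataset$X)))
      stop("unknown sample(s) requested", call. = FALSE)
  }
  rknn_dataset(dataset$X[si, fi, drop = FALSE],
               as.character(dataset$y)[si],
               feature_ids = dataset$feature_ids[fi],
               sample_ids = dataset$sample_ids[si])
}

#' Z-score features of a dataset
#'
#' Optional per-feature standardisation (mean 0, sd 1). KNN distances are
#' scale-sensitive, so whether to standardise is left as an explicit user
#' choice; nothing in the package scales silently. Constant features are
#' mapped to 0 with a warning.
#'
#' @param dataset An [rknn_dataset].
#' @return A standardised `rknn_dataset`.
#' @export
zscore_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "rknn_dataset"))
  X <- dataset$X
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " constant feature(s) set to 0 by z-scoring")
    sdv[zero] <- 1
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  rknn_dataset(Xs, as.character(dataset$y),
               feature_ids = dataset$feature_ids,
               sample_ids = dataset$sample_ids)
}

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a labelled expression table from delimited text
#'
#' Expects a header row, samples in rows and features in columns, with one
#' column holding the class label. A column named `sample_id` (or the one
#' named by `id_column`) supplies sample identifiers; otherwise `s1..sn` are
#' generated. Labels are taken verbatim as strings. Gzip-compressed files
#' are detected by the `.gz` extension.
#'
#' @param path Path to a CSV/TSV file (optionally `.gz`).
#' @param label_column Name of the label column (default `"class"`).
#' @param delimiter Field delimiter; `NULL` sniffs `","` vs tab from the
#'   extension (`.csv*` means comma, anything else tab).
#' @param id_column Name of the sample-id column, or `NULL` to use
#'   `"sample_id"` when present.
#' @return An [rknn_dataset].
#' @seealso [write_dataset()] for the inverse.
#' @export
read_dataset <- function(path, label_column = "class", delimiter = NULL,
                         id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- open_text(path, "rt")
  on.exit(close(con), add = TRUE)
  df <- utils::read.delim(con, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in header of ", path,
         call. = FALSE)
  if (is.null(id_column) && "sample_id" %in% names(df)) id_column <- "sample_id"
  if (!is.null(id_column) && !id_column %in% names(df))
    stop("sample-id column '", id_column, "' not found in header of ", path,
         call. = FALSE)
  y <- as.character(df[[label_column]])
  sample_ids <- if (!is.null(id_column)) as.character(df[[id_column]]) else NULL
  feat <- setdiff(names(df), c(label_column, id_column))
  if (length(feat) == 0)
    stop("no feature columns left after removing label/id columns",
         call. = FALSE)
  Xdf <- df[feat]
  for (j in seq_along(Xdf)) {
    v <- Xdf[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) | v == "")
      if (length(bad))
        stop("non-numeric or missing value in column '", feat[j],
             "', data row ", bad[1], " of ", path, call. = FALSE)
      Xdf[[j]] <- vn
    } else if (anyNA(v)) {
      stop("missing value in column '", feat[j], "', data row ",
           which(is.na(v))[1], " of ", path, call. = FALSE)
    }
  }
  X <- as.matrix(Xdf)
  rknn_dataset(X, y, feature_ids = feat, sample_ids = sample_ids)
}

#' Write a dataset as delimited text
#'
#' Emits a header of `sample_id`, the feature ids, and the label column,
#' then one row per sample. Numeric values are printed with 17 significant
#' digits so that [read_dataset()] inverts the write exactly.
#'
#' @param dataset An [rknn_dataset].
#' @param path Destination path; a `.gz` extension gzip-compresses.
#' @param delimiter Field delimiter; `NULL` sniffs from the extension as in
#'   [read_dataset()].
#' @param label_column Header name for the label column.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, delimiter = NULL,
                          label_column = "class") {
  stopifnot(inherits(dataset, "rknn_dataset"))
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  if (label_column %in% dataset$feature_ids)
    stop("label column name '", label_column, "' collides with a feature id",
         call. = FALSE)
  num <- vapply(seq_len(ncol(dataset$X)),
                function(j) sprintf("%.17g", dataset$X[, j]),
                character(nrow(dataset$X)))
  if (nrow(dataset$X) == 1) num <- matrix(num, nrow = 1)
  out <- cbind(sample_id = dataset$sample_ids, num,
               stats::setNames(list(as.character(dataset$y)), label_column)[[1]])
  colnames(out) <- c("sample_id", dataset$feature_ids, label_column)
  con <- open_text(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.table(out, con, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
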