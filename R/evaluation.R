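#' External leave-one-out cross-validation of RKNN-FS
#'
#' For each sample in turn, the *entire* selection pipeline ([rknn_fs()]) is
#' rerun from scratch on the remaining `n - 1` samples, and the resulting
#' model predicts the held-out sample. Because feature selection is redone
#' inside every fold, the accuracy estimate carries no selection bias — the
#' held-out sample never influences support computation or elimination in
#' its own fold. Per-fold seeds are derived deterministically from the
#' master seed, so folds are independent yet fully reproducible.
#'
#' A fold whose removal leaves a class empty is flagged and skipped with a
#' warning; accuracy is then computed over the evaluated folds.
#'
#' @param dataset An [rknn_dataset] with at least 3 samples.
#' @param params An [rknn_params]; `params$seed` is the master seed.
#' @param stage1_only Passed to [rknn_fs()].
#' @param fold_callback Optional `function(fold, fold_dataset, fit)` called
#'   after each fold with the training data the fold actually used and its
#'   `rknn_fs` result — an instrumentation hook for auditing fold hygiene.
#' @return An object of class `rknn_eval`: list with `folds` (data frame:
#'   `fold`, `sample_id`, `truth`, `predicted`, `correct`, `n_selected`,
#'   `evaluated`), `loocv_accuracy`, `set_size_mean`, `set_size_sd`,
#'   `n_evaluated`.
#' @export
loocv_external <- function(dataset, params = rknn_params(),
                           stage1_only = FALSE, fold_callback = NULL) {
  stopifnot(inherits(dataset, "rknn_dataset"), inherits(params, "rknn_params"))
  n <- nrow(dataset$X)
  if (n < 3) stop("external LOOCV needs at least 3 samples", call. = FALSE)
  master <- if (is.null(params$seed)) {
    sample.int(.Machine$integer.max, 1)
  } else params$seed
  folds <- data.frame(fold = seq_len(n), sample_id = dataset$sample_ids,
                      truth = as.character(dataset$y),
                      predicted = NA_character_, correct = NA,
                      n_selected = NA_integer_, evaluated = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    if (length(unique(dataset$y[keep])) < nlevels(dataset$y)) {
      warning("fold ", i, " (sample ", dataset$sample_ids[i],
              ") would remove the last case of class ",
              as.character(dataset$y[i]), "; fold skipped")
      next
    }
    fold_params <- params
    fold_params$seed <- derive_seed(master, i)
    fold_data <- subset_dataset(dataset, samples = keep)
    fit <- rknn_fs(fold_data, fold_params, stage1_only = stage1_only)
    sel <- match(fit$selected, dataset$feature_ids)
    pred <- predict(fit$model,
                    dataset$X[i, sel, drop = FALSE])
    folds$predicted[i] <- pred
    folds$correct[i] <- pred == folds$truth[i]
    folds$n_selected[i] <- length(fit$selected)
    folds$evaluated[i] <- TRUE
    if (!is.null(fold_callback)) fold_callback(i, fold_data, fit)
  }
  ev <- folds$evaluated
  structure(
    list(folds = folds,
         loocv_accuracy = mean(folds$correct[ev]),
         set_size_mean = mean(folds$n_selected[ev]),
         set_size_sd = if (sum(ev) > 1) stats::sd(folds$n_selected[ev]) else 0,
         n_evaluated = sum(ev), seed = master),
    class = "rknn_eval"
  )
}

#' @export
print.rknn_eval <- function(x, ...) {
  cat("External LOOCV over", x$n_evaluated, "folds\n")
  cat("  accuracy:", format(x$loocv_accuracy, digits = 4), "\n")
  cat("  selected-set size:", format(x$set_size_mean, digits = 4),
      "+/-", format(x$set_size_sd, digits = 4), "\n")
  invisible(x)
}

#' Stability summary over repeated evaluations
#'
#' Summarises repeated [loocv_external()] runs (e.g. over different master
#' seeds) by the mean, standard deviation and coefficient of variation
#' (x100) of the accuracy, and the mean and standard deviation of the
#' selected-set sizes pooled over all evaluated folds — the usual stability
#' columns for feature-selection benchmarks. Standard deviations are sample
#' (n - 1) standard deviations; a single result yields sd 0 with a note.
#'
#' @param results List of `rknn_eval` objects.
#' @return List with `n_runs`, `acc_mean`, `acc_sd`, `acc_cv`,
#'   `set_size_mean`, `set_size_sd`, and `note` when degenerate.
#' @export
stability_summary <- function(results) {
  if (inherits(results, "rknn_eval")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "rknn_eval")))
  accs <- vapply(results, function(r) r$loocv_accuracy, numeric(1))
  sizes <- unlist(lapply(results, function(r)
    r$folds$n_selected[r$folds$evaluated]))
  note <- NULL
  if (length(results) == 1) {
    acc_sd <- 0
    note <- "single run: accuracy sd degenerate, reported as 0"
  } else {
    acc_sd <- stats::sd(accs)
  }
  list(n_runs = length(results),
       acc_mean = mean(accs), acc_sd = acc_sd,
       acc_cv = 100 * acc_sd / mean(accs),
       set_size_mean = mean(sizes),
       set_size_sd = if (length(sizes) > 1) stats::sd(sizes) else 0,
       note = note)
}

#' Write per-fold LOOCV results as TSV
#'
#' @param eval An `rknn_eval` object.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_eval <- function(eval, path) {
  stopifnot(inherits(eval, "rknn_eval"))
  utils::write.table(eval$folds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
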