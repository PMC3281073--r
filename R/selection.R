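#' Geometric-stage elimination schedule
#'
#' Closed-form schedule of retained feature counts for the geometric stage:
#' at most `floor(log(min_dim / p) / log(1 - q))` iterations, with iteration
#' 1 on all `p` features and each later iteration retaining
#' `ceiling(p_prev * (1 - q))` of them. The schedule stops early if a step
#' would fall below `min_dim` or fail to drop any feature (possible at
#' small `p` where `q * p < 1`).
#'
#' @param p Starting feature count.
#' @param q Proportion dropped per iteration, in (0, 1).
#' @param min_dim Floor on the retained count.
#' @return Integer vector of feature counts, one per iteration
#'   (first element is `p`).
#' @export
geometric_schedule <- function(p, q, min_dim = 4) {
  p <- as.integer(p)
  if (!(q > 0 && q < 1)) stop("`q` must lie in (0, 1)", call. = FALSE)
  ni <- max(1L, as.integer(floor(log(min_dim / p) / log(1 - q))))
  counts <- p
  while (length(counts) < ni) {
    nxt <- as.integer(ceiling(counts[length(counts)] * (1 - q)))
    if (nxt < min_dim || nxt >= counts[length(counts)]) break
    counts <- c(counts, nxt)
  }
  counts
}

#' Linear-stage elimination schedule
#'
#' `floor((p_start - min_dim) / d)` elimination steps of `d` features each,
#' preceded by an evaluation of the full start set.
#'
#' @param p_start Starting feature count.
#' @param d Features dropped per step.
#' @param min_dim Floor on the retained count.
#' @return Integer vector of feature counts, one per iteration.
#' @export
linear_schedule <- function(p_start, d, min_dim = 4) {
  p_start <- as.integer(p_start)
  steps <- max(0L, as.integer(floor((p_start - min_dim) / d)))
  as.integer(p_start - d * (0:steps))
}

new_trace <- function(stage, iterations, chosen_index) {
  structure(list(stage = stage, iterations = iterations,
                 chosen_index = chosen_index),
            class = "rknn_trace")
}

trace_acc <- function(trace) {
  vapply(trace$iterations, function(it) it$mean_accuracy, numeric(1))
}

trace_counts <- function(trace) {
  vapply(trace$iterations, function(it) it$n_features, integer(1))
}

#' @export
print.rknn_trace <- function(x, ...) {
  cat("RKNN-FS ", x$stage, " stage: ", length(x$iterations),
      " iteration(s)\n", sep = "")
  df <- data.frame(iteration = seq_along(x$iterations),
                   n_features = trace_counts(x),
                   mean_accuracy = round(trace_acc(x), 4))
  df$chosen <- ifelse(df$iteration == x$chosen_index, "*", "")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

# One elimination iteration: supports on the given feature subset.
eval_feature_set <- function(dataset, features, params) {
  sub <- subset_dataset(dataset, features = features)
  sup <- compute_supports(sub, params)
  list(feature_ids = sub$feature_ids, n_features = ncol(sub$X),
       supports = sup, mean_accuracy = attr(sup, "mean_acc"))
}

# Earliest argmax: ties keep the larger (earlier) feature set.
argmax_first <- function(acc) which.max(acc)

# The iteration just before the accuracy maximum seeds stage two; when the
# maximum is already the first iteration there is nothing before it, so it
# clamps to 1.
pre_max_index <- function(acc) max(1L, argmax_first(acc) - 1L)

#' Geometric (stage-one) backward elimination
#'
#' Iteration 1 computes feature supports on the full feature set; each later
#' iteration keeps the top `ceiling(p_prev * (1 - q))` features of the
#' previous ranking and recomputes supports on them (see
#' [geometric_schedule()] for the iteration count). The ensemble mean
#' accuracy of each iteration is recorded, and the chosen iteration is the
#' *pre-max*: the one just before the accuracy maximum (clamped to the
#' first iteration). Under the default square-root rule, `m` is recomputed
#' from the current feature count at every iteration.
#'
#' @param dataset An [rknn_dataset].
#' @param params An [rknn_params].
#' @return An `rknn_trace` with `stage = "geometric"`, one record per
#'   iteration (`feature_ids`, `n_features`, `supports`, `mean_accuracy`)
#'   and `chosen_index` set to the pre-max iteration.
#' @export
geometric_stage <- function(dataset, params = rknn_params()) {
  stopifnot(inherits(dataset, "rknn_dataset"), inherits(params, "rknn_params"))
  maybe_set_seed(params)
  inner <- params; inner$seed <- NULL
  p <- ncol(dataset$X)
  counts <- geometric_schedule(p, params$q, params$min_dim)
  iterations <- vector("list", length(counts))
  feats <- dataset$feature_ids
  for (i in seq_along(counts)) {
    if (i > 1) {
      ranked <- rank_features(iterations[[i - 1]]$supports)
      feats <- ranked$feature_id[seq_len(counts[i])]
    }
    iterations[[i]] <- eval_feature_set(dataset, feats, inner)
  }
  acc <- vapply(iterations, function(it) it$mean_accuracy, numeric(1))
  new_trace("geometric", iterations, pre_max_index(acc))
}

#' Linear (stage-two) backward elimination
#'
#' Starting from the feature set chosen by the geometric stage, iteration 1
#' re-evaluates the start set, then each later iteration drops the `d`
#' lowest-ranked features and re-evaluates, for
#' `floor((p_start - min_dim) / d)` elimination steps. The chosen iteration
#' is the accuracy argmax (earliest on ties — the conservative, larger set).
#'
#' @param dataset An [rknn_dataset].
#' @param start_features Character vector of feature ids to start from.
#' @param params An [rknn_params].
#' @return An `rknn_trace` with `stage = "linear"`.
#' @export
linear_stage <- function(dataset, start_features, params = rknn_params()) {
  stopifnot(inherits(dataset, "rknn_dataset"), inherits(params, "rknn_params"))
  maybe_set_seed(params)
  inner <- params; inner$seed <- NULL
  counts <- linear_schedule(length(start_features), params$d, params$min_dim)
  iterations <- vector("list", length(counts))
  feats <- start_features
  for (i in seq_along(counts)) {
    if (i > 1) {
      ranked <- rank_features(iterations[[i - 1]]$supports)
      feats <- ranked$feature_id[seq_len(counts[i])]
    }
    iterations[[i]] <- eval_feature_set(dataset, feats, inner)
  }
  acc <- vapply(iterations, function(it) it$mean_accuracy, numeric(1))
  new_trace("linear", iterations, argmax_first(acc))
}

#' RKNN-FS: two-stage backward feature elimination
#'
#' Runs [geometric_stage()] (fast multiplicative shrinking of the feature
#' set), hands the pre-max feature set to [linear_stage()] (one-at-a-time
#' fine tuning by default), and returns the feature set with maximal
#' ensemble mean accuracy together with a final Random KNN model refit on
#' it. The whole procedure is deterministic given `params$seed`.
#'
#' @param dataset An [rknn_dataset].
#' @param params An [rknn_params].
#' @param stage1_only If `TRUE`, skip the linear stage and select the
#'   geometric pre-max set directly (the faster protocol commonly used for
#'   benchmarking).
#' @return An object of class `rknn_fs`: list with `selected` (feature
#'   ids), `model` (an [rknn()] fit on the selected features), `geometric`
#'   and `linear` traces, and `params`.
#' @examples
#' sim <- synthetic_dataset(n = 40, p = 60, n_informative = 5, seed = 3)
#' fit <- rknn_fs(sim$dataset, rknn_params(r = 100, seed = 3))
#' fit$selected
#' @export
rknn_fs <- function(dataset, params = rknn_params(), stage1_only = FALSE) {
  stopifnot(inherits(dataset, "rknn_dataset"), inherits(params, "rknn_params"))
  maybe_set_seed(params)
  inner <- params; inner$seed <- NULL
  p <- ncol(dataset$X)
  if (p <= params$min_dim) {
    model <- rknn(dataset, inner)
    return(structure(list(selected = dataset$feature_ids, model = model,
                          geometric = NULL, linear = NULL, params = params,
                          note = "p <= min_dim; no elimination possible"),
                     class = "rknn_fs"))
  }
  geo <- geometric_stage(dataset, inner)
  start <- geo$iterations[[geo$chosen_index]]$feature_ids
  lin <- NULL
  selected <- start
  if (!stage1_only && length(start) > params$min_dim) {
    lin <- linear_stage(dataset, start, inner)
    selected <- lin$iterations[[lin$chosen_index]]$feature_ids
  }
  final_data <- subset_dataset(dataset, features = selected)
  model <- rknn(final_data, inner)
  structure(list(selected = final_data$feature_ids, model = model,
                 geometric = geo, linear = lin, params = params),
            class = "rknn_fs")
}

#' @export
print.rknn_fs <- function(x, ...) {
  cat("RKNN-FS selection:", length(x$selected), "features selected\n")
  if (!is.null(x$geometric))
    cat("  geometric stage:", length(x$geometric$iterations),
        "iterations, pre-max at", x$geometric$chosen_index, "\n")
  if (!is.null(x$linear))
    cat("  linear stage:", length(x$linear$iterations),
        "iterations, best at", x$linear$chosen_index, "\n")
  cat("  selected:", paste(utils::head(x$selected, 10), collapse = ", "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

#' Write selection traces as TSV
#'
#' One row per iteration with columns `stage`, `iteration`, `n_features`,
#' `mean_accuracy`, `chosen`, `feature_ids` (semicolon-joined).
#'
#' @param fs An `rknn_fs` result (or a single `rknn_trace`).
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(fs, path) {
  traces <- if (inherits(fs, "rknn_trace")) list(fs)
            else Filter(Negate(is.null), list(fs$geometric, fs$linear))
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(stage = tr$stage,
               iteration = seq_along(tr$iterations),
               n_features = trace_counts(tr),
               mean_accuracy = sprintf("%.17g", trace_acc(tr)),
               chosen = as.integer(seq_along(tr$iterations) ==
                                     tr$chosen_index),
               feature_ids = vapply(tr$iterations, function(it)
                 paste(it$feature_ids, collapse = ";"), character(1)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the selected feature list
#'
#' Plain text, one feature id per line.
#'
#' @param fs An `rknn_fs` result.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_selected <- function(fs, path) {
  writeLines(fs$selected, path)
  invisible(path)
}
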