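#' Write a reproducibility metadata record
#'
#' JSON record describing a run: parameters, seed, package version, input
#' file checksum (when given), timestamp and any extra fields. Every CLI
#' run drops one of these next to its outputs so the run can be reproduced
#' exactly.
#'
#' @param path Destination `.json` path.
#' @param params An [rknn_params].
#' @param input Optional input file path; its MD5 checksum is recorded.
#' @param extra Named list of additional fields to record.
#' @return Invisibly, `path`.
#' @export
write_run_metadata <- function(path, params, input = NULL, extra = list()) {
  stopifnot(inherits(params, "rknn_params"))
  meta <- list(
    package = "rknnfs",
    version = as.character(utils::packageVersion("rknnfs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = list(k = params$k, r = params$r,
                  m = if (is.null(params$m)) "sqrt" else params$m,
                  q = params$q, d = params$d,
                  partition_mode = params$partition_mode,
                  min_dim = params$min_dim,
                  seed = if (is.null(params$seed)) NA else params$seed)
  )
  if (!is.null(input)) {
    meta$input <- list(path = input,
                       md5 = unname(tools::md5sum(input)))
  }
  meta <- c(meta, extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
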