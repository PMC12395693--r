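#' Write a results table to TSV
#'
#' Tables are plain data frames, one row per (object, metric) with a `units`
#' column for physical quantities. Numerics are written with 17 significant
#' digits so that [read_results()] round-trips values to better than 1e-9
#' relative.
#'
#' @param table a data.frame.
#' @param path output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a run configuration from YAML
#'
#' @param path YAML file holding channel maps, thresholds and module
#'   parameters (see [run_scene_analysis()] for the recognised keys).
#' @return named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config: %s", path))
  yaml::read_yaml(path)
}

# package-local logging state
.plq_env <- new.env(parent = emptyenv())

#' Direct package log messages to a file as well as stderr
#' @param path log file path, or NULL to log to stderr only.
#' @return previous path, invisibly.
#' @export
plq_log_file <- function(path = NULL) {
  old <- .plq_env$log_file
  .plq_env$log_file <- path
  invisible(old)
}

#' Log a message to stderr (and the optional log file)
#' @param fmt sprintf format.
#' @param ... format arguments.
#' @keywords internal
#' @export
plq_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  line <- sprintf("[plaquescope %s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(.plq_env$log_file))
    cat(line, "\n", file = .plq_env$log_file, append = TRUE, sep = "")
  invisible(msg)
}
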