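# Plain-text I/O: events and traces as CSV, ground truth and reports as JSON.

#' Write / read an event log as CSV
#'
#' Columns: \code{time_s}, \code{kind}, \code{solution}, \code{volume_ul}.
#'
#' @param events an \code{\link{event_log}}.
#' @param path CSV file path.
#' @return \code{write_event_log} returns \code{path} invisibly;
#'   \code{read_event_log} returns an \code{\link{event_log}}.
#' @export
write_event_log <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_log(df$time_s, df$kind, df$solution, df$volume_ul)
}

#' Write / read a trace matrix as long-format CSV
#'
#' Columns: \code{neuron_id}, \code{time_s}, \code{value}. The sample rate is
#' recovered on read from the time grid.
#'
#' @param traces a \code{\link{trace_matrix}}.
#' @param path CSV file path.
#' @return \code{write_trace_csv} returns \code{path} invisibly;
#'   \code{read_trace_csv} returns a \code{\link{trace_matrix}}.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_matrix"))
  n_samp <- ncol(traces$values)
  df <- data.frame(
    neuron_id = rep(traces$neuron_ids, each = n_samp),
    time_s = rep((seq_len(n_samp) - 1) / traces$sample_rate,
                 times = length(traces$neuron_ids)),
    value = as.vector(t(traces$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$neuron_id)
  t_s <- sort(unique(df$time_s))
  fs <- 1 / median(diff(t_s))
  values <- t(vapply(ids, function(id) {
    sub <- df[df$neuron_id == id, ]
    sub$value[order(sub$time_s)]
  }, numeric(length(t_s))))
  trace_matrix(values, fs, ids)
}

#' Write ground truth (or any report list) as a JSON sidecar
#'
#' @param x a \code{ground_truth} data.frame or report list.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", force = TRUE)
  invisible(path)
}
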