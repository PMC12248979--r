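gaze_columns <- c("time_ms", "lx_deg", "ly_deg", "rx_deg", "ry_deg",
                  "valid_l", "valid_r")

#' Write a gaze trace as tab-separated text
#'
#' @param trace A \code{"gaze_trace"}.
#' @param path Output file.
#' @export
write_gaze_tsv <- function(trace, path) {
  utils::write.table(as.data.frame(trace)[gaze_columns], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gaze trace from tab-separated text
#'
#' Validates the column contract, checks that timestamps are uniform and
#' increasing, infers the sampling rate, and marks blink samples invalid.
#'
#' @param path Input file (columns \code{time_ms}, \code{lx_deg},
#'   \code{ly_deg}, \code{rx_deg}, \code{ry_deg}, \code{valid_l},
#'   \code{valid_r}).
#' @return A \code{"gaze_trace"}.
#' @export
read_gaze_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  missing <- setdiff(gaze_columns, names(df))
  if (length(missing) > 0)
    stop("gaze file missing columns: ", paste(missing, collapse = ", "))
  df <- df[gaze_columns]
  d <- diff(df$time_ms)
  if (any(d <= 0)) stop("timestamps not strictly increasing")
  if (max(d) - min(d) > 1e-6 * stats::median(d) + 1e-9)
    stop("non-uniform sampling interval")
  attr(df, "sampling_rate") <- 1000 / stats::median(d)
  df$valid_l <- as.integer(df$valid_l)
  df$valid_r <- as.integer(df$valid_r)
  class(df) <- c("gaze_trace", "data.frame")
  df
}

#' Write / read detected events
#'
#' @param events Event table (with identifier columns).
#' @param path CSV file.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the per-trial metrics table
#'
#' @param metrics Metrics table from \code{\link{summarize_trials}}.
#' @param path CSV file.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a structured (YAML) configuration file
#'
#' Keys must match \code{\link{sim_config}} field names; unknown keys are
#' rejected to catch typos early.
#'
#' @param path YAML file.
#' @return A \code{"sim_config"}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Write a configuration as YAML
#'
#' @param cfg A \code{"sim_config"}.
#' @param path Output file.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
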