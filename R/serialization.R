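#' Write a spike raster to CSV
#'
#' Two columns `time_ms,neuron_id`, time-sorted, with a header line.
#'
#' @param raster a [spike_raster].
#' @param path output file.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  df <- data.frame(time_ms = raster$events$time_ms,
                   neuron_id = raster$events$neuron)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike raster from CSV
#'
#' @param path CSV written by [write_raster()].
#' @param n_exc,n_inh population sizes.
#' @param t_start_ms,t_end_ms raster span; inferred from the data when
#'   omitted.
#' @return A [spike_raster].
#' @export
read_raster <- function(path, n_exc, n_inh = 0, t_start_ms = NULL,
                        t_end_ms = NULL) {
  df <- read.csv(path)
  spike_raster(df$time_ms, df$neuron_id,
               t_start_ms %||% if (nrow(df)) min(df$time_ms) else 0,
               t_end_ms %||% if (nrow(df)) max(df$time_ms) else 0,
               n_exc = n_exc, n_inh = n_inh)
}

#' Write a weight matrix to CSV with a JSON sidecar
#'
#' Dense CSV without header, one row per postsynaptic neuron; the sidecar
#' (`<path>.json`) records the orientation convention and the weight
#' bound.
#'
#' @param weights a [weight_matrix].
#' @param path output CSV file.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_matrix"))
  utils::write.table(unclass(weights), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(orientation = "entry (i, j) = weight of synapse from neuron j onto neuron i; row = postsynaptic index",
               w_max = attr(weights, "w_max"), n = nrow(weights))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a weight matrix written by [write_weights()]
#'
#' @param path CSV file; the `<path>.json` sidecar supplies `w_max`.
#' @return A [weight_matrix].
#' @export
read_weights <- function(path) {
  W <- as.matrix(read.csv(path, header = FALSE))
  dimnames(W) <- NULL
  side <- paste0(path, ".json")
  w_max <- if (file.exists(side)) jsonlite::fromJSON(side)$w_max else max(W)
  weight_matrix(W, w_max)
}

#' Serialize a loop or hub report to JSON
#'
#' All raw counts and degrees are retained.
#'
#' @param report a `loop_report` or `hub_report`.
#' @param path optional output file.
#' @return JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- if (inherits(report, "loop_report")) {
    list(kind = "loop_report", theta = report$theta,
         n_shuffles = report$n_shuffles, seed = report$seed,
         census = report$census, recurrence_index = report$recurrence_index)
  } else if (inherits(report, "hub_report")) {
    list(kind = "hub_report", theta = report$theta,
         slope = report$slope, intercept = report$intercept,
         slope_defined = report$slope_defined, degrees = report$degrees)
  } else stop("unsupported report type")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
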