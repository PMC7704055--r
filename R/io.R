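# Tabular and trace I/O with fixed schemas, plus run manifests.

table_schemas <- list(
  trace = c("time_ms", "current_pA", "n_Ga", "n_GaPLC", "n_DAG", "n_open"),
  features = c("amplitude", "latency10", "t_peak", "half_width",
               "rise_20_80", "decay_80_20", "rise_slope"),
  sweep = c("parameter", "value", "n_trials", "n_bumps", "median_latency",
            "latency_scatter", "mean_amplitude", "amplitude_sd",
            "mean_half_width", "half_width_sd", "flagged"),
  freqresp = c("frequency_hz", "signal"),
  surface = c("half_width", "latency_sd", "snr", "f3dB", "ic")
)

#' Write / read a schema-checked CSV table
#'
#' CSV with header, fixed column order per schema, C-locale decimal
#' points, and floats at 17 significant digits so a write-read round
#' trip is lossless.
#'
#' @param table data.frame to write.
#' @param path file path.
#' @param schema one of `names(microbump:::table_schemas)`, or `NULL` to
#'   skip the check.
#' @return `write_table()` returns `path` invisibly; `read_table()`
#'   returns the data.frame.
#' @export
write_table <- function(table, path, schema = NULL) {
  stopifnot(is.data.frame(table))
  check_schema(table, schema)
  fmt <- as.data.frame(lapply(table, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(tab, schema)
  tab
}

check_schema <- function(table, schema) {
  if (is.null(schema)) return(invisible(TRUE))
  if (!schema %in% names(table_schemas))
    stop("unknown table schema: ", schema)
  miss <- setdiff(table_schemas[[schema]], names(table))
  if (length(miss))
    stop("table does not match schema '", schema, "': missing column(s) ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Export a bump trace as CSV
#'
#' Columns: `time_ms`, `current_pA`, `n_Ga`, `n_GaPLC`, `n_DAG`,
#' `n_open`.
#'
#' @param trace a `bump_trace`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "bump_trace"))
  write_table(as.data.frame(trace), path, schema = "trace")
}

#' JSON round-trip for latency fits
#'
#' @param fit a `latency_fit` ([fit_latency_lognormal()]).
#' @param path JSON file path.
#' @return `read_latency_fit()` returns a `latency_fit`.
#' @export
write_latency_fit <- function(fit, path) {
  stopifnot(inherits(fit, "latency_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_latency_fit
#' @export
read_latency_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("mu", "sigma", "scatter", "sample_sd", "n", "method")],
            class = "latency_fit")
}

write_manifest <- function(out_dir, command, config, files, started) {
  manifest <- list(
    package = "microbump",
    version = as.character(utils::packageVersion("microbump")),
    command = command,
    seed = config$seed,
    config = config,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    elapsed_s = round(as.numeric(Sys.time() - started, units = "secs"), 2),
    timestamp = format(started, "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}
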