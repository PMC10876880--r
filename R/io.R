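#' Read and write the package's file formats
#'
#' Plain-text interchange: TGA traces and composition tables as CSV, DTG
#' matrices as CSV with the temperature in the first column, interval sets
#' and metadata as JSON, synthetic specs and pipeline configs as YAML.
#'
#' @param trace,table,X,intervals object to write.
#' @param path file path.
#' @param sample_id sample identifier attached on read.
#' @name pyrocal_io
NULL

#' @rdname pyrocal_io
#' @export
write_tga_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_min", "temperature_C", "mass_mg")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyrocal_io
#' @export
read_tga_csv <- function(path, sample_id = basename(path)) {
  df <- utils::read.csv(path)
  req <- c("time_min", "temperature_C", "mass_mg")
  if (!all(req %in% names(df)))
    stop("TGA CSV needs columns ", paste(req, collapse = ", "))
  structure(df[, req], sample_id = sample_id,
            class = c("tga_trace", "data.frame"))
}

#' @rdname pyrocal_io
#' @export
write_composition_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyrocal_io
#' @export
read_composition_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname pyrocal_io
#' @export
write_dtg_csv <- function(X, path) {
  temps <- attr(X, "temperature") %||% as.numeric(colnames(X))
  df <- data.frame(temperature_C = temps, t(X), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyrocal_io
#' @export
read_dtg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  temps <- df[[1]]
  X <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(X) <- formatC(temps, format = "fg")
  attr(X, "temperature") <- temps
  X
}

#' @rdname pyrocal_io
#' @export
write_intervals_json <- function(intervals, path) {
  jsonlite::write_json(as.data.frame(intervals), path, digits = NA)
  invisible(path)
}

#' @rdname pyrocal_io
#' @export
read_intervals_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(df)) interval_set(numeric(0), numeric(0))
  else interval_set(df$t_lo, df$t_hi)
}
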