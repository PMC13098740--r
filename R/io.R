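#' Read and write FD-NIRS measurement tables
#'
#' CSV dialect with columns `frame, time_s, wavelength_nm, mod_freq_hz,
#' amplitude, phase_rad` (units fixed at the interface: seconds, nm, Hz,
#' radians). Unknown extra columns are kept with a warning; missing
#' required columns or non-numeric entries fail with the offending row
#' named.
#'
#' @param path CSV path.
#' @param df Measurement tibble.
#' @return `read_fd_measurements()` returns a tibble;
#'   `write_fd_measurements()` returns `path` invisibly.
#' @export
read_fd_measurements <- function(path) {
  df <- as_tibble(read.csv(path))
  validate_columns(df, c("frame", "time_s", "wavelength_nm", "mod_freq_hz",
                         "amplitude", "phase_rad"), path)
  bad <- which(df$amplitude < 0)
  if (length(bad))
    abort(sprintf("negative amplitude at row %d of %s", bad[1], path),
          class = "mldos_schema_error")
  df
}

#' @rdname read_fd_measurements
#' @export
write_fd_measurements <- function(df, path) {
  validate_columns(df, c("frame", "time_s", "wavelength_nm", "mod_freq_hz",
                         "amplitude", "phase_rad"), "input")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write DCS autocorrelation tables
#'
#' CSV dialect with columns `frame, time_s, tau_s, g2`. A g2 value below
#' zero is physically impossible for an intensity autocorrelation and
#' fails schema validation with the row named.
#'
#' @inheritParams read_fd_measurements
#' @return `read_dcs_measurements()` returns a tibble;
#'   `write_dcs_measurements()` returns `path` invisibly.
#' @export
read_dcs_measurements <- function(path) {
  df <- as_tibble(read.csv(path))
  validate_columns(df, c("frame", "time_s", "tau_s", "g2"), path)
  bad <- which(df$g2 < 0)
  if (length(bad))
    abort(sprintf("non-physical g2 < 0 at row %d of %s", bad[1], path),
          class = "mldos_schema_error")
  df
}

#' @rdname read_dcs_measurements
#' @export
write_dcs_measurements <- function(df, path) {
  validate_columns(df, c("frame", "time_s", "tau_s", "g2"), "input")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

validate_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "mldos_schema_error")
  extra <- setdiff(names(df), required)
  if (length(extra))
    warn(sprintf("ignoring unknown column(s): %s",
                 paste(extra, collapse = ", ")))
  for (col in required) {
    if (!is.numeric(df[[col]]))
      abort(sprintf("column '%s' must be numeric in %s", col, what),
            class = "mldos_schema_error")
  }
  invisible(df)
}

#' Write fit results with provenance to JSON
#'
#' Serializes a results tibble (e.g. from [fit_timeseries()] or
#' [hemodynamics_from_fits()]) together with the package version, an md5
#' content hash and any supplied options, so that a results file is
#' self-describing and reproducible.
#'
#' @param results A data frame of results.
#' @param path Output `.json` path.
#' @param options Optional named list recorded alongside (seeds, LUT
#'   hashes, model tags).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, options = list()) {
  payload <- list(
    schema = "mldos_results", version = 1L,
    package_version = as.character(utils::packageVersion("mldos")),
    options = options,
    results = results
  )
  payload$content_md5 <- object_md5(payload$results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "mldos_results"))
    abort("not an mldos results file", class = "mldos_schema_error")
  if (!identical(object_md5(as_tibble(p$results)), p$content_md5) &&
      !identical(object_md5(p$results), p$content_md5))
    warn("results content hash mismatch; file may have been edited")
  as_tibble(p$results)
}
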