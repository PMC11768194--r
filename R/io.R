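## Plain-text interchange formats: torque curves and colour readings as
## CSV with fixed headers, configs as JSON or YAML. Floats are written
## with 12 significant digits so curves round-trip well below 1e-9 Nm.

.CURVE_HEADER <- c("time_min", "torque_nm", "temp_c")
.COLOR_HEADER <- c("group", "replicate", "L", "a", "b")

#' Read a torque curve from CSV
#'
#' Expects the header `time_min,torque_nm,temp_c`. Errors are named and
#' carry the offending line number (header = line 1).
#'
#' @param path CSV file.
#' @param water_absorption optional metadata to attach.
#' @return a [new_torque_curve()].
#' @export
read_curve_csv <- function(path, water_absorption = NA_real_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                "crumblab_io_error")
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(tab), .CURVE_HEADER)) {
    abort(sprintf("missing/misnamed columns in %s: expected '%s', found '%s'",
                  path, paste(.CURVE_HEADER, collapse = ","),
                  paste(names(tab), collapse = ",")),
          "crumblab_io_error")
  }
  num <- lapply(tab, function(col) suppressWarnings(as.numeric(col)))
  for (col in .CURVE_HEADER) {
    bad <- which(is.na(num[[col]]) & !tolower(tab[[col]]) %in% c("na", ""))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value in column '%s' at line %d of %s: '%s'",
                    col, bad[1L] + 1L, path, tab[[col]][bad[1L]]),
            "crumblab_io_error")
    }
  }
  if (any(diff(num$time_min) <= 0)) {
    i <- which(diff(num$time_min) <= 0)[1L]
    abort(sprintf("time not increasing at line %d of %s", i + 2L, path),
          "crumblab_io_error")
  }
  new_torque_curve(num$time_min, num$torque_nm, num$temp_c,
                   water_absorption = water_absorption)
}

#' Write a torque curve to CSV
#'
#' @param curve a [new_torque_curve()].
#' @param path destination CSV path (header `time_min,torque_nm,temp_c`).
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "torque_curve"))
  df <- data.frame(time_min = sprintf("%.12g", curve$time),
                   torque_nm = sprintf("%.12g", curve$torque),
                   temp_c = sprintf("%.12g", curve$temperature))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read replicate colour readings from CSV
#'
#' Expects the header `group,replicate,L,a,b`.
#'
#' @param path CSV file.
#' @return data.frame of readings.
#' @export
read_color_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                "crumblab_io_error")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), .COLOR_HEADER)) {
    abort(sprintf("missing/misnamed columns in %s: expected '%s'",
                  path, paste(.COLOR_HEADER, collapse = ",")),
          "crumblab_io_error")
  }
  for (col in c("L", "a", "b")) {
    if (!is.numeric(tab[[col]])) {
      abort(sprintf("non-numeric value in column '%s' of %s", col, path),
            "crumblab_io_error")
    }
  }
  tab
}

#' Write colour readings to CSV
#'
#' @param readings data.frame as returned by [generate_color_readings()].
#' @param path destination CSV path (header `group,replicate,L,a,b`).
#' @return `path`, invisibly.
#' @export
write_color_csv <- function(readings, path) {
  df <- data.frame(group = readings$group, replicate = readings$replicate,
                   L = sprintf("%.12g", readings$L),
                   a = sprintf("%.12g", readings$a),
                   b = sprintf("%.12g", readings$b))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ground-truth region table to CSV
#'
#' @param truth `crumb_ground_truth` from [generate_crumb_image()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(truth, path) {
  write.csv(truth$region_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## config files: format by extension
read_config_file <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path),
                                "crumblab_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be .json or .yaml/.yml", "crumblab_io_error")
  }
}
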