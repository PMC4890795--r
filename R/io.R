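#' Read an observed timecourse from CSV
#'
#' Reads a `time_min,value` CSV (other column names can be mapped). A
#' pre-meal sample at a negative time (the -30-min draw of the standard
#' design), if present as the first row, is remapped to t = 0.
#'
#' @param path CSV file path.
#' @param analyte analyte label for the resulting [timecourse()].
#' @param time_col,value_col column names holding times (min) and values.
#' @return A [timecourse()].
#' @export
read_timecourse <- function(path, analyte = c("acetaminophen", "glucose",
                                              "insulin"),
                            time_col = "time_min", value_col = "value") {
  analyte <- match.arg(analyte)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0) stop("empty timecourse file: ", path)
  missing <- setdiff(c(time_col, value_col), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  tt <- df[[time_col]]
  vv <- df[[value_col]]
  dup <- which(duplicated(tt))
  if (length(dup))
    stop("duplicated time row ", dup[1], " (t = ", tt[dup[1]], " min) in ",
         path)
  if (is.unsorted(tt, strictly = TRUE))
    stop("times must be strictly increasing in ", path)
  if (any(vv < 0)) stop("negative value(s) in ", path)
  # pre-meal draw becomes the basal t = 0 point
  if (tt[1] < 0) tt[1] <- 0
  timecourse(tt, vv, analyte)
}

#' @rdname read_timecourse
#' @param tc a [timecourse()].
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(data.frame(time_min = tc$time_min, value = tc$value),
                   path, row.names = FALSE)
  invisible(path)
}

# flatten a result object into plain lists for serialization
.serialize_result <- function(x) {
  if (inherits(x, "sensitivity_table") || inherits(x, "timecourse") ||
      inherits(x, "gi_trajectory"))
    return(as.data.frame(x))
  if (inherits(x, "z_schedule"))
    return(list(breakpoints = x$breakpoints, values = x$values))
  if (is.list(x)) {
    out <- lapply(unclass(x), .serialize_result)
    out$.class <- class(x)[1]
    return(out)
  }
  x
}

#' Write a result object to JSON or CSV
#'
#' JSON serialization keeps full double precision (values round-trip to
#' 1e-12 or better; integers exactly). CSV is available for tabular
#' results (sensitivity tables, timecourses, trajectories).
#'
#' @param result a package result object (e.g. `ac_fit`, `gi_fit`,
#'   `sensitivity_table`, [timecourse()]).
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(.serialize_result(result), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    df <- .serialize_result(result)
    if (!is.data.frame(df))
      stop("CSV output requires a tabular result; use format = 'json'")
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
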