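#' Read a time series from a delimited text file
#'
#' Reads one column of a CSV/TSV file as a numeric series. The delimiter is
#' sniffed from the first line (comma, tab, or semicolon) unless given, and
#' a header row is auto-detected (a first line that does not parse as
#' numbers is skipped). Any non-numeric or non-finite cell is an error
#' naming the offending row.
#'
#' @param path Path to a delimited text file.
#' @param column Column to read, 1-based (default 1). Two-column files are
#'   conventionally (source, target); read them with `column = 1` and
#'   `column = 2`.
#' @param delim Field delimiter; `NULL` (default) to sniff.
#' @return Numeric vector with attributes `path` and `column` recording
#'   provenance.
#' @export
read_series <- function(path, column = 1L, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  }
  probe <- strsplit(first, delim, fixed = TRUE)[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(probe))))
  df <- utils::read.delim(path, sep = delim, header = header,
                          colClasses = "character", strip.white = TRUE)
  if (column < 1L || column > ncol(df)) {
    stop(sprintf("column %d requested but file has %d column(s)",
                 column, ncol(df)), call. = FALSE)
  }
  raw <- df[[column]]
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) | !is.finite(x))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite value %s at data row %d, column %d of %s",
                 dQuote(raw[bad[1L]]), bad[1L], column, path), call. = FALSE)
  }
  structure(x, path = path, column = as.integer(column))
}

#' Write an analysis result to a versioned JSON document
#'
#' Serializes any of the package's result objects (a `te_result`,
#' `te_surrogate`, `te_scan`, `te_sweep`, detection table, or
#' `prepost_study`) to JSON, together with the method, parameters, seed,
#' and an explicit unit marker (`"bits"`), so that a published run can be
#' reproduced from its output document alone. [read_result()] restores the
#' document.
#'
#' @param result A result object or plain list/data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  doc <- list(
    format = "tentropy-result",
    version = 1L,
    class = class(result)[[1L]],
    unit = "bits",
    payload = strip_result(result)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

strip_result <- function(x) {
  if (is.data.frame(x)) {
    payload <- list(data = as.data.frame(x))
    extra <- attributes(x)
    keep <- setdiff(names(extra), c("names", "row.names", "class"))
    payload$attributes <- extra[keep]
    payload
  } else if (is.list(x)) {
    lapply(unclass(x), function(el) if (is.data.frame(el)) as.data.frame(el) else el)
  } else {
    x
  }
}

#' Read back a result document written by [write_result()]
#'
#' @param path Path to a JSON document produced by [write_result()].
#' @return A list with elements `class`, `unit`, and `payload` (tables
#'   restored as tibbles).
#' @export
read_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "tentropy-result")) {
    stop("not a tentropy result document: ", path, call. = FALSE)
  }
  restore <- function(el) if (is.data.frame(el)) tibble::as_tibble(el) else el
  if (is.list(doc$payload)) doc$payload <- lapply(doc$payload, restore)
  doc[c("class", "unit", "payload")]
}
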