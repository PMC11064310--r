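# Cohort CSV input/output with schema validation.

#' Cohort CSV schema
#'
#' @param required Named character vector mapping required column names to
#'   types (`"integer"`, `"numeric"`, `"character"`, `"logical"`).
#' @param id_column Column that must be unique (default `"id"`).
#' @return A `cohort_schema`.
#' @export
cohort_schema <- function(required = c(id = "integer"), id_column = "id") {
  ok <- c("integer", "numeric", "character", "logical")
  if (!all(required %in% ok))
    stop("unknown column types: ",
         paste(setdiff(required, ok), collapse = ", "), call. = FALSE)
  structure(list(required = required, id_column = id_column),
            class = "cohort_schema")
}

.coerce_column <- function(x, type, name) {
  x[x == ""] <- NA
  if (type == "character") return(x)
  conv <- switch(type,
                 integer = suppressWarnings(as.integer(x)),
                 numeric = suppressWarnings(as.numeric(x)),
                 logical = suppressWarnings(as.logical(x)))
  bad <- which(!is.na(x) & is.na(conv))
  if (length(bad))
    stop("column '", name, "': unparseable ", type, " in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  conv
}

#' Read a cohort CSV
#'
#' UTF-8, comma-separated, header row; empty cells are missing. Required
#' columns are validated against the schema (error names the column and the
#' offending rows); remaining columns are auto-typed.
#'
#' @param path File path.
#' @param schema A [cohort_schema()].
#' @return Typed data.frame.
#' @export
read_cohort_csv <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  absent <- setdiff(names(schema$required), names(raw))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  out <- raw
  for (nm in names(raw)) {
    if (nm %in% names(schema$required)) {
      out[[nm]] <- .coerce_column(raw[[nm]], schema$required[[nm]], nm)
    } else {
      out[[nm]] <- utils::type.convert(raw[[nm]], as.is = TRUE,
                                       na.strings = c("NA", ""))
    }
  }
  idc <- schema$id_column
  if (idc %in% names(out) && anyDuplicated(out[[idc]]))
    stop("duplicate participant id(s): ",
         paste(utils::head(unique(out[[idc]][duplicated(out[[idc]])]), 5),
               collapse = ", "), call. = FALSE)
  out
}

#' Write a cohort CSV
#'
#' Missing values become empty cells; column order is preserved, so a
#' write-then-read round trip reproduces the table.
#'
#' @param cohort Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
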