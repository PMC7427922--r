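#' Variable schema for a mixed-type cohort table
#'
#' A schema declares, for every clinical variable, whether it is numeric or
#' categorical, the ordered factor levels (categorical only) and the units of
#' measurement. All encoding, reporting and simulation functions consult the
#' schema rather than guessing types from the data.
#'
#' @param name character vector of variable names (unique).
#' @param kind character vector, each `"numeric"` or `"categorical"`.
#' @param levels list of character vectors; ordered levels for categorical
#'   variables, `NULL` entries for numeric ones.
#' @param units character vector of measurement units (`""` if unitless).
#' @return A data frame of class `"variable_schema"` with columns
#'   `name`, `kind`, `levels` (list column) and `units`.
#' @examples
#' variable_schema(
#'   name   = c("gfr", "diabetes"),
#'   kind   = c("numeric", "categorical"),
#'   levels = list(NULL, c("yes", "no")),
#'   units  = c("mL/min/1.73m2", "")
#' )
#' @export
variable_schema <- function(name, kind, levels, units = rep("", length(name))) {
  stopifnot(length(name) == length(kind), length(name) == length(levels),
            length(name) == length(units))
  if (anyDuplicated(name)) {
    stop("duplicate variable names in schema: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (!all(kind %in% c("numeric", "categorical"))) {
    stop("kind must be 'numeric' or 'categorical'")
  }
  for (i in seq_along(name)) {
    if (kind[i] == "categorical") {
      lv <- levels[[i]]
      if (is.null(lv) || length(lv) < 2L) {
        stop("categorical variable '", name[i], "' needs >= 2 levels")
      }
      if (anyDuplicated(lv)) {
        stop("categorical variable '", name[i], "' has duplicated levels")
      }
    } else if (!is.null(levels[[i]])) {
      stop("numeric variable '", name[i], "' must not declare levels")
    }
  }
  out <- data.frame(name = as.character(name), kind = as.character(kind),
                    units = as.character(units), stringsAsFactors = FALSE)
  out$levels <- levels
  out <- out[, c("name", "kind", "levels", "units")]
  class(out) <- c("variable_schema", "data.frame")
  out
}

#' @export
print.variable_schema <- function(x, ...) {
  cat("Variable schema:", nrow(x), "variables (",
      sum(x$kind == "numeric"), "numeric,",
      sum(x$kind == "categorical"), "categorical )\n")
  lv <- vapply(x$levels, function(l) {
    if (is.null(l)) "-" else paste(l, collapse = "|")
  }, character(1))
  print(data.frame(name = x$name, kind = x$kind, levels = lv,
                   units = x$units, stringsAsFactors = FALSE), ...)
  invisible(x)
}

schema_lookup <- function(schema, variable) {
  i <- match(variable, schema$name)
  if (is.na(i)) stop("variable '", variable, "' not in schema")
  schema[i, , drop = FALSE]
}

#' Write / read a variable schema as tab-separated text
#'
#' Levels are serialised pipe-separated, preserving order. The same dialect is
#' accepted for user-supplied cohorts.
#'
#' @param schema a [variable_schema()].
#' @param path file path.
#' @return `write_schema` returns `path` invisibly; `read_schema` returns a
#'   `variable_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "variable_schema"))
  out <- data.frame(
    name = schema$name, kind = schema$kind,
    levels = vapply(schema$levels, function(l) {
      if (is.null(l)) "" else paste(l, collapse = "|")
    }, character(1)),
    units = schema$units, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  lv <- lapply(seq_len(nrow(raw)), function(i) {
    if (raw$kind[i] == "numeric" || !nzchar(raw$levels[i])) NULL
    else strsplit(raw$levels[i], "|", fixed = TRUE)[[1]]
  })
  variable_schema(raw$name, raw$kind, lv, raw$units)
}
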