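#' Load an interaction-detection-method conversion table
#'
#' The conversion table maps PSI-MI detection-method codes (`MI:nnnn`) to
#' technique categories so that technically similar methods count once in
#' the method score: for example the classic yeast two-hybrid code and its
#' array/pooling variants all fall into a single "Two Hybrid (2Hyb)"
#' category. The bundled table groups the common detection-method codes at
#' the assay-family level; supply `path` to use a custom table.
#'
#' @param path Two-column tab-separated file (`MI:nnnn` code, category
#'   label); an optional header line is skipped. `NULL` loads the bundled
#'   table.
#' @return A `method_table`: a named character vector mapping code to
#'   category.
#' @details A code mapped to two different categories is a fatal load
#'   error: the table is the single authority for method grouping and must
#'   be unambiguous. Category labels may not contain tabs or semicolons
#'   (both are output delimiters).
#' @export
load_method_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "method_categories.tsv", package = "ppinet")
  }
  if (!file.exists(path)) stop("method table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(structure(stats::setNames(character(0), character(0)),
                     class = "method_table"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate a single header row
  if (!grepl("^MI:[0-9]{4}$", parts[[1]][1])) parts <- parts[-1]
  if (!length(parts)) {
    return(structure(stats::setNames(character(0), character(0)),
                     class = "method_table"))
  }
  if (any(lengths(parts) < 2L)) {
    stop("malformed method-table row(s): ",
         paste(which(lengths(parts) < 2L), collapse = ", "), call. = FALSE)
  }
  code <- vapply(parts, `[[`, character(1), 1L)
  category <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (any(!grepl("^MI:[0-9]{4}$", code))) {
    stop("invalid PSI-MI code(s) in method table: ",
         paste(utils::head(code[!grepl("^MI:[0-9]{4}$", code)], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[;\t]", category))) {
    stop("category labels may not contain ';' or tab characters", call. = FALSE)
  }
  by_code <- split(category, code)
  conflicting <- names(by_code)[vapply(by_code, function(v) length(unique(v)) > 1L, logical(1))]
  if (length(conflicting)) {
    stop("conflicting category assignments for: ",
         paste(conflicting, collapse = ", "), call. = FALSE)
  }
  map <- vapply(by_code, `[[`, character(1), 1L)
  structure(map, class = "method_table")
}

#' Convert detection-method codes to categories
#'
#' Pure reassignment of PSI-MI codes to the categories of a conversion
#' table. Codes absent from the table are handled per filter mode: under
#' lenient filtering the raw code becomes its own singleton category (the
#' evidence is kept but never merges with anything), under stringent
#' filtering the result is `NA`, which marks the carrying evidence unit
#' for discard.
#'
#' @param codes Character vector of `MI:nnnn` codes.
#' @param table A `method_table` from [load_method_table()].
#' @param filter_mode `"lenient"` or `"stringent"`.
#' @return Character vector of category labels, `NA` for codes dropped
#'   under stringent filtering.
#' @export
convert_method <- function(codes, table, filter_mode = c("lenient", "stringent")) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(inherits(table, "method_table"))
  if (!length(codes)) return(character(0))
  out <- unname(unclass(table)[codes])
  miss <- is.na(out)
  if (any(miss) && filter_mode == "lenient") out[miss] <- codes[miss]
  out
}

#' Category inventory of a method table
#'
#' @param table A `method_table`.
#' @return Sorted unique category labels.
#' @export
method_categories <- function(table) {
  stopifnot(inherits(table, "method_table"))
  radix_sort(unique(unname(unclass(table))))
}

#' Report conversion-table coverage of a code set
#'
#' Utility for auditing a corpus: which detection-method codes seen in the
#' data are covered by the conversion table, and which would fall through
#' to singleton categories (lenient) or discards (stringent).
#'
#' @param codes Character vector of `MI:nnnn` codes (repeats allowed).
#' @param table A `method_table`.
#' @return Data frame with one row per distinct code: `code`, `mapped`
#'   (logical) and `category` (`NA` when unmapped).
#' @export
method_coverage <- function(codes, table) {
  stopifnot(inherits(table, "method_table"))
  code <- radix_sort(unique(codes))
  category <- unname(unclass(table)[code])
  data.frame(code = code, mapped = !is.na(category), category = category,
             stringsAsFactors = FALSE)
}

#' @export
print.method_table <- function(x, ...) {
  cat("Detection-method conversion table: ", length(x), " codes, ",
      length(unique(unclass(x))), " categories\n", sep = "")
  invisible(x)
}
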