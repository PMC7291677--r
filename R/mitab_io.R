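#' @keywords internal
"_PACKAGE"

# Column names of the network table, in output order. NameA/NameB double as
# Cytoscape source/target node columns.
NETWORK_HEADER <- c(
  "NameA", "SwissA", "EntrezA", "NameB", "SwissB", "EntrezB",
  "Method.Score", "Method", "Publication.Score", "PMIDS", "Final.Score"
)

MITAB_MIN_COLS <- 15L

# Locale-independent (bytewise) string sort; all identifiers handled here are
# ASCII but the C collation keeps output identical across locales.
radix_sort <- function(x) sort(x, method = "radix")

radix_order <- function(...) order(..., method = "radix")

#' Parse PSI-MITAB interaction records
#'
#' Reads tab-separated PSI-MITAB 2.5/2.7 lines, tolerating the dialect
#' differences between providers (quoted or bare ontology terms, 15 or more
#' columns, `-` null markers). Only columns 1-11 are interpreted: interactor
#' identifiers and alternatives, detection-method codes, publication
#' identifiers and interactor taxonomy. Lines starting with `#` are treated
#' as headers/comments; lines with fewer than 15 columns are reported as
#' malformed and skipped, never raised as errors, so quality control stays a
#' downstream decision.
#'
#' @param text Path to a MITAB file, or a character vector of MITAB lines
#'   (a single string may contain embedded newlines).
#' @param source_db Provider label the records originate from; stored
#'   lowercase in every record.
#' @return A list with two data frames: `records`, one row per well-formed
#'   data line with columns `source_db`, `id_a`, `id_b`, `taxid_a`,
#'   `taxid_b`, `line_no`, `record_uid` and list-columns `alt_ids_a`,
#'   `alt_ids_b`, `detection_codes` (strings of the form `MI:nnnn`), `pmids`
#'   (digit strings); and `malformed`, one row per skipped line with its
#'   `line_no` and a reason token.
#' @examples
#' line <- paste(c("uniprotkb:P37840", "uniprotkb:P99999", "-", "-", "-", "-",
#'   "psi-mi:\"MI:0018\"(two hybrid)", "-", "pubmed:12345678",
#'   "taxid:9606(human)", "taxid:9606(human)", "-", "-", "-", "-"),
#'   collapse = "\t")
#' parse_mitab(line, "intact")$records$detection_codes[[1]]
#' @export
parse_mitab <- function(text, source_db) {
  stopifnot(is.character(source_db), length(source_db) == 1L, nzchar(source_db))
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      !grepl("\t", text, fixed = TRUE) && file.exists(text)) {
    lines <- tryCatch(readLines(text, warn = FALSE),
                      error = function(e) stop("cannot read MITAB input '", text,
                                               "': ", conditionMessage(e), call. = FALSE))
  } else {
    lines <- as.character(unlist(strsplit(as.character(text), "\n", fixed = TRUE),
                                 use.names = FALSE))
  }
  src <- tolower(source_db)
  trimmed <- trimws(lines)
  is_data <- nzchar(trimmed) & !startsWith(trimmed, "#")
  idx <- which(is_data)

  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= MITAB_MIN_COLS

  malformed <- data.frame(
    source_db = rep(src, sum(!ok)),
    line_no = idx[!ok],
    reason = rep("malformed_line", sum(!ok)),
    stringsAsFactors = FALSE
  )

  good <- fields[ok]
  col <- function(k) vapply(good, `[[`, character(1), k)
  n <- length(good)
  if (n == 0L) {
    records <- new_raw_records(
      source_db = character(0), id_a = character(0), id_b = character(0),
      taxid_a = integer(0), taxid_b = integer(0), line_no = integer(0),
      alt_ids_a = list(), alt_ids_b = list(),
      detection_codes = list(), pmids = list()
    )
  } else {
    records <- new_raw_records(
      source_db = rep(src, n),
      id_a = col(1L),
      id_b = col(2L),
      taxid_a = extract_taxid(col(10L)),
      taxid_b = extract_taxid(col(11L)),
      line_no = idx[ok],
      alt_ids_a = split_multifield(col(3L)),
      alt_ids_b = split_multifield(col(4L)),
      detection_codes = extract_mi_codes(col(7L)),
      pmids = extract_pmids(col(9L))
    )
  }
  list(records = records, malformed = malformed)
}

new_raw_records <- function(source_db, id_a, id_b, taxid_a, taxid_b, line_no,
                            alt_ids_a, alt_ids_b, detection_codes, pmids) {
  df <- data.frame(
    source_db = source_db, id_a = id_a, id_b = id_b,
    taxid_a = taxid_a, taxid_b = taxid_b, line_no = line_no,
    stringsAsFactors = FALSE
  )
  df$alt_ids_a <- alt_ids_a
  df$alt_ids_b <- alt_ids_b
  df$detection_codes <- detection_codes
  df$pmids <- pmids
  df$record_uid <- if (nrow(df)) paste(source_db, line_no, sep = ":") else character(0)
  df
}

extract_mi_codes <- function(x) {
  m <- regmatches(x, gregexpr("MI:[0-9]{4}", x))
  lapply(m, unique)
}

extract_pmids <- function(x) {
  m <- regmatches(x, gregexpr("pubmed:[0-9]+", x))
  lapply(m, function(v) sub("^pubmed:", "", v))
}

extract_taxid <- function(x) {
  out <- rep(NA_integer_, length(x))
  r <- regexpr("taxid:-?[0-9]+", x)
  hit <- r > 0L
  out[hit] <- as.integer(sub("^taxid:", "", regmatches(x, r)))
  out
}

split_multifield <- function(x) {
  lapply(strsplit(x, "|", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v) & v != "-"]
  })
}

#' Write the network table
#'
#' Writes scored interactions as the tab-separated 11-column table
#' (`final_network.txt`): identifier triples for both interactors, the
#' distinct method categories and their count (`Method.Score`), the distinct
#' PubMed IDs and their count (`Publication.Score`) and their sum
#' (`Final.Score`). The file imports directly into Cytoscape with `NameA`
#' and `NameB` as source and target node columns. Field values are
#' sanitised so every data line holds exactly 11 tab-separated fields.
#'
#' @param rows Data frame of scored interactions with the columns named in
#'   the table header (as produced by [aggregate_evidence()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_network()] for the inverse, [write_logs()] for the
#'   companion log files.
#' @export
write_network <- function(rows, path) {
  rows <- validate_output_rows(rows)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write network file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste(NETWORK_HEADER, collapse = "\t"), con)
  if (nrow(rows)) {
    cols <- lapply(rows[NETWORK_HEADER], function(v) gsub("[\t\r\n]+", " ", as.character(v)))
    writeLines(do.call(paste, c(unname(cols), sep = "\t")), con)
  }
  invisible(path)
}

validate_output_rows <- function(rows) {
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(NETWORK_HEADER, names(rows))
  if (length(missing_cols)) {
    stop("network rows lack required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(rows)) return(rows)
  ms <- as.integer(rows$Method.Score)
  ps <- as.integer(rows$Publication.Score)
  fs <- as.integer(rows$Final.Score)
  n_methods <- lengths(strsplit(as.character(rows$Method), ";", fixed = TRUE))
  n_pmids <- lengths(strsplit(as.character(rows$PMIDS), ";", fixed = TRUE))
  bad <- fs != ms + ps | ms != n_methods | ps != n_pmids | fs < 2L
  if (any(bad)) {
    stop("invalid output rows (score/list mismatch or Final.Score < 2) at: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  rows
}

#' Read a previously written network table
#'
#' @param path Path to a file written by [write_network()].
#' @return Data frame with the 11 network columns; scores are integer,
#'   everything else character.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(NETWORK_HEADER, names(df))
  if (length(missing_cols)) {
    stop("not a network table, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[NETWORK_HEADER]
  for (k in c("Method.Score", "Publication.Score", "Final.Score")) {
    df[[k]] <- as.integer(df[[k]])
  }
  df
}

#' Write the run log files
#'
#' Writes `final_network_log.txt`, listing every discarded seed and every
#' discarded interaction record with a one-token reason, and (for human
#' runs) `final_network_providers.txt`, listing each configured provider
#' with its status and the number of records it returned. The providers
#' file is omitted for C. elegans runs, whose data come from the local
#' internal store rather than from provider queries.
#'
#' @param report A run report as produced by [run_pipeline()], or any list
#'   with `seeds`, `discards` and `providers` data frames in the same
#'   layout.
#' @param dir Output directory (created if absent).
#' @param species `"human"` or `"celegans"`.
#' @return Invisibly, the paths written.
#' @export
write_logs <- function(report, dir, species = c("human", "celegans")) {
  species <- match.arg(species)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  log_path <- file.path(dir, "final_network_log.txt")
  lines <- character(0)
  seeds <- report$seeds
  if (!is.null(seeds) && nrow(seeds)) {
    flagged <- seeds[seeds$status != "ok", , drop = FALSE]
    if (nrow(flagged)) {
      lines <- c(lines, paste("seed", flagged$seed, flagged$status, sep = "\t"))
    }
  }
  discards <- report$discards
  if (!is.null(discards) && nrow(discards)) {
    lines <- c(lines, paste(discards$stage,
                            paste0(discards$source_db, ":line", discards$line_no),
                            discards$reason, sep = "\t"))
  }
  writeLines(lines, log_path)
  paths <- log_path

  if (species == "human") {
    prov_path <- file.path(dir, "final_network_providers.txt")
    providers <- report$providers
    prov_lines <- if (!is.null(providers) && nrow(providers)) {
      paste(providers$name, providers$state, providers$records_returned, sep = "\t")
    } else character(0)
    writeLines(prov_lines, prov_path)
    paths <- c(paths, prov_path)
  }
  invisible(paths)
}
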