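# C. elegans internal network.
#
# Worm queries are not answered live: an interaction store is built once
# from a local WormBase/Alliance-style MITAB dump, passing the same
# parse -> taxonomy (6239) -> PMID -> method stages as the human data,
# and seed queries are answered from that store through the shared
# aggregation and scoring code.

#' Build the C. elegans interaction store from a MITAB-like dump
#'
#' Parses the dump, applies the standard quality-control screens with the
#' worm taxonomy (6239), and keeps the surviving evidence units keyed by
#' WBGene pair. Identifiers must be WormBase gene IDs (`WBGene` + 8
#' digits, optionally namespaced, e.g. `wormbase:WBGene00000001`); other
#' identifiers are discarded as unmapped.
#'
#' @param dump Path to the dump file, or a character vector of MITAB
#'   lines.
#' @param method_table A `method_table`; default the bundled one.
#' @param filter_mode `"lenient"` or `"stringent"`.
#' @param mapping Optional `worm_mapping` (see [read_worm_mapping()]) used
#'   to fill Swiss-Prot/Entrez fields; genes absent from it keep their
#'   WBGene ID echoed.
#' @return A `worm_store`: list with `units`, `discards`, `malformed` and
#'   `provenance` (source name and record counts).
#' @export
build_worm_store <- function(dump, method_table = load_method_table(),
                             filter_mode = c("lenient", "stringent"),
                             mapping = NULL) {
  filter_mode <- match.arg(filter_mode)
  parsed <- parse_mitab(dump, "wormbase")
  fb <- filter_batch(parsed$records, "celegans", method_table, mapping, filter_mode)
  if (nrow(parsed$records) > 0L && nrow(fb$units) == 0L) {
    warning("no records retained from worm dump; store is empty", call. = FALSE)
  }
  source_name <- if (length(dump) == 1L && !grepl("\n", dump, fixed = TRUE) &&
                     file.exists(dump)) basename(dump) else "in-memory"
  structure(
    list(units = fb$units, discards = fb$discards, malformed = parsed$malformed,
         provenance = list(source = source_name,
                           records_in = nrow(parsed$records),
                           records_retained = length(unique(fb$units$record_uid)),
                           filter_mode = filter_mode)),
    class = "worm_store"
  )
}

#' Write a worm store to a plain-text file
#'
#' Serialises the evidence units as a tab-separated table with a
#' provenance comment header, so a store built once can be reloaded
#' without the original dump.
#'
#' @param store A `worm_store`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_worm_store <- function(store, path) {
  stopifnot(inherits(store, "worm_store"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# worm interaction store; source=%s; filter=%s",
                     store$provenance$source, store$provenance$filter_mode), con)
  cols <- names(empty_units())
  writeLines(paste(cols, collapse = "\t"), con)
  u <- store$units
  if (nrow(u)) {
    writeLines(do.call(paste, c(lapply(u[cols], as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a worm store written by [write_worm_store()]
#'
#' @param path Path to a serialised store.
#' @return A `worm_store` (discard/malformed reports are empty; they
#'   belong to the build step).
#' @export
read_worm_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header_comment <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  cols <- names(empty_units())
  units <- if (length(body) > 1L) {
    df <- utils::read.delim(text = paste(body, collapse = "\n"), header = TRUE,
                            sep = "\t", quote = "", colClasses = "character",
                            check.names = FALSE)
    df$line_no <- as.integer(df$line_no)
    df[cols]
  } else {
    empty_units()
  }
  source_name <- sub("^.*source=([^;]*);.*$", "\\1",
                     if (length(header_comment)) header_comment[1] else "source=unknown;")
  structure(
    list(units = units, discards = empty_discards(),
         malformed = data.frame(source_db = character(0), line_no = integer(0),
                                reason = character(0), stringsAsFactors = FALSE),
         provenance = list(source = source_name,
                           records_in = NA_integer_,
                           records_retained = length(unique(units$record_uid)),
                           filter_mode = NA_character_)),
    class = "worm_store"
  )
}

#' Query the worm store for a list of seeds
#'
#' Validates the WBGene seeds, retains store evidence for pairs touching
#' at least one seed, and scores interactions exactly as in the human
#' pipeline. Seeds absent from the store are reported as
#' `no_interactions`; a pair shared by two seeds is emitted once.
#'
#' @param seeds Character vector of WBGene identifiers.
#' @param store A `worm_store`.
#' @param min_score Final.Score threshold (default 2, the floor).
#' @return List with `network` (11-column data frame) and `seeds` (per
#'   seed status data frame).
#' @export
query_worm <- function(seeds, store, min_score = 2L) {
  stopifnot(inherits(store, "worm_store"))
  seeds <- unique(seeds)
  status <- data.frame(seed = seeds, status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(seeds)) {
    v <- validate_seed(seeds[i], "celegans")
    if (!v$valid) status$status[i] <- paste0("invalid_", v$reason)
  }
  valid <- status$seed[status$status == "ok"]

  u <- store$units
  seed_rows <- lapply(valid, function(s) {
    ia <- match(s, u$name_a)
    if (!is.na(ia)) {
      return(data.frame(gene_name = u$name_a[ia], swiss = u$swiss_a[ia],
                        entrez = u$entrez_a[ia], stringsAsFactors = FALSE))
    }
    ib <- match(s, u$name_b)
    if (!is.na(ib)) {
      return(data.frame(gene_name = u$name_b[ib], swiss = u$swiss_b[ib],
                        entrez = u$entrez_b[ib], stringsAsFactors = FALSE))
    }
    NULL
  })
  absent <- valid[vapply(seed_rows, is.null, logical(1))]
  status$status[status$seed %in% absent] <- "no_interactions"
  seed_triples <- do.call(rbind, c(
    list(data.frame(gene_name = character(0), swiss = character(0),
                    entrez = character(0), stringsAsFactors = FALSE)),
    seed_rows[!vapply(seed_rows, is.null, logical(1))]
  ))

  network <- score_threshold(aggregate_evidence(u, seed_triples), min_score)
  list(network = network, seeds = status)
}

#' @export
print.worm_store <- function(x, ...) {
  cat("C. elegans interaction store\n",
      "  source: ", x$provenance$source, "\n",
      "  evidence units: ", nrow(x$units), "\n", sep = "")
  invisible(x)
}
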