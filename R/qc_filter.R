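# Record-level quality control.
#
# Every parsed record either yields at least one evidence unit (a
# QC-passing (pair, method category, PMID) tuple) or exactly one discard
# entry carrying the stage and reason, so the accounting
#   records yielding units + record-level discards = records in
# is exact. Discard checks run in a fixed order (taxonomy, pmid, method,
# mapping) so a record failing several screens reports a deterministic
# reason.
#
# Lenient vs stringent: both modes require a single distinct PMID, at
# least one detection-method code, within-species taxids where stated, and
# univocally resolvable interactors. Stringent additionally demands
# completeness: records missing a taxid on either interactor are
# discarded, and detection codes absent from the conversion table are
# dropped (a record left with no mapped code is discarded). The stringent
# evidence set is therefore a subset of the lenient one for any input.

empty_units <- function() {
  data.frame(
    name_a = character(0), swiss_a = character(0), entrez_a = character(0),
    name_b = character(0), swiss_b = character(0), entrez_b = character(0),
    category = character(0), pmid = character(0),
    source_db = character(0), line_no = integer(0), record_uid = character(0),
    stringsAsFactors = FALSE
  )
}

empty_discards <- function() {
  data.frame(
    stage = character(0), reason = character(0), source_db = character(0),
    line_no = integer(0), record_uid = character(0), item = character(0),
    stringsAsFactors = FALSE
  )
}

discard_entry <- function(rec, stage, reason) {
  data.frame(
    stage = stage, reason = reason, source_db = rec$source_db,
    line_no = rec$line_no, record_uid = rec$record_uid,
    item = paste(rec$id_a, rec$id_b, sep = "|"),
    stringsAsFactors = FALSE
  )
}

#' Quality-filter a single interaction record
#'
#' Applies the record-level completeness screens: the record is discarded
#' when either interactor carries a taxid differing from the query
#' species, when it cites no PubMed ID or more than one distinct PubMed
#' ID, when it has no detection-method annotation, or when either
#' interactor fails univocal resolution. A surviving record yields one
#' evidence unit per detection code, each code converted to its method
#' category. See the module comment for the extra stringent-mode screens.
#'
#' @param rec One-row slice of a parsed record data frame (see
#'   [parse_mitab()]).
#' @param species `"human"` or `"celegans"`.
#' @param method_table A `method_table` from [load_method_table()].
#' @param mapping Mapping snapshot matching the species (see
#'   [read_mapping_table()], [read_worm_mapping()]); may be `NULL` for
#'   worm runs.
#' @param filter_mode `"lenient"` or `"stringent"`.
#' @return List with exactly one of `units` (data frame of evidence
#'   units) or `discard` (one-row discard entry) non-`NULL`.
#' @export
filter_record <- function(rec, species = c("human", "celegans"),
                          method_table, mapping = NULL,
                          filter_mode = c("lenient", "stringent")) {
  species <- match.arg(species)
  filter_mode <- match.arg(filter_mode)
  tax <- TAXID[[species]]

  rec <- as.list(rec)
  scalars <- c("source_db", "id_a", "id_b", "taxid_a", "taxid_b", "line_no", "record_uid")
  for (k in scalars) rec[[k]] <- rec[[k]][[1L]]
  for (k in c("alt_ids_a", "alt_ids_b", "detection_codes", "pmids")) {
    if (is.list(rec[[k]])) rec[[k]] <- rec[[k]][[1L]]
  }

  fail <- function(stage, reason) list(units = NULL, discard = discard_entry(rec, stage, reason))

  ta <- rec$taxid_a
  tb <- rec$taxid_b
  if ((!is.na(ta) && ta != tax) || (!is.na(tb) && tb != tax)) {
    return(fail("taxonomy", "wrong_taxid"))
  }
  if (filter_mode == "stringent" && (is.na(ta) || is.na(tb))) {
    return(fail("taxonomy", "missing_taxid"))
  }

  pm <- unique(rec$pmids)
  if (length(pm) == 0L) return(fail("pmid", "no_pmid"))
  if (length(pm) > 1L) return(fail("pmid", "multiple_pmids"))

  codes <- rec$detection_codes
  if (length(codes) == 0L) return(fail("method", "no_method"))

  res_a <- resolve_triple(rec$id_a, mapping, rec$alt_ids_a, species)
  if (res_a$status != "ok") return(fail("mapping", res_a$status))
  res_b <- resolve_triple(rec$id_b, mapping, rec$alt_ids_b, species)
  if (res_b$status != "ok") return(fail("mapping", res_b$status))

  categories <- convert_method(codes, method_table, filter_mode)
  categories <- categories[!is.na(categories)]
  if (length(categories) == 0L) return(fail("method", "unmapped_method"))

  n <- length(categories)
  units <- data.frame(
    name_a = rep(res_a$triple$gene_name, n),
    swiss_a = rep(res_a$triple$swiss, n),
    entrez_a = rep(res_a$triple$entrez, n),
    name_b = rep(res_b$triple$gene_name, n),
    swiss_b = rep(res_b$triple$swiss, n),
    entrez_b = rep(res_b$triple$entrez, n),
    category = categories,
    pmid = rep(pm, n),
    source_db = rep(rec$source_db, n),
    line_no = rep(rec$line_no, n),
    record_uid = rep(rec$record_uid, n),
    stringsAsFactors = FALSE
  )
  list(units = units, discard = NULL)
}

#' Quality-filter a batch of records
#'
#' Applies [filter_record()] to every row and concatenates the results.
#' The conservation property holds exactly: every input record either
#' contributes at least one evidence unit or appears in exactly one
#' discard entry.
#'
#' @inheritParams filter_record
#' @param records Parsed record data frame (see [parse_mitab()]).
#' @return List with `units` and `discards` data frames.
#' @export
filter_batch <- function(records, species = c("human", "celegans"),
                         method_table, mapping = NULL,
                         filter_mode = c("lenient", "stringent")) {
  species <- match.arg(species)
  filter_mode <- match.arg(filter_mode)
  n <- if (is.null(records)) 0L else nrow(records)
  if (n == 0L) return(list(units = empty_units(), discards = empty_discards()))

  unit_acc <- vector("list", n)
  disc_acc <- vector("list", n)
  for (i in seq_len(n)) {
    res <- filter_record(records[i, , drop = FALSE], species, method_table,
                         mapping, filter_mode)
    unit_acc[[i]] <- res$units
    disc_acc[[i]] <- res$discard
  }
  units <- do.call(rbind, c(list(empty_units()), unit_acc[!vapply(unit_acc, is.null, logical(1))]))
  discards <- do.call(rbind, c(list(empty_discards()), disc_acc[!vapply(disc_acc, is.null, logical(1))]))
  rownames(units) <- NULL
  rownames(discards) <- NULL
  list(units = units, discards = discards)
}
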