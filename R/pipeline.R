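# End-to-end pipeline: validate seeds -> acquire records (providers or
# worm store) -> parse -> quality control -> method conversion ->
# merge/score -> threshold -> write the three output files and a
# machine-readable run report. Every input seed and fetched record is
# accounted for in exactly one of {output, report}.

#' Run the full interaction-integration pipeline
#'
#' @param seeds Character vector of seed identifiers (HGNC symbols or
#'   Swiss-Prot accessions for human; WBGene IDs for C. elegans).
#'   Duplicates are removed case-sensitively, order preserved.
#' @param species `"human"` or `"celegans"`.
#' @param filter_mode `"lenient"` (default; maximises recall) or
#'   `"stringent"` (additionally requires taxonomy completeness and a
#'   conversion-table hit for every counted method).
#' @param mode `"offline"` (read per-provider files under `offline_root`)
#'   or `"live"` (query PSICQUIC).
#' @param offline_root Directory with `<provider>/<seed>.mitab` files
#'   (offline human mode).
#' @param out_dir Output directory; when non-`NULL` the function writes
#'   `final_network.txt`, `final_network_log.txt`, `run_report.json` and
#'   (human only) `final_network_providers.txt` there.
#' @param min_score Final.Score threshold, >= 2.
#' @param method_table `method_table`; default the bundled conversion
#'   table.
#' @param mapping Identifier-mapping snapshot; default the bundled
#'   miniature human snapshot (human runs) or `NULL` (worm runs).
#' @param providers Provider configuration data frame; default
#'   [default_providers()].
#' @param worm_store A prebuilt `worm_store` (worm runs); alternatively
#'   give `worm_dump` to build one on the fly.
#' @param worm_dump Path to a worm MITAB dump (worm runs, ignored if
#'   `worm_store` given).
#' @return Invisibly, a list with `network` (the scored 11-column data
#'   frame) and `report` (a `run_report` with seed statuses, discards,
#'   provider statuses and reconciled stage counts).
#' @export
run_pipeline <- function(seeds,
                         species = c("human", "celegans"),
                         filter_mode = c("lenient", "stringent"),
                         mode = c("offline", "live"),
                         offline_root = NULL,
                         out_dir = NULL,
                         min_score = 2L,
                         method_table = NULL,
                         mapping = NULL,
                         providers = NULL,
                         worm_store = NULL,
                         worm_dump = NULL) {
  species <- match.arg(species)
  filter_mode <- match.arg(filter_mode)
  mode <- match.arg(mode)
  if (is.null(method_table)) method_table <- load_method_table()

  seeds <- as.character(seeds)
  seeds <- seeds[!is.na(seeds) & nzchar(trimws(seeds))]
  seeds <- unique(trimws(seeds))
  if (!length(seeds)) stop("empty seed list", call. = FALSE)

  seed_status <- data.frame(seed = seeds, status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(seeds)) {
    v <- validate_seed(seeds[i], species)
    if (!v$valid) seed_status$status[i] <- paste0("invalid_", v$reason)
  }

  if (species == "celegans") {
    if (is.null(worm_store)) {
      if (is.null(worm_dump)) stop("worm runs need worm_store or worm_dump", call. = FALSE)
      worm_store <- build_worm_store(worm_dump, method_table, filter_mode, mapping)
    }
    valid <- seed_status$seed[seed_status$status == "ok"]
    qw <- query_worm(valid, worm_store, min_score)
    m <- match(qw$seeds$seed, seed_status$seed)
    seed_status$status[m] <- qw$seeds$status
    network <- qw$network
    report <- build_run_report(
      species, filter_mode, seed_status,
      discards = worm_store$discards, malformed = worm_store$malformed,
      providers = NULL,
      records_in = worm_store$provenance$records_in,
      units = worm_store$units, network = network
    )
  } else {
    if (is.null(mapping)) mapping <- read_mapping_table()
    if (is.null(providers)) providers <- default_providers()

    # resolve seeds (accession seeds resolve to their symbol) and query
    valid_idx <- which(seed_status$status == "ok")
    triple_acc <- list()
    rec_acc <- list()
    mal_acc <- list()
    status_acc <- list()
    for (i in valid_idx) {
      s <- seed_status$seed[i]
      res <- resolve_seed_triple(s, mapping)
      if (res$status != "ok") {
        seed_status$status[i] <- if (res$status == "ambiguous") "ambiguous" else "unmapped"
        next
      }
      triple_acc[[length(triple_acc) + 1L]] <-
        data.frame(gene_name = res$triple$gene_name, swiss = res$triple$swiss,
                   entrez = res$triple$entrez, stringsAsFactors = FALSE)
      fetched <- fetch_seed_records(res$triple$gene_name, providers, mode, offline_root)
      rec_acc[[length(rec_acc) + 1L]] <- fetched$records
      if (nrow(fetched$malformed)) mal_acc[[length(mal_acc) + 1L]] <- fetched$malformed
      status_acc[[length(status_acc) + 1L]] <- fetched$statuses
    }
    seed_triples <- do.call(rbind, c(
      list(data.frame(gene_name = character(0), swiss = character(0),
                      entrez = character(0), stringsAsFactors = FALSE)),
      triple_acc
    ))
    seed_triples <- unique(seed_triples)

    records <- if (length(rec_acc)) do.call(rbind, rec_acc) else NULL
    if (!is.null(records)) rownames(records) <- NULL
    malformed <- if (length(mal_acc)) do.call(rbind, mal_acc) else
      data.frame(source_db = character(0), line_no = integer(0),
                 reason = character(0), stringsAsFactors = FALSE)
    provider_status <- summarise_provider_statuses(status_acc, providers)

    fb <- filter_batch(records, "human", method_table, mapping, filter_mode)

    # seeds whose resolved identity touches no evidence unit
    touched <- unique(c(fb$units$swiss_a, fb$units$swiss_b))
    for (i in seq_len(nrow(seed_status))) {
      if (seed_status$status[i] != "ok") next
      s <- seed_status$seed[i]
      res <- resolve_seed_triple(s, mapping)
      if (res$status == "ok" && !(res$triple$swiss %in% touched)) {
        seed_status$status[i] <- "no_interactions"
      }
    }

    network <- score_threshold(aggregate_evidence(fb$units, seed_triples), min_score)
    report <- build_run_report(
      species, filter_mode, seed_status,
      discards = fb$discards, malformed = malformed,
      providers = provider_status,
      records_in = if (is.null(records)) 0L else nrow(records),
      units = fb$units, network = network
    )
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_network(network, file.path(out_dir, "final_network.txt"))
    write_logs(report, out_dir, species)
    write_run_report(report, file.path(out_dir, "run_report.json"))
  }
  invisible(list(network = network, report = report))
}

# Collapse per-seed provider statuses into one row per configured
# provider: responded if any query succeeded, with summed record counts.
summarise_provider_statuses <- function(status_list, providers) {
  if (!length(status_list)) {
    return(data.frame(name = providers$name,
                      state = ifelse(providers$enabled, "failed", "skipped"),
                      records_returned = 0L, stringsAsFactors = FALSE))
  }
  all_status <- do.call(rbind, status_list)
  out <- lapply(providers$name, function(nm) {
    rows <- all_status[all_status$name == nm, , drop = FALSE]
    state <- if (any(rows$state == "responded")) "responded"
             else if (any(rows$state == "failed")) "failed"
             else "skipped"
    provider_status_row(nm, state, sum(rows$records_returned))
  })
  do.call(rbind, out)
}

build_run_report <- function(species, filter_mode, seed_status, discards,
                             malformed, providers, records_in, units, network) {
  retained_uids <- unique(units$record_uid)
  counts <- list(
    seeds_in = nrow(seed_status),
    seeds_valid = sum(!startsWith(seed_status$status, "invalid")),
    seeds_invalid = sum(startsWith(seed_status$status, "invalid")),
    malformed_lines = nrow(malformed),
    records_in = if (is.na(records_in)) NA_integer_ else as.integer(records_in),
    records_retained_sources = length(retained_uids),
    records_discarded = nrow(discards),
    evidence_units = nrow(units),
    interactions = nrow(network)
  )
  structure(
    list(species = species, filter_mode = filter_mode,
         seeds = seed_status, discards = discards, malformed = malformed,
         providers = providers, counts = counts),
    class = "run_report"
  )
}

write_run_report <- function(report, path) {
  payload <- list(
    species = report$species,
    filter_mode = report$filter_mode,
    counts = report$counts,
    seeds = report$seeds,
    discards = report$discards,
    malformed = report$malformed,
    providers = report$providers
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, dataframe = "rows",
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  c_ <- x$counts
  cat("Interaction-integration run (", x$species, ", ", x$filter_mode, " filter)\n",
      "  seeds: ", c_$seeds_in, " in, ", c_$seeds_valid, " valid\n",
      "  records: ", c_$records_in, " in, ", c_$records_retained_sources,
      " retained, ", c_$records_discarded, " discarded, ",
      c_$malformed_lines, " malformed lines\n",
      "  interactions reported: ", c_$interactions, "\n", sep = "")
  invisible(x)
}
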