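# Acquisition of raw MITAB text per seed and per provider.
#
# Human interaction evidence comes from seven primary databases that
# curate PPIs directly from the peer-reviewed literature, all exposing the
# PSICQUIC REST interface. Live querying is supported but intentionally
# outside the automated test surface (results drift as providers update);
# offline mode reads one local MITAB file per provider and seed from
# `<offline_root>/<provider>/<seed>.mitab` and is bit-deterministic.

#' Default provider configuration
#'
#' The seven human PPI databases queried by default: bhf-ucl, BioGRID,
#' InnateDB, IntAct, MBInfo, MINT and UniProt. Endpoint templates are
#' PSICQUIC query URLs with `%s` in place of the (URL-encoded) query
#' identifier; offline mode ignores them.
#'
#' @return Data frame with columns `name`, `endpoint`, `enabled`.
#' @export
default_providers <- function() {
  data.frame(
    name = c("bhf-ucl", "BioGRID", "InnateDB", "IntAct", "MBInfo", "MINT", "UniProt"),
    endpoint = c(
      "https://www.ebi.ac.uk/Tools/webservices/psicquic/bhf-ucl/webservices/current/search/query/%s",
      "https://psicquic.thebiogrid.org/webservices/current/search/query/%s",
      "https://psicquic.curated.innatedb.com/webservices/current/search/query/%s",
      "https://www.ebi.ac.uk/Tools/webservices/psicquic/intact/webservices/current/search/query/%s",
      "https://www.ebi.ac.uk/Tools/webservices/psicquic/mbinfo/webservices/current/search/query/%s",
      "https://www.ebi.ac.uk/Tools/webservices/psicquic/mint/webservices/current/search/query/%s",
      "https://www.ebi.ac.uk/Tools/webservices/psicquic/uniprot/webservices/current/search/query/%s"
    ),
    enabled = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Read a provider configuration file
#'
#' A YAML list of providers overriding the built-in seven; each entry has
#' `name`, optionally `endpoint` (live mode) and `enabled` (default
#' `TRUE`).
#'
#' @param path YAML file path.
#' @return Data frame with columns `name`, `endpoint`, `enabled`.
#' @export
read_providers_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$providers)) cfg$providers else cfg
  if (!length(entries)) stop("provider config is empty: ", path, call. = FALSE)
  rows <- lapply(entries, function(e) {
    if (is.null(e$name)) stop("provider entry without a name in ", path, call. = FALSE)
    data.frame(
      name = e$name,
      endpoint = if (!is.null(e$endpoint)) e$endpoint else NA_character_,
      enabled = if (!is.null(e$enabled)) isTRUE(e$enabled) else TRUE,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

provider_status_row <- function(name, state, records) {
  data.frame(name = name, state = state,
             records_returned = if (state == "responded") records else 0L,
             stringsAsFactors = FALSE)
}

#' Fetch interaction records for one seed from all providers
#'
#' Queries every enabled provider for one validated seed and concatenates
#' the parsed records, each tagged with its source database. A failing
#' provider is recorded as `failed` and never aborts the run; only the
#' failure of every enabled provider (or an empty provider set) is a
#' run-level error. In offline mode each provider's records are read from
#' `<offline_root>/<provider-lowercase>/<seed>.mitab`; a missing file
#' marks that provider failed. In live mode each provider is queried once
#' and retried once before being marked failed.
#'
#' @param seed Validated seed identifier (the file/query key).
#' @param providers Provider configuration data frame (see
#'   [default_providers()]).
#' @param mode `"offline"` or `"live"`.
#' @param offline_root Root directory of per-provider fixture files
#'   (offline mode).
#' @return List with `records` (parsed record data frame, `record_uid`
#'   keyed by provider, seed and line), `statuses` (one row per
#'   configured provider: `name`, `state` in responded/failed/skipped,
#'   `records_returned`) and `malformed` (malformed-line report).
#' @export
fetch_seed_records <- function(seed, providers = default_providers(),
                               mode = c("offline", "live"),
                               offline_root = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(providers), nrow(providers) >= 1L)
  if (mode == "offline" && (is.null(offline_root) || !dir.exists(offline_root))) {
    stop("offline mode requires an existing offline_root directory", call. = FALSE)
  }

  rec_acc <- list()
  mal_acc <- list()
  statuses <- vector("list", nrow(providers))
  for (i in seq_len(nrow(providers))) {
    p <- providers[i, ]
    if (!isTRUE(p$enabled)) {
      statuses[[i]] <- provider_status_row(p$name, "skipped", 0L)
      next
    }
    text <- if (mode == "offline") {
      path <- file.path(offline_root, tolower(p$name), paste0(seed, ".mitab"))
      if (file.exists(path)) path else NULL
    } else {
      fetch_live(p$endpoint, seed)
    }
    if (is.null(text)) {
      statuses[[i]] <- provider_status_row(p$name, "failed", 0L)
      next
    }
    parsed <- parse_mitab(text, p$name)
    recs <- parsed$records
    if (nrow(recs)) {
      recs$query_seed <- seed
      recs$record_uid <- paste(recs$source_db, seed, recs$line_no, sep = ":")
    } else {
      recs$query_seed <- character(0)
    }
    rec_acc[[length(rec_acc) + 1L]] <- recs
    if (nrow(parsed$malformed)) mal_acc[[length(mal_acc) + 1L]] <- parsed$malformed
    statuses[[i]] <- provider_status_row(p$name, "responded", nrow(recs))
  }
  statuses <- do.call(rbind, statuses)

  enabled <- providers$enabled
  if (!any(enabled) || all(statuses$state[enabled] == "failed")) {
    stop("no data source available", call. = FALSE)
  }

  records <- if (length(rec_acc)) {
    out <- do.call(rbind, rec_acc)
    rownames(out) <- NULL
    out
  } else {
    r <- new_raw_records(character(0), character(0), character(0), integer(0),
                         integer(0), integer(0), list(), list(), list(), list())
    r$query_seed <- character(0)
    r
  }
  malformed <- if (length(mal_acc)) do.call(rbind, mal_acc) else
    data.frame(source_db = character(0), line_no = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(records = records, statuses = statuses, malformed = malformed)
}

# One PSICQUIC GET with a single retry; NULL on failure. Species
# filtering is done client-side downstream, as provider-side filters are
# inconsistently implemented.
fetch_live <- function(endpoint, seed) {
  if (is.na(endpoint) || !nzchar(endpoint)) return(NULL)
  url <- sprintf(endpoint, utils::URLencode(seed, reserved = TRUE))
  for (attempt in 1:2) {
    text <- tryCatch(suppressWarnings(readLines(url, warn = FALSE)),
                     error = function(e) NULL)
    if (!is.null(text)) return(text)
  }
  NULL
}
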