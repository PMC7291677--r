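# Seed validation and identifier resolution.
#
# Human seeds may be HGNC gene symbols or Swiss-Prot accessions; worm seeds
# are WormBase gene IDs (WBGene + 8 digits). Every interactor in the output
# must resolve to a univocal (gene name, Swiss-Prot, Entrez) triple through
# a mapping snapshot; anything ambiguous or unmapped is discarded and
# logged rather than silently propagated.

TAXID <- c(human = 9606L, celegans = 6239L)

# Official UniProt accession grammar (6 or 10 characters).
UNIPROT_PATTERN <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
# HGNC-style symbol: uppercase alphanumerics, limited '-'/'@', no leading
# digit; the C#orf# family is admitted explicitly.
HGNC_PATTERN <- "^([A-Z][A-Z0-9@-]*|C[0-9]+orf[0-9]+)$"
WBGENE_PATTERN <- "^WBGene[0-9]{8}$"

# Identifier namespaces that denote non-protein interactors (chemicals,
# RNAs); records carrying them are discarded as non_protein.
NON_PROTEIN_NS <- c("chebi", "chembl", "chembl compound", "pubchem",
                    "pubchem-compound", "rnacentral", "mirbase", "drugbank")
UNIPROT_NS <- c("uniprotkb", "uniprot", "swiss-prot", "sp")
ENTREZ_NS <- c("entrez gene/locuslink", "entrezgene/locuslink", "entrez gene",
               "entrezgene", "entrez", "locuslink", "ncbigene")
SYMBOL_NS <- c("", "hgnc", "gene name", "genename", "symbol")

#' Validate a seed identifier
#'
#' Lexical validation only; whether the seed maps to a known gene is a
#' separate (resolution) step. Human seeds must look like an HGNC gene
#' symbol or a UniProt accession; C. elegans seeds must be `WBGene`
#' followed by exactly eight digits. Validation is case-sensitive and
#' total: invalid seeds are reported, never raised.
#'
#' @param seed A single identifier string.
#' @param species `"human"` or `"celegans"`.
#' @return List with `valid` (logical) and `reason` (`NA` when valid,
#'   otherwise a one-token reason).
#' @examples
#' validate_seed("ATP13A2", "human")$valid        # TRUE
#' validate_seed("WBGene00000001", "celegans")$valid  # TRUE
#' validate_seed("WBGene123", "celegans")$reason  # "format"
#' @export
validate_seed <- function(seed, species = c("human", "celegans")) {
  species <- match.arg(species)
  if (!is.character(seed) || length(seed) != 1L || is.na(seed) || !nzchar(seed)) {
    return(list(valid = FALSE, reason = "empty"))
  }
  ok <- if (species == "celegans") {
    grepl(WBGENE_PATTERN, seed)
  } else {
    grepl(HGNC_PATTERN, seed) || grepl(UNIPROT_PATTERN, seed)
  }
  list(valid = ok, reason = if (ok) NA_character_ else "format")
}

#' Load an identifier-mapping snapshot
#'
#' A mapping snapshot is a tab-separated table with columns `symbol`,
#' `uniprot` and `entrez`, one row per univocal gene mapping. The bundled
#' miniature snapshot covers a few dozen well-known human genes and exists
#' so the package is testable without downloads; real analyses should
#' supply a current full snapshot.
#'
#' @param path Path to a snapshot; `NULL` loads the bundled miniature one.
#' @return A `mapping_table` data frame.
#' @export
read_mapping_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hsapiens_idmap_mini.tsv", package = "ppinet")
  }
  if (!file.exists(path)) stop("mapping snapshot not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  need <- c("symbol", "uniprot", "entrez")
  if (!all(need %in% names(df))) {
    stop("mapping snapshot must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(df[need], class = c("mapping_table", "data.frame"))
}

#' Load a C. elegans identifier-mapping snapshot
#'
#' Optional WBGene-keyed mapping used to fill the Swiss-Prot/Entrez output
#' columns for worm runs; genes absent from the snapshot keep their WBGene
#' ID echoed in those columns. The bundled file is a synthetic miniature
#' used by the test suite.
#'
#' @param path Tab-separated file with columns `wbgene`, `uniprot`,
#'   `entrez`; `NULL` loads the bundled synthetic miniature.
#' @return A `worm_mapping` data frame.
#' @export
read_worm_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "celegans_idmap_synthetic.tsv", package = "ppinet")
  }
  if (!file.exists(path)) stop("worm mapping snapshot not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  need <- c("wbgene", "uniprot", "entrez")
  if (!all(need %in% names(df))) {
    stop("worm mapping snapshot must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(df[need], class = c("worm_mapping", "data.frame"))
}

strip_namespace <- function(id) {
  pos <- regexpr(":", id, fixed = TRUE)
  if (pos > 0L) {
    list(ns = tolower(substr(id, 1L, pos - 1L)),
         value = substr(id, pos + 1L, nchar(id)))
  } else {
    list(ns = "", value = id)
  }
}

# Isoform (-1, -2, ...) and processed-chain (-PRO_nnn) suffixes denote the
# same gene product for mapping purposes.
strip_uniprot_suffix <- function(acc) {
  sub("-(PRO_[0-9]+|[0-9]+)$", "", acc)
}

#' Resolve an interactor identifier to a (name, Swiss-Prot, Entrez) triple
#'
#' Resolution succeeds only when the identifier matches exactly one row of
#' the mapping snapshot: one-to-many matches come back as
#' `ambiguous`, zero matches as `unmapped` (after falling back to any
#' alternative identifiers carried by the record), and chemical/RNA
#' namespaces as `non_protein`. UniProt isoform and PRO-chain suffixes are
#' stripped before lookup. For worm runs the WBGene ID itself is the gene
#' name and the optional worm mapping fills the remaining fields.
#'
#' @param id Primary identifier string, usually namespaced
#'   (`uniprotkb:P37840`).
#' @param mapping A `mapping_table` (human) or `worm_mapping`/`NULL`
#'   (worm).
#' @param alt_ids Character vector of alternative identifiers to fall back
#'   on when the primary does not map.
#' @param species `"human"` or `"celegans"`.
#' @return List with `status` (`"ok"`, `"unmapped"`, `"ambiguous"` or
#'   `"non_protein"`) and, when `status == "ok"`, `triple`: a list with
#'   `gene_name`, `swiss`, `entrez`.
#' @export
resolve_triple <- function(id, mapping, alt_ids = character(0),
                           species = c("human", "celegans")) {
  species <- match.arg(species)
  if (species == "celegans") return(resolve_worm(id, mapping))
  res <- resolve_one_human(id, mapping)
  if (res$status %in% c("ok", "ambiguous", "non_protein")) return(res)
  for (alt in alt_ids) {
    alt_res <- resolve_one_human(alt, mapping)
    if (alt_res$status == "ok") return(alt_res)
  }
  res
}

resolve_one_human <- function(id, mapping) {
  stopifnot(inherits(mapping, "mapping_table"))
  parts <- strip_namespace(id)
  if (parts$ns %in% NON_PROTEIN_NS) return(list(status = "non_protein"))
  if (parts$ns %in% UNIPROT_NS) {
    key <- strip_uniprot_suffix(parts$value)
    col <- "uniprot"
  } else if (parts$ns %in% ENTREZ_NS) {
    key <- parts$value
    col <- "entrez"
  } else if (parts$ns %in% SYMBOL_NS) {
    key <- parts$value
    col <- "symbol"
  } else {
    return(list(status = "unmapped"))
  }
  if (!nzchar(key) || key == "-") return(list(status = "unmapped"))
  rows <- mapping[mapping[[col]] == key, , drop = FALSE]
  if (nrow(rows) == 1L) {
    list(status = "ok",
         triple = list(gene_name = rows$symbol, swiss = rows$uniprot,
                       entrez = rows$entrez))
  } else if (nrow(rows) > 1L) {
    list(status = "ambiguous")
  } else {
    list(status = "unmapped")
  }
}

resolve_worm <- function(id, mapping) {
  parts <- strip_namespace(id)
  if (parts$ns %in% NON_PROTEIN_NS) return(list(status = "non_protein"))
  wb <- parts$value
  if (!grepl(WBGENE_PATTERN, wb)) return(list(status = "unmapped"))
  swiss <- wb
  entrez <- wb
  if (!is.null(mapping) && inherits(mapping, "worm_mapping")) {
    rows <- mapping[mapping$wbgene == wb, , drop = FALSE]
    if (nrow(rows) > 1L) return(list(status = "ambiguous"))
    if (nrow(rows) == 1L) {
      if (nzchar(rows$uniprot)) swiss <- rows$uniprot
      if (nzchar(rows$entrez)) entrez <- rows$entrez
    }
  }
  list(status = "ok",
       triple = list(gene_name = wb, swiss = swiss, entrez = entrez))
}

# Resolve a user-supplied human seed (symbol or accession) to its triple.
# Accession seeds are resolved to the symbol so both entry forms query and
# report identically.
resolve_seed_triple <- function(seed, mapping) {
  by_symbol <- mapping[mapping$symbol == seed, , drop = FALSE]
  if (nrow(by_symbol) == 1L) {
    return(list(status = "ok",
                triple = list(gene_name = by_symbol$symbol,
                              swiss = by_symbol$uniprot,
                              entrez = by_symbol$entrez)))
  }
  if (nrow(by_symbol) > 1L) return(list(status = "ambiguous"))
  if (grepl(UNIPROT_PATTERN, seed)) {
    return(resolve_one_human(paste0("uniprotkb:", seed), mapping))
  }
  list(status = "unmapped")
}
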