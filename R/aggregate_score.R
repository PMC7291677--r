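# Evidence merging and confidence scoring.
#
# Evidence units from all providers are pooled onto unique undirected
# interactor pairs. Per pair, the Method Score (MS) is the number of
# distinct method categories after conversion, the Publication Score (PS)
# the number of distinct PubMed IDs, and the Final Score (FS) their sum.
# Because quality control guarantees at least one method and one PMID per
# retained record, FS >= 2 for every reported interaction; FS = 2 marks a
# single-study, single-technique interaction. Duplicate evidence (the
# same pair/category/PMID seen in several databases) counts once.

#' Canonical key for an undirected interactor pair
#'
#' Orders the two identifier triples by bytewise comparison of their
#' Swiss-Prot accessions, so that the key is invariant under swapping the
#' interactors. Self-pairs (homodimers) are valid. The seed-side
#' orientation of the output table is restored later, at aggregation
#' time; this key only serves deduplication.
#'
#' @param a,b Identifier triples: lists with `gene_name`, `swiss`,
#'   `entrez`.
#' @return List with the ordered triples `first` and `second` and a
#'   string `key`.
#' @export
canonical_pair <- function(a, b) {
  swap <- radix_order(c(a$swiss, b$swiss))[1L] == 2L
  first <- if (swap) b else a
  second <- if (swap) a else b
  list(first = first, second = second,
       key = paste(first$swiss, first$gene_name, second$swiss, second$gene_name,
                   sep = "\r"))
}

#' Merge evidence units into scored seed-centred interactions
#'
#' Groups evidence units by canonical undirected pair, keeps the pairs
#' that involve at least one seed, and scores each retained pair:
#' `Method.Score` = number of distinct method categories,
#' `Publication.Score` = number of distinct PubMed IDs, `Final.Score` =
#' their sum. The seed member is reported as interactor A; when both
#' members are seeds the pair is emitted once, oriented to the
#' lexicographically earlier gene name. Category and PMID lists are
#' sorted and joined with `;`, and rows are ordered by `NameA` then
#' `NameB`, so output is deterministic.
#'
#' @param units Evidence-unit data frame (see [filter_batch()]).
#' @param seeds Data frame of resolved seed triples with columns
#'   `gene_name`, `swiss`, `entrez`.
#' @return Data frame in the 11-column network layout (see
#'   [write_network()]); zero rows when no pair touches a seed.
#' @export
aggregate_evidence <- function(units, seeds) {
  stopifnot(is.data.frame(seeds), all(c("gene_name", "swiss", "entrez") %in% names(seeds)))
  empty <- data.frame(
    NameA = character(0), SwissA = character(0), EntrezA = character(0),
    NameB = character(0), SwissB = character(0), EntrezB = character(0),
    Method.Score = integer(0), Method = character(0),
    Publication.Score = integer(0), PMIDS = character(0),
    Final.Score = integer(0), stringsAsFactors = FALSE
  )
  if (is.null(units) || nrow(units) == 0L) return(empty)

  # orient each unit to canonical (bytewise Swiss-Prot) order
  swap <- vapply(seq_len(nrow(units)), function(i) {
    radix_order(c(units$swiss_a[i], units$swiss_b[i]))[1L] == 2L
  }, logical(1))
  pick <- function(a, b) ifelse(swap, b, a)
  name_1 <- pick(units$name_a, units$name_b)
  swiss_1 <- pick(units$swiss_a, units$swiss_b)
  entrez_1 <- pick(units$entrez_a, units$entrez_b)
  name_2 <- pick(units$name_b, units$name_a)
  swiss_2 <- pick(units$swiss_b, units$swiss_a)
  entrez_2 <- pick(units$entrez_b, units$entrez_a)
  key <- paste(swiss_1, name_1, swiss_2, name_2, sep = "\r")

  groups <- split(seq_len(nrow(units)), key)
  rows <- lapply(groups, function(ix) {
    i1 <- ix[1L]
    m1 <- list(gene_name = name_1[i1], swiss = swiss_1[i1], entrez = entrez_1[i1])
    m2 <- list(gene_name = name_2[i1], swiss = swiss_2[i1], entrez = entrez_2[i1])
    seed1 <- m1$swiss %in% seeds$swiss
    seed2 <- m2$swiss %in% seeds$swiss
    if (!seed1 && !seed2) return(NULL)
    if (seed1 && seed2) {
      # both seeds: single row, oriented to the earlier gene name
      if (radix_order(c(m1$gene_name, m2$gene_name))[1L] == 2L) {
        tmp <- m1; m1 <- m2; m2 <- tmp
      }
    } else if (!seed1) {
      tmp <- m1; m1 <- m2; m2 <- tmp
    }
    cats <- radix_sort(unique(units$category[ix]))
    pmids <- radix_sort(unique(units$pmid[ix]))
    data.frame(
      NameA = m1$gene_name, SwissA = m1$swiss, EntrezA = m1$entrez,
      NameB = m2$gene_name, SwissB = m2$swiss, EntrezB = m2$entrez,
      Method.Score = length(cats), Method = paste(cats, collapse = ";"),
      Publication.Score = length(pmids), PMIDS = paste(pmids, collapse = ";"),
      Final.Score = length(cats) + length(pmids),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[radix_order(out$NameA, out$NameB, out$SwissB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply a confidence-score threshold
#'
#' Retains interactions with `Final.Score >= min_fs`. The default of 2 is
#' the attainable floor (one method, one publication) and is a no-op;
#' raising it to 3 removes exactly the interactions lacking any
#' replication across methods or publications.
#'
#' @param interactions Scored interaction data frame from
#'   [aggregate_evidence()].
#' @param min_fs Minimum Final.Score to retain; must be at least 2, since
#'   lower scores are unattainable.
#' @return Filtered data frame.
#' @export
score_threshold <- function(interactions, min_fs = 2L) {
  if (!is.numeric(min_fs) || length(min_fs) != 1L || min_fs < 2) {
    stop("min_fs must be a single number >= 2 (scores below 2 are unattainable)",
         call. = FALSE)
  }
  out <- interactions[interactions$Final.Score >= min_fs, , drop = FALSE]
  rownames(out) <- NULL
  out
}
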