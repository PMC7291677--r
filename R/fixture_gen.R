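# Synthetic fixture generation.
#
# The generator emulates the curation landscape the pipeline is built
# for: multiple providers serving the same underlying evidence in
# slightly different MITAB dialects, with a controlled rate of
# completeness defects (missing/multiple PMIDs, missing methods, foreign
# or absent taxids, ambiguous identifier mappings). Alongside the
# provider files it writes a ground-truth manifest recording each
# record's intended fate and each pair's true (MS, PS, FS) under both
# filter modes; the manifest is computed by the generator's own
# bookkeeping, independently of the pipeline code, and is the oracle for
# the end-to-end tests. Fixtures test plumbing and scoring, not biology:
# no attempt is made at realistic network topology.

FIXTURE_PROVIDERS <- c("bhf-ucl", "biogrid", "innatedb", "intact", "mbinfo",
                       "mint", "uniprot")

MI_LABELS <- c(
  "MI:0018" = "two hybrid", "MI:0397" = "two hybrid array",
  "MI:0398" = "two hybrid pooling approach",
  "MI:0004" = "affinity chromatography technology",
  "MI:0019" = "coimmunoprecipitation", "MI:0096" = "pull down",
  "MI:0114" = "x-ray crystallography",
  "MI:0090" = "protein complementation assay",
  "MI:7777" = "uncatalogued assay"
)

#' Specification of a synthetic fixture corpus
#'
#' Bundles the generation parameters: universe size, per-record defect
#' probabilities, cross-provider overlap, the detection-method code
#' palette (which includes the three two-hybrid codes that must merge
#' into one category, plus one code deliberately absent from the
#' conversion table) and the mandatory RNG seed. Defect draws are
#' mutually exclusive per record, so each defective record has exactly
#' one injected discard reason.
#'
#' @param n_records Total MITAB record lines to write (including
#'   cross-provider duplicates).
#' @param n_seeds Number of query seed genes.
#' @param partners_per_seed Interactor pool size per seed.
#' @param p_no_pmid,p_multi_pmid,p_no_method,p_wrong_taxid,p_no_taxid,p_ambiguous
#'   Per-record defect probabilities (mutually exclusive draws).
#'   `p_no_taxid` records stay valid under lenient filtering but fail the
#'   stringent completeness screen; `p_ambiguous` records point at an
#'   interactor whose accession maps to two Entrez IDs.
#' @param overlap Probability that a record is a cross-provider duplicate
#'   of earlier evidence (same content, different database).
#' @param mi_palette Detection-method codes to sample from; must include
#'   at least one code absent from the generated conversion table.
#' @param providers Provider directory names to distribute records over.
#' @param rng_seed Mandatory integer RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_records = 500L,
                         n_seeds = 6L,
                         partners_per_seed = 8L,
                         p_no_pmid = 0.05,
                         p_multi_pmid = 0.05,
                         p_no_method = 0.05,
                         p_wrong_taxid = 0.05,
                         p_no_taxid = 0.05,
                         p_ambiguous = 0.05,
                         overlap = 0.3,
                         mi_palette = names(MI_LABELS),
                         providers = FIXTURE_PROVIDERS,
                         rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory (reproducibility)", call. = FALSE)
  probs <- c(p_no_pmid, p_multi_pmid, p_no_method, p_wrong_taxid, p_no_taxid, p_ambiguous)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1) {
    stop("defect probabilities must lie in [0,1] and sum to at most 1", call. = FALSE)
  }
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0,1]", call. = FALSE)
  structure(list(
    n_records = as.integer(n_records), n_seeds = as.integer(n_seeds),
    partners_per_seed = as.integer(partners_per_seed),
    p_no_pmid = p_no_pmid, p_multi_pmid = p_multi_pmid,
    p_no_method = p_no_method, p_wrong_taxid = p_wrong_taxid,
    p_no_taxid = p_no_taxid, p_ambiguous = p_ambiguous,
    overlap = overlap, mi_palette = mi_palette, providers = providers,
    rng_seed = as.integer(rng_seed)
  ), class = "fixture_spec")
}

mi_term <- function(code, quoted = TRUE) {
  label <- MI_LABELS[code]
  label[is.na(label)] <- "assay"
  if (quoted) sprintf('psi-mi:"%s"(%s)', code, label)
  else sprintf("psi-mi:%s(%s)", code, label)
}

#' Generate a synthetic offline fixture corpus with a ground-truth manifest
#'
#' Writes the offline directory layout consumed by
#' [fetch_seed_records()] (`<out_dir>/<provider>/<seed>.mitab`, every
#' provider/seed combination present, each provider using a slightly
#' different MITAB dialect), an identifier-mapping snapshot
#' (`mapping.tsv`, including deliberately ambiguous entries), a
#' detection-method conversion table (`method_table.tsv`, the two-hybrid
#' codes grouped into one category and one palette code deliberately
#' absent), and a JSON manifest (`manifest.json`) with per-record fates
#' and per-pair true scores under both filter modes.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list (`seeds`, `partners`,
#'   `records`, `pairs_lenient`, `pairs_stringent`, `paths`).
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(spec$rng_seed)

  ns <- spec$n_seeds
  np <- ns * spec$partners_per_seed
  seeds <- data.frame(
    symbol = sprintf("SEED%d", seq_len(ns)),
    uniprot = sprintf("P%05d", 10000L + seq_len(ns)),
    entrez = as.character(1000L + seq_len(ns)),
    stringsAsFactors = FALSE
  )
  partners <- data.frame(
    symbol = sprintf("PART%d", seq_len(np)),
    uniprot = sprintf("P%05d", 20000L + seq_len(np)),
    entrez = as.character(20000L + seq_len(np)),
    stringsAsFactors = FALSE
  )
  # accessions that map to two Entrez IDs -> resolution must fail
  ambig <- data.frame(
    symbol = c("AMBIG1", "AMBIG1", "AMBIG2", "AMBIG2"),
    uniprot = c("P30001", "P30001", "P30002", "P30002"),
    entrez = c("30001", "30011", "30002", "30012"),
    stringsAsFactors = FALSE
  )

  # each seed interacts with a fixed partner subset
  partner_sets <- lapply(seq_len(ns), function(i) {
    sample(np, spec$partners_per_seed)
  })
  # two candidate PMIDs per potential pair, so distinct-publication
  # counts vary between 1 and 2 plus whatever multi-defects inject
  pair_pmids <- new.env(parent = emptyenv())
  pmid_for <- function(key) {
    if (is.null(pair_pmids[[key]])) {
      pair_pmids[[key]] <- sprintf("%08d", sample.int(99999999L, 2L))
    }
    sample(pair_pmids[[key]], 1L)
  }

  defect_levels <- c("clean", "no_pmid", "multi_pmid", "no_method",
                     "wrong_taxid", "no_taxid", "ambiguous")
  defect_probs <- c(1 - (spec$p_no_pmid + spec$p_multi_pmid + spec$p_no_method +
                           spec$p_wrong_taxid + spec$p_no_taxid + spec$p_ambiguous),
                    spec$p_no_pmid, spec$p_multi_pmid, spec$p_no_method,
                    spec$p_wrong_taxid, spec$p_no_taxid, spec$p_ambiguous)

  n <- spec$n_records
  recs <- vector("list", n)
  for (r in seq_len(n)) {
    is_dup <- r > 1L && stats::runif(1) < spec$overlap
    if (is_dup) {
      base <- recs[[sample.int(r - 1L, 1L)]]
      rec <- base
      others <- setdiff(spec$providers, base$provider)
      rec$provider <- if (length(others)) sample(others, 1L) else base$provider
      rec$duplicate_of <- base$rec_id
    } else {
      si <- sample.int(ns, 1L)
      defect <- sample(defect_levels, 1L, prob = defect_probs)
      if (defect == "ambiguous") {
        pj <- sample.int(2L, 1L)
        partner <- list(symbol = c("AMBIG1", "AMBIG2")[pj],
                        uniprot = c("P30001", "P30002")[pj])
      } else {
        pj <- partner_sets[[si]][sample.int(spec$partners_per_seed, 1L)]
        partner <- list(symbol = partners$symbol[pj], uniprot = partners$uniprot[pj])
      }
      code <- sample(spec$mi_palette, 1L)
      key <- paste(seeds$symbol[si], partner$symbol, sep = "~")
      pmid <- pmid_for(key)
      rec <- list(
        seed = seeds$symbol[si], seed_acc = seeds$uniprot[si],
        partner = partner$symbol, partner_acc = partner$uniprot,
        code = code, pmid = pmid,
        pmid2 = if (defect == "multi_pmid") sprintf("%08d", sample.int(99999999L, 1L)) else NA_character_,
        defect = defect,
        flipped = stats::runif(1) < 0.5,
        provider = sample(spec$providers, 1L),
        duplicate_of = NA_integer_
      )
    }
    rec$rec_id <- r
    recs[[r]] <- rec
  }

  method_table <- fixture_method_table(spec$mi_palette)
  manifest_records <- build_manifest_records(recs, method_table)
  pairs_lenient <- tally_pairs(manifest_records, mode = "lenient")
  pairs_stringent <- tally_pairs(manifest_records, mode = "stringent")

  paths <- write_fixture_files(spec, out_dir, recs, seeds, partners, ambig,
                               method_table, manifest_records)
  manifest_records$file <- paths$record_files
  manifest_records$file_line <- paths$record_lines

  manifest <- list(
    rng_seed = spec$rng_seed,
    n_records = n,
    seeds = seeds,
    partners = partners,
    records = manifest_records,
    pairs_lenient = pairs_lenient,
    pairs_stringent = pairs_stringent,
    paths = paths$top
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", na = "null",
                       pretty = TRUE)
  invisible(manifest)
}

# conversion table covering the palette except codes >= MI:7000, which
# stay deliberately out-of-table
fixture_method_table <- function(palette) {
  groups <- c(
    "MI:0018" = "Two Hybrid (2Hyb)", "MI:0397" = "Two Hybrid (2Hyb)",
    "MI:0398" = "Two Hybrid (2Hyb)",
    "MI:0004" = "Affinity Purification (AP)", "MI:0019" = "Affinity Purification (AP)",
    "MI:0096" = "Affinity Purification (AP)",
    "MI:0114" = "Structure (Struct)", "MI:0090" = "Complementation (PCA)"
  )
  keep <- intersect(palette, names(groups))
  groups[keep]
}

# Generator-side fate bookkeeping: mirrors the documented QC rules by
# direct table lookup on the injected defect, not by running the
# pipeline.
build_manifest_records <- function(recs, method_table) {
  n <- length(recs)
  df <- data.frame(
    rec_id = vapply(recs, `[[`, integer(1), "rec_id"),
    provider = vapply(recs, `[[`, character(1), "provider"),
    seed = vapply(recs, `[[`, character(1), "seed"),
    partner = vapply(recs, `[[`, character(1), "partner"),
    code = vapply(recs, `[[`, character(1), "code"),
    pmid = vapply(recs, `[[`, character(1), "pmid"),
    defect = vapply(recs, `[[`, character(1), "defect"),
    duplicate_of = vapply(recs, function(r) as.integer(r$duplicate_of), integer(1)),
    stringsAsFactors = FALSE
  )
  code_mapped <- df$code %in% names(method_table)
  reason_map <- c(no_pmid = "no_pmid", multi_pmid = "multiple_pmids",
                  no_method = "no_method", wrong_taxid = "wrong_taxid",
                  ambiguous = "ambiguous")

  df$lenient_fate <- ifelse(df$defect %in% c("clean", "no_taxid"), "retained", "discarded")
  df$lenient_reason <- ifelse(df$lenient_fate == "retained", NA_character_,
                              unname(reason_map[df$defect]))
  df$lenient_category <- ifelse(df$lenient_fate == "retained",
                                ifelse(code_mapped, unname(method_table[df$code]), df$code),
                                NA_character_)

  stringent_retained <- df$defect == "clean" & code_mapped
  df$stringent_fate <- ifelse(stringent_retained, "retained", "discarded")
  df$stringent_reason <- ifelse(stringent_retained, NA_character_,
                                ifelse(df$defect == "clean" & !code_mapped, "unmapped_method",
                                       ifelse(df$defect == "no_taxid", "missing_taxid",
                                              unname(reason_map[df$defect]))))
  df$stringent_category <- ifelse(stringent_retained, unname(method_table[df$code]),
                                  NA_character_)
  df
}

# independent per-pair tally of distinct categories and publications
tally_pairs <- function(manifest_records, mode) {
  fate <- manifest_records[[paste0(mode, "_fate")]]
  cat_col <- manifest_records[[paste0(mode, "_category")]]
  kept <- manifest_records[fate == "retained", , drop = FALSE]
  kept_cat <- cat_col[fate == "retained"]
  if (!nrow(kept)) {
    return(data.frame(name_a = character(0), name_b = character(0),
                      ms = integer(0), ps = integer(0), fs = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(kept$seed, kept$partner, sep = "~")
  out <- lapply(split(seq_len(nrow(kept)), key), function(ix) {
    ms <- length(unique(kept_cat[ix]))
    ps <- length(unique(kept$pmid[ix]))
    data.frame(name_a = kept$seed[ix[1]], name_b = kept$partner[ix[1]],
               ms = ms, ps = ps, fs = ms + ps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[radix_order(out$name_a, out$name_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_fixture_files <- function(spec, out_dir, recs, seeds, partners, ambig,
                                method_table, manifest_records) {
  # per-provider dialects cycle over a few axes of MITAB heterogeneity
  dialects <- lapply(seq_along(spec$providers), function(i) {
    list(ncol = if (i %% 2L == 0L) 17L else 15L,
         quoted = i %% 3L != 0L,
         alt_entrez = i %% 2L == 1L,
         header = i %% 2L == 0L,
         extra_ref = i %% 4L == 0L)
  })
  names(dialects) <- spec$providers

  entrez_of <- function(symbol) {
    i <- match(symbol, seeds$symbol)
    if (!is.na(i)) return(seeds$entrez[i])
    j <- match(symbol, partners$symbol)
    if (!is.na(j)) return(partners$entrez[j])
    NA_character_
  }

  make_line <- function(rec, d) {
    a_acc <- rec$seed_acc; b_acc <- rec$partner_acc
    a_sym <- rec$seed; b_sym <- rec$partner
    if (isTRUE(rec$flipped)) {
      tmp <- a_acc; a_acc <- b_acc; b_acc <- tmp
      tmp <- a_sym; a_sym <- b_sym; b_sym <- tmp
    }
    alt <- function(sym) {
      ez <- entrez_of(sym)
      if (d$alt_entrez && !is.na(ez)) sprintf("entrez gene/locuslink:%s", ez) else "-"
    }
    col7 <- if (rec$defect == "no_method") "-" else mi_term(rec$code, d$quoted)
    col9 <- if (rec$defect == "no_pmid") {
      if (d$extra_ref) "imex:IM-12345-1" else "-"
    } else if (rec$defect == "multi_pmid") {
      sprintf("pubmed:%s|pubmed:%s", rec$pmid, rec$pmid2)
    } else if (d$extra_ref) {
      sprintf("pubmed:%s|imex:IM-%s-1", rec$pmid, rec$pmid)
    } else {
      sprintf("pubmed:%s", rec$pmid)
    }
    tax_a <- "taxid:9606(human)"
    tax_b <- "taxid:9606(human)"
    if (rec$defect == "wrong_taxid") tax_b <- "taxid:10090(mouse)"
    if (rec$defect == "no_taxid") tax_a <- tax_b <- "-"
    fields <- c(
      sprintf("uniprotkb:%s", a_acc), sprintf("uniprotkb:%s", b_acc),
      alt(a_sym), alt(b_sym),
      sprintf("uniprotkb:%s(gene name)", a_sym),
      sprintf("uniprotkb:%s(gene name)", b_sym),
      col7, "-", col9, tax_a, tax_b,
      if (d$quoted) 'psi-mi:"MI:0915"(physical association)' else "psi-mi:MI:0915(physical association)",
      sprintf("psi-mi:\"MI:0000\"(%s)", rec$provider),
      sprintf("%s:EBI-%07d", rec$provider, rec$rec_id), "-"
    )
    if (d$ncol > 15L) fields <- c(fields, rep("-", d$ncol - 15L))
    paste(fields, collapse = "\t")
  }

  # group records into per-provider, per-seed files
  file_of <- character(length(recs))
  line_of <- integer(length(recs))
  for (pr in spec$providers) {
    dir.create(file.path(out_dir, pr), showWarnings = FALSE)
    d <- dialects[[pr]]
    for (s in seeds$symbol) {
      path <- file.path(out_dir, pr, paste0(s, ".mitab"))
      sel <- which(vapply(recs, function(r) r$provider == pr && r$seed == s, logical(1)))
      lines <- character(0)
      offset <- 0L
      if (d$header) {
        lines <- "#ID(s) interactor A\tID(s) interactor B\tAlt. ID(s) A\tAlt. ID(s) B\tAlias(es) A\tAlias(es) B\tInteraction detection method(s)\tPublication 1st author(s)\tPublication Identifier(s)\tTaxid interactor A\tTaxid interactor B\tInteraction type(s)\tSource database(s)\tInteraction identifier(s)\tConfidence value(s)"
        offset <- 1L
      }
      for (k in seq_along(sel)) {
        lines <- c(lines, make_line(recs[[sel[k]]], d))
        file_of[sel[k]] <- file.path(pr, paste0(s, ".mitab"))
        line_of[sel[k]] <- offset + k
      }
      writeLines(lines, path)
    }
  }

  mapping_path <- file.path(out_dir, "mapping.tsv")
  map <- rbind(seeds, partners, ambig)
  writeLines(c("symbol\tuniprot\tentrez",
               paste(map$symbol, map$uniprot, map$entrez, sep = "\t")),
             mapping_path)

  table_path <- file.path(out_dir, "method_table.tsv")
  writeLines(c("mi_code\tcategory",
               paste(names(method_table), unname(method_table), sep = "\t")),
             table_path)

  # manifest paths are corpus-relative, so fixtures stay byte-identical
  # wherever they are generated
  list(top = list(mapping = "mapping.tsv", method_table = "method_table.tsv",
                  offline_root = "."),
       record_files = file_of, record_lines = line_of)
}

#' Generate a synthetic C. elegans interaction dump
#'
#' Writes a MITAB-like dump of WBGene-identified interactions with a
#' controlled number of records lacking PMIDs or carrying a foreign
#' taxid, and returns the injected truth for each record.
#'
#' @param path Output file path.
#' @param n_genes Gene universe size.
#' @param n_records Number of interaction records.
#' @param n_no_pmid Exact number of records written without a PMID.
#' @param n_wrong_taxid Exact number of records written with a human
#'   taxid (must be discarded by the worm build).
#' @param rng_seed Mandatory integer RNG seed.
#' @return Data frame with one row per record: `gene_a`, `gene_b`,
#'   `code`, `pmid`, `defect`.
#' @export
generate_worm_dump <- function(path, n_genes = 6L, n_records = 8L,
                               n_no_pmid = 2L, n_wrong_taxid = 0L, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory (reproducibility)", call. = FALSE)
  stopifnot(n_no_pmid + n_wrong_taxid <= n_records)
  set.seed(rng_seed)
  genes <- sprintf("WBGene%08d", seq_len(n_genes))
  defect <- sample(c(rep("no_pmid", n_no_pmid), rep("wrong_taxid", n_wrong_taxid),
                     rep("clean", n_records - n_no_pmid - n_wrong_taxid)))
  truth <- data.frame(
    gene_a = genes[sample.int(n_genes, n_records, replace = TRUE)],
    gene_b = genes[sample.int(n_genes, n_records, replace = TRUE)],
    code = sample(c("MI:0018", "MI:0397", "MI:0004", "MI:0114"), n_records, replace = TRUE),
    pmid = sprintf("%08d", sample.int(99999999L, n_records, replace = TRUE)),
    defect = defect,
    stringsAsFactors = FALSE
  )
  lines <- vapply(seq_len(n_records), function(i) {
    tax <- if (truth$defect[i] == "wrong_taxid") "taxid:9606(human)" else "taxid:6239(caenorhabditis elegans)"
    col9 <- if (truth$defect[i] == "no_pmid") "-" else sprintf("pubmed:%s", truth$pmid[i])
    paste(c(
      sprintf("wormbase:%s", truth$gene_a[i]), sprintf("wormbase:%s", truth$gene_b[i]),
      "-", "-", "-", "-", mi_term(truth$code[i]), "-", col9, tax, tax,
      'psi-mi:"MI:0915"(physical association)', "wormbase", sprintf("wb:%d", i), "-"
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(truth)
}
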