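# Shared in-code fixtures: a MITAB line builder, miniature mapping and
# method tables, triple/unit constructors and a deliberately naive
# brute-force scoring oracle used to cross-check the aggregator.

mitab_line <- function(id_a = "uniprotkb:P99999", id_b = "uniprotkb:P37840",
                       alt_a = "-", alt_b = "-",
                       method = 'psi-mi:"MI:0018"(two hybrid)',
                       pub = "pubmed:12345678",
                       tax_a = "taxid:9606(human)", tax_b = "taxid:9606(human)",
                       ncol = 15L) {
  fields <- c(id_a, id_b, alt_a, alt_b, "-", "-", method, "-", pub, tax_a, tax_b,
              'psi-mi:"MI:0915"(physical association)',
              'psi-mi:"MI:0469"(IntAct)', "intact:EBI-0000001", "-")
  if (ncol > 15L) fields <- c(fields, rep("-", ncol - 15L))
  paste(fields, collapse = "\t")
}

tiny_mapping <- function() {
  df <- data.frame(
    symbol = c("CYCS", "SNCA", "PINK1", "PRKN", "LRRK2", "AMBX", "AMBX"),
    uniprot = c("P99999", "P37840", "Q9BXM7", "O60260", "Q5S007", "P77777", "P77777"),
    entrez = c("54205", "6622", "65018", "5071", "120892", "77001", "77002"),
    stringsAsFactors = FALSE
  )
  structure(df, class = c("mapping_table", "data.frame"))
}

tiny_method_table <- function() {
  structure(
    c("MI:0018" = "Two Hybrid (2Hyb)", "MI:0397" = "Two Hybrid (2Hyb)",
      "MI:0398" = "Two Hybrid (2Hyb)", "MI:0004" = "Affinity Purification (AP)",
      "MI:0114" = "Structure (Struct)"),
    class = "method_table"
  )
}

tri <- function(sym, acc, ez = paste0("E", acc)) {
  list(gene_name = sym, swiss = acc, entrez = ez)
}

make_unit <- function(a, b, category, pmid, db = "intact", line_no = 1L) {
  data.frame(
    name_a = a$gene_name, swiss_a = a$swiss, entrez_a = a$entrez,
    name_b = b$gene_name, swiss_b = b$swiss, entrez_b = b$entrez,
    category = category, pmid = pmid, source_db = db, line_no = line_no,
    record_uid = paste(db, line_no, sep = ":"),
    stringsAsFactors = FALSE
  )
}

seeds_df <- function(...) {
  triples <- list(...)
  do.call(rbind, lapply(triples, function(t) {
    data.frame(gene_name = t$gene_name, swiss = t$swiss, entrez = t$entrez,
               stringsAsFactors = FALSE)
  }))
}

# Naive nested-loop recount of per-pair distinct categories/publications;
# pair identity by unordered set comparison of the Swiss-Prot accessions.
brute_scores <- function(units) {
  pairs <- list()
  for (i in seq_len(nrow(units))) {
    members <- sort(c(units$swiss_a[i], units$swiss_b[i]))
    found <- FALSE
    for (j in seq_along(pairs)) {
      if (identical(pairs[[j]]$members, members)) {
        pairs[[j]]$cats <- c(pairs[[j]]$cats, units$category[i])
        pairs[[j]]$pmids <- c(pairs[[j]]$pmids, units$pmid[i])
        found <- TRUE
        break
      }
    }
    if (!found) {
      pairs[[length(pairs) + 1L]] <- list(members = members,
                                          cats = units$category[i],
                                          pmids = units$pmid[i])
    }
  }
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(swiss_lo = p$members[1], swiss_hi = p$members[2],
               ms = length(unique(p$cats)), ps = length(unique(p$pmids)),
               fs = length(unique(p$cats)) + length(unique(p$pmids)),
               stringsAsFactors = FALSE)
  }))
}

# fixture corpus + loaded tables, generated fresh in a temp dir
make_fixture <- function(n_records, rng_seed, ...) {
  td <- tempfile("fixture")
  dir.create(td)
  manifest <- generate_fixtures(fixture_spec(n_records = n_records,
                                             rng_seed = rng_seed, ...), td)
  list(
    dir = td,
    manifest = manifest,
    method_table = load_method_table(file.path(td, "method_table.tsv")),
    mapping = read_mapping_table(file.path(td, "mapping.tsv"))
  )
}

network_as_truth <- function(network) {
  got <- network[, c("NameA", "NameB", "Method.Score", "Publication.Score", "Final.Score")]
  names(got) <- c("name_a", "name_b", "ms", "ps", "fs")
  rownames(got) <- NULL
  got
}
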