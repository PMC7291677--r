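test_that("detection codes, pmids and taxids are extracted from MITAB columns", {
  line <- mitab_line(method = 'psi-mi:"MI:0018"(two hybrid)',
                     pub = "pubmed:12345678|imex:IM-12345-1",
                     tax_a = "taxid:9606(human)", tax_b = "taxid:10090(mouse)")
  parsed <- parse_mitab(line, "IntAct")
  rec <- parsed$records
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$source_db, "intact")
  expect_equal(rec$detection_codes[[1]], "MI:0018")
  expect_equal(rec$pmids[[1]], "12345678")  # non-pubmed references ignored
  expect_equal(rec$taxid_a, 9606L)
  expect_equal(rec$taxid_b, 10090L)
  expect_equal(rec$id_a, "uniprotkb:P99999")
})

test_that("parser tolerates dialect variation and null markers", {
  unquoted <- mitab_line(method = "psi-mi:MI:0397(two hybrid array)", ncol = 17L)
  rec <- parse_mitab(unquoted, "biogrid")$records
  expect_equal(rec$detection_codes[[1]], "MI:0397")

  nulls <- mitab_line(method = "-", pub = "-", tax_a = "-", tax_b = "-")
  rec <- parse_mitab(nulls, "mint")$records
  expect_length(rec$detection_codes[[1]], 0L)
  expect_length(rec$pmids[[1]], 0L)
  expect_true(is.na(rec$taxid_a))

  multi <- mitab_line(method = 'psi-mi:"MI:0018"(two hybrid)|psi-mi:"MI:0004"(affinity chromatography)',
                      pub = "pubmed:111|pubmed:222",
                      alt_a = "entrez gene/locuslink:54205|ensembl:ENSG1")
  rec <- parse_mitab(multi, "uniprot")$records
  expect_equal(rec$detection_codes[[1]], c("MI:0018", "MI:0004"))
  expect_equal(rec$pmids[[1]], c("111", "222"))
  expect_equal(rec$alt_ids_a[[1]], c("entrez gene/locuslink:54205", "ensembl:ENSG1"))
})

test_that("empty input and comment lines yield no records", {
  expect_equal(nrow(parse_mitab(character(0), "intact")$records), 0L)
  expect_equal(nrow(parse_mitab(c("# header", "", "   "), "intact")$records), 0L)
})

test_that("short lines are reported as malformed, never fatal", {
  lines <- c("#header", vapply(1:5, function(i) mitab_line(pub = paste0("pubmed:", i)),
                               character(1)),
             "too\tfew\tcolumns")
  parsed <- parse_mitab(lines, "intact")
  expect_equal(nrow(parsed$records), 5L)
  expect_equal(nrow(parsed$malformed), 1L)
  expect_equal(parsed$malformed$reason, "malformed_line")
  expect_equal(parsed$malformed$line_no, 7L)
})

test_that("parsing is lossless for QC-relevant fields on generated corpora", {
  fx <- make_fixture(n_records = 60, rng_seed = 311)
  mr <- fx$manifest$records
  for (i in sample(nrow(mr), 10L)) {
    parsed <- parse_mitab(file.path(fx$dir, mr$file[i]), mr$provider[i])
    rec <- parsed$records[parsed$records$line_no == mr$file_line[i], ]
    if (mr$defect[i] == "no_method") {
      expect_length(rec$detection_codes[[1]], 0L)
    } else {
      expect_equal(rec$detection_codes[[1]], mr$code[i])
    }
    if (mr$defect[i] == "no_pmid") {
      expect_length(rec$pmids[[1]], 0L)
    } else if (mr$defect[i] != "multi_pmid") {
      expect_equal(rec$pmids[[1]], mr$pmid[i])
    } else {
      expect_length(unique(rec$pmids[[1]]), 2L)
    }
  }
})

test_that("network writing produces the 11-column table and round-trips", {
  path <- tempfile(fileext = ".txt")

  write_network(aggregate_evidence(empty_units <- make_unit(tri("A", "P1"), tri("B", "P2"),
                                                            "x", "1")[0, ],
                                   seeds_df(tri("A", "P1"))), path)
  lines <- readLines(path)
  expect_equal(lines, paste(c("NameA", "SwissA", "EntrezA", "NameB", "SwissB",
                              "EntrezB", "Method.Score", "Method",
                              "Publication.Score", "PMIDS", "Final.Score"),
                            collapse = "\t"))

  a <- tri("SNCA", "P37840", "6622")
  b <- tri("CYCS", "P99999", "54205")
  units <- rbind(make_unit(a, b, "Two Hybrid (2Hyb)", "111"),
                 make_unit(a, b, "Affinity Purification (AP)", "222"))
  net <- aggregate_evidence(units, seeds_df(a))
  write_network(net, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2L)
  expect_equal(lengths(strsplit(lines, "\t", fixed = TRUE)), c(11L, 11L))
  expect_equal(read_network(path), net)
})

test_that("every written data line has exactly ten tabs even for hostile labels", {
  a <- tri("SNCA", "P37840", "6622")
  b <- tri("BAD\tGENE", "P99999", "54205")
  units <- make_unit(a, b, "odd\tcategory", "111")
  net <- aggregate_evidence(units, seeds_df(a))
  path <- tempfile()
  write_network(net, path)
  body <- readLines(path)[-1]
  expect_true(all(lengths(gregexpr("\t", body, fixed = TRUE)) == 10L))
})

test_that("invalid output rows are rejected by the writer", {
  bad <- data.frame(NameA = "A", SwissA = "P1", EntrezA = "1",
                    NameB = "B", SwissB = "P2", EntrezB = "2",
                    Method.Score = 2L, Method = "x",  # claims 2, lists 1
                    Publication.Score = 1L, PMIDS = "111",
                    Final.Score = 3L, stringsAsFactors = FALSE)
  expect_error(write_network(bad, tempfile()), "invalid output rows")
})

test_that("log files list discarded seeds and providers with statuses", {
  report <- list(
    seeds = data.frame(seed = c("SNCA", "FAKEGENE"), status = c("ok", "unmapped"),
                       stringsAsFactors = FALSE),
    discards = data.frame(stage = "pmid", reason = "no_pmid", source_db = "intact",
                          line_no = 3L, record_uid = "intact:3", item = "a|b",
                          stringsAsFactors = FALSE),
    providers = data.frame(name = default_providers()$name, state = "responded",
                           records_returned = 5L, stringsAsFactors = FALSE)
  )
  d <- tempfile(); dir.create(d)
  write_logs(report, d, "human")
  log <- readLines(file.path(d, "final_network_log.txt"))
  expect_true(any(grepl("FAKEGENE\tunmapped", log)))
  expect_true(any(grepl("no_pmid", log)))
  prov <- readLines(file.path(d, "final_network_providers.txt"))
  expect_length(prov, 7L)

  # empty report -> files exist with empty bodies
  d2 <- tempfile(); dir.create(d2)
  write_logs(list(seeds = NULL, discards = NULL, providers = NULL), d2, "human")
  expect_length(readLines(file.path(d2, "final_network_log.txt")), 0L)
  expect_length(readLines(file.path(d2, "final_network_providers.txt")), 0L)

  # worm runs get no providers file
  d3 <- tempfile(); dir.create(d3)
  write_logs(report, d3, "celegans")
  expect_false(file.exists(file.path(d3, "final_network_providers.txt")))
})
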