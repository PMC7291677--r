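qc_batch <- function(lines, mode = "lenient", mapping = tiny_mapping(),
                     table = tiny_method_table()) {
  records <- parse_mitab(lines, "intact")$records
  filter_batch(records, "human", table, mapping, mode)
}

test_that("completeness screens discard with the documented reasons", {
  res <- qc_batch(mitab_line(pub = "-"))
  expect_equal(res$discards$reason, "no_pmid")
  expect_equal(res$discards$stage, "pmid")

  res <- qc_batch(mitab_line(pub = "pubmed:111|pubmed:222"))
  expect_equal(res$discards$reason, "multiple_pmids")

  res <- qc_batch(mitab_line(method = "-"))
  expect_equal(res$discards$reason, "no_method")
  expect_equal(res$discards$stage, "method")

  res <- qc_batch(mitab_line(tax_b = "taxid:10090(mouse)"))
  expect_equal(res$discards$reason, "wrong_taxid")

  res <- qc_batch(mitab_line(id_b = "uniprotkb:P77777"))
  expect_equal(res$discards$reason, "ambiguous")
  expect_equal(res$discards$stage, "mapping")

  res <- qc_batch(mitab_line(id_b = "uniprotkb:P00000"))
  expect_equal(res$discards$reason, "unmapped")
})

test_that("repeated identical pubmed tokens are one publication, not several", {
  res <- qc_batch(mitab_line(pub = "pubmed:111|pubmed:111"))
  expect_equal(nrow(res$units), 1L)
  expect_equal(res$units$pmid, "111")
})

test_that("a complete record yields one evidence unit per detection code", {
  res <- qc_batch(mitab_line(
    method = 'psi-mi:"MI:0018"(two hybrid)|psi-mi:"MI:0004"(affinity chromatography)'))
  expect_equal(nrow(res$units), 2L)
  expect_setequal(res$units$category,
                  c("Two Hybrid (2Hyb)", "Affinity Purification (AP)"))
  expect_equal(unique(res$units$pmid), "12345678")
  expect_equal(res$units$name_a[1], "CYCS")
  expect_equal(res$units$name_b[1], "SNCA")
})

test_that("self-interactions are retained", {
  res <- qc_batch(mitab_line(id_a = "uniprotkb:P37840", id_b = "uniprotkb:P37840"))
  expect_equal(nrow(res$units), 1L)
  expect_equal(res$units$swiss_a, res$units$swiss_b)
})

test_that("stringent mode additionally enforces completeness", {
  # missing taxid tolerated leniently, discarded stringently
  line <- mitab_line(tax_a = "-", tax_b = "-")
  expect_equal(nrow(qc_batch(line, "lenient")$units), 1L)
  res <- qc_batch(line, "stringent")
  expect_equal(res$discards$reason, "missing_taxid")

  # out-of-table code: singleton category vs discard
  line <- mitab_line(method = 'psi-mi:"MI:9999"(exotic assay)')
  len <- qc_batch(line, "lenient")
  expect_equal(len$units$category, "MI:9999")
  str <- qc_batch(line, "stringent")
  expect_equal(str$discards$reason, "unmapped_method")

  # mixed codes: stringent keeps only the mapped one
  line <- mitab_line(method = 'psi-mi:"MI:0018"(two hybrid)|psi-mi:"MI:9999"(exotic)')
  str <- qc_batch(line, "stringent")
  expect_equal(str$units$category, "Two Hybrid (2Hyb)")
})

test_that("batch filtering conserves records and is pure", {
  lines <- c(
    vapply(1:6, function(i) mitab_line(pub = paste0("pubmed:", 100 + i)), character(1)),
    mitab_line(pub = "-"),
    mitab_line(pub = "-"),
    mitab_line(pub = "pubmed:1|pubmed:2"),
    mitab_line(tax_a = "taxid:10090(mouse)")
  )
  records <- parse_mitab(lines, "intact")$records
  res <- filter_batch(records, "human", tiny_method_table(), tiny_mapping(), "lenient")
  expect_equal(length(unique(res$units$record_uid)) + nrow(res$discards), 10L)
  expect_equal(nrow(res$discards), 4L)
  expect_equal(sort(res$discards$reason),
               sort(c("no_pmid", "no_pmid", "multiple_pmids", "wrong_taxid")))

  res2 <- filter_batch(records, "human", tiny_method_table(), tiny_mapping(), "lenient")
  expect_identical(res, res2)

  empty <- filter_batch(records[0, ], "human", tiny_method_table(), tiny_mapping())
  expect_equal(nrow(empty$units), 0L)
  expect_equal(nrow(empty$discards), 0L)
})

test_that("stringent evidence is a subset of lenient evidence on random corpora", {
  for (s in c(741, 742)) {
    fx <- make_fixture(n_records = 120, rng_seed = s)
    records <- do.call(rbind, lapply(FIXTURE_SEEDS <- fx$manifest$seeds$symbol, function(seed) {
      fetch_seed_records(seed, offline_root = fx$dir)$records
    }))
    len <- filter_batch(records, "human", fx$method_table, fx$mapping, "lenient")
    str <- filter_batch(records, "human", fx$method_table, fx$mapping, "stringent")
    len_keys <- paste(len$units$record_uid, len$units$category, len$units$pmid)
    str_keys <- paste(str$units$record_uid, str$units$category, str$units$pmid)
    expect_true(all(str_keys %in% len_keys))
    expect_lte(nrow(str$units), nrow(len$units))
  }
})

test_that("no retained evidence carries a foreign taxid", {
  fx <- make_fixture(n_records = 150, rng_seed = 955, p_wrong_taxid = 0.3)
  for (seed in fx$manifest$seeds$symbol) {
    records <- fetch_seed_records(seed, offline_root = fx$dir)$records
    res <- filter_batch(records, "human", fx$method_table, fx$mapping, "lenient")
    kept <- records[records$record_uid %in% res$units$record_uid, ]
    expect_true(all(is.na(kept$taxid_a) | kept$taxid_a == 9606L))
    expect_true(all(is.na(kept$taxid_b) | kept$taxid_b == 9606L))
  }
})
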