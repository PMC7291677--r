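test_that("canonical pair key is order-invariant and supports homodimers", {
  a <- tri("SNCA", "P37840")
  b <- tri("CYCS", "P99999")
  expect_equal(canonical_pair(a, b)$key, canonical_pair(b, a)$key)
  expect_equal(canonical_pair(a, b)$first$swiss, "P37840")
  self <- canonical_pair(a, a)
  expect_equal(self$first, self$second)
})

test_that("key equality is equivalent to unordered pair equality (100 random pairs)", {
  set.seed(515)
  pool <- lapply(1:12, function(i) tri(sprintf("G%d", i), sprintf("P%05d", i)))
  pairs <- replicate(100, sample(12, 2, replace = TRUE), simplify = FALSE)
  for (i in seq_along(pairs)) {
    for (j in seq_along(pairs)) {
      ki <- canonical_pair(pool[[pairs[[i]][1]]], pool[[pairs[[i]][2]]])$key
      kj <- canonical_pair(pool[[pairs[[j]][1]]], pool[[pairs[[j]][2]]])$key
      same_set <- setequal(pairs[[i]], pairs[[j]]) &&
        identical(sort(pairs[[i]]), sort(pairs[[j]]))
      expect_equal(ki == kj, same_set)
    }
  }
})

test_that("single-evidence interaction scores MS=1, PS=1, FS=2", {
  s <- tri("SNCA", "P37840", "6622")
  x <- tri("CYCS", "P99999", "54205")
  net <- aggregate_evidence(make_unit(s, x, "Two Hybrid (2Hyb)", "111"), seeds_df(s))
  expect_equal(nrow(net), 1L)
  expect_equal(net$Method.Score, 1L)
  expect_equal(net$Publication.Score, 1L)
  expect_equal(net$Final.Score, 2L)
  expect_equal(net$NameA, "SNCA")  # seed side reported as interactor A
  expect_equal(net$NameB, "CYCS")
})

test_that("evidence merged across providers and orientations counts once", {
  s <- tri("SNCA", "P37840", "6622")
  x <- tri("CYCS", "P99999", "54205")
  units <- rbind(
    make_unit(s, x, "Two Hybrid (2Hyb)", "111", db = "intact"),
    make_unit(x, s, "Two Hybrid (2Hyb)", "111", db = "biogrid", line_no = 9L),
    make_unit(s, x, "Affinity Purification (AP)", "111", db = "mint", line_no = 3L),
    make_unit(x, s, "Two Hybrid (2Hyb)", "222", db = "uniprot", line_no = 4L)
  )
  net <- aggregate_evidence(units, seeds_df(s))
  expect_equal(nrow(net), 1L)
  expect_equal(net$Method.Score, 2L)
  expect_equal(net$Method, "Affinity Purification (AP);Two Hybrid (2Hyb)")
  expect_equal(net$Publication.Score, 2L)
  expect_equal(net$PMIDS, "111;222")
  expect_equal(net$Final.Score, 4L)
})

test_that("pairs touching no seed are excluded; seed-seed pairs emitted once", {
  s1 <- tri("PINK1", "Q9BXM7", "65018")
  s2 <- tri("PRKN", "O60260", "5071")
  x <- tri("CYCS", "P99999", "54205")
  y <- tri("SNCA", "P37840", "6622")
  units <- rbind(
    make_unit(s1, s2, "Two Hybrid (2Hyb)", "111"),
    make_unit(s2, s1, "Two Hybrid (2Hyb)", "222", line_no = 2L),
    make_unit(x, y, "Two Hybrid (2Hyb)", "333", line_no = 3L)  # no seed
  )
  net <- aggregate_evidence(units, seeds_df(s1, s2))
  expect_equal(nrow(net), 1L)
  expect_equal(net$NameA, "PINK1")  # lexicographically earlier seed name
  expect_equal(net$NameB, "PRKN")
  expect_equal(net$Publication.Score, 2L)
})

test_that("duplicating the entire unit list leaves scores unchanged", {
  fx <- make_fixture(n_records = 100, rng_seed = 606)
  records <- do.call(rbind, lapply(fx$manifest$seeds$symbol, function(seed) {
    fetch_seed_records(seed, offline_root = fx$dir)$records
  }))
  units <- filter_batch(records, "human", fx$method_table, fx$mapping)$units
  seeds <- fx$manifest$seeds
  names(seeds) <- c("gene_name", "swiss", "entrez")
  once <- aggregate_evidence(units, seeds)
  twice <- aggregate_evidence(rbind(units, units), seeds)
  expect_identical(once, twice)
})

test_that("adding evidence never decreases any score (monotonicity)", {
  s <- tri("SNCA", "P37840", "6622")
  x <- tri("CYCS", "P99999", "54205")
  set.seed(77)
  units <- make_unit(s, x, "Two Hybrid (2Hyb)", "111")
  prev <- aggregate_evidence(units, seeds_df(s))
  for (i in 1:20) {
    extra <- make_unit(s, x, sample(c("Two Hybrid (2Hyb)", "AP", "Struct", "Img"), 1),
                       sample(as.character(100:105), 1), line_no = i + 1L)
    units <- rbind(units, extra)
    cur <- aggregate_evidence(units, seeds_df(s))
    expect_gte(cur$Method.Score, prev$Method.Score)
    expect_gte(cur$Publication.Score, prev$Publication.Score)
    expect_gte(cur$Final.Score, prev$Final.Score)
    prev <- cur
  }
})

test_that("scores equal a naive brute-force recount on random unit sets", {
  set.seed(888)
  pool <- lapply(1:20, function(i) tri(sprintf("G%02d", i), sprintf("P%05d", 40000 + i),
                                       as.character(40000 + i)))
  units <- do.call(rbind, lapply(1:200, function(i) {
    ab <- sample(20, 2, replace = TRUE)
    make_unit(pool[[ab[1]]], pool[[ab[2]]],
              sample(c("2Hyb", "AP", "Struct", "PCA"), 1),
              as.character(sample(100:110, 1)), line_no = i)
  }))
  seeds <- do.call(rbind, lapply(pool, function(t) seeds_df(t)))  # all are seeds
  net <- aggregate_evidence(units, seeds)
  oracle <- brute_scores(units)
  expect_equal(nrow(net), nrow(oracle))
  for (i in seq_len(nrow(net))) {
    lo <- min(net$SwissA[i], net$SwissB[i])
    hi <- max(net$SwissA[i], net$SwissB[i])
    o <- oracle[oracle$swiss_lo == lo & oracle$swiss_hi == hi, ]
    expect_equal(net$Method.Score[i], o$ms)
    expect_equal(net$Publication.Score[i], o$ps)
    expect_equal(net$Final.Score[i], o$fs)
  }
})

test_that("score threshold enforces the floor and filters correctly", {
  s <- tri("SNCA", "P37840", "6622")
  x <- tri("CYCS", "P99999", "54205")
  y <- tri("PINK1", "Q9BXM7", "65018")
  units <- rbind(
    make_unit(s, x, "2Hyb", "111"),
    make_unit(s, y, "2Hyb", "111", line_no = 2L),
    make_unit(s, y, "AP", "222", line_no = 3L)
  )
  net <- aggregate_evidence(units, seeds_df(s))
  expect_identical(score_threshold(net, 2), net)       # floor is a no-op
  expect_equal(score_threshold(net, 3)$NameB, "PINK1") # removes the 1x1 pair
  expect_equal(nrow(score_threshold(net, 10)), 0L)
  expect_error(score_threshold(net, 1), "unattainable")
})
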