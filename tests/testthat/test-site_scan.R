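test_that("seed matches are located left to right with overlaps allowed", {
  fx <- tiny_fixture()
  trf <- fx$trfs[1, ]  # seed GGUUCG -> rc CGAACC
  s <- scan_seed_matches(trf, "AAACGAACCAAA", "tx")
  expect_equal(nrow(s), 1)
  expect_equal(c(s$start, s$end), c(3, 9))
  expect_equal(s$dist5, 3)
  expect_equal(s$dist3, 3)
  expect_equal(s$dist_nearest, 3)

  expect_equal(nrow(scan_seed_matches(trf, "AAAAAAAAAAAA", "tx")), 0)

  # overlapping motif occurrences are all reported
  trf2 <- trf_catalog("t", "AGGUUCGGUUCGAA", "tRF-3")[1, ]  # seed GGUUCG
  s2 <- scan_seed_matches(trf2, "CGAACCGAACC", "tx")
  expect_equal(s2$start, c(0, 5))
})

test_that("scan agrees with a naive sliding-window oracle on random inputs", {
  set.seed(21)
  for (i in 1:40) {
    trf <- trf_catalog("t", random_rna(sample(14:31, 1)), "tRF-3")[1, ]
    utr <- random_rna(sample(20:400, 1), gc = runif(1, 0.3, 0.7))
    s <- scan_seed_matches(trf, utr, "tx")
    expect_equal(s$start, oracle_scan(utr, reverse_complement(trf$seed)))
  }
})

test_that("site typing flags follow the flanking bases and UTR edges", {
  # tRF with pos1 = U, pos8 = A; seed positions 2-7 = GGUUCG
  trf <- trf_catalog("t", "UGGUUCGAGUCCAAGG", "tRF-3")[1, ]
  expect_equal(trf$seed, "GGUUCG")
  # UTR: U | CGAACC | A  -> pos8 (U~A) true, pos1 (A~U) true, pos1A true
  s <- scan_seed_matches(trf, "UCGAACCA", "tx")
  expect_true(s$pos8_match)
  expect_true(s$pos1_match)
  expect_true(s$pos1A)
  # site at offset 0: no upstream base
  s2 <- scan_seed_matches(trf, "CGAACCA", "tx")
  expect_false(s2$pos8_match)
  # 3'-adjacent G: neither pos1 match (G !~ U) nor pos1A
  s3 <- scan_seed_matches(trf, "UCGAACCG", "tx")
  expect_false(s3$pos1_match)
  expect_false(s3$pos1A)
  # site at the UTR 3' edge: downstream flags false
  s4 <- scan_seed_matches(trf, "UCGAACC", "tx")
  expect_false(s4$pos1_match)
  expect_false(s4$pos1A)
})

test_that("3'-UTR isoform selection prefers tags, then length, then order", {
  iso <- data.frame(transcript_id = "NM_1",
                    utr3 = c(strrep("A", 200), strrep("C", 300)),
                    tag_count = c(10, 3), stringsAsFactors = FALSE)
  expect_equal(select_utr_isoform(iso)$tag_count, 10)
  iso$tag_count <- c(5, 5)
  expect_equal(nchar(select_utr_isoform(iso)$utr3), 300)
  iso2 <- data.frame(transcript_id = "NM_1", utr3 = "ACGUACGU",
                     stringsAsFactors = FALSE)
  sel <- select_utr_isoform(iso2)
  expect_equal(sel$utr3, "ACGUACGU")
})

test_that("background excludes every transcript hosting a positive pair", {
  fx <- tiny_fixture()
  # positive on NM_000001; NM_000002 carries trf_b's match
  positives <- data.frame(trf_id = "trf_a", transcript_id = "NM_000001",
                          start = 40, end = 46, stringsAsFactors = FALSE)
  bg <- build_background(fx$trfs, fx$transcripts, positives)
  expect_false("NM_000001" %in% bg$transcript_id)
  expect_true(all(bg$label == "background"))
  # set-difference oracle: whole-set scan minus positive-transcript sites
  all_sites <- 0
  excl_sites <- 0
  for (i in seq_len(nrow(fx$trfs))) {
    for (j in seq_len(nrow(fx$transcripts))) {
      n <- nrow(scan_seed_matches(fx$trfs[i, ], fx$transcripts$utr3[j], "x"))
      all_sites <- all_sites + n
      if (fx$transcripts$transcript_id[j] %in% positives$transcript_id) {
        excl_sites <- excl_sites + n
      }
    }
  }
  expect_equal(nrow(bg), all_sites - excl_sites)
})
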