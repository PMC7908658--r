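test_that("chimeric reads decompose into an exact catalog tRF plus fragment", {
  fx <- tiny_fixture()
  trf <- fx$trfs[1, ]
  frag <- "CGAACCAAAGG"
  d <- decompose_read("r1", paste0(trf$sequence, frag), fx$trfs)
  expect_null(d$reason)
  expect_equal(d$trf_id, "trf_a")
  expect_equal(d$orientation, "trf_first")
  expect_equal(d$target_fragment, frag)
  expect_equal(c(d$trf_start, d$trf_end), c(0, nchar(trf$sequence)))

  d2 <- decompose_read("r2", paste0(frag, trf$sequence), fx$trfs)
  expect_equal(d2$orientation, "trf_last")
  expect_equal(d2$target_fragment, frag)

  # one internal substitution breaks the exact-match rule
  mut <- trf$sequence
  substr(mut, 9, 9) <- if (substr(mut, 9, 9) == "A") "C" else "A"
  d3 <- decompose_read("r3", paste0(mut, frag), fx$trfs)
  expect_equal(d3$reason, "no_trf_match")

  # read shorter than any catalog tRF
  d4 <- decompose_read("r4", "ACGUACGUACGU", fx$trfs)
  expect_equal(d4$reason, "no_trf_match")

  # fragment below 6 nt
  d5 <- decompose_read("r5", paste0(trf$sequence, "ACGUA"), fx$trfs)
  expect_equal(d5$reason, "fragment_too_short")
})

test_that("ambiguous reads with two distinct equal-length tRF matches are rejected", {
  set.seed(9)
  a <- random_rna(18)
  b <- random_rna(18)
  trfs <- trf_catalog(c("t1", "t2"), c(a, b), "tRF-3")
  read <- paste0(a, "ACGUACGUAC", b)  # t1 prefix and t2 suffix, same length
  d <- decompose_read("amb", read, trfs)
  expect_equal(d$reason, "ambiguous")
})

test_that("target fragments map to all exact 3'-UTR occurrences", {
  fx <- tiny_fixture()
  hit <- map_target_fragment("CGAACC", fx$transcripts)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$transcript_id, "NM_000001")
  expect_equal(substr(fx$transcripts$utr3[1], hit$frag_start + 1,
                      hit$frag_end), "CGAACC")
  expect_false(hit$multi_mapping[1])
  # absent fragment
  expect_equal(nrow(map_target_fragment("GGGGGGGG", fx$transcripts)), 0)
  # fragment present in two UTRs is flagged
  tx <- fx$transcripts
  tx$utr3[3] <- paste0(tx$utr3[3], "CGAACC")
  hit2 <- map_target_fragment("CGAACC", tx)
  expect_equal(nrow(hit2), 2)
  expect_true(all(hit2$multi_mapping))
})

test_that("interaction pairs require a perfect seed match inside the fragment", {
  fx <- tiny_fixture()
  trf <- fx$trfs[1, ]  # seed GGUUCG, match CGAACC
  reads <- c(r1 = paste0(trf$sequence, "AGCUAGCUCGAACCUUACUUAC"))
  # r1 fragment occurs in NM_000001's UTR? build a transcript holding it
  tx <- fx$transcripts
  tx$utr3[1] <- paste0("ACGU", "AGCUAGCUCGAACCUUACUUAC", "GGAC")
  dec <- decompose_reads(reads, fx$trfs)
  pairs <- build_interaction_pairs(dec$decompositions, tx, fx$trfs)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$label, "positive")
  expect_equal(substr(tx$utr3[1], pairs$start + 1, pairs$end),
               "CGAACC")

  # 5/6 seed complementarity is dropped
  tx$utr3[1] <- paste0("ACGU", "AGCUAGCUCGAUCCUUACUUAC", "GGAC")
  reads2 <- c(r1 = paste0(trf$sequence, "AGCUAGCUCGAUCCUUACUUAC"))
  dec2 <- decompose_reads(reads2, fx$trfs)
  pairs2 <- build_interaction_pairs(dec2$decompositions, tx, fx$trfs)
  expect_equal(nrow(pairs2), 0)

  # duplicate reads collapse to one pair
  tx$utr3[1] <- paste0("ACGU", "AGCUAGCUCGAACCUUACUUAC", "GGAC")
  reads3 <- c(r1 = paste0(trf$sequence, "AGCUAGCUCGAACCUUACUUAC"),
              r2 = paste0(trf$sequence, "AGCUAGCUCGAACCUUACUUAC"))
  dec3 <- decompose_reads(reads3, fx$trfs)
  pairs3 <- build_interaction_pairs(dec3$decompositions, tx, fx$trfs)
  expect_equal(nrow(pairs3), 1)
})

test_that("duplicate collapser keeps the first read id per sequence", {
  reads <- c(a = "ACGUACGUACGUACGUACGU", b = "ACGUACGUACGUACGUACGU",
             c = "GGGGCCCCAAAAUUUUGGCC")
  out <- collapse_duplicates(reads)
  expect_equal(names(out), c("a", "c"))
})
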