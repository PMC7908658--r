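test_that("distance-weighted AU score sums 1/d over A/U positions", {
  expect_equal(flank_au_score("GGGG"), 0)
  expect_equal(flank_au_score("AU"), 1.5)
  expect_equal(flank_au_score(strrep("A", 35)), sum(1 / (1:35)))
  expect_equal(flank_au_score(strrep("A", 35), exclude_first = 10),
               sum(1 / (11:35)))
  expect_equal(flank_au_score(""), 0)
})

test_that("AU score is monotone when a G/C becomes A/U", {
  set.seed(31)
  for (i in 1:25) {
    w <- random_rna(sample(5:35, 1))
    gcpos <- which(strsplit(w, "")[[1]] %in% c("G", "C"))
    if (length(gcpos) == 0) next
    p <- if (length(gcpos) == 1) gcpos else sample(gcpos, 1)
    w2 <- w
    substr(w2, p, p) <- "A"
    expect_gte(flank_au_score(w2), flank_au_score(w))
  }
})

test_that("window composition fractions normalize and handle empty windows", {
  wc <- window_composition("AAAA")
  expect_equal(unname(wc$base["A"]), 1)
  expect_equal(unname(wc$dinuc["AA"]), 1)
  expect_equal(wc$gc, 0)
  wc2 <- window_composition("ACGU")
  expect_equal(unname(wc2$base), rep(0.25, 4))
  expect_equal(wc2$gc, 50)
  set.seed(41)
  for (i in 1:10) {
    wc3 <- window_composition(random_rna(sample(10:80, 1)))
    expect_equal(sum(wc3$base), 1, tolerance = 1e-9)
    expect_equal(sum(wc3$dinuc), 1, tolerance = 1e-9)
  }
  wc4 <- window_composition("")
  expect_true(all(is.na(wc4$base)))
  expect_true(is.na(wc4$gc))
})

test_that("site features cover the registry roster and flag edges", {
  fx <- tiny_fixture()
  trf <- fx$trfs[1, ]
  utr <- fx$transcripts$utr3[1]
  st <- find_site <- scan_seed_matches(trf, utr, "NM_000001")
  sf <- site_features(trf, utr, st$start, st$end)
  reg <- feature_registry()
  expect_setequal(names(sf), reg$name[reg$family == "site_sequence"])
  expect_true(all(sf[c("pos8_match", "pos1_match", "pos1A")] %in% 0:1))
  expect_equal(unname(sf["dist5"]), st$start)
  # all-GC flanks: AU scores 0, flank GC 100
  utr_gc <- paste0(strrep("GC", 20), "CGAACC", strrep("CG", 10))
  sf2 <- site_features(trf, utr_gc, 40, 46)
  expect_equal(unname(sf2["sau_up35"]), 0)
  expect_equal(unname(sf2["gc_up35"]), 100)
  # truncated upstream at the 5' edge still computes
  sf3 <- site_features(trf, paste0("AU", "CGAACC", strrep("A", 20)), 2, 8)
  expect_equal(unname(sf3["sau_up35"]), 1.5)  # U at d=1, A at d=2
  expect_error(site_features(trf, utr, -1, 5), "outside")
})

test_that("transcript features report per-kb seed-match frequency", {
  fx <- tiny_fixture()
  trf <- fx$trfs[1, ]  # match CGAACC
  tx <- data.frame(transcript_id = "t", gene_symbol = "g",
                   utr5 = "", cds = "AUGUAA",
                   utr3 = paste0(strrep("A", 497), "CGAACC",
                                 strrep("A", 497)),
                   stringsAsFactors = FALSE)
  tf <- transcript_features(trf, tx[1, ])
  expect_equal(unname(tf["seedfreq_utr3"]), 1.0)  # 1 match per 1000 nt
  expect_equal(unname(tf["len_utr3"]), 1000)
  expect_true(is.na(tf["len_utr5"]))  # empty region flagged missing
  expect_true(is.na(tf["seedfreq_utr5"]))
  tx$utr3 <- strrep("AU", 100)
  expect_equal(unname(transcript_features(trf, tx[1, ])["gc_utr3"]), 0)
})

test_that("tRF features include target abundance summed over UTRs", {
  trfs <- trf_catalog("t", "GCCGGCGCCGGCGCGGCC", "tRF-3")
  trf <- trfs[1, ]  # all G/C
  expect_equal(unname(trf_features(trf, tiny_fixture()$transcripts)[
    c("trf_length", "trf_gc", "seed_gc")]), c(18, 100, 100))
  # summation oracle
  fx <- tiny_fixture()
  motif <- reverse_complement(fx$trfs$seed[1])
  per_utr <- vapply(fx$transcripts$utr3,
                    function(u) length(oracle_scan(u, motif)), integer(1))
  tf <- trf_features(fx$trfs[1, ], fx$transcripts)
  expect_equal(unname(tf["ta_utr3"]), sum(per_utr))
  expect_true(is.na(tf["ta_genome"]))
  tf2 <- trf_features(fx$trfs[1, ], fx$transcripts,
                      genome = c(chr1 = paste0("AAA", motif, "CCC", motif)))
  expect_equal(unname(tf2["ta_genome"]), 2)
})

test_that("feature assembly is deterministic with one registry row per pair", {
  fx <- tiny_fixture()
  pairs <- rbind(
    scan_seed_matches(fx$trfs[1, ], fx$transcripts$utr3[1], "NM_000001"),
    scan_seed_matches(fx$trfs[2, ], fx$transcripts$utr3[2], "NM_000002"))
  fm <- assemble_feature_matrix(pairs, fx$trfs, fx$transcripts)
  expect_equal(nrow(fm$matrix), nrow(pairs))
  expect_equal(ncol(fm$matrix), nrow(fm$registry))
  expect_equal(colnames(fm$matrix), fm$registry$name)
  fm2 <- assemble_feature_matrix(pairs, fx$trfs, fx$transcripts)
  expect_identical(fm$matrix, fm2$matrix)
  # identical pairs give identical rows
  fm3 <- assemble_feature_matrix(pairs[c(1, 1), ], fx$trfs, fx$transcripts)
  expect_identical(fm3$matrix[1, ], fm3$matrix[2, ])
})
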