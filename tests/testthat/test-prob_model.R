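test_that("Markov background reproduces empirical base and transition frequencies", {
  bg <- fit_markov_background("AAAA")
  expect_equal(unname(bg$initial["A"]), 1)
  expect_equal(bg$transition["A", "A"], 1)
  # deterministic cycle ACGUACGU...
  suppressMessages(bg2 <- fit_markov_background(strrep("ACGU", 10)))
  expect_equal(bg2$transition["A", "C"], 1)
  expect_equal(bg2$transition["C", "G"], 1)
  expect_equal(bg2$transition["G", "U"], 1)
  expect_equal(bg2$transition["U", "A"], 1)
  # rows sum to one on random sequences
  set.seed(23)
  for (i in 1:10) {
    b <- suppressMessages(fit_markov_background(random_rna(sample(50:500, 1))))
    expect_equal(unname(rowSums(b$transition)), rep(1, 4), tolerance = 1e-12)
    expect_equal(sum(b$initial), 1, tolerance = 1e-12)
  }
  expect_error(fit_markov_background("A"), "too short")
})

test_that("seed-match probability is the order-1 chain product", {
  bg <- fit_markov_background(strrep("A", 50))
  expect_equal(seed_match_probability(bg, "AAAAAA"), 1)
  bg2 <- suppressMessages(fit_markov_background(strrep("ACGU", 25)))
  expect_equal(seed_match_probability(bg2, "ACGUAC"), 0.25)
  # chain normalization: sum over all 4^6 motifs is 1
  set.seed(29)
  bg3 <- suppressMessages(fit_markov_background(random_rna(300)))
  motifs <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")), 6)))
  tot <- sum(vapply(motifs, function(m) seed_match_probability(bg3, m),
                    numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("binomial overrepresentation matches direct term summation", {
  expect_equal(binomial_enrichment(P = 0.3, l = 50, f = 0), 1)
  expect_equal(binomial_enrichment(P = 0, l = 50, f = 1), 0)
  expect_equal(binomial_enrichment(P = 0.2, l = 10, f = 2), 0.26272)
  # direct-summation oracle to 1e-12
  set.seed(31)
  for (i in 1:50) {
    P <- runif(1, 0.01, 0.5)
    l <- sample(10:500, 1)
    n <- l - 5L
    f <- sample(0:min(n, 10), 1)
    direct <- sum(choose(n, f:n) * P^(f:n) * (1 - P)^(n - (f:n)))
    expect_equal(binomial_enrichment(P, l, f), direct, tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(0.2, l = 10, f = 6), "exceeds")
})

test_that("Ps is non-increasing in the observed count", {
  set.seed(37)
  for (i in 1:10) {
    P <- runif(1, 0.05, 0.4)
    l <- sample(20:200, 1)
    fmax <- min(l - 5L, 12L)
    ps <- vapply(0:fmax, function(f) binomial_enrichment(P, l, f),
                 numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(41)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in the raw ranking
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("enrichment table recovers implanted overrepresentation", {
  set.seed(43)
  trfs <- trf_catalog("t1", random_rna(18), "tRF-3")
  motif <- reverse_complement(trfs$seed[1])
  n_tx <- 24
  utr <- vapply(seq_len(n_tx), function(i) random_rna(400), character(1))
  # implant 5 extra copies of the motif in the first 8 transcripts
  for (i in 1:8) {
    for (s in seq(20, 380, by = 75)) {
      substr(utr[i], s, s + 5) <- motif
    }
  }
  tx <- data.frame(transcript_id = sprintf("NM_%03d", seq_len(n_tx)),
                   gene_symbol = "g", utr5 = "", cds = "",
                   utr3 = utr, stringsAsFactors = FALSE)
  en <- suppressMessages(enrichment_table(trfs, tx))
  expect_equal(nrow(en), n_tx)
  expect_true(all(en$Ps >= 0 & en$Ps <= 1))
  expect_true(all(en$ps_adjusted >= en$Ps - 1e-15))
  implanted <- en$transcript_id %in% sprintf("NM_%03d", 1:8)
  expect_lt(median(en$ps_adjusted[implanted]),
            median(en$ps_adjusted[!implanted]))
  ranked <- rank_overrepresented(en, fdr_cutoff = 0.05)
  expect_true(all(diff(ranked$ps_adjusted) >= 0))
  expect_true(all(ranked$fdr_flag == (ranked$ps_adjusted < 0.05)))
})

test_that("binomial tail agrees with Monte-Carlo frequency within 3 SE", {
  set.seed(47)
  n_draws <- 1e5
  for (i in 1:12) {
    P <- runif(1, 0.05, 0.4)
    l <- sample(15:80, 1)
    n <- l - 5L
    f <- sample(1:max(1, round(n * P)), 1)
    ps <- binomial_enrichment(P, l, f)
    x <- rbinom(n_draws, n, P)
    freq <- mean(x >= f)
    se <- sqrt(max(ps * (1 - ps), 1e-12) / n_draws)
    expect_lte(abs(ps - freq), 3 * se + 1e-4)
  }
})
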