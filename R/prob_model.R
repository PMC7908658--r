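# Independent probabilistic predictor: an order-1 Markov background gives
# the per-position probability of a seed match; a binomial upper tail tests
# whether the observed seed-match count in a 3'-UTR is overrepresented;
# Benjamini-Hochberg adjustment controls the FDR across all tested pairs.

#' Fit an order-1 Markov background to a sequence
#'
#' Initial distribution = empirical base frequencies; transition matrix =
#' empirical conditional frequencies. A base never observed as a
#' transition source gets a uniform fallback row (logged via message).
#' N positions are dropped before fitting.
#'
#' @param seq Residue string, length >= 2 after N removal.
#' @return List: \code{initial} (named length-4 probability vector),
#'   \code{transition} (4x4 row-stochastic matrix).
#' @export
fit_markov_background <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  vn <- v[v != "N"]
  if (length(vn) < 2L) stop("sequence too short to fit a Markov background")
  initial <- vapply(RNA_BASES, function(b) mean(vn == b), numeric(1L))
  trans <- matrix(0, 4L, 4L, dimnames = list(RNA_BASES, RNA_BASES))
  from <- v[-length(v)]
  to <- v[-1L]
  ok <- from != "N" & to != "N"  # no transition spans an N (or a pooling gap)
  from <- from[ok]
  to <- to[ok]
  for (b in RNA_BASES) {
    sel <- from == b
    if (!any(sel)) {
      message("no transitions observed from ", b, "; uniform fallback row")
      trans[b, ] <- 0.25
    } else {
      trans[b, ] <- vapply(RNA_BASES, function(d) mean(to[sel] == d),
                           numeric(1L))
    }
  }
  list(initial = initial, transition = trans)
}

#' Fit a pooled Markov background over several sequences
#'
#' Counts are pooled across sequences (no transition spans a sequence
#' boundary); used for the transcriptome-wide background option.
#'
#' @param seqs Character vector of residue strings.
#' @return As \code{\link{fit_markov_background}}.
#' @export
fit_markov_background_pooled <- function(seqs) {
  fit_markov_background(paste(seqs, collapse = "N"))
}

#' Probability of one seed-match occurrence under the background
#'
#' Chain product P = initial(m1) * prod transition(m_i -> m_{i+1}) for the
#' 6-mer motif; sums to 1 over all 4^6 motifs.
#'
#' @param bg Markov background.
#' @param motif 6-mer residue string.
#' @return Probability in \[0, 1\].
#' @export
seed_match_probability <- function(bg, motif) {
  stopifnot(nchar(motif) == 6L)
  v <- strsplit(motif, "", fixed = TRUE)[[1L]]
  stopifnot(all(v %in% RNA_BASES))
  p <- bg$initial[v[1L]]
  for (i in 1:5) p <- p * bg$transition[v[i], v[i + 1L]]
  unname(p)
}

#' Binomial overrepresentation of seed matches in a target sequence
#'
#' Upper-tail probability of observing at least \code{f} seed matches in
#' \code{l - k + 1} candidate positions when each position carries a match
#' with probability \code{P}:
#' Ps = sum_{i=f}^{l-k+1} C(l-k+1, i) P^i (1-P)^(l-k+1-i).
#' Computed with the regularized incomplete beta (stable in log space for
#' large l), exact for f = 0 (Ps = 1).
#'
#' @param P Per-position seed-match probability.
#' @param l Target sequence length (nt), l >= k.
#' @param f Observed seed-match count (all occurrences, overlaps included).
#' @param k Seed length (default 6).
#' @return Ps in \[0, 1\].
#' @export
#' @examples
#' binomial_enrichment(P = 0.2, l = 10, f = 2)  # 0.26272
binomial_enrichment <- function(P, l, f, k = 6L) {
  stopifnot(P >= 0, P <= 1, l >= k, f >= 0)
  n <- l - k + 1L
  if (f > n) stop("observed count exceeds the number of candidate positions")
  if (f == 0L) return(1)
  pbinom(f - 1L, size = n, prob = P, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; order-preserving,
#' adjusted >= raw, capped at 1.
#'
#' @param ps Numeric vector of raw values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(ps) {
  stopifnot(all(ps >= 0 & ps <= 1, na.rm = TRUE))
  p.adjust(ps, method = "BH")
}

#' Binomial enrichment over all tRF x 3'-UTR pairs
#'
#' For every tRF and transcript: fits the Markov background (per UTR by
#' default, or a pooled transcriptome-wide background), computes the
#' seed-match probability of the tRF's complementary 6-mer, counts
#' observed matches, and evaluates the binomial upper tail. Adjusted
#' values cover the whole tested family.
#'
#' @param trfs tRF catalog.
#' @param transcripts Transcript data.frame.
#' @param background \code{"per_utr"} (default: each UTR's own base
#'   composition) or \code{"pooled"}.
#' @param k Seed length (default 6).
#' @return data.frame \code{trf_id}, \code{transcript_id}, \code{P},
#'   \code{l}, \code{k}, \code{f}, \code{Ps}, \code{ps_adjusted}.
#' @export
enrichment_table <- function(trfs, transcripts,
                             background = c("per_utr", "pooled"), k = 6L) {
  background <- match.arg(background)
  pooled <- if (background == "pooled") {
    fit_markov_background_pooled(transcripts$utr3)
  } else NULL
  rows <- list()
  for (j in seq_len(nrow(transcripts))) {
    utr <- transcripts$utr3[j]
    l <- nchar(utr)
    if (l < k + 1L) next
    bg <- if (is.null(pooled)) fit_markov_background(utr) else pooled
    for (i in seq_len(nrow(trfs))) {
      motif <- reverse_complement(trfs$seed[i])
      P <- seed_match_probability(bg, motif)
      f <- length(find_motif(utr, motif))
      rows[[length(rows) + 1L]] <- data.frame(
        trf_id = trfs$trf_id[i],
        transcript_id = transcripts$transcript_id[j],
        P = P, l = l, k = k, f = f,
        Ps = binomial_enrichment(P, l, f, k),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$ps_adjusted <- bh_adjust(res$Ps)
  res
}

#' Rank pairs by adjusted overrepresentation
#'
#' @param enrich Result of \code{\link{enrichment_table}}.
#' @param fdr_cutoff Flag threshold on the adjusted value (default 0.05).
#' @return \code{enrich} sorted ascending by \code{ps_adjusted} (stable),
#'   with an \code{fdr_flag} column.
#' @export
rank_overrepresented <- function(enrich, fdr_cutoff = 0.05) {
  out <- enrich[order(enrich$ps_adjusted), , drop = FALSE]
  out$fdr_flag <- out$ps_adjusted < fdr_cutoff
  rownames(out) <- NULL
  out
}
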