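# Seed-match discovery in 3'-UTRs, site typing, isoform selection and the
# background site set.

# all 0-based start offsets of exact (possibly overlapping) occurrences of
# `motif` in `s`; matches containing N are excluded
find_motif <- function(s, motif) {
  n <- nchar(s)
  k <- nchar(motif)
  if (n < k) return(integer(0))
  starts <- 0:(n - k)
  hits <- starts[substring(s, starts + 1L, starts + k) == motif]
  if (length(hits) == 0L) return(integer(0))
  hits[!grepl("N", substring(s, hits + 1L, hits + k), fixed = TRUE)]
}

#' Scan a 3'-UTR for perfect seed matches of a tRF
#'
#' A seed match is the 6-mer reverse complement of tRF positions 2-7.
#' All occurrences are reported, overlaps allowed, left to right.
#'
#' @param trf One-row slice of a tRF catalog (see \code{\link{trf_catalog}}).
#' @param utr3 3'-UTR residue string (length >= 6).
#' @param transcript_id Id recorded in the output.
#' @return Site data.frame: \code{trf_id}, \code{transcript_id},
#'   \code{start}, \code{end} (0-based half-open on the UTR),
#'   \code{pos8_match}, \code{pos1_match}, \code{pos1A} (logical),
#'   \code{dist5}, \code{dist3}, \code{dist_nearest} (nt to the UTR ends).
#'   Zero rows when the UTR lacks the 6-mer.
#' @export
#' @examples
#' cat <- trf_catalog("tRF1", "UGGUUCGAGUCCAAUU", "tRF-3")
#' scan_seed_matches(cat[1, ], "AAACGAACCAAA", "NM_1")
scan_seed_matches <- function(trf, utr3, transcript_id) {
  stopifnot(nrow(trf) == 1L)
  if (nchar(utr3) < 6L) return(empty_sites())
  motif <- reverse_complement(trf$seed)
  starts <- find_motif(utr3, motif)
  if (length(starts) == 0L) return(empty_sites())
  flags <- classify_site_type(trf, utr3, starts)
  n <- nchar(utr3)
  data.frame(
    trf_id = trf$trf_id,
    transcript_id = transcript_id,
    start = starts,
    end = starts + 6L,
    pos8_match = flags$pos8_match,
    pos1_match = flags$pos1_match,
    pos1A = flags$pos1A,
    dist5 = starts,
    dist3 = n - (starts + 6L),
    dist_nearest = pmin(starts, n - (starts + 6L)),
    stringsAsFactors = FALSE
  )
}

empty_sites <- function() {
  data.frame(trf_id = character(0), transcript_id = character(0),
             start = integer(0), end = integer(0),
             pos8_match = logical(0), pos1_match = logical(0),
             pos1A = logical(0), dist5 = integer(0), dist3 = integer(0),
             dist_nearest = integer(0), stringsAsFactors = FALSE)
}

#' Type seed-match sites by their flanking bases
#'
#' \code{pos8_match}: the UTR base immediately 5' of the site exists and
#' Watson-Crick complements tRF position 8 (a 7mer-m8-style site).
#' \code{pos1_match}: the UTR base immediately 3' of the site exists and
#' complements tRF position 1. \code{pos1A}: that 3'-adjacent base is A.
#' Sites at a UTR edge get \code{FALSE} for the missing flank.
#'
#' @param trf One-row tRF catalog slice.
#' @param utr3 UTR residue string.
#' @param starts Integer vector of 0-based seed-match start offsets.
#' @return List of three logical vectors.
#' @export
classify_site_type <- function(trf, utr3, starts) {
  n <- nchar(utr3)
  p1 <- substr(trf$sequence, 1L, 1L)
  p8 <- substr(trf$sequence, 8L, 8L)
  up <- ifelse(starts > 0L, substring(utr3, starts, starts), "")
  dn <- ifelse(starts + 6L < n, substring(utr3, starts + 7L, starts + 7L), "")
  list(
    pos8_match = up != "" & wc_complement(up, p8),
    pos1_match = dn != "" & wc_complement(dn, p1),
    pos1A = dn == "A"
  )
}

#' Select the 3'-UTR isoform with the strongest 3P-seq support
#'
#' Among alternative 3'-UTR isoforms of one transcript, keeps the one with
#' the most poly(A)-position profiling (3P-seq) tags; ties go to the longest
#' UTR, remaining ties to input order. Missing tag counts count as 0.
#'
#' @param isoforms data.frame with columns \code{transcript_id}, \code{utr3}
#'   and optionally \code{tag_count}.
#' @return The selected one-row data.frame.
#' @export
select_utr_isoform <- function(isoforms) {
  stopifnot(nrow(isoforms) >= 1L)
  tags <- if ("tag_count" %in% names(isoforms)) {
    ifelse(is.na(isoforms$tag_count), 0, isoforms$tag_count)
  } else {
    rep(0, nrow(isoforms))
  }
  ord <- order(-tags, -nchar(isoforms$utr3), seq_len(nrow(isoforms)))
  isoforms[ord[1L], , drop = FALSE]
}

#' Build the background site set
#'
#' Scans the 3'-UTRs of every transcript that hosts no positive pair (for
#' any tRF) for seed matches of each tRF; every match becomes a background
#' pair. Exclusion is transcript-level: a transcript with one supported
#' site contributes no background sites at all.
#'
#' @param trfs tRF catalog.
#' @param transcripts Transcript data.frame.
#' @param positive_pairs Site data.frame of positives (needs
#'   \code{transcript_id}); may have zero rows.
#' @return Site data.frame with \code{label = "background"}.
#' @export
build_background <- function(trfs, transcripts, positive_pairs) {
  excluded <- unique(positive_pairs$transcript_id)
  keep <- transcripts[!(transcripts$transcript_id %in% excluded), ,
                      drop = FALSE]
  out <- vector("list", nrow(trfs) * nrow(keep))
  idx <- 1L
  for (i in seq_len(nrow(trfs))) {
    for (j in seq_len(nrow(keep))) {
      s <- scan_seed_matches(trfs[i, ], keep$utr3[j], keep$transcript_id[j])
      if (nrow(s) > 0L) {
        out[[idx]] <- s
        idx <- idx + 1L
      }
    }
  }
  res <- do.call(rbind, out[seq_len(idx - 1L)])
  if (is.null(res)) res <- empty_sites()
  if (nrow(res) > 0L) res$label <- "background"
  else res$label <- character(0)
  res
}

#' Write a site table as TSV (1-based inclusive coordinates)
#'
#' @param sites Site data.frame.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  out <- sites
  out$start <- out$start + 1L  # report coordinates are 1-based inclusive
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
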